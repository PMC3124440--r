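#' Accession counts per allele
#'
#' The crude polymorphism estimate starts from counting, for each retained
#' allele, the distinct accessions in which it was observed.
#'
#' @param snv An `snv` object.
#' @return A list with `allele_accessions` (per allele, the character vector
#'   of accessions supporting it, in the snv's allele order) and
#'   `n_accessions_total` (distinct accessions with any observation at the
#'   SNV).
#' @export
accession_counts <- function(snv) {
  sets <- lapply(snv$acc_counts, function(cc) sort(names(cc)[cc > 0]))
  list(allele_accessions = sets,
       n_accessions_total = length(unique(unlist(sets))))
}

#' Frequency of the most common allele, by accession counts
#'
#' @param counts Result of [accession_counts()].
#' @return `max(set sizes) / sum(set sizes)`.
#' @export
most_common_allele_freq <- function(counts) {
  sizes <- lengths(counts$allele_accessions)
  stopifnot(length(sizes) >= 1L, sum(sizes) > 0L)
  max(sizes) / sum(sizes)
}

#' Polymorphic information content
#'
#' Computed by default as expected heterozygosity, `1 - sum(p_i^2)`. The
#' second-order correction of Botstein et al.
#' (`1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`) is available via
#' `method = "botstein"`.
#'
#' @param allele_freqs Numeric allele frequencies, non-negative, summing to 1
#'   (tolerance 1e-9).
#' @param method `"het"` (default) or `"botstein"`.
#' @return PIC value in `[0, 1)`.
#' @examples
#' pic(c(0.5, 0.5))   # 0.5
#' pic(1)             # 0
#' @export
pic <- function(allele_freqs, method = c("het", "botstein")) {
  method <- match.arg(method)
  if (any(allele_freqs < 0)) stop("allele frequencies must be non-negative")
  if (abs(sum(allele_freqs) - 1) > 1e-9) {
    stop("allele frequencies must sum to 1")
  }
  h <- 1 - sum(allele_freqs^2)
  if (method == "het") return(h)
  p2 <- allele_freqs^2
  # sum_{i<j} 2 p_i^2 p_j^2 == (sum p^2)^2 - sum p^4
  h - (sum(p2)^2 - sum(p2^2))
}

#' Set membership criteria
#'
#' @param po_min_accessions Minimum distinct accessions for the PO set.
#' @param po_maf_max Strict upper bound on the most-common-allele frequency
#'   for PO.
#' @param polymorphic_call_max_freq Strict upper bound on the most frequent
#'   allele frequency for a marker to be called polymorphic in a genotyped
#'   panel.
#' @return A `set_criteria` list.
#' @export
set_criteria <- function(po_min_accessions = 6, po_maf_max = 0.67,
                         polymorphic_call_max_freq = 0.95) {
  stopifnot(po_maf_max > 0, po_maf_max <= 1,
            polymorphic_call_max_freq > 0, polymorphic_call_max_freq <= 1)
  structure(list(po_min_accessions = po_min_accessions,
                 po_maf_max = po_maf_max,
                 polymorphic_call_max_freq = polymorphic_call_max_freq),
            class = "set_criteria")
}

variable_on_platform <- function(snv, platform) {
  sum(vapply(snv$plat_counts, function(cc) {
    sum(cc[names(cc) == platform]) > 0
  }, TRUE)) >= 2L
}

#' Classify SNVs into the SA / IL / CO / PO sets
#'
#' An SNV is *variable* on a platform when at least two of its retained
#' alleles have observations from that platform. `SA` marks SNVs variable
#' only among long (Sanger-class) reads, `IL` only among short
#' (Illumina-class) reads, and `CO` (common) those variable on both. `PO`
#' (polymorphic) flags SNVs seen in at least `po_min_accessions` distinct
#' accessions whose most-common-allele frequency (by accession counts, in
#' exact rational arithmetic) is strictly below `po_maf_max`; PO is
#' independent of the SA/IL/CO partition.
#'
#' @param snvs An `snv_set`.
#' @param criteria A [set_criteria()].
#' @return A data.frame with logical columns `SA`, `IL`, `CO`, `PO` plus
#'   `n_accessions` and `mcaf` (most-common-allele frequency), one row per
#'   SNV.
#' @export
classify_sets <- function(snvs, criteria = set_criteria()) {
  rows <- lapply(snvs, function(s) {
    v_long <- variable_on_platform(s, "long")
    v_short <- variable_on_platform(s, "short")
    ac <- accession_counts(s)
    sizes <- lengths(ac$allele_accessions)
    po <- ac$n_accessions_total >= criteria$po_min_accessions &&
      frac_lt(max(sizes), sum(sizes), criteria$po_maf_max)
    data.frame(SA = v_long && !v_short, IL = v_short && !v_long,
               CO = v_long && v_short, PO = po,
               n_accessions = ac$n_accessions_total,
               mcaf = max(sizes) / sum(sizes))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- make.unique(
    vapply(snvs, function(s) paste0(s$unigene, ":", s$pos), ""))
  out
}

#' Is a marker polymorphic in a genotyped panel?
#'
#' @param genotypes Vector of allele calls, one per genotyped accession
#'   (names optional).
#' @param threshold Strict upper bound on the most frequent allele frequency
#'   (default 0.95).
#' @return `TRUE` iff the most frequent allele's frequency is below the
#'   threshold.
#' @export
polymorphic_in_panel <- function(genotypes, threshold = 0.95) {
  stopifnot(length(genotypes) >= 1L)
  counts <- table(genotypes)
  frac_lt(max(counts), sum(counts), threshold)
}

#' Preset marker sets from the filter tag matrix
#'
#' The high-likelihood (HL) set passes the MAF and HVR filters; the easily
#' usable (EU) set additionally passes UCR, I30 and CL.
#'
#' @param tags Logical tag matrix from [snv_tags()].
#' @return A data.frame with logical columns `HL` and `EU`.
#' @export
marker_sets <- function(tags) {
  need <- function(cols) {
    missing <- setdiff(cols, colnames(tags))
    if (length(missing)) {
      abort_missing_input("tag matrix lacks filter(s): ",
                          paste(missing, collapse = ", "))
    }
    rowSums(!tags[, cols, drop = FALSE]) == 0L
  }
  data.frame(HL = need(c("MAF", "HVR")),
             EU = need(c("MAF", "HVR", "UCR", "I30", "CL")),
             row.names = rownames(tags))
}

#' Per-SNV summary table
#'
#' One row per SNV: location, alleles, accession counting summary, PIC
#' (accession-count based allele frequencies), SA/IL/CO/PO flags and the
#' filter tags.
#'
#' @param snvs An `snv_set`.
#' @param criteria A [set_criteria()].
#' @return A data.frame.
#' @export
snv_table <- function(snvs, criteria = set_criteria()) {
  if (!length(snvs)) {
    return(data.frame(unigene = character(0), pos = integer(0),
                      kind = character(0), alleles = character(0)))
  }
  sets <- classify_sets(snvs, criteria)
  base <- do.call(rbind, lapply(snvs, function(s) {
    ac <- accession_counts(s)
    sizes <- lengths(ac$allele_accessions)
    freqs <- sizes / sum(sizes)
    data.frame(
      unigene = s$unigene, pos = s$pos, kind = s$kind,
      alleles = paste(paste0(substr(s$alleles$kind, 1, 1), ":",
                             s$alleles$seq), collapse = ","),
      n_alleles = nrow(s$alleles),
      pic = pic(freqs))
  }))
  tags <- snv_tags(snvs)
  out <- cbind(base, sets[, c("n_accessions", "mcaf", "SA", "IL", "CO", "PO")])
  if (ncol(tags)) out <- cbind(out, as.data.frame(tags))
  rownames(out) <- NULL
  out
}
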