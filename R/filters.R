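#' Marker-selection filter configuration
#'
#' Thresholds and label sets for the nine SNV selection filters. Defaults are
#' the standard pass conditions: most-frequent-allele frequency in the pool
#' `< 0.80` (MAF), unigene divergence `<= 4`% (HVR), no similarity hit (UCR),
#' distance to intron/exon boundary `> 30` (I30), distance to unigene ends
#' `> 30` (CL), distance to the nearest other SNV `> 60` (CS), a differential
#' restriction site within the flanks (CEF), marker kind (VK), and
#' most-frequent-allele frequency in the selected libraries `< 0.67` (GF).
#' Frequency comparisons are performed in exact rational arithmetic, so e.g.
#' an allele seen in 2 of 3 reads passes GF (2/3 < 0.67).
#'
#' @param maf_max Pool most-frequent-allele frequency bound (strict `<`).
#' @param hvr_max_pct Unigene divergence bound in percent (inclusive `<=`).
#' @param i30_min_dist Minimum intron/exon boundary distance (strict `>`).
#' @param cl_min_dist Minimum distance to unigene ends (strict `>`).
#' @param cs_min_dist Minimum distance to a neighboring SNV (strict `>`).
#' @param gf_max Library most-frequent-allele frequency bound (strict `<`).
#' @param vk_kind `"snp"`, `"indel"` or `"any"`.
#' @param maf_pool Accession labels forming the MAF pool; empty = all.
#' @param gf_libraries Library labels for GF; empty = all.
#' @param enzymes Restriction enzyme table (data.frame `name`, `site`);
#'   defaults to the table shipped with the package.
#' @param flank_len Bases of flanking sequence per side for CEF.
#' @return A `filter_config` list.
#' @export
filter_config <- function(maf_max = 0.80, hvr_max_pct = 4, i30_min_dist = 30,
                          cl_min_dist = 30, cs_min_dist = 60, gf_max = 0.67,
                          vk_kind = c("snp", "indel", "any"),
                          maf_pool = character(0), gf_libraries = character(0),
                          enzymes = NULL, flank_len = 60) {
  vk_kind <- match.arg(vk_kind)
  stopifnot(maf_max > 0, maf_max <= 1, gf_max > 0, gf_max <= 1,
            i30_min_dist >= 0, cl_min_dist >= 0, cs_min_dist >= 0,
            flank_len >= 0)
  if (is.null(enzymes)) enzymes <- default_enzymes()
  structure(list(maf_max = maf_max, hvr_max_pct = hvr_max_pct,
                 i30_min_dist = i30_min_dist, cl_min_dist = cl_min_dist,
                 cs_min_dist = cs_min_dist, gf_max = gf_max, vk_kind = vk_kind,
                 maf_pool = maf_pool, gf_libraries = gf_libraries,
                 enzymes = enzymes, flank_len = flank_len),
            class = "filter_config")
}

#' Restriction enzyme table shipped with the package
#'
#' Common 4-6 bp cutters with IUPAC recognition sites, read from
#' `inst/extdata/restriction_enzymes.tsv`. Users can supply their own
#' two-column (`name`, `site`) table instead.
#'
#' @param path Optional path to an alternative tab-delimited enzyme table.
#' @return A data.frame with columns `name` and `site`.
#' @export
default_enzymes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "restriction_enzymes.tsv",
                        package = "snvmine", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           col.names = c("name", "site"))
  tab$site <- toupper(tab$site)
  bad <- nchar(tab$site) < 4L | grepl("[^ACGTRYSWKMBDHVN]", tab$site)
  if (any(bad)) {
    abort_format("invalid enzyme recognition site(s): ",
                 paste(tab$name[bad], collapse = ", "))
  }
  tab
}

#' Per-unigene annotation context for the filters
#'
#' Collects the per-unigene facts the positional filters read: sequence and
#' length, the positions of all called SNVs, intron/exon boundaries from a
#' GFF3 annotation (start/end of `intron`/`exon` features projected to
#' 0-based unigene coordinates), and the similarity flag from a two-column
#' unigene-similarity report (a precomputed stand-in for a BLAST
#' self-comparison). Unigenes absent from the similarity report are treated
#' as having no hit, with a warning.
#'
#' @param reference `DNAStringSet` of unigenes.
#' @param snvs `snv_set` (or list of `snv`) whose positions populate
#'   `snv_positions`.
#' @param gff_path Optional GFF3 path with intron/exon features.
#' @param similarity_path Optional tab-delimited similarity report
#'   (`unigene_id`, `flag` 0/1).
#' @return Named list of `unigene_context` lists (fields: `unigene_id`,
#'   `length`, `sequence`, `snv_positions`, `intron_boundaries`,
#'   `has_similarity_hit`, plus `has_gff`/`has_similarity` availability
#'   flags).
#' @export
build_contexts <- function(reference, snvs = list(), gff_path = NULL,
                           similarity_path = NULL) {
  names(reference) <- sub("\\s.*$", "", names(reference))
  ids <- names(reference)
  uni <- vapply(snvs, `[[`, "", "unigene")
  pos <- vapply(snvs, `[[`, 0L, "pos")
  boundaries <- stats::setNames(rep(list(integer(0)), length(ids)), ids)
  has_gff <- !is.null(gff_path)
  if (has_gff) {
    if (!file.exists(gff_path)) {
      abort_missing_input("GFF file not found: ", gff_path)
    }
    gff <- as.data.frame(rtracklayer::readGFF(gff_path))
    gff <- gff[tolower(gff$type) %in% c("intron", "exon"), , drop = FALSE]
    for (i in seq_len(nrow(gff))) {
      id <- as.character(gff$seqid[i])
      if (!id %in% ids) next
      boundaries[[id]] <- sort(unique(c(boundaries[[id]],
                                        gff$start[i] - 1L, gff$end[i] - 1L)))
    }
  }
  flags <- stats::setNames(rep(FALSE, length(ids)), ids)
  has_similarity <- !is.null(similarity_path)
  if (has_similarity) {
    if (!file.exists(similarity_path)) {
      abort_missing_input("similarity report not found: ", similarity_path)
    }
    rep_tab <- utils::read.delim(similarity_path, stringsAsFactors = FALSE,
                                 col.names = c("unigene_id", "flag"))
    missing <- setdiff(ids, rep_tab$unigene_id)
    if (length(missing)) {
      warning(length(missing), " unigene(s) absent from the similarity ",
              "report; treated as having no hit")
    }
    hit <- rep_tab$unigene_id[rep_tab$flag != 0]
    flags[ids %in% hit] <- TRUE
  }
  out <- lapply(ids, function(id) {
    structure(list(
      unigene_id = id,
      length = Biostrings::width(reference[id]),
      sequence = as.character(reference[[id]]),
      snv_positions = sort(unique(pos[uni == id])),
      intron_boundaries = boundaries[[id]],
      has_similarity_hit = unname(flags[[id]]),
      has_gff = has_gff,
      has_similarity = has_similarity), class = "unigene_context")
  })
  stats::setNames(out, ids)
}

allele_pool_counts <- function(count_maps, labels) {
  vapply(count_maps, function(cc) {
    if (!length(labels)) sum(cc) else sum(cc[names(cc) %in% labels])
  }, 0)
}

#' @rdname snv_filters
#' @export
filter_maf <- function(snv, pool = character(0), maf_max = 0.80) {
  counts <- allele_pool_counts(snv$acc_counts, pool)
  total <- sum(counts)
  if (total == 0) return(FALSE)
  frac_lt(max(counts), total, maf_max)
}

#' @rdname snv_filters
#' @export
filter_gf <- function(snv, libraries = character(0), gf_max = 0.67) {
  counts <- allele_pool_counts(snv$lib_counts, libraries)
  total <- sum(counts)
  if (total == 0) return(FALSE)
  frac_lt(max(counts), total, gf_max)
}

#' @rdname snv_filters
#' @export
filter_hvr <- function(snv, context, hvr_max_pct = 4) {
  stopifnot(context$length > 0)
  pct_le(length(context$snv_positions), context$length, hvr_max_pct)
}

#' @rdname snv_filters
#' @export
filter_ucr <- function(snv, context) {
  !isTRUE(context$has_similarity_hit)
}

#' @rdname snv_filters
#' @export
filter_i30 <- function(snv, context, min_dist = 30) {
  b <- context$intron_boundaries
  if (!length(b)) return(TRUE)
  min(abs(snv$pos - b)) > min_dist
}

#' @rdname snv_filters
#' @export
filter_cl <- function(snv, context, min_dist = 30) {
  min(snv$pos, context$length - 1L - snv$pos) > min_dist
}

#' @rdname snv_filters
#' @export
filter_cs <- function(snv, context, min_dist = 60) {
  others <- setdiff(context$snv_positions, snv$pos)
  if (!length(others)) return(TRUE)
  min(abs(snv$pos - others)) > min_dist
}

#' @rdname snv_filters
#' @export
filter_vk <- function(snv, vk_kind = "snp") {
  vk_kind == "any" || snv$kind == vk_kind
}

# Local sequence per allele. Every allele replaces the same reference span
# [pos, pos + dmax) — dmax being the longest deletion at the column (1
# otherwise) — so all windows share their outer coordinates and site-count
# differences can only come from the alleles themselves, never from window
# extent.
allele_local_seqs <- function(sequence, pos, alleles, flank_len) {
  n <- nchar(sequence)
  dels <- nchar(alleles$seq[alleles$kind == "deletion"])
  dmax <- max(1L, dels)
  left <- substr(sequence, max(1L, pos - flank_len + 1L), pos)
  right <- substr(sequence, pos + dmax + 1L, min(n, pos + dmax + flank_len))
  ref_base <- substr(sequence, pos + 1L, pos + 1L)
  span_tail <- substr(sequence, pos + 2L, pos + dmax)
  vapply(seq_len(nrow(alleles)), function(i) {
    mid <- switch(alleles$kind[i],
                  ref = ,
                  snp = paste0(alleles$seq[i], span_tail),
                  insertion = paste0(ref_base, alleles$seq[i], span_tail),
                  deletion = substr(sequence,
                                    pos + 1L + nchar(alleles$seq[i]),
                                    pos + dmax))
    paste0(left, mid, right)
  }, "")
}

#' @rdname snv_filters
#' @export
filter_cef <- function(snv, context, enzymes = default_enzymes(),
                       flank_len = 60) {
  stopifnot(nrow(enzymes) > 0)
  seqs <- Biostrings::DNAStringSet(
    allele_local_seqs(context$sequence, snv$pos, snv$alleles, flank_len))
  for (e in seq_len(nrow(enzymes))) {
    counts <- Biostrings::vcountPattern(enzymes$site[e], seqs,
                                        fixed = "subject")
    if (length(unique(counts)) > 1L) return(TRUE)
  }
  FALSE
}

#' SNV selection filters
#'
#' Pure pass/fail predicates over a called SNV and its per-unigene
#' annotation context. Each returns `TRUE` (pass) or `FALSE` (fail) and
#' never modifies or removes records:
#'
#' * `filter_maf`: the most frequent allele's read frequency among the pool
#'   accessions is strictly below `maf_max`; an SNV with no pool
#'   observations fails.
#' * `filter_hvr`: the unigene's divergence (100 x SNVs / length) is at most
#'   `hvr_max_pct` percent.
#' * `filter_ucr`: the unigene has no hit in the similarity report.
#' * `filter_i30`: the distance to every intron/exon boundary exceeds
#'   `min_dist`; unigenes without annotated boundaries pass.
#' * `filter_cl`: the distance to both unigene ends exceeds `min_dist`.
#' * `filter_cs`: the nearest other SNV on the unigene is farther than
#'   `min_dist`; a sole SNV passes.
#' * `filter_cef`: some enzyme's recognition site occurs a different number
#'   of times in the flanking sequence of at least one allele pair (a CAPS
#'   marker exists).
#' * `filter_vk`: the SNV is of the selected marker kind.
#' * `filter_gf`: like `filter_maf` over library labels against `gf_max`.
#'
#' @param snv An `snv` object.
#' @param context A `unigene_context` from [build_contexts()].
#' @param pool,libraries Accession / library label sets (empty = all).
#' @param maf_max,gf_max,hvr_max_pct,min_dist,flank_len Thresholds; see
#'   [filter_config()].
#' @param vk_kind `"snp"`, `"indel"` or `"any"`.
#' @param enzymes Enzyme table, as from [default_enzymes()].
#' @return Logical scalar: `TRUE` = pass.
#' @name snv_filters
NULL

filter_names <- c("MAF", "HVR", "UCR", "I30", "CL", "CS", "CEF", "VK", "GF")

apply_one_filter <- function(snv, name, context, config) {
  switch(name,
         MAF = filter_maf(snv, config$maf_pool, config$maf_max),
         HVR = filter_hvr(snv, context, config$hvr_max_pct),
         UCR = filter_ucr(snv, context),
         I30 = filter_i30(snv, context, config$i30_min_dist),
         CL = filter_cl(snv, context, config$cl_min_dist),
         CS = filter_cs(snv, context, config$cs_min_dist),
         CEF = filter_cef(snv, context, config$enzymes, config$flank_len),
         VK = filter_vk(snv, config$vk_kind),
         GF = filter_gf(snv, config$gf_libraries, config$gf_max),
         abort_config("unknown filter: ", name))
}

#' Apply selection filters to called SNVs
#'
#' Filters tag, never delete: every SNV gains one pass/fail entry per
#' applied filter and the record count is unchanged. Filters are independent
#' pure predicates, so the application order does not affect the result.
#'
#' @param snvs An `snv_set` (or list of `snv` objects).
#' @param contexts Named list from [build_contexts()].
#' @param config A [filter_config()].
#' @param filters Character vector of filter short names to apply (subset of
#'   MAF, HVR, UCR, I30, CL, CS, CEF, VK, GF).
#' @return The `snv_set` with each record's `filters` map populated.
#' @export
apply_filters <- function(snvs, contexts, config = filter_config(),
                          filters = filter_names) {
  unknown <- setdiff(filters, filter_names)
  if (length(unknown)) {
    abort_config("unknown filter(s): ", paste(unknown, collapse = ", "))
  }
  if (length(filters) && length(snvs)) {
    ctx1 <- contexts[[snvs[[1]]$unigene]]
    if ("I30" %in% filters && !isTRUE(ctx1$has_gff)) {
      abort_missing_input("the I30 filter needs intron/exon annotations; ",
                          "supply a GFF file to build_contexts()")
    }
    if ("UCR" %in% filters && !isTRUE(ctx1$has_similarity)) {
      abort_missing_input("the UCR filter needs a unigene similarity report; ",
                          "supply it to build_contexts()")
    }
  }
  out <- lapply(snvs, function(s) {
    ctx <- contexts[[s$unigene]]
    if (is.null(ctx)) {
      abort_missing_input("no annotation context for unigene ", s$unigene)
    }
    tags <- vapply(filters, apply_one_filter, TRUE, snv = s, context = ctx,
                   config = config)
    s$filters[filters] <- tags
    s
  })
  attributes(out) <- attributes(snvs)
  out
}

#' Filter tag matrix
#'
#' @param snvs An `snv_set` whose records carry filter tags.
#' @return A logical matrix, one row per SNV (named `unigene:pos`), one
#'   column per filter; `TRUE` = pass.
#' @export
snv_tags <- function(snvs) {
  cols <- unique(unlist(lapply(snvs, function(s) names(s$filters))))
  m <- matrix(NA, nrow = length(snvs), ncol = length(cols),
              dimnames = list(
                vapply(snvs, function(s) paste0(s$unigene, ":", s$pos), ""),
                cols))
  for (i in seq_along(snvs)) {
    f <- snvs[[i]]$filters
    m[i, names(f)] <- f
  }
  m
}
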