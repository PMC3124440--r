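#' Allele quality from supporting base qualities
#'
#' The quality of an allele is accumulated from the three most reliable reads
#' supporting it: `PQ1 + 0.25 * (PQ2 + PQ3)`, where `PQ1 >= PQ2 >= PQ3` are
#' the three highest supporting base qualities. With only two observations
#' the score degrades to `PQ1 + 0.25 * PQ2`, with one to `PQ1`; observations
#' beyond the best three are ignored.
#'
#' @param sorted_quals Numeric vector of Phred qualities, descending.
#' @return The allele quality score (numeric scalar).
#' @examples
#' allele_quality(c(30, 20, 20))  # 40
#' allele_quality(25)             # 25
#' @export
allele_quality <- function(sorted_quals) {
  if (!length(sorted_quals)) {
    stop("allele_quality() requires at least one supporting quality")
  }
  q <- sort(sorted_quals, decreasing = TRUE)
  q1 <- q[1]
  q2 <- if (length(q) >= 2L) q[2] else 0
  q3 <- if (length(q) >= 3L) q[3] else 0
  q1 + 0.25 * (q2 + q3)
}

#' Caller configuration
#'
#' @param min_map_qual Reads below this mapping quality are not considered
#'   (default 15).
#' @param min_allele_qual Minimum allele quality score for an allele to count
#'   as high quality (default 20, the conventional Phred reliability floor).
#' @return A `caller_config` list.
#' @export
caller_config <- function(min_map_qual = 15, min_allele_qual = 20) {
  stopifnot(min_map_qual >= 0)
  structure(list(min_map_qual = min_map_qual,
                 min_allele_qual = min_allele_qual,
                 max_reads_per_allele_quality = 3L),
            class = "caller_config")
}

# Stable allele ordering: descending read count, then descending quality,
# then kind/seq as the final deterministic tiebreak.
order_alleles <- function(df) {
  order(-df$read_count, -df$quality, df$kind, df$seq)
}

#' Call an SNV from one pileup column
#'
#' Observations below the mapping-quality cutoff are discarded; the remainder
#' are grouped by allele (reference-matching observations form the reference
#' allele) and each allele is scored with [allele_quality()]. A variant is
#' reported iff at least two distinct alleles — the reference allele counts —
#' reach the allele-quality threshold.
#'
#' @param column A pileup column: data.table/data.frame of observations as
#'   produced by [build_pileups()] (single `unigene`/`pos`).
#' @param config A [caller_config()].
#' @return An object of class `snv`, or `NULL` when the position does not
#'   qualify.
#' @export
call_snv <- function(column, config = caller_config()) {
  column <- as.data.frame(column)
  if (!nrow(column)) return(NULL)
  obs <- column[column$map_qual >= config$min_map_qual, , drop = FALSE]
  if (!nrow(obs)) return(NULL)
  key <- paste(obs$kind, obs$seq, sep = "\r")
  groups <- split(seq_len(nrow(obs)), key)
  alleles <- lapply(groups, function(idx) {
    g <- obs[idx, , drop = FALSE]
    list(kind = g$kind[1], seq = g$seq[1],
         quality = allele_quality(g$base_qual),
         read_count = nrow(g),
         acc = table(g$accession),
         lib = table(g$library),
         plat = table(g$platform))
  })
  qualities <- vapply(alleles, `[[`, 0, "quality")
  alleles <- alleles[qualities >= config$min_allele_qual]
  if (length(alleles) < 2L) return(NULL)
  df <- data.frame(
    kind = vapply(alleles, `[[`, "", "kind"),
    seq = vapply(alleles, `[[`, "", "seq"),
    quality = vapply(alleles, `[[`, 0, "quality"),
    read_count = vapply(alleles, `[[`, 0L, "read_count"),
    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order_alleles(df)
  to_named_int <- function(tb) stats::setNames(as.integer(tb), names(tb))
  alt_kinds <- df$kind[df$kind != "ref"]
  kind <- if (!length(alt_kinds)) {
    "snp"
  } else if (all(alt_kinds == "snp")) {
    "snp"
  } else if (all(alt_kinds %in% c("insertion", "deletion"))) {
    "indel"
  } else {
    "complex"
  }
  structure(list(
    unigene = column$unigene[1],
    pos = column$pos[1],
    ref_base = column$ref_base[1],
    alleles = df[ord, , drop = FALSE],
    acc_counts = lapply(alleles[ord], function(a) to_named_int(a$acc)),
    lib_counts = lapply(alleles[ord], function(a) to_named_int(a$lib)),
    plat_counts = lapply(alleles[ord], function(a) to_named_int(a$plat)),
    kind = kind,
    filters = stats::setNames(logical(0), character(0))),
    class = "snv")
}

#' @export
print.snv <- function(x, ...) {
  al <- paste0(ifelse(x$alleles$kind == "ref", "*",
                      substr(x$alleles$kind, 1, 1)), ":", x$alleles$seq,
               collapse = ",")
  cat(sprintf("<snv %s:%d %s [%s] %s>\n", x$unigene, x$pos, x$ref_base,
              x$kind, al))
  invisible(x)
}

#' Call SNVs across a whole pileup
#'
#' Vectorized scan for candidate columns (two or more high-quality alleles
#' after the mapping-quality cut), then per-column calls via [call_snv()].
#' Output is sorted by reference (in reference order) and position.
#'
#' @param pileup An `snv_pileup` from [build_pileups()].
#' @param config A [caller_config()].
#' @return A list of `snv` objects (class `snv_set`), with the reference
#'   attached as attribute `reference`.
#' @export
call_snvs <- function(pileup, config = caller_config()) {
  obs <- pileup$observations
  snvs <- list()
  if (nrow(obs)) {
    dt <- obs[map_qual >= config$min_map_qual]
    if (nrow(dt)) {
      data.table::setorder(dt, unigene, pos, kind, seq, -base_qual)
      al <- dt[, .(aq = base_qual[1] +
                     0.25 * ((if (.N >= 2L) base_qual[2] else 0) +
                             (if (.N >= 3L) base_qual[3] else 0))),
               by = .(unigene, pos, kind, seq)]
      cand <- al[aq >= config$min_allele_qual][, .N, by = .(unigene, pos)][N >= 2L]
      if (nrow(cand)) {
        ref_order <- names(pileup$ref_lengths)
        cand[, uo := match(unigene, ref_order)]
        data.table::setorder(cand, uo, pos)
        # join returns observation rows in cand's (reference, position) order
        cols <- obs[cand[, .(unigene, pos)], on = c("unigene", "pos")]
        snvs <- lapply(split(cols, by = c("unigene", "pos"), sorted = FALSE),
                       call_snv, config = config)
        snvs <- unname(snvs[!vapply(snvs, is.null, TRUE)])
      }
    }
  }
  structure(snvs, class = "snv_set", reference = pileup$reference)
}

#' @export
print.snv_set <- function(x, ...) {
  cat(sprintf("<snv_set: %d variants>\n", length(x)))
  invisible(x)
}
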