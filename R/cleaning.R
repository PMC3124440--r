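#' Trim low-quality ends from a read
#'
#' Selects a single contiguous high-quality subread. Two algorithms are
#' available:
#'
#' * `"running_sum"` (default): the modified-Mott trimmer. Each base scores
#'   `quality - threshold`; the subread with the maximal cumulative score is
#'   kept, provided its score is strictly positive. Score ties are broken by
#'   leftmost start, then by longest segment, so the result is deterministic.
#' * `"sliding_window"`: clips from each end until a window of width 4 has
#'   mean quality at or above the threshold; reads shorter than the window
#'   are assessed as a single whole-read window.
#'
#' A read with no qualifying segment comes back empty (zero length), never an
#' error. Both modes are idempotent and always return a contiguous slice of
#' the input.
#'
#' @param read A [seq_read()].
#' @param threshold Phred quality threshold in `[0, 93]`.
#' @param mode `"running_sum"` or `"sliding_window"`.
#' @return A [seq_read()] with the same `id`, possibly empty.
#' @examples
#' r <- seq_read("r", "ACGTACGT", c(2, 2, 35, 35, 35, 35, 2, 2))
#' trim_quality(r, threshold = 20)$bases
#' @export
trim_quality <- function(read, threshold = 20,
                         mode = c("running_sum", "sliding_window")) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0, threshold <= 93)
  n <- read_length(read)
  if (n == 0L) return(read)
  q <- read$quals
  if (mode == "running_sum") {
    sc <- q - threshold
    best <- 0; bs <- 0L; be <- -1L
    minpref <- 0; min_idx <- 0L
    p <- 0
    for (e in seq_len(n)) {
      if (p < minpref) { minpref <- p; min_idx <- e - 1L }
      p <- p + sc[e]
      cand <- p - minpref
      s <- min_idx + 1L
      if (cand > best ||
          (cand == best && best > 0 &&
           (s < bs || (s == bs && e > be)))) {
        best <- cand; bs <- s; be <- e
      }
    }
    if (best <= 0) return(subread(read, 1L, 0L))
    subread(read, bs, be)
  } else {
    w <- 4L
    if (n < w) {
      if (mean(q) >= threshold) return(read)
      return(subread(read, 1L, 0L))
    }
    cs <- cumsum(as.numeric(q))
    starts <- seq_len(n - w + 1L)
    means <- (cs[starts + w - 1L] - c(0, cs)[starts]) / w
    ok <- which(means >= threshold)
    if (!length(ok)) return(subread(read, 1L, 0L))
    subread(read, min(ok), max(ok) + w - 1L)
  }
}

#' Remove adaptor sequence from a read
#'
#' Each adaptor is located by its best gap-free placement inside the read,
#' allowing up to `floor(max_mismatch_rate * nchar(adaptor))` mismatches.
#' When a hit is found, the adaptor span is removed and the longer flanking
#' segment is kept (qualities sliced in step; ties keep the 5' flank).
#' Removal is repeated until no adaptor matches, so an adaptor at each end is
#' handled. A read without any hit is returned unchanged.
#'
#' @param read A [seq_read()].
#' @param adaptors Character vector of adaptor sequences.
#' @param max_mismatch_rate Allowed mismatch fraction of the adaptor length.
#' @return A [seq_read()].
#' @export
trim_adaptor <- function(read, adaptors, max_mismatch_rate = 0.1) {
  stopifnot(length(adaptors) > 0L, all(nzchar(adaptors)))
  repeat {
    n <- read_length(read)
    if (n == 0L) return(read)
    subject <- Biostrings::DNAString(read$bases)
    best <- NULL  # list(start, end, mism, adaptor_rank)
    for (k in seq_along(adaptors)) {
      ad <- toupper(adaptors[[k]])
      m <- nchar(ad)
      if (m > n) next
      max_mm <- floor(max_mismatch_rate * m)
      hits <- Biostrings::matchPattern(ad, subject, max.mismatch = max_mm,
                                       with.indels = FALSE)
      if (!length(hits)) next
      starts <- BiocGenerics::start(hits)
      mism <- Biostrings::neditStartingAt(Biostrings::DNAString(ad), subject,
                                          starting.at = starts,
                                          with.indels = FALSE)
      for (h in seq_along(starts)) {
        cand <- list(start = starts[h], end = starts[h] + m - 1L,
                     mism = mism[h], rank = k)
        if (is.null(best) ||
            cand$mism < best$mism ||
            (cand$mism == best$mism &&
             (cand$start < best$start ||
              (cand$start == best$start && cand$rank < best$rank)))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) return(read)
    left_len <- best$start - 1L
    right_len <- n - best$end
    read <- if (left_len >= right_len) {
      subread(read, 1L, left_len)
    } else {
      subread(read, best$end + 1L, n)
    }
  }
}

#' Keep only reads of at least a minimum length
#'
#' @param reads List of [seq_read()] objects.
#' @param min_len Minimum length in bases.
#' @return List of reads with `read_length(read) >= min_len`, order preserved.
#' @export
filter_min_length <- function(reads, min_len) {
  stopifnot(min_len >= 0)
  reads[vapply(reads, read_length, 1L) >= min_len]
}

#' Per-position quality summary across reads
#'
#' For each position, summarizes the qualities of all reads long enough to
#' reach it with the five boxplot statistics. Quartiles follow the
#' inclusive-median (Tukey hinge) convention, so the summary is
#' bit-reproducible.
#'
#' @param reads List of [seq_read()] objects.
#' @return A data.frame with columns `position` (1-based), `n`, `min`, `q1`,
#'   `median`, `q3`, `max`; zero rows for empty input.
#' @export
quality_profile <- function(reads) {
  lens <- vapply(reads, read_length, 1L)
  reads <- reads[lens > 0L]
  lens <- lens[lens > 0L]
  if (!length(reads)) {
    return(data.frame(position = integer(0), n = integer(0), min = numeric(0),
                      q1 = numeric(0), median = numeric(0), q3 = numeric(0),
                      max = numeric(0)))
  }
  maxlen <- max(lens)
  mat <- matrix(NA_integer_, nrow = length(reads), ncol = maxlen)
  for (i in seq_along(reads)) mat[i, seq_len(lens[i])] <- reads[[i]]$quals
  out <- lapply(seq_len(maxlen), function(p) {
    qs <- mat[, p]
    qs <- qs[!is.na(qs)]
    fn <- stats::fivenum(qs)
    data.frame(position = p, n = length(qs), min = fn[1], q1 = fn[2],
               median = fn[3], q3 = fn[4], max = fn[5])
  })
  do.call(rbind, out)
}

#' Histogram of read lengths
#'
#' @param reads List of [seq_read()] objects.
#' @return A data.frame with columns `length` and `count`; the counts sum to
#'   the number of reads.
#' @export
length_distribution <- function(reads) {
  if (!length(reads)) return(data.frame(length = integer(0), count = integer(0)))
  tab <- table(vapply(reads, read_length, 1L))
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

#' Clean a set of reads
#'
#' The full cleaning stage: adaptor removal (if adaptors are given), quality
#' trimming, then a minimum-length filter. Returns the surviving reads
#' together with a conservation-checked cleaning report.
#'
#' @param reads List of [seq_read()] objects.
#' @param adaptors Character vector of adaptors, or `NULL` to skip.
#' @param quality_threshold Phred threshold for [trim_quality()].
#' @param mode Trimming mode for [trim_quality()].
#' @param min_len Minimum post-trim length.
#' @param max_mismatch_rate Adaptor mismatch budget for [trim_adaptor()].
#' @return A list with elements `reads` (the cleaned reads) and `report`, a
#'   `cleaning_report` with counts `reads_in`, `reads_out`,
#'   `bases_trimmed_quality`, `bases_trimmed_adaptor`, `reads_dropped_short`
#'   satisfying `reads_in == reads_out + reads_dropped_short`.
#' @export
clean_reads <- function(reads, adaptors = NULL, quality_threshold = 20,
                        mode = c("running_sum", "sliding_window"),
                        min_len = 40, max_mismatch_rate = 0.1) {
  mode <- match.arg(mode)
  reads_in <- length(reads)
  bases_ad <- 0L
  bases_q <- 0L
  out <- vector("list", reads_in)
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    if (!is.null(adaptors) && length(adaptors)) {
      len0 <- read_length(r)
      r <- trim_adaptor(r, adaptors, max_mismatch_rate)
      bases_ad <- bases_ad + (len0 - read_length(r))
    }
    len0 <- read_length(r)
    r <- trim_quality(r, threshold = quality_threshold, mode = mode)
    bases_q <- bases_q + (len0 - read_length(r))
    out[[i]] <- r
  }
  kept <- filter_min_length(out, min_len)
  report <- structure(
    list(reads_in = reads_in, reads_out = length(kept),
         bases_trimmed_quality = bases_q, bases_trimmed_adaptor = bases_ad,
         reads_dropped_short = reads_in - length(kept)),
    class = "cleaning_report")
  list(reads = kept, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Read cleaning report\n")
  cat(sprintf("  reads in:             %d\n", x$reads_in))
  cat(sprintf("  reads out:            %d\n", x$reads_out))
  cat(sprintf("  dropped (too short):  %d\n", x$reads_dropped_short))
  cat(sprintf("  bases trimmed (qual): %d\n", x$bases_trimmed_quality))
  cat(sprintf("  bases trimmed (adpt): %d\n", x$bases_trimmed_adaptor))
  invisible(x)
}

#' Write a statistics table as tab-delimited text
#'
#' @param stats A data.frame (e.g. from [quality_profile()],
#'   [length_distribution()] or [coverage_distribution()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_table <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
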