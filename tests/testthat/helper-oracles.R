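# Independent brute-force oracles and fixture builders used across the suite.
# These deliberately re-derive results by enumeration / direct arithmetic and
# never call the code paths they check.

make_read <- function(quals, bases = NULL, id = "r", platform = "short") {
  if (is.null(bases)) {
    bases <- paste(rep_len(c("A", "C", "G", "T"), length(quals)), collapse = "")
  }
  seq_read(id, bases, quals, platform = platform)
}

random_read <- function(n, id = "r", qmin = 0, qmax = 40, platform = "short") {
  make_read(sample(qmin:qmax, n, replace = TRUE),
            paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = ""),
            id = id, platform = platform)
}

# Exhaustive O(n^2) best-substring scan: maximal sum of (qual - threshold),
# strictly positive, ties resolved to the leftmost start then the longest.
oracle_best_segment <- function(quals, threshold) {
  n <- length(quals)
  best <- list(score = 0, start = NA_integer_, end = NA_integer_)
  for (s in seq_len(n)) {
    acc <- 0
    for (e in s:n) {
      acc <- acc + quals[e] - threshold
      better <- acc > best$score ||
        (acc == best$score && !is.na(best$start) &&
         (s < best$start || (s == best$start && e > best$end)))
      if (better && acc > 0) best <- list(score = acc, start = s, end = e)
    }
  }
  best
}

# Inclusive-median quartiles computed by explicit sort-and-halve
oracle_five <- function(x) {
  x <- sort(x)
  n <- length(x)
  med <- function(v) {
    m <- length(v)
    if (m %% 2L == 1L) v[(m + 1L) / 2L] else (v[m / 2L] + v[m / 2L + 1L]) / 2
  }
  lower <- x[seq_len(ceiling(n / 2))]
  upper <- x[seq.int(floor(n / 2) + 1L, n)]
  c(min = x[1], q1 = med(lower), median = med(x), q3 = med(upper), max = x[n])
}

# Independent re-implementation of the calling rules over one column
oracle_call_column <- function(col, min_map_qual = 15, min_allele_qual = 20) {
  col <- as.data.frame(col)
  col <- col[col$map_qual >= min_map_qual, , drop = FALSE]
  if (!nrow(col)) return(NULL)
  keys <- paste(col$kind, col$seq)
  kept <- character(0)
  for (k in unique(keys)) {
    qs <- sort(col$base_qual[keys == k], decreasing = TRUE)
    top <- qs[seq_len(min(3, length(qs)))]
    score <- top[1] + 0.25 * sum(top[-1])
    if (score >= min_allele_qual) kept <- c(kept, k)
  }
  if (length(kept) < 2L) return(NULL)
  sort(kept)
}

random_column <- function(unigene = "u", pos = 10L, n_obs = NULL) {
  if (is.null(n_obs)) n_obs <- sample(1:12, 1)
  kinds <- sample(c("ref", "snp", "snp", "insertion", "deletion"), n_obs,
                  replace = TRUE)
  seqs <- ifelse(kinds == "ref", "A",
                 ifelse(kinds == "snp", sample(c("C", "G", "T"), n_obs,
                                               replace = TRUE),
                        sample(c("C", "CA", "GT"), n_obs, replace = TRUE)))
  data.frame(unigene = unigene, pos = pos, ref_base = "A", kind = kinds,
             seq = seqs,
             base_qual = sample(0:45, n_obs, replace = TRUE),
             map_qual = sample(0:60, n_obs, replace = TRUE),
             accession = sample(paste0("acc", 1:4), n_obs, replace = TRUE),
             library = sample(paste0("lib", 1:3), n_obs, replace = TRUE),
             platform = sample(c("short", "long"), n_obs, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Direct construction of an snv record, bypassing the caller
make_snv <- function(unigene = "u1", pos = 100L, ref_base = "A",
                     alleles = data.frame(kind = c("ref", "snp"),
                                          seq = c("A", "G"),
                                          quality = c(50, 45),
                                          read_count = c(5L, 4L)),
                     acc_counts = NULL, lib_counts = NULL, plat_counts = NULL,
                     filters = stats::setNames(logical(0), character(0))) {
  n <- nrow(alleles)
  if (is.null(acc_counts)) {
    acc_counts <- lapply(seq_len(n), function(i) {
      stats::setNames(alleles$read_count[i], paste0("acc", i))
    })
  }
  if (is.null(lib_counts)) {
    lib_counts <- lapply(seq_len(n), function(i) {
      stats::setNames(alleles$read_count[i], paste0("lib", i))
    })
  }
  if (is.null(plat_counts)) {
    plat_counts <- lapply(seq_len(n), function(i) {
      stats::setNames(alleles$read_count[i], "short")
    })
  }
  alt <- alleles$kind[alleles$kind != "ref"]
  kind <- if (!length(alt) || all(alt == "snp")) {
    "snp"
  } else if (all(alt %in% c("insertion", "deletion"))) {
    "indel"
  } else {
    "complex"
  }
  structure(list(unigene = unigene, pos = as.integer(pos),
                 ref_base = ref_base, alleles = alleles,
                 acc_counts = acc_counts, lib_counts = lib_counts,
                 plat_counts = plat_counts, kind = kind, filters = filters),
            class = "snv")
}

# A small deterministic simulated project shared by heavier tests
tiny_sim_config <- function(seed = 11, ...) {
  simulation_config(n_unigenes = 4, unigene_len_range = c(400, 500),
                    reads_per_unigene = c(short = 120, long = 6),
                    read_len = c(short = 75, long = 300), seed = seed, ...)
}

random_unigene <- function(len, id = "u1") {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  stats::setNames(Biostrings::DNAStringSet(s), id)
}
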