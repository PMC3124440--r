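# context builders for direct filter tests
ctx <- function(length = 1000L, snv_positions = integer(0),
                intron_boundaries = integer(0), has_similarity_hit = FALSE,
                sequence = NULL) {
  if (is.null(sequence)) {
    sequence <- paste(rep_len(c("A", "C", "G", "T"), length), collapse = "")
  }
  structure(list(unigene_id = "u1", length = length, sequence = sequence,
                 snv_positions = snv_positions,
                 intron_boundaries = intron_boundaries,
                 has_similarity_hit = has_similarity_hit,
                 has_gff = TRUE, has_similarity = TRUE),
            class = "unigene_context")
}

snv_with_acc <- function(acc_counts, pos = 100L) {
  n <- length(acc_counts)
  make_snv(pos = pos,
           alleles = data.frame(kind = c("ref", rep("snp", n - 1)),
                                seq = c("A", rep_len(c("G", "T", "C"), n - 1)),
                                quality = 50, read_count = vapply(acc_counts, sum, 0L)),
           acc_counts = acc_counts,
           lib_counts = lapply(acc_counts, function(cc) {
             stats::setNames(as.integer(cc), sub("^a", "lib", names(cc)))
           }))
}

test_that("MAF compares pool read frequencies strictly below the threshold", {
  s <- snv_with_acc(list(c(a1 = 5L), c(a2 = 5L)))
  expect_true(filter_maf(s, c("a1", "a2"), 0.80))
  # single-allele pool: frequency 1 fails
  expect_false(filter_maf(snv_with_acc(list(c(a1 = 7L))), "a1", 0.80))
  # no pool observations fails
  expect_false(filter_maf(s, "a9", 0.80))
  # 8/10 is not < 0.80
  expect_false(filter_maf(snv_with_acc(list(c(a1 = 8L), c(a2 = 2L))),
                          c("a1", "a2"), 0.80))
  expect_true(filter_maf(snv_with_acc(list(c(a1 = 7L), c(a2 = 3L))),
                         c("a1", "a2"), 0.80))
})

test_that("GF uses exact rational arithmetic at the 2/3 boundary", {
  s23 <- snv_with_acc(list(c(a1 = 2L), c(a2 = 1L)))
  # 2/3 = 0.666... < 0.67: passes only under exact comparison
  expect_true(filter_gf(s23, c("lib1", "lib2"), 0.67))
  s34 <- snv_with_acc(list(c(a1 = 67L), c(a2 = 33L)))
  expect_false(filter_gf(s34, c("lib1", "lib2"), 0.67))  # 67/100 not < 0.67
  expect_true(filter_gf(snv_with_acc(list(c(a1 = 1L), c(a2 = 1L))),
                        c("lib1", "lib2"), 0.67))
})

test_that("HVR divergence is inclusive at the printed percentage", {
  s <- make_snv()
  expect_true(filter_hvr(s, ctx(1000L, snv_positions = 0:39), 4))   # 4.0%
  expect_false(filter_hvr(s, ctx(1000L, snv_positions = 0:40), 4))  # 4.1%
})

test_that("UCR passes exactly the unigenes without similarity hits", {
  s <- make_snv()
  expect_false(filter_ucr(s, ctx(has_similarity_hit = TRUE)))
  expect_true(filter_ucr(s, ctx(has_similarity_hit = FALSE)))
  withr::with_seed(413, {
    flagged <- sample(c(TRUE, FALSE), 100, replace = TRUE)
    got <- vapply(flagged, function(f) filter_ucr(s, ctx(has_similarity_hit = f)),
                  TRUE)
    expect_identical(got, !flagged)
  })
})

test_that("I30 boundary distance is strict", {
  s131 <- make_snv(pos = 131L)
  s130 <- make_snv(pos = 130L)
  expect_true(filter_i30(s131, ctx(intron_boundaries = 100L), 30))   # 31 > 30
  expect_false(filter_i30(s130, ctx(intron_boundaries = 100L), 30))  # 30 not > 30
  expect_true(filter_i30(s130, ctx(intron_boundaries = integer(0)), 30))
})

test_that("CL end distance is strict on both ends", {
  expect_true(filter_cl(make_snv(pos = 31L), ctx(200L), 30))
  expect_false(filter_cl(make_snv(pos = 30L), ctx(200L), 30))
  expect_false(filter_cl(make_snv(pos = 0L), ctx(200L), 30))
  expect_false(filter_cl(make_snv(pos = 169L), ctx(200L), 30))  # 200-1-169 = 30
  expect_true(filter_cl(make_snv(pos = 168L), ctx(200L), 30))
})

test_that("CS neighbour distance is strict and a sole SNV passes", {
  c61 <- ctx(1000L, snv_positions = c(100L, 161L))
  expect_true(filter_cs(make_snv(pos = 100L), c61, 60))
  expect_true(filter_cs(make_snv(pos = 161L), c61, 60))
  c60 <- ctx(1000L, snv_positions = c(100L, 160L))
  expect_false(filter_cs(make_snv(pos = 100L), c60, 60))
  expect_false(filter_cs(make_snv(pos = 160L), c60, 60))
  expect_true(filter_cs(make_snv(pos = 100L), ctx(1000L, snv_positions = 100L), 60))
})

test_that("CEF detects a differential MspI site", {
  # ref ...C CGG...: the C allele completes CCGG, the T allele destroys it
  seqchars <- rep("A", 200)
  seqchars[100] <- "C"   # 0-based 99 = the variant column
  seqchars[101] <- "C"; seqchars[102] <- "G"; seqchars[103] <- "G"
  sq <- paste(seqchars, collapse = "")
  s <- make_snv(pos = 99L, ref_base = "C",
                alleles = data.frame(kind = c("ref", "snp"), seq = c("C", "T"),
                                     quality = 50, read_count = 5L))
  enz <- data.frame(name = "MspI", site = "CCGG")
  expect_true(filter_cef(s, ctx(200L, sequence = sq), enz, 60))
  # with an enzyme whose site occurs in neither allele: fail
  enz2 <- data.frame(name = "EcoRI", site = "GAATTC")
  expect_false(filter_cef(s, ctx(200L, sequence = sq), enz2, 60))
})

test_that("CEF agrees with brute-force site regeneration on random SNVs", {
  enz <- default_enzymes()[1:10, ]
  withr::with_seed(414, {
    for (i in 1:100) {
      len <- 300L
      sq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
      pos <- sample(10:(len - 10), 1)
      rb <- substr(sq, pos + 1, pos + 1)
      kind <- sample(c("snp", "insertion", "deletion"), 1)
      alt <- switch(kind,
                    snp = sample(setdiff(c("A", "C", "G", "T"), rb), 1),
                    insertion = paste(sample(c("A", "C", "G", "T"),
                                             sample(1:3, 1), replace = TRUE),
                                      collapse = ""),
                    deletion = substr(sq, pos + 1, pos + sample(1:2, 1)))
      s <- make_snv(pos = pos, ref_base = rb,
                    alleles = data.frame(kind = c("ref", kind),
                                         seq = c(rb, alt),
                                         quality = 50, read_count = 5L))
      got <- filter_cef(s, ctx(len, sequence = sq), enz, 60)
      # oracle: rebuild both allele windows by plain string surgery and count
      # pattern hits with a regex over the IUPAC expansion
      win <- function(mid) {
        a <- max(0, pos - 60); b <- min(len, pos + 61)
        left <- substr(sq, a + 1, pos)
        right <- switch(kind,
                        snp = substr(sq, pos + 2, b),
                        insertion = substr(sq, pos + 2, b),
                        deletion = substr(sq, pos + 1 + nchar(alt), b))
        paste0(left, mid, right)
      }
      ref_win <- win(switch(kind, deletion = alt, rb))
      alt_win <- win(switch(kind, snp = alt,
                            insertion = paste0(rb, alt), deletion = ""))
      iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
                 D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
      count_hits <- function(site, x) {
        pat <- paste(iupac[strsplit(site, "")[[1]]], collapse = "")
        hits <- gregexpr(paste0("(?=", pat, ")"), x, perl = TRUE)[[1]]
        sum(hits > 0)
      }
      want <- any(vapply(enz$site, function(site) {
        count_hits(site, ref_win) != count_hits(site, alt_win)
      }, TRUE))
      expect_identical(got, want)
    }
  })
})

test_that("VK selects the marker kind", {
  snp <- make_snv()
  ind <- make_snv(alleles = data.frame(kind = c("ref", "insertion"),
                                       seq = c("A", "GG"), quality = 50,
                                       read_count = 4L))
  cpx <- make_snv(alleles = data.frame(kind = c("snp", "deletion"),
                                       seq = c("G", "AA"), quality = 50,
                                       read_count = 4L))
  expect_true(filter_vk(snp, "snp"))
  expect_false(filter_vk(ind, "snp"))
  expect_true(filter_vk(ind, "indel"))
  expect_false(filter_vk(cpx, "snp"))
  expect_false(filter_vk(cpx, "indel"))
  expect_true(all(filter_vk(snp, "any"), filter_vk(ind, "any"),
                  filter_vk(cpx, "any")))
})

test_that("frequency filters agree with direct arithmetic on random counts", {
  withr::with_seed(415, {
    for (i in 1:300) {
      n_all <- sample(2:4, 1)
      accs <- paste0("a", 1:5)
      acc_counts <- lapply(seq_len(n_all), function(j) {
        k <- sample(1:3, 1)
        who <- sample(accs, k)
        stats::setNames(sample(1:6, k, replace = TRUE), who)
      })
      s <- snv_with_acc(acc_counts)
      pool <- sample(accs, sample(1:5, 1))
      thr <- sample(c(0.5, 0.67, 0.80, 0.95), 1)
      counts <- vapply(acc_counts, function(cc) sum(cc[names(cc) %in% pool]), 0)
      # integer cross-multiplication keeps the oracle exact at boundaries
      den <- 100L
      num <- as.integer(round(thr * den))
      want <- sum(counts) > 0 && max(counts) * den < num * sum(counts)
      expect_identical(filter_maf(s, pool, thr), want,
                       label = paste("counts", paste(counts, collapse = "/"),
                                     "thr", thr))
    }
  })
})

test_that("positional filters agree with linear-scan oracles", {
  withr::with_seed(416, {
    for (i in 1:200) {
      len <- sample(200:1200, 1)
      pos <- sample(0:(len - 1), 1)
      nb <- sample(0:5, 1)
      bounds <- if (nb) sort(sample(0:(len - 1), nb)) else integer(0)
      others <- sort(sample(0:(len - 1), sample(1:8, 1)))
      snv_pos <- sort(unique(c(pos, others)))
      cx <- ctx(len, snv_positions = snv_pos, intron_boundaries = bounds)
      s <- make_snv(pos = pos)
      d_i30 <- if (length(bounds)) min(abs(pos - bounds)) else Inf
      expect_identical(filter_i30(s, cx, 30), d_i30 > 30)
      expect_identical(filter_cl(s, cx, 30), min(pos, len - 1 - pos) > 30)
      rest <- setdiff(snv_pos, pos)
      d_cs <- if (length(rest)) min(abs(pos - rest)) else Inf
      expect_identical(filter_cs(s, cx, 60), d_cs > 60)
      expect_identical(filter_hvr(s, cx, 4),
                       length(snv_pos) * 100 <= 4 * len)
    }
  })
})

test_that("filters tag without deleting and independently of order", {
  cfg <- tiny_sim_config(seed = 24)
  dir <- withr::local_tempdir()
  p <- simulate_project(cfg, dir)
  ref <- Biostrings::readDNAStringSet(p$reference)
  snvs <- call_snvs(build_pileups(read_alignments(p$alignments), ref))
  contexts <- build_contexts(ref, snvs, gff_path = p$gff,
                             similarity_path = p$similarity)
  fcfg <- filter_config(vk_kind = "any")
  all_f <- c("MAF", "HVR", "UCR", "I30", "CL", "CS", "CEF", "VK", "GF")
  t1 <- apply_filters(snvs, contexts, fcfg, all_f)
  expect_identical(length(t1), length(snvs))
  expect_true(all(vapply(t1, function(s) length(s$filters) == 9L, TRUE)))
  withr::with_seed(417, perm <- sample(all_f))
  t2 <- apply_filters(snvs, contexts, fcfg, perm)
  m1 <- snv_tags(t1)
  m2 <- snv_tags(t2)[, colnames(snv_tags(t1)), drop = FALSE]
  expect_identical(m1, m2)
  # reapplication is idempotent
  t3 <- apply_filters(t1, contexts, fcfg, all_f)
  expect_identical(snv_tags(t3), m1)
})

test_that("loosening thresholds never converts a pass into a fail", {
  withr::with_seed(418, {
    for (i in 1:100) {
      len <- 800L
      pos <- sample(0:(len - 1), 1)
      cx <- ctx(len,
                snv_positions = sort(unique(c(pos, sample(0:(len - 1), 5)))),
                intron_boundaries = sort(sample(0:(len - 1), 2)))
      acc_counts <- list(stats::setNames(sample(1:8, 1), "a1"),
                         stats::setNames(sample(1:8, 1), "a2"))
      s <- snv_with_acc(acc_counts, pos = pos)
      for (pair in list(
        c(filter_maf(s, c("a1", "a2"), 0.6), filter_maf(s, c("a1", "a2"), 0.9)),
        c(filter_hvr(s, cx, 1), filter_hvr(s, cx, 10)),
        c(filter_i30(s, cx, 50), filter_i30(s, cx, 10)),
        c(filter_cl(s, cx, 50), filter_cl(s, cx, 10)),
        c(filter_cs(s, cx, 80), filter_cs(s, cx, 20)),
        c(filter_gf(s, character(0), 0.5), filter_gf(s, character(0), 0.9)))) {
        expect_false(pair[1] && !pair[2])
      }
    }
  })
})

test_that("requesting annotation filters without their inputs is an error", {
  cfg <- tiny_sim_config(seed = 25)
  dir <- withr::local_tempdir()
  p <- simulate_project(cfg, dir)
  ref <- Biostrings::readDNAStringSet(p$reference)
  snvs <- call_snvs(build_pileups(read_alignments(p$alignments), ref))
  contexts <- build_contexts(ref, snvs)  # no GFF, no similarity report
  expect_error(apply_filters(snvs, contexts, filter_config(), "I30"), "GFF")
  expect_error(apply_filters(snvs, contexts, filter_config(), "UCR"),
               "similarity")
  # empty filter list leaves records untouched
  t0 <- apply_filters(snvs, contexts, filter_config(), character(0))
  expect_identical(t0, snvs)
})
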