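test_that("simulation is byte-identical under a fixed seed", {
  cfg <- tiny_sim_config(seed = 31)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_project(cfg, d1)
  p2 <- simulate_project(cfg, d2)
  for (k in c("reference", "reads_short", "reads_long", "alignments",
              "truth_variants", "truth_reads", "gff", "similarity")) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     label = paste("file", k))
  }
  # a different seed must change the data
  p3 <- simulate_project(tiny_sim_config(seed = 32), withr::local_tempdir())
  expect_false(identical(readLines(p1$reference), readLines(p3$reference)))
})

test_that("reference simulation respects counts and length ranges", {
  cfg <- simulation_config(n_unigenes = 50, unigene_len_range = c(300, 350))
  ref <- simulate_reference(cfg)
  expect_identical(length(ref), 50L)
  expect_true(all(Biostrings::width(ref) >= 300 &
                    Biostrings::width(ref) <= 350))
  expect_identical(length(simulate_reference(
    simulation_config(n_unigenes = 0))), 0L)
})

test_that("a zero variant rate plants nothing and keeps haplotypes identical", {
  cfg <- simulation_config(n_unigenes = 3, unigene_len_range = c(300, 350),
                           variant_rate = 0, seed = 33)
  ref <- simulate_reference(cfg)
  pl <- plant_variants(ref, cfg)
  expect_identical(nrow(pl$truth), 0L)
  for (uni in names(ref)) {
    for (acc in names(pl$haplotypes[[uni]])) {
      expect_identical(pl$haplotypes[[uni]][[acc]]$seq,
                       as.character(ref[[uni]]))
    }
  }
})

test_that("planted variant counts stay within the binomial 3-sigma bound", {
  # ~100 kb of reference at rate 0.01
  cfg <- simulation_config(n_unigenes = 100, unigene_len_range = c(1000, 1000),
                           variant_rate = 0.01, seed = 34)
  ref <- simulate_reference(cfg)
  pl <- plant_variants(ref, cfg)
  n <- sum(Biostrings::width(ref))
  expected <- n * 0.01
  sigma <- sqrt(n * 0.01 * 0.99)
  expect_lt(abs(nrow(pl$truth) - expected), 3 * sigma)
  # positions valid and well separated
  expect_true(all(pl$truth$pos >= 5 & pl$truth$pos <= 994))
  by_uni <- split(pl$truth$pos, pl$truth$unigene)
  expect_true(all(vapply(by_uni, function(p) all(diff(sort(p)) >= 4), TRUE)))
})

test_that("a balanced biallelic spectrum puts both alleles among accessions", {
  cfg <- simulation_config(n_unigenes = 5, unigene_len_range = c(500, 600),
                           variant_rate = 0.02,
                           allele_freq_spectrum = data.frame(freq = 0.5,
                                                             weight = 1),
                           seed = 35)
  pl <- plant_variants(simulate_reference(cfg), cfg)
  n_carriers <- lengths(strsplit(pl$truth$accessions, ","))
  expect_true(all(n_carriers == 4L))  # half of 8 accessions
})

test_that("error-free reads are exact substrings of their haplotype", {
  cfg <- simulation_config(n_unigenes = 2, unigene_len_range = c(400, 450),
                           reads_per_unigene = c(short = 40, long = 3),
                           read_len = c(short = 60, long = 300),
                           error_rate = 0, adaptor_rate = 0, seed = 36)
  ref <- simulate_reference(cfg)
  pl <- plant_variants(ref, cfg)
  sr <- simulate_reads(pl, cfg)
  expect_identical(length(sr$reads), nrow(sr$truth))
  for (i in seq_along(sr$reads)) {
    tr <- sr$truth[i, ]
    hap <- pl$haplotypes[[tr$unigene]][[tr$accession]]$seq
    expect_identical(sr$reads[[i]]$bases,
                     substr(hap, tr$hap_start + 1, tr$hap_start + tr$core_len))
  }
  none <- simulation_config(n_unigenes = 2, unigene_len_range = c(400, 450),
                            reads_per_unigene = c(short = 0, long = 0),
                            seed = 36)
  expect_identical(length(simulate_reads(pl, none)$reads), 0L)
})

test_that("mean coverage tracks reads x length / unigene length", {
  cfg <- simulation_config(n_unigenes = 3, unigene_len_range = c(500, 500),
                           reads_per_unigene = c(short = 200, long = 0),
                           read_len = c(short = 50, long = 300),
                           variant_rate = 0, error_rate = 0, seed = 37)
  ref <- simulate_reference(cfg)
  pl <- plant_variants(ref, cfg)
  sr <- simulate_reads(pl, cfg)
  total_bases <- sum(sr$truth$core_len)
  exp_cov <- 200 * 50 / 500
  obs_cov <- total_bases / sum(Biostrings::width(ref))
  # binomial-style bound on the mean coverage
  expect_lt(abs(obs_cov - exp_cov), 3 * sqrt(exp_cov))
})

test_that("adaptor contamination is planted where the truth table says", {
  cfg <- simulation_config(n_unigenes = 2, unigene_len_range = c(300, 350),
                           reads_per_unigene = c(short = 50, long = 0),
                           read_len = c(short = 50, long = 300),
                           adaptor_rate = 0.5, error_rate = 0, seed = 38)
  pl <- plant_variants(simulate_reference(cfg), cfg)
  sr <- simulate_reads(pl, cfg)
  has_ad <- sr$truth$adaptor_side != "none"
  expect_gt(sum(has_ad), 0)
  for (i in which(has_ad)) {
    r <- sr$reads[[i]]
    tr <- sr$truth[i, ]
    if (tr$adaptor_side == "5p") {
      expect_identical(substr(r$bases, 1, tr$adaptor_len), cfg$adaptor_seq)
    } else {
      n <- nchar(r$bases)
      expect_identical(substr(r$bases, n - tr$adaptor_len + 1, n),
                       cfg$adaptor_seq)
    }
    # cleaning removes the planted adaptor span
    cleaned <- trim_adaptor(r, cfg$adaptor_seq, 0.1)
    expect_lte(read_length(cleaned), tr$core_len)
  }
})

test_that("simulated alignments reproduce truth allele counts in pileups", {
  cfg <- simulation_config(n_unigenes = 3, unigene_len_range = c(400, 500),
                           reads_per_unigene = c(short = 150, long = 5),
                           read_len = c(short = 75, long = 300),
                           error_rate = 0, lowmapq_fraction = 0, seed = 39)
  dir <- withr::local_tempdir()
  p <- simulate_project(cfg, dir)
  ref <- Biostrings::readDNAStringSet(p$reference)
  pu <- build_pileups(read_alignments(p$alignments), ref)
  tr <- p$truth
  for (i in seq_len(nrow(tr))) {
    col <- pileup_column(pu, tr$unigene[i], tr$pos[i])
    carriers <- strsplit(tr$accessions[i], ",")[[1]]
    alt_obs <- col[col$kind == tr$kind[i] & col$seq == tr$alt[i]]
    # with no sequencing error, every alt observation comes from a carrier
    # and every carrier read over the column shows the alt allele
    expect_true(all(alt_obs$accession %in% carriers))
    carrier_obs <- col[col$accession %in% carriers]
    expect_identical(nrow(carrier_obs), nrow(alt_obs))
  }
})

test_that("no indels means pure-match CIGARs; empty read sets give header-only SAM", {
  cfg <- simulation_config(n_unigenes = 2, unigene_len_range = c(300, 350),
                           indel_fraction = 0, variant_rate = 0.01,
                           reads_per_unigene = c(short = 30, long = 2),
                           read_len = c(short = 50, long = 200), seed = 40)
  ref <- simulate_reference(cfg)
  pl <- plant_variants(ref, cfg)
  sr <- simulate_reads(pl, cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  simulate_alignments(sr, pl, ref, cfg, sam)
  recs <- grep("^@", readLines(sam), invert = TRUE, value = TRUE)
  cigars <- vapply(strsplit(recs, "\t"), `[[`, "", 6)
  expect_true(all(grepl("^\\d+M$", cigars)))

  empty_cfg <- simulation_config(n_unigenes = 2,
                                 unigene_len_range = c(300, 350),
                                 reads_per_unigene = c(short = 0, long = 0),
                                 seed = 40)
  sr0 <- simulate_reads(pl, empty_cfg)
  simulate_alignments(sr0, pl, ref, empty_cfg, sam)
  expect_true(all(startsWith(readLines(sam), "@")))
})

test_that("annotation truth drives UCR and I30 outcomes on the fixtures", {
  cfg <- simulation_config(n_unigenes = 6, unigene_len_range = c(400, 500),
                           similarity_fraction = 1, intron_rate = 0,
                           seed = 41)
  ref <- simulate_reference(cfg)
  dir <- withr::local_tempdir()
  ann <- simulate_annotations(ref, cfg, dir)
  expect_true(all(ann$similarity_truth$flag == 1L))
  expect_identical(nrow(ann$intron_truth), 0L)
  contexts <- build_contexts(ref, list(), gff_path = ann$gff,
                             similarity_path = ann$similarity)
  s <- make_snv(unigene = names(ref)[1], pos = 200L)
  expect_false(filter_ucr(s, contexts[[1]]))      # every unigene flagged
  expect_true(filter_i30(s, contexts[[1]], 30))   # no boundaries annotated

  cfg2 <- simulation_config(n_unigenes = 6, unigene_len_range = c(400, 500),
                            similarity_fraction = 0, intron_rate = 1,
                            seed = 41)
  ann2 <- simulate_annotations(ref, cfg2, dir)
  contexts2 <- build_contexts(ref, list(), gff_path = ann2$gff,
                              similarity_path = ann2$similarity)
  expect_true(filter_ucr(s, contexts2[[1]]))
  # boundary positions come straight from the truth sidecar (0-based)
  tr <- ann2$intron_truth
  row <- tr[tr$unigene == names(ref)[1], ]
  expect_identical(contexts2[[1]]$intron_boundaries,
                   sort(c(row$start - 1L, row$end - 1L)))
})
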