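#' Simulation configuration
#'
#' Defines a complete synthetic study: unigene references, per-accession
#' planted variants, platform-specific reads with decaying quality profiles,
#' alignments, and annotations, all deterministic under `seed`. Defaults
#' describe a small transcriptome resequencing study: 20 unigenes of about
#' 1 kb, 8 accessions, roughly 30x short-read and 5x long-read coverage and
#' a 0.5% sequencing error rate.
#'
#' @param n_unigenes Number of reference unigenes.
#' @param unigene_len_range Length range (min, max) in bases.
#' @param n_accessions Number of accessions (plant lines).
#' @param variant_rate Per-base probability of planting a variant.
#' @param indel_fraction Fraction of planted variants that are indels.
#' @param allele_freq_spectrum data.frame with columns `freq` (fraction of
#'   accessions carrying the alternative allele) and `weight` (sampling
#'   weight).
#' @param reads_per_unigene Named vector, reads per unigene for `short` and
#'   `long` platforms.
#' @param read_len Named vector of read lengths per platform.
#' @param qual_profile Named list per platform: `c(start=, end=, sd=)`, the
#'   mean Phred quality at the first and last read position (linear decay)
#'   and its per-base standard deviation.
#' @param error_rate Mean per-base substitution error probability. Error
#'   positions are drawn proportionally to `10^(-q/10)` (errors concentrate
#'   where recorded confidence is low) and an erroneous base's recorded
#'   quality is resampled from 2-12, emulating a calibrated base caller.
#' @param adaptor_seq Adaptor sequence for contamination.
#' @param adaptor_rate Fraction of reads carrying the adaptor.
#' @param lowmapq_fraction Fraction of alignments assigned a mapping quality
#'   below 15, to exercise the caller's exclusion rule.
#' @param intron_rate Fraction of unigenes receiving an intron annotation.
#' @param similarity_fraction Fraction of unigenes flagged as similarity
#'   hits.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_unigenes = 20,
                              unigene_len_range = c(900, 1100),
                              n_accessions = 8,
                              variant_rate = 0.01,
                              indel_fraction = 0.1,
                              allele_freq_spectrum = data.frame(
                                freq = c(0.5, 0.25, 0.125),
                                weight = c(1, 1, 1)),
                              reads_per_unigene = c(short = 400, long = 13),
                              read_len = c(short = 75, long = 400),
                              qual_profile = list(
                                short = c(start = 38, end = 22, sd = 3),
                                long = c(start = 35, end = 20, sd = 4)),
                              error_rate = 0.005,
                              adaptor_seq = "AGATCGGAAGAGC",
                              adaptor_rate = 0,
                              lowmapq_fraction = 0.1,
                              intron_rate = 0.5,
                              similarity_fraction = 0.2,
                              seed = 42) {
  stopifnot(n_unigenes >= 0, n_accessions >= 1,
            variant_rate >= 0, variant_rate <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            error_rate >= 0, error_rate <= 1,
            adaptor_rate >= 0, adaptor_rate <= 1,
            lowmapq_fraction >= 0, lowmapq_fraction <= 1,
            all(c("short", "long") %in% names(reads_per_unigene)),
            all(c("short", "long") %in% names(read_len)))
  structure(list(n_unigenes = n_unigenes,
                 unigene_len_range = unigene_len_range,
                 n_accessions = n_accessions, variant_rate = variant_rate,
                 indel_fraction = indel_fraction,
                 allele_freq_spectrum = allele_freq_spectrum,
                 reads_per_unigene = reads_per_unigene, read_len = read_len,
                 qual_profile = qual_profile, error_rate = error_rate,
                 adaptor_seq = toupper(adaptor_seq),
                 adaptor_rate = adaptor_rate,
                 lowmapq_fraction = lowmapq_fraction,
                 intron_rate = intron_rate,
                 similarity_fraction = similarity_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

sim_accessions <- function(config) {
  sprintf("acc%02d", seq_len(config$n_accessions))
}

#' Simulate a unigene reference
#'
#' @param config A [simulation_config()].
#' @return A `DNAStringSet` of random unigene sequences, deterministic under
#'   the config seed.
#' @export
simulate_reference <- function(config = simulation_config()) {
  withr::with_seed(config$seed + 1L, {
    if (config$n_unigenes == 0L) {
      return(Biostrings::DNAStringSet())
    }
    span <- config$unigene_len_range[2] - config$unigene_len_range[1] + 1L
    lens <- config$unigene_len_range[1] +
      sample.int(span, config$n_unigenes, replace = TRUE) - 1L
    seqs <- vapply(lens, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, "")
    stats::setNames(Biostrings::DNAStringSet(seqs),
                    sprintf("unigene%03d", seq_len(config$n_unigenes)))
  })
}

# keep candidate positions at least `spacing` apart (greedy left-to-right)
thin_positions <- function(pos, spacing) {
  keep <- integer(0)
  last <- -Inf
  for (p in pos) {
    if (p - last >= spacing) {
      keep <- c(keep, p)
      last <- p
    }
  }
  keep
}

#' Plant variants into per-accession haplotypes
#'
#' Variant positions are drawn per base at `variant_rate` (kept at least
#' 4 bp apart and at least 5 bp from the unigene ends so deletion spans stay
#' disjoint and VCF anchoring is well defined). Each variant is a SNP or, at
#' `indel_fraction`, a 1-3 bp insertion or deletion; its alternative allele
#' is assigned to a random subset of accessions sized by a draw from the
#' allele frequency spectrum.
#'
#' @param reference `DNAStringSet` from [simulate_reference()].
#' @param config A [simulation_config()].
#' @return A list with `haplotypes` (nested list
#'   `[[unigene]][[accession]] = list(seq, map)`, `map` giving each
#'   haplotype base's 0-based reference position, `NA` for inserted bases)
#'   and `truth`, the ground-truth data.frame (unigene, pos, ref, alt, kind,
#'   accessions, freq).
#' @export
plant_variants <- function(reference, config = simulation_config()) {
  accs <- sim_accessions(config)
  names(reference) <- sub("\\s.*$", "", names(reference))
  withr::with_seed(config$seed + 2L, {
    truth <- list()
    haplotypes <- list()
    for (uni in names(reference)) {
      refstr <- as.character(reference[[uni]])
      len <- nchar(refstr)
      cand <- which(stats::runif(len) < config$variant_rate) - 1L  # 0-based
      cand <- cand[cand >= 5L & cand <= len - 6L]
      pos <- thin_positions(cand, 4L)
      vars <- lapply(pos, function(p) {
        ref_char <- substr(refstr, p + 1L, p + 1L)
        is_indel <- stats::runif(1) < config$indel_fraction
        if (!is_indel) {
          kind <- "snp"
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref_char), 1L)
          ref_allele <- ref_char
        } else if (stats::runif(1) < 0.5) {
          kind <- "insertion"
          alt <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1L),
                              replace = TRUE), collapse = "")
          ref_allele <- ref_char
        } else {
          kind <- "deletion"
          d <- sample(1:3, 1L)
          alt <- substr(refstr, p + 1L, p + d)  # the deleted bases
          ref_allele <- alt
        }
        spec <- config$allele_freq_spectrum
        freq <- sample(spec$freq, 1L, prob = spec$weight)
        k <- max(1L, round(freq * config$n_accessions))
        carriers <- sort(sample(accs, k))
        list(pos = p, kind = kind, ref = ref_allele, alt = alt,
             carriers = carriers, freq = k / config$n_accessions)
      })
      if (length(vars)) {
        truth[[uni]] <- data.frame(
          unigene = uni,
          pos = vapply(vars, `[[`, 0L, "pos"),
          ref = vapply(vars, `[[`, "", "ref"),
          alt = vapply(vars, `[[`, "", "alt"),
          kind = vapply(vars, `[[`, "", "kind"),
          accessions = vapply(vars, function(v) {
            paste(v$carriers, collapse = ",")
          }, ""),
          freq = vapply(vars, `[[`, 0, "freq"))
      }
      haplotypes[[uni]] <- lapply(stats::setNames(accs, accs), function(a) {
        chars <- strsplit(refstr, "")[[1]]
        map <- seq_len(len) - 1L
        for (v in rev(vars)) {   # right-to-left keeps earlier coordinates valid
          if (!a %in% v$carriers) next
          i <- v$pos + 1L        # 1-based
          if (v$kind == "snp") {
            chars[i] <- v$alt
          } else if (v$kind == "insertion") {
            ins <- strsplit(v$alt, "")[[1]]
            chars <- append(chars, ins, after = i)
            map <- append(map, rep(NA_integer_, length(ins)), after = i)
          } else {
            drop <- i:(i + nchar(v$alt) - 1L)
            chars <- chars[-drop]
            map <- map[-drop]
          }
        }
        list(seq = paste(chars, collapse = ""), map = map)
      })
    }
    truth <- if (length(truth)) {
      do.call(rbind, c(truth, make.row.names = FALSE))
    } else {
      data.frame(unigene = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), kind = character(0),
                 accessions = character(0), freq = numeric(0))
    }
    list(haplotypes = haplotypes, truth = truth)
  })
}

sim_library <- function(accession, platform) {
  paste0(accession, "_", platform, "lib")
}

#' Simulate reads from planted haplotypes
#'
#' Reads are sampled uniformly along each haplotype (start and end adjusted
#' onto reference-mapped bases so alignments need no clipping), with
#' linearly decaying mean quality plus Gaussian noise, substitution errors
#' placed proportionally to `10^(-q/10)` (erroneous bases get their quality
#' resampled low), and optional adaptor contamination with the planted
#' position recorded in the truth table.
#'
#' @param planted Result of [plant_variants()].
#' @param config A [simulation_config()].
#' @param platforms Platforms to simulate.
#' @return A list with `reads` (list of [seq_read()]) and `truth`
#'   (data.frame: read_id, unigene, accession, library, platform, hap_start,
#'   core_len, n_errors, adaptor_side, adaptor_len).
#' @export
simulate_reads <- function(planted, config = simulation_config(),
                           platforms = c("short", "long")) {
  haps <- planted$haplotypes
  withr::with_seed(config$seed + 3L, {
    reads <- list()
    rows <- list()
    counter <- 0L
    for (uni in names(haps)) {
      for (platform in platforms) {
        n_reads <- config$reads_per_unigene[[platform]]
        prof <- config$qual_profile[[platform]]
        for (i in seq_len(n_reads)) {
          acc <- sample(names(haps[[uni]]), 1L)
          hap <- haps[[uni]][[acc]]
          hap_len <- nchar(hap$seq)
          L <- min(config$read_len[[platform]], hap_len)
          s <- sample.int(hap_len - L + 1L, 1L) - 1L  # 0-based hap start
          # nudge endpoints onto reference-mapped bases
          while (s + 1L <= hap_len && is.na(hap$map[s + 1L])) s <- s + 1L
          while (L > 1L && is.na(hap$map[s + L])) L <- L - 1L
          if (s + L > hap_len || L < 1L) next
          bases <- strsplit(substr(hap$seq, s + 1L, s + L), "")[[1]]
          mq <- prof[["start"]] +
            (prof[["end"]] - prof[["start"]]) * (seq_len(L) - 1L) / max(1L, L - 1L)
          q <- pmin(40L, pmax(2L, as.integer(round(
            stats::rnorm(L, mean = mq, sd = prof[["sd"]])))))
          n_err <- 0L
          if (config$error_rate > 0) {
            p <- 10^(-q / 10)
            perr <- pmin(1, p * config$error_rate * L / sum(p))
            err <- which(stats::runif(L) < perr)
            n_err <- length(err)
            for (e in err) {
              bases[e] <- sample(setdiff(c("A", "C", "G", "T"), bases[e]), 1L)
              q[e] <- sample(2:12, 1L)
            }
          }
          counter <- counter + 1L
          id <- sprintf("%s_%s_r%05d", uni, platform, counter)
          bstr <- paste(bases, collapse = "")
          ad_side <- "none"; ad_len <- 0L
          if (config$adaptor_rate > 0 &&
              stats::runif(1) < config$adaptor_rate) {
            ad <- config$adaptor_seq
            ad_len <- nchar(ad)
            adq <- pmin(40L, pmax(2L, as.integer(round(
              stats::rnorm(ad_len, mean = 33, sd = 3)))))
            if (stats::runif(1) < 0.5) {
              ad_side <- "5p"
              bstr <- paste0(ad, bstr)
              q <- c(adq, q)
            } else {
              ad_side <- "3p"
              bstr <- paste0(bstr, ad)
              q <- c(q, adq)
            }
          }
          reads[[counter]] <- seq_read(id, bstr, q, platform = platform)
          rows[[counter]] <- data.frame(
            read_id = id, unigene = uni, accession = acc,
            library = sim_library(acc, platform), platform = platform,
            hap_start = s, core_len = L, n_errors = n_err,
            adaptor_side = ad_side, adaptor_len = ad_len)
        }
      }
    }
    list(reads = reads,
         truth = if (length(rows)) {
           do.call(rbind, c(rows, make.row.names = FALSE))
         } else {
           data.frame(read_id = character(0), unigene = character(0),
                      accession = character(0), library = character(0),
                      platform = character(0), hap_start = integer(0),
                      core_len = integer(0), n_errors = integer(0),
                      adaptor_side = character(0), adaptor_len = integer(0))
         })
  })
}

# CIGAR for a haplotype slice given its reference map (NA = inserted base)
cigar_from_map <- function(map_slice) {
  n <- length(map_slice)
  ops <- character(0)
  lens <- integer(0)
  push <- function(op, len) {
    if (length(ops) && ops[length(ops)] == op) {
      lens[length(lens)] <<- lens[length(lens)] + len
    } else {
      ops <<- c(ops, op)
      lens <<- c(lens, len)
    }
  }
  ins_run <- rle(is.na(map_slice))
  idx <- 1L
  for (k in seq_along(ins_run$lengths)) {
    len <- ins_run$lengths[k]
    if (ins_run$values[k]) {
      push("I", len)
      idx <- idx + len
    } else {
      vals <- map_slice[idx:(idx + len - 1L)]
      # deletions appear as jumps inside a mapped run
      jumps <- which(diff(vals) > 1L)
      seg_start <- 1L
      for (j in c(jumps, len)) {
        push("M", j - seg_start + 1L)
        if (j < len) push("D", vals[j + 1L] - vals[j] - 1L)
        seg_start <- j + 1L
      }
      idx <- idx + len
    }
  }
  paste0(lens, ops, collapse = "")
}

#' Write simulated alignments as a coordinate-sorted SAM file
#'
#' Each read is placed at its true origin; the CIGAR is derived from the
#' accession haplotype's planted indels, so the caller is exercised in
#' isolation from mapping error. Read groups carry the accession (`SM`),
#' library (`LB`) and platform (`PL`); a configurable fraction of
#' alignments receives a mapping quality below 15 to exercise the caller's
#' exclusion rule.
#'
#' @param sim_reads Result of [simulate_reads()].
#' @param planted Result of [plant_variants()].
#' @param reference The reference `DNAStringSet`.
#' @param config A [simulation_config()].
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
simulate_alignments <- function(sim_reads, planted, reference,
                                config = simulation_config(), path) {
  names(reference) <- sub("\\s.*$", "", names(reference))
  truth <- sim_reads$truth
  reads <- sim_reads$reads
  withr::with_seed(config$seed + 4L, {
    n <- nrow(truth)
    lines <- character(n)
    unis <- character(n)
    poss <- integer(n)
    for (i in seq_len(n)) {
      tr <- truth[i, ]
      r <- reads[[i]]
      # strip adaptor contamination: alignments carry the core read
      core_q <- r$quals
      core_b <- r$bases
      if (tr$adaptor_side == "5p") {
        core_b <- substr(core_b, tr$adaptor_len + 1L, nchar(core_b))
        core_q <- core_q[-seq_len(tr$adaptor_len)]
      } else if (tr$adaptor_side == "3p") {
        keep <- nchar(core_b) - tr$adaptor_len
        core_b <- substr(core_b, 1L, keep)
        core_q <- core_q[seq_len(keep)]
      }
      hap <- planted$haplotypes[[tr$unigene]][[tr$accession]]
      map_slice <- hap$map[(tr$hap_start + 1L):(tr$hap_start + tr$core_len)]
      cigar <- cigar_from_map(map_slice)
      ref_start <- map_slice[!is.na(map_slice)][1L]
      mapq <- if (stats::runif(1) < config$lowmapq_fraction) {
        sample(0:14, 1L)
      } else {
        60L
      }
      unis[i] <- tr$unigene
      poss[i] <- ref_start + 1L
      lines[i] <- paste(tr$read_id, 0L, tr$unigene, ref_start + 1L, mapq,
                        cigar, "*", 0L, 0L, core_b,
                        phred_int_to_chars(core_q),
                        paste0("RG:Z:", tr$accession, ".", tr$platform),
                        sep = "\t")
    }
    rgs <- unique(truth[, c("accession", "library", "platform")])
    rgs <- rgs[order(rgs$accession, rgs$platform), , drop = FALSE]
    hdr <- c(
      "@HD\tVN:1.6\tSO:coordinate",
      sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
              Biostrings::width(reference)),
      sprintf("@RG\tID:%s.%s\tSM:%s\tLB:%s\tPL:%s",
              rgs$accession, rgs$platform, rgs$accession, rgs$library,
              ifelse(rgs$platform == "long", "SANGER", "ILLUMINA")))
    ord <- order(match(unis, names(reference)), poss)
    writeLines(c(hdr, lines[ord]), path)
  })
  invisible(path)
}

#' Simulate annotations: introns, similarity report, enzyme table
#'
#' @param reference The reference `DNAStringSet`.
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @return Named list of paths (`gff`, `similarity`, `enzymes`,
#'   `truth_introns`) plus `intron_truth` and `similarity_truth`
#'   data.frames.
#' @export
simulate_annotations <- function(reference, config = simulation_config(),
                                 dir) {
  names(reference) <- sub("\\s.*$", "", names(reference))
  withr::with_seed(config$seed + 5L, {
    gff_path <- file.path(dir, "annotations.gff3")
    sim_path <- file.path(dir, "similarity.tsv")
    enz_path <- file.path(dir, "enzymes.tsv")
    intron_rows <- list()
    for (uni in names(reference)) {
      len <- Biostrings::width(reference[uni])
      if (len < 120L || stats::runif(1) >= config$intron_rate) next
      a <- sample(50:(len - 70L), 1L)
      b <- a + sample(20:50, 1L)
      intron_rows[[uni]] <- data.frame(unigene = uni, start = a, end = min(b, len - 10L))
    }
    introns <- if (length(intron_rows)) {
      do.call(rbind, c(intron_rows, make.row.names = FALSE))
    } else {
      data.frame(unigene = character(0), start = integer(0), end = integer(0))
    }
    if (nrow(introns)) {
      gr <- GenomicRanges::GRanges(
        seqnames = introns$unigene,
        ranges = IRanges::IRanges(start = introns$start, end = introns$end),
        type = "intron", source = "snvmine_sim")
      rtracklayer::export(gr, gff_path, format = "gff3")
    } else {
      writeLines("##gff-version 3", gff_path)
    }
    flags <- as.integer(stats::runif(length(reference)) <
                          config$similarity_fraction)
    sim_tab <- data.frame(unigene_id = names(reference), flag = flags)
    utils::write.table(sim_tab, sim_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.copy(system.file("extdata", "restriction_enzymes.tsv",
                          package = "snvmine", mustWork = TRUE),
              enz_path, overwrite = TRUE)
    truth_introns_path <- file.path(dir, "truth_introns.tsv")
    utils::write.table(introns, truth_introns_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(gff = gff_path, similarity = sim_path, enzymes = enz_path,
         truth_introns = truth_introns_path, intron_truth = introns,
         similarity_truth = sim_tab)
  })
}

#' Materialize a complete synthetic test project
#'
#' Writes the full fixture set — reference FASTA, planted-variant truth
#' table, per-platform FASTQ files with read-origin truth, a
#' coordinate-sorted SAM, and annotation files — into a directory. All
#' outputs are byte-identical under a fixed config seed.
#'
#' @param config A [simulation_config()].
#' @param dir Target directory (created if absent).
#' @return Named list of file paths, invisibly, with the in-memory `truth`
#'   tables attached.
#' @export
simulate_project <- function(config = simulation_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_reference(config)
  planted <- plant_variants(reference, config)
  sim_reads <- simulate_reads(planted, config)
  paths <- list(
    reference = file.path(dir, "reference.fasta"),
    reads_short = file.path(dir, "reads_short.fastq"),
    reads_long = file.path(dir, "reads_long.fastq"),
    alignments = file.path(dir, "alignments.sam"),
    truth_variants = file.path(dir, "truth_variants.tsv"),
    truth_reads = file.path(dir, "truth_reads.tsv"))
  Biostrings::writeXStringSet(reference, paths$reference)
  platforms <- vapply(sim_reads$reads, `[[`, "", "platform")
  write_fastq(sim_reads$reads[platforms == "short"], paths$reads_short)
  write_fastq(sim_reads$reads[platforms == "long"], paths$reads_long)
  simulate_alignments(sim_reads, planted, reference, config,
                      paths$alignments)
  utils::write.table(planted$truth, paths$truth_variants, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim_reads$truth, paths$truth_reads, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann <- simulate_annotations(reference, config, dir)
  paths <- c(paths, ann[c("gff", "similarity", "enzymes", "truth_introns")])
  out <- paths
  out$truth <- planted$truth
  out$read_truth <- sim_reads$truth
  invisible(out)
}
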