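#' Load mapped reads from a SAM or BAM file
#'
#' SAM input is converted to BAM with Rsamtools and scanned; read-group tags
#' provide the accession (`SM`) and library (`LB`) labels the caller and the
#' polymorphism statistics rely on, and the platform class is taken from the
#' read group `PL` (`SANGER`/`LS454`/`CAPILLARY` map to `"long"`, everything
#' else to `"short"`).
#'
#' @param path SAM or BAM file.
#' @return A list with `records` (data.table of alignments: qname, unigene,
#'   pos (1-based leftmost), mapq, cigar, seq, qual, accession, library,
#'   platform) and `ref_lengths` (named integer vector from the header).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort_missing_input("alignment file not found: ", path)
  bam <- if (grepl("\\.sam(\\.gz)?$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), indexDestination = FALSE)
  } else {
    path
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  ref_lengths <- hdr$targets
  rg_lines <- hdr$text[names(hdr$text) == "@RG"]
  rg_map <- list()
  for (ln in rg_lines) {
    fields <- strsplit(ln, ":", fixed = TRUE)
    kv <- stats::setNames(
      vapply(fields, function(f) paste(f[-1], collapse = ":"), ""),
      vapply(fields, `[[`, "", 1L))
    if (!"ID" %in% names(kv)) next
    pl <- toupper(kv["PL"] %||% "")
    rg_map[[kv[["ID"]]]] <- list(
      accession = unname(kv["SM"]),
      library = unname(kv["LB"]),
      platform = if (isTRUE(pl %in% c("SANGER", "LS454", "CAPILLARY", "454",
                                      "PACBIO", "ONT"))) "long" else "short")
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "RG")
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  mapped <- !is.na(b$pos) & !bitwAnd(b$flag, 4L)
  rg <- b$tag$RG
  if (is.null(rg)) rg <- rep(NA_character_, length(b$pos))
  lookup <- function(id, field, default) {
    if (!is.na(id) && !is.null(rg_map[[id]])) {
      v <- rg_map[[id]][[field]]
      if (!is.null(v) && !is.na(v)) return(v)
    }
    default
  }
  recs <- data.table::data.table(
    qname = b$qname[mapped],
    unigene = as.character(b$rname[mapped]),
    pos = b$pos[mapped],
    mapq = b$mapq[mapped],
    cigar = b$cigar[mapped],
    seq = as.character(b$seq)[mapped],
    qual = as.character(b$qual)[mapped],
    rg = rg[mapped])
  if (nrow(recs)) {
    acc <- vapply(recs$rg, lookup, "", field = "accession", default = NA_character_)
    if (anyNA(acc)) {
      warning("alignments without an accession-labelled read group; ",
              "assigning accession 'unknown'")
      acc[is.na(acc)] <- "unknown"
    }
    recs[, `:=`(
      accession = acc,
      library = vapply(rg, lookup, "", field = "library", default = "unknown"),
      platform = vapply(rg, lookup, "", field = "platform", default = "short"),
      rg = NULL)]
  }
  list(records = recs, ref_lengths = ref_lengths)
}

parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]", "", ops)),
       op = sub("\\d+", "", ops))
}

#' Build per-position pileups from mapped reads
#'
#' Walks each alignment's CIGAR and emits one allele observation per aligned
#' base or indel event. Insertions are attached to the column of the base to
#' their left; deletions to the column of their first deleted base; the base
#' quality recorded for an indel is that of the flanking (preceding) read
#' base. Observations whose base call is `N` are discarded. Alignments must
#' arrive coordinate-sorted within each reference; unsorted input is an
#' error.
#'
#' @param alignments Result of [read_alignments()].
#' @param reference A `DNAStringSet` of unigene sequences (names matching the
#'   alignment references).
#' @return An object of class `snv_pileup`: a list with `observations` (a
#'   data.table with columns unigene, pos (0-based), ref_base, kind
#'   (`ref`/`snp`/`insertion`/`deletion`), seq, base_qual, map_qual,
#'   accession, library, platform), `ref_lengths`, and `reference`.
#' @export
build_pileups <- function(alignments, reference) {
  recs <- alignments$records
  ref_names <- sub("\\s.*$", "", names(reference))
  names(reference) <- ref_names
  ref_lengths <- alignments$ref_lengths
  if (nrow(recs)) {
    split_pos <- split(recs$pos, recs$unigene)
    if (any(vapply(split_pos, is.unsorted, TRUE))) {
      abort_format("alignments are not coordinate-sorted; ",
                   "sort the SAM/BAM before building pileups")
    }
  }
  ref_chars <- lapply(as.character(reference), function(s) strsplit(s, "")[[1]])
  out <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    uni <- recs$unigene[i]
    rc <- ref_chars[[uni]]
    if (is.null(rc)) {
      abort_format("alignment reference '", uni, "' absent from the FASTA")
    }
    cg <- parse_cigar(recs$cigar[i])
    seq_chars <- strsplit(recs$seq[i], "")[[1]]
    quals <- phred_chars_to_int(recs$qual[i])
    rpos <- recs$pos[i] - 1L  # 0-based reference cursor
    qpos <- 1L                # 1-based read cursor
    rows <- vector("list", length(cg$op))
    for (k in seq_along(cg$op)) {
      op <- cg$op[k]; len <- cg$len[k]
      if (op %in% c("M", "=", "X")) {
        p <- rpos + seq_len(len) - 1L
        rows[[k]] <- data.table::data.table(
          pos = p,
          ref_base = rc[p + 1L],
          kind = "snp",
          seq = seq_chars[qpos + seq_len(len) - 1L],
          base_qual = quals[qpos + seq_len(len) - 1L])
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "I") {
        flank <- if (qpos > 1L) qpos - 1L else qpos
        if (rpos > 0L) {
          rows[[k]] <- data.table::data.table(
            pos = rpos - 1L,
            ref_base = rc[rpos],
            kind = "insertion",
            seq = paste(seq_chars[qpos + seq_len(len) - 1L], collapse = ""),
            base_qual = quals[flank])
        }
        qpos <- qpos + len
      } else if (op == "D") {
        flank <- if (qpos > 1L) qpos - 1L else qpos
        rows[[k]] <- data.table::data.table(
          pos = rpos,
          ref_base = rc[rpos + 1L],
          kind = "deletion",
          seq = paste(rc[rpos + seq_len(len)], collapse = ""),
          base_qual = quals[flank])
        rpos <- rpos + len
      } else if (op == "N") {
        rpos <- rpos + len
      } else if (op == "S") {
        qpos <- qpos + len
      }  # H, P: no cursor movement
    }
    dt <- data.table::rbindlist(rows)
    if (nrow(dt)) {
      dt[kind == "snp" & seq == ref_base, kind := "ref"]
      dt <- dt[!(kind %in% c("ref", "snp") & seq == "N")]
      dt[, `:=`(unigene = uni, map_qual = recs$mapq[i],
                accession = recs$accession[i], library = recs$library[i],
                platform = recs$platform[i])]
    }
    out[[i]] <- dt
  }
  obs <- data.table::rbindlist(out)
  if (!nrow(obs)) {
    obs <- data.table::data.table(
      unigene = character(0), pos = integer(0), ref_base = character(0),
      kind = character(0), seq = character(0), base_qual = integer(0),
      map_qual = integer(0), accession = character(0), library = character(0),
      platform = character(0))
  }
  if (nrow(obs)) {
    data.table::setcolorder(obs, c("unigene", "pos", "ref_base", "kind", "seq",
                                   "base_qual", "map_qual", "accession",
                                   "library", "platform"))
    data.table::setorder(obs, unigene, pos)
  }
  structure(list(observations = obs, ref_lengths = ref_lengths,
                 reference = reference),
            class = "snv_pileup")
}

#' @export
print.snv_pileup <- function(x, ...) {
  cat(sprintf("<snv_pileup: %d observations over %d reference sequences>\n",
              nrow(x$observations), length(x$ref_lengths)))
  invisible(x)
}

#' Extract one pileup column
#'
#' @param pileup An `snv_pileup`.
#' @param unigene Reference id.
#' @param pos 0-based position.
#' @return A data.table of the observations at that position (possibly empty).
#' @export
pileup_column <- function(pileup, unigene, pos) {
  u <- unigene; p <- pos
  pileup$observations[unigene == u & pos == p]
}

#' Per-position coverage histogram
#'
#' Coverage counts aligned bases (CIGAR `M` columns) per reference position;
#' positions with no aligned base contribute to the zero bin, so the
#' histogram always accounts for every reference position.
#'
#' @param pileup An `snv_pileup` from [build_pileups()].
#' @return A data.frame with columns `coverage` and `n_positions`.
#' @export
coverage_distribution <- function(pileup) {
  obs <- pileup$observations[kind %in% c("ref", "snp")]
  cov <- obs[, .N, by = .(unigene, pos)]
  total_pos <- sum(pileup$ref_lengths)
  tab <- table(cov$N)
  covered <- data.frame(coverage = as.integer(names(tab)),
                        n_positions = as.integer(tab))
  zero <- total_pos - nrow(cov)
  out <- rbind(data.frame(coverage = 0L, n_positions = as.integer(zero)), covered)
  out[out$n_positions > 0L | out$coverage == 0L, , drop = FALSE]
}
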