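vcf_filter_descriptions <- c(
  MAF = "Frequency of most frequent allele in the selected pool is less than the threshold",
  HVR = "Percentage of divergence in the unigene is smaller than or equal to the threshold",
  UCR = "No duplicated or fragment regions detected in the unigene similarity report",
  I30 = "Distance from intron/exon boundary is greater than the threshold",
  CL  = "Distance to the ends of the unigene is greater than the threshold",
  CS  = "Distance from neighboring SNVs is greater than the threshold",
  CEF = "The SNV can be detected by endonuclease restriction (CAPS)",
  VK  = "The SNV is of the selected marker kind (SNP or indel)",
  GF  = "Frequency of most frequent allele in the selected libraries is less than the threshold")

# 0-based replacement interval of an allele relative to its pileup column
allele_interval <- function(kind, seq, pos) {
  switch(kind,
         ref = list(start = pos, end = pos + 1L, repl = seq),
         snp = list(start = pos, end = pos + 1L, repl = seq),
         insertion = list(start = pos + 1L, end = pos + 1L, repl = seq),
         deletion = list(start = pos, end = pos + nchar(seq), repl = ""))
}

fmt_num <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE), "")
}

encode_counts <- function(counts) {
  # per-allele "label:count|label:count", alleles joined by ","
  paste(vapply(counts, function(cc) {
    paste(paste0(names(cc), ":", cc), collapse = "|")
  }, ""), collapse = ",")
}

decode_counts <- function(s) {
  lapply(strsplit(s, ",", fixed = TRUE)[[1]], function(part) {
    kv <- strsplit(strsplit(part, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(vapply(kv, function(x) as.integer(x[[2]]), 1L),
                    vapply(kv, `[[`, "", 1L))
  })
}

vcf_record <- function(snv, ref_seq) {
  al <- snv$alleles
  alt_idx <- which(al$kind != "ref")
  pos <- snv$pos
  has_indel <- any(al$kind %in% c("insertion", "deletion"))
  refstr <- as.character(ref_seq)
  if (!has_indel) {
    vpos <- pos + 1L
    ref_field <- substr(refstr, pos + 1L, pos + 1L)
    alt_field <- al$seq[alt_idx]
  } else {
    iv <- lapply(seq_len(nrow(al)),
                 function(i) allele_interval(al$kind[i], al$seq[i], pos))
    starts <- vapply(iv[alt_idx], `[[`, 0L, "start")
    ends <- vapply(iv[alt_idx], `[[`, 0L, "end")
    start0 <- min(starts); end0 <- max(ends)
    if (start0 > 0L) {
      a <- start0 - 1L
      vpos <- a + 1L
      ref_field <- substr(refstr, a + 1L, end0)
      alt_field <- vapply(iv[alt_idx], function(v) {
        paste0(substr(refstr, a + 1L, v$start), v$repl,
               substr(refstr, v$end + 1L, end0))
      }, "")
    } else {
      # variant at the very start of the unigene: anchor on the right
      if (end0 >= nchar(refstr)) {
        abort_format("cannot anchor indel at ", snv$unigene, ":", pos)
      }
      vpos <- 1L
      ref_field <- substr(refstr, 1L, end0 + 1L)
      alt_field <- vapply(iv[alt_idx], function(v) {
        paste0(substr(refstr, 1L, v$start), v$repl,
               substr(refstr, v$end + 1L, end0 + 1L))
      }, "")
    }
  }
  ra <- which(al$kind == "ref")
  info <- paste0(
    "CP=", pos,
    ";RA=", if (length(ra)) ra else 0L,
    ";AK=", paste(substr(al$kind, 1, 1), collapse = ","),
    ";AS=", paste(al$seq, collapse = ","),
    ";AQ=", paste(fmt_num(al$quality), collapse = ","),
    ";RC=", paste(al$read_count, collapse = ","),
    ";ACS=", encode_counts(snv$acc_counts),
    ";LCS=", encode_counts(snv$lib_counts),
    ";PCS=", encode_counts(snv$plat_counts))
  filt <- if (!length(snv$filters)) {
    "."
  } else if (all(snv$filters)) {
    "PASS"
  } else {
    paste(names(snv$filters)[!snv$filters], collapse = ";")
  }
  paste(snv$unigene, vpos, ".", ref_field,
        paste(alt_field, collapse = ","),
        fmt_num(min(al$quality)), filt, info, sep = "\t")
}

#' Write called SNVs to a VCF file
#'
#' Positions are converted to 1-based VCF coordinates; indel records are
#' anchored on the preceding reference base per VCF convention. Every applied
#' filter appears as a `FILTER` header line and failed filters are listed
#' per record (all pass = `PASS`; no filters applied = `.`). Allele
#' qualities, read counts and the per-accession / per-library / per-platform
#' supporting counts travel in declared `INFO` fields, making the records
#' lossless for [read_vcf()].
#'
#' @param snvs An `snv_set` (or list of `snv` objects), coordinate-sorted.
#' @param path Output path.
#' @param reference `DNAStringSet` of unigenes; defaults to the set attached
#'   to `snvs`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snvs, path, reference = attr(snvs, "reference")) {
  if (is.null(reference)) abort_missing_input("write_vcf() needs the reference")
  names(reference) <- sub("\\s.*$", "", names(reference))
  if (length(snvs)) {
    uni <- vapply(snvs, `[[`, "", "unigene")
    pos <- vapply(snvs, `[[`, 0L, "pos")
    o <- order(match(uni, names(reference)), pos)
    if (any(o != seq_along(o))) {
      abort_format("SNVs must be coordinate-sorted before writing VCF")
    }
  }
  applied <- unique(unlist(lapply(snvs, function(s) names(s$filters))))
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=snvmine-", as.character(utils::packageVersion("snvmine"))),
    vapply(names(reference), function(nm) {
      sprintf("##contig=<ID=%s,length=%d>", nm, Biostrings::width(reference[nm]))
    }, ""),
    "##INFO=<ID=CP,Number=1,Type=Integer,Description=\"0-based pileup column position of the variant\">",
    "##INFO=<ID=RA,Number=1,Type=Integer,Description=\"1-based index of the reference allele among the listed alleles (0 if absent)\">",
    "##INFO=<ID=AK,Number=.,Type=String,Description=\"Allele kinds (r=reference,s=snp,i=insertion,d=deletion)\">",
    "##INFO=<ID=AS,Number=.,Type=String,Description=\"Allele sequences in pileup representation\">",
    "##INFO=<ID=AQ,Number=.,Type=Float,Description=\"Allele quality PQ1 + 0.25*(PQ2+PQ3)\">",
    "##INFO=<ID=RC,Number=.,Type=Integer,Description=\"Supporting read count per allele\">",
    "##INFO=<ID=ACS,Number=1,Type=String,Description=\"Per-allele accession read counts\">",
    "##INFO=<ID=LCS,Number=1,Type=String,Description=\"Per-allele library read counts\">",
    "##INFO=<ID=PCS,Number=1,Type=String,Description=\"Per-allele platform read counts\">",
    if (length(applied)) {
      vapply(applied, function(f) {
        sprintf("##FILTER=<ID=%s,Description=\"%s\">", f,
                vcf_filter_descriptions[f] %||% f)
      }, "")
    },
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- vapply(snvs, function(s) vcf_record(s, reference[[s$unigene]]), "")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

parse_info <- function(info) {
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                  vapply(kv, `[[`, "", 1L))
}

# minimal-common-prefix decomposition of one REF/ALT pair into a single event
decompose_alt <- function(vpos, ref_field, alt_field) {
  r <- strsplit(ref_field, "")[[1]]
  t <- strsplit(alt_field, "")[[1]]
  nr <- length(r); nt <- length(t)
  if (nr == nt) {
    d <- which(r != t)
    if (length(d) != 1L) abort_format("cannot decompose ", ref_field, ">", alt_field)
    return(list(kind = "snp", seq = t[d], pos = vpos - 1L + d - 1L))
  }
  if (nt > nr) {
    dlen <- nt - nr
    for (k in seq_len(nr)) {
      if (!all(r[seq_len(k)] == t[seq_len(k)])) break
      tail_r <- if (k < nr) r[(k + 1L):nr] else character(0)
      tail_t <- if (k + dlen < nt) t[(k + dlen + 1L):nt] else character(0)
      if (length(tail_r) == length(tail_t) && all(tail_r == tail_t)) {
        return(list(kind = "insertion",
                    seq = paste(t[(k + 1L):(k + dlen)], collapse = ""),
                    pos = vpos - 1L + k - 1L))
      }
    }
  } else {
    dlen <- nr - nt
    for (k in seq_len(nt)) {
      if (!all(r[seq_len(k)] == t[seq_len(k)])) break
      tail_r <- if (k + dlen < nr) r[(k + dlen + 1L):nr] else character(0)
      tail_t <- if (k < nt) t[(k + 1L):nt] else character(0)
      if (length(tail_r) == length(tail_t) && all(tail_r == tail_t)) {
        return(list(kind = "deletion",
                    seq = paste(r[(k + 1L):(k + dlen)], collapse = ""),
                    pos = vpos - 1L + k))
      }
    }
  }
  abort_format("cannot decompose ", ref_field, ">", alt_field)
}

#' Read a VCF file written by [write_vcf()] back into SNV records
#'
#' Reconstructs the full `snv` objects, including allele qualities, counts
#' and filter tags (failed filters from the FILTER column; applied filters
#' from the header). Files lacking the package's INFO annotation are
#' reconstructed from REF/ALT decomposition alone (alleles left-anchored).
#'
#' @param path VCF path.
#' @return An `snv_set` (list of `snv` objects); header contig lengths in
#'   attribute `contigs`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort_missing_input("VCF file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "##")]
  body <- lines[!startsWith(lines, "#")]
  contig_lines <- hdr[startsWith(hdr, "##contig=")]
  contigs <- stats::setNames(
    as.integer(sub(".*length=(\\d+).*", "\\1", contig_lines)),
    sub(".*ID=([^,>]+).*", "\\1", contig_lines))
  applied <- sub("##FILTER=<ID=([^,>]+).*", "\\1",
                 hdr[startsWith(hdr, "##FILTER=")])
  snvs <- lapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    vpos <- as.integer(f[2])
    info <- parse_info(f[8])
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    if (all(c("CP", "RA", "AK", "AS", "AQ", "RC") %in% names(info))) {
      kinds <- c(r = "ref", s = "snp", i = "insertion", d = "deletion")[
        strsplit(info[["AK"]], ",", fixed = TRUE)[[1]]]
      al <- data.frame(
        kind = unname(kinds),
        seq = strsplit(info[["AS"]], ",", fixed = TRUE)[[1]],
        quality = as.numeric(strsplit(info[["AQ"]], ",", fixed = TRUE)[[1]]),
        read_count = as.integer(strsplit(info[["RC"]], ",", fixed = TRUE)[[1]]),
        stringsAsFactors = FALSE)
      pos <- as.integer(info[["CP"]])
      acc <- decode_counts(info[["ACS"]])
      lib <- decode_counts(info[["LCS"]])
      plat <- decode_counts(info[["PCS"]])
    } else {
      ev <- lapply(alts, function(a) decompose_alt(vpos, f[4], a))
      pos <- ev[[1]]$pos
      al <- data.frame(
        kind = vapply(ev, `[[`, "", "kind"),
        seq = vapply(ev, `[[`, "", "seq"),
        quality = NA_real_, read_count = NA_integer_,
        stringsAsFactors = FALSE)
      acc <- lib <- plat <- rep(list(stats::setNames(integer(0), character(0))),
                                nrow(al))
    }
    alt_kinds <- al$kind[al$kind != "ref"]
    kind <- if (!length(alt_kinds) || all(alt_kinds == "snp")) {
      "snp"
    } else if (all(alt_kinds %in% c("insertion", "deletion"))) {
      "indel"
    } else {
      "complex"
    }
    filters <- stats::setNames(logical(0), character(0))
    if (f[7] != "." && length(applied)) {
      failed <- if (f[7] == "PASS") character(0) else
        strsplit(f[7], ";", fixed = TRUE)[[1]]
      filters <- stats::setNames(!(applied %in% failed), applied)
    }
    # the REF field spans reference positions (vpos-1)..(vpos-1+nchar-1),
    # 0-based, so the column's reference base sits at offset pos-(vpos-1)
    ref_base <- substr(f[4], pos - vpos + 2L, pos - vpos + 2L)
    structure(list(unigene = f[1], pos = pos, ref_base = ref_base,
                   alleles = al, acc_counts = acc, lib_counts = lib,
                   plat_counts = plat, kind = kind, filters = filters),
              class = "snv")
  })
  structure(snvs, class = "snv_set", contigs = contigs)
}
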