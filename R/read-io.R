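#' Construct a sequencing read
#'
#' A read couples a nucleotide string with per-base Phred qualities and a
#' platform class. `"short"` covers Illumina/SOLiD-style reads, `"long"`
#' Sanger/454-style reads; the two classes can be routed through different
#' cleaning parameters.
#'
#' @param id Character identifier.
#' @param bases Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param quals Integer vector of Phred qualities, one per base, in `[0, 93]`.
#' @param platform `"short"` or `"long"`.
#' @return An object of class `seq_read`.
#' @examples
#' seq_read("r1", "ACGT", c(30, 30, 35, 20))
#' @export
seq_read <- function(id, bases, quals, platform = c("short", "long")) {
  platform <- match.arg(platform)
  bases <- toupper(bases)
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals)) {
    abort_format("read '", id, "': bases (", nchar(bases),
                 ") and qualities (", length(quals), ") differ in length")
  }
  if (length(quals) && (min(quals) < 0L || max(quals) > 93L)) {
    abort_format("read '", id, "': qualities must lie in [0, 93]")
  }
  structure(list(id = id, bases = bases, quals = quals, platform = platform),
            class = "seq_read")
}

#' @export
print.seq_read <- function(x, ...) {
  cat(sprintf("<seq_read %s [%s] %d bp>\n", x$id, x$platform, read_length(x)))
  invisible(x)
}

#' Read length
#' @param read A [seq_read()].
#' @return Integer number of bases.
#' @export
read_length <- function(read) nchar(read$bases)

# 1-based inclusive slice; start > end yields the empty read.
subread <- function(read, start, end) {
  if (start > end) {
    read$bases <- ""
    read$quals <- integer(0)
  } else {
    read$bases <- substr(read$bases, start, end)
    read$quals <- read$quals[start:end]
  }
  read
}

#' Read a FASTQ file into a list of reads
#'
#' Only Sanger-style Phred+33 quality encoding is accepted. Files that look
#' Phred+64 encoded (all quality characters at or above `@` with some beyond
#' the Phred+33 range used by current instruments) are rejected with an
#' explicit error rather than silently mis-decoded.
#'
#' @param path FASTQ file path.
#' @param platform Platform class assigned to every read in the file.
#' @return List of [seq_read()] objects.
#' @export
read_fastq <- function(path, platform = c("short", "long")) {
  platform <- match.arg(platform)
  if (!file.exists(path)) abort_missing_input("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual_strings <- as.character(S4Vectors::mcols(x)$qualities)
  if (length(qual_strings)) {
    codes <- utf8ToInt(paste(qual_strings, collapse = ""))
    if (length(codes)) {
      if (min(codes) < 33L) {
        abort_format(path, ": quality characters below '!' are not valid Phred+33")
      }
      if (min(codes) >= 64L && max(codes) > 75L) {
        abort_format(path, ": qualities look Phred+64 encoded; ",
                     "only Phred+33 (Sanger) FASTQ is supported")
      }
    }
  }
  ids <- sub("\\s.*$", "", names(x))
  bases <- as.character(x)
  lapply(seq_along(x), function(i) {
    seq_read(ids[[i]], bases[[i]], phred_chars_to_int(qual_strings[[i]]),
             platform = platform)
  })
}

#' Write reads to a Phred+33 FASTQ file
#'
#' @param reads List of [seq_read()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * length(reads))
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    j <- 4L * (i - 1L)
    lines[j + 1L] <- paste0("@", r$id)
    lines[j + 2L] <- r$bases
    lines[j + 3L] <- "+"
    lines[j + 4L] <- phred_int_to_chars(r$quals)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read paired FASTA + QUAL files into reads
#'
#' The classic long-read (Sanger/454) deliverable: a FASTA of base calls and
#' a parallel `.qual` file of whitespace-separated integer qualities.
#'
#' @param fasta_path FASTA file path.
#' @param qual_path QUAL file path (same record ids, same order).
#' @param platform Platform class; long by default.
#' @return List of [seq_read()] objects.
#' @export
read_fasta_qual <- function(fasta_path, qual_path, platform = c("long", "short")) {
  platform <- match.arg(platform)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  lines <- readLines(qual_path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort_format(qual_path, ": no QUAL records found")
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  body <- vapply(split(lines[!hdr], rec[!hdr]), paste, "", collapse = " ")
  quals <- lapply(body, function(s) as.integer(strsplit(trimws(s), "\\s+")[[1]]))
  if (length(seqs) != length(quals)) {
    abort_format("FASTA and QUAL record counts differ (",
                 length(seqs), " vs ", length(quals), ")")
  }
  seq_ids <- sub("\\s.*$", "", names(seqs))
  lapply(seq_along(seqs), function(i) {
    if (seq_ids[[i]] != ids[[i]]) {
      abort_format("FASTA/QUAL id mismatch at record ", i, ": ",
                   seq_ids[[i]], " vs ", ids[[i]])
    }
    seq_read(seq_ids[[i]], as.character(seqs[[i]]), quals[[i]], platform = platform)
  })
}
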