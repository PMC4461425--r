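#' Read a FASTQ file
#'
#' Parses a plain or gzipped four-line-per-record FASTQ file with phred+33
#' quality encoding into a [read_set]. Record order is preserved and
#' qualities are decoded to integers.
#'
#' @param path path to a FASTQ file (plain or `.gz`).
#' @return A [read_set].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0) return(read_set())
  if (n %% 4 != 0)
    stop(sprintf("malformed FASTQ near record %d: %d leftover line(s)",
                 n %/% 4 + 1, n %% 4))
  hd <- lines[seq(1, n, by = 4)]
  sq <- lines[seq(2, n, by = 4)]
  pl <- lines[seq(3, n, by = 4)]
  qu <- lines[seq(4, n, by = 4)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d: header does not start with '@'",
                 bad[1]))
  bad <- which(!startsWith(pl, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d: separator does not start with '+'",
                 bad[1]))
  bad <- which(nchar(sq) != nchar(qu))
  if (length(bad))
    stop(sprintf(
      "malformed FASTQ record %d: sequence and quality lengths differ",
      bad[1]))
  id <- sub("\\s.*$", "", substring(hd, 2))
  qual <- lapply(qu, function(s) {
    if (!nzchar(s)) return(integer())
    as.integer(utf8ToInt(s)) - 33L
  })
  read_set(id = id, seq = sq, qual = qual)
}

#' Write a FASTQ file
#'
#' Writes a [read_set] as four-line FASTQ records with phred+33 qualities.
#'
#' @param reads a [read_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(reads$qual, function(q) {
    if (!length(q)) return("")
    intToUtf8(q + 33L)
  }, character(1))
  out <- character(4L * length(reads))
  if (length(reads)) {
    out[seq(1, length(out), by = 4)] <- paste0("@", reads$id)
    out[seq(2, length(out), by = 4)] <- reads$seq
    out[seq(3, length(out), by = 4)] <- "+"
    out[seq(4, length(out), by = 4)] <- qual
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an unaligned FASTA file
#'
#' Headers are split at the first whitespace to form `seq_id`. Sequences may
#' be wrapped over multiple lines; lowercase and `U` are normalised (see
#' [clean_sequence]). A record containing the gap character `-` is rejected:
#' use [read_aligned_fasta] for alignments.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `seq_id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  ids <- sub("\\s.*$", "", names(x))
  if (any(grepl("-", seqs, fixed = TRUE))) {
    bad <- which(grepl("-", seqs, fixed = TRUE))[1]
    stop(sprintf(
      "record %d ('%s') contains '-': aligned FASTA, use read_aligned_fasta()",
      bad, ids[bad]))
  }
  if (any(grepl("[^A-Za-z]", seqs, perl = TRUE))) {
    bad <- which(grepl("[^A-Za-z]", seqs, perl = TRUE))[1]
    stop(sprintf("record %d ('%s') contains non-letter characters",
                 bad, ids[bad]))
  }
  data.frame(seq_id = ids, sequence = clean_sequence(seqs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' Sequences are wrapped at 80 columns. `x` may be a named character vector
#' or a data.frame whose first two columns are id and sequence (such as the
#' output of [read_fasta]).
#'
#' @param x sequences to write.
#' @param path output path.
#' @param width line-wrap width in columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  if (is.data.frame(x)) x <- setNames(as.character(x[[2]]), as.character(x[[1]]))
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read an aligned FASTA file (MSA)
#'
#' All rows must have equal gapped width; the gap character is `-`.
#'
#' @param path path to an aligned FASTA file.
#' @return data.frame with columns `seq_id` and `gapped_sequence`; the
#'   common row width is attached as attribute `width`.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  w <- nchar(seqs)
  if (length(w) && length(unique(w)) != 1L)
    stop(sprintf("ragged alignment: row widths %s",
                 paste(unique(w), collapse = ", ")))
  ung <- gsub("-", "", seqs, fixed = TRUE)
  if (any(grepl("[^ACGTNU]", ung, perl = TRUE)))
    stop("alignment rows contain characters outside {A,C,G,T,N,U,-}")
  seqs <- vapply(seqs, function(s) {
    s <- chartr("U", "T", s)
    s
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(seq_id = ids, gapped_sequence = seqs,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "width") <- if (length(w)) unname(w[1]) else 0L
  out
}
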