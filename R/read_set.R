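#' Construct a set of sequencing reads
#'
#' A `read_set` is the package's in-memory representation of a FASTQ file:
#' parallel vectors of read identifiers, nucleotide sequences over
#' `{A,C,G,T,N}`, and per-base phred quality scores. Sequences are
#' normalised on construction: uppercased, `U` mapped to `T`, and any other
#' letter replaced by `N`.
#'
#' @param id character vector of read identifiers (nonempty, unique).
#' @param seq character vector of nucleotide sequences.
#' @param qual list of integer vectors of phred scores, one per read, each
#'   the same length as its sequence and within `[0, 60]`.
#' @return An object of class `read_set`.
#' @examples
#' rs <- read_set("r1", "ACGT", list(c(40L, 40L, 38L, 2L)))
#' length(rs)
#' @export
read_set <- function(id = character(), seq = character(), qual = list()) {
  id <- as.character(id)
  seq <- clean_sequence(as.character(seq))
  qual <- lapply(qual, function(q) as.integer(round(q)))
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (anyDuplicated(id)) stop("read ids must be unique")
  if (length(id) && any(!nzchar(id))) stop("read ids must be nonempty")
  nc <- nchar(seq)
  nq <- lengths(qual)
  if (any(nc != nq)) {
    bad <- which(nc != nq)[1L]
    stop(sprintf("read %d ('%s'): sequence length %d != quality length %d",
                 bad, id[bad], nc[bad], nq[bad]))
  }
  if (length(qual) && (min(unlist(qual, use.names = FALSE), 60L) < 0L ||
                       max(unlist(qual, use.names = FALSE), 0L) > 60L))
    stop("phred qualities must lie in [0, 60]")
  structure(list(id = id, seq = seq, qual = qual), class = "read_set")
}

#' Normalise a nucleotide string
#'
#' Uppercases, maps `U` to `T`, and replaces any character outside
#' `{A,C,G,T,N}` with `N` (single internal alphabet).
#'
#' @param x character vector of sequences.
#' @return character vector, same length.
#' @export
clean_sequence <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[^ACGTN]", "N", x, perl = TRUE)
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
`[.read_set` <- function(x, i) {
  structure(list(id = x$id[i], seq = x$seq[i], qual = x$qual[i]),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  n <- length(x)
  cat(sprintf("read_set with %d read%s", n, if (n == 1) "" else "s"))
  if (n) {
    rng <- range(nchar(x$seq))
    cat(sprintf("; lengths %d-%d nt", rng[1], rng[2]))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.read_set <- function(x, ...) {
  data.frame(id = x$id, seq = x$seq, length = nchar(x$seq),
             stringsAsFactors = FALSE)
}

# concatenate read sets (ids must stay unique)
#' @export
c.read_set <- function(...) {
  parts <- list(...)
  read_set(unlist(lapply(parts, `[[`, "id")),
           unlist(lapply(parts, `[[`, "seq")),
           do.call(c, lapply(parts, `[[`, "qual")))
}
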