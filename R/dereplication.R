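#' Dereplicate reads into unique sequences
#'
#' Collapses reads with identical full-length sequences into unique records
#' carrying an abundance and the member read ids. Identity is exact string
#' equality (prefix matches do not collapse, so length variants stay
#' distinct). Output is sorted by decreasing abundance, ties broken by
#' lexicographic sequence order; unique ids `U00001`, `U00002`, ... follow
#' that order.
#'
#' @param reads a [read_set].
#' @return A `unique_set`: data.frame with columns `uid`, `sequence`,
#'   `abundance` and list-column `member_ids`.
#' @examples
#' rs <- read_set(c("a", "b", "c"), c("ACGT", "ACGT", "AGGT"),
#'                list(rep(40L, 4), rep(40L, 4), rep(40L, 4)))
#' dereplicate(rs)
#' @export
dereplicate <- function(reads) {
  if (!length(reads)) {
    out <- data.frame(uid = character(), sequence = character(),
                      abundance = integer(), stringsAsFactors = FALSE)
    out$member_ids <- list()
    class(out) <- c("unique_set", "data.frame")
    return(out)
  }
  grp <- split(reads$id, reads$seq)  # names sorted lexicographically
  seqs <- names(grp)
  ab <- lengths(grp)
  ord <- order(-ab, seqs, method = "radix")  # radix = C locale, deterministic
  out <- data.frame(uid = sprintf("U%05d", seq_along(ord)),
                    sequence = seqs[ord], abundance = as.integer(ab[ord]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$member_ids <- unname(grp[ord])
  class(out) <- c("unique_set", "data.frame")
  out
}

#' Construct a unique_set directly
#'
#' Builds the dereplicated-sequence container from explicit sequences and
#' abundances (used for hand-built fixtures). Sequences must be distinct;
#' rows are sorted by decreasing abundance with lexicographic ties, and
#' member ids default to synthetic placeholders.
#'
#' @param sequence character vector of distinct nucleotide sequences.
#' @param abundance integer vector of abundances (>= 1).
#' @param member_ids optional list of read-id vectors, lengths matching
#'   `abundance`.
#' @return a `unique_set`.
#' @export
unique_set <- function(sequence, abundance, member_ids = NULL) {
  sequence <- clean_sequence(sequence)
  abundance <- as.integer(abundance)
  stopifnot(length(sequence) == length(abundance), all(abundance >= 1L),
            !anyDuplicated(sequence))
  if (is.null(member_ids)) {
    member_ids <- lapply(seq_along(sequence), function(i)
      sprintf("seq%03d_r%03d", i, seq_len(abundance[i])))
  }
  stopifnot(all(lengths(member_ids) == abundance))
  ord <- order(-abundance, sequence, method = "radix")
  out <- data.frame(uid = sprintf("U%05d", seq_along(ord)),
                    sequence = sequence[ord], abundance = abundance[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$member_ids <- member_ids[ord]
  class(out) <- c("unique_set", "data.frame")
  out
}

#' Remove singleton unique sequences
#'
#' Drops unique sequences with abundance 1, preserving order. Idempotent.
#'
#' @param uniques a `unique_set` from [dereplicate].
#' @return filtered `unique_set`.
#' @export
remove_singletons <- function(uniques) {
  out <- uniques[uniques$abundance >= 2L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write unique sequences as FASTA with size annotations
#'
#' Headers carry the USEARCH-dialect `;size=N` abundance annotation:
#' `>U00001;size=57`.
#'
#' @param uniques a `unique_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_uniques_fasta <- function(uniques, path) {
  hdr <- sprintf("%s;size=%d", uniques$uid, uniques$abundance)
  write_fasta(setNames(uniques$sequence, hdr), path)
}

#' Write the unique-to-reads map as JSON
#'
#' One key per unique id, value = member read ids.
#'
#' @param uniques a `unique_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_uniques_members_json <- function(uniques, path) {
  jsonlite::write_json(setNames(uniques$member_ids, uniques$uid), path)
  invisible(path)
}

#' @export
print.unique_set <- function(x, ...) {
  cat(sprintf("unique_set: %d unique sequence(s), %d read(s), %d singleton(s)\n",
              nrow(x), sum(x$abundance), sum(x$abundance == 1L)))
  if (nrow(x)) print(utils::head(as.data.frame(x)[c("uid", "abundance")], 5))
  invisible(x)
}
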