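#' Alignment scoring scheme
#'
#' Scoring for the affine-gap global aligner. Defaults: match +1,
#' mismatch -2, gap open -10, gap extension -1 per base, and free terminal
#' gaps (`free_end_gaps = TRUE`). Free end gaps let length variants align
#' flush with terminal gap runs instead of scattering end differences as
#' internal gaps, which is the alignment structure whose terminal-gap
#' treatment this package measures.
#'
#' @param match,mismatch per-column scores.
#' @param gap_open opening penalty of a gap run (charged once per run).
#' @param gap_extend per-base gap penalty.
#' @param free_end_gaps are terminal gap runs unpenalised?
#' @param n_wildcard do columns containing `N` count (and score) as matches?
#' @return object of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap_open = -10,
                          gap_extend = -1, free_end_gaps = TRUE,
                          n_wildcard = TRUE) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 free_end_gaps = isTRUE(free_end_gaps),
                 n_wildcard = isTRUE(n_wildcard)),
            class = "align_scoring")
}

#' Optimal global alignment of two sequences
#'
#' Needleman-Wunsch alignment with affine gap costs and deterministic
#' traceback (ties prefer a match/mismatch column, then a gap in `b`, then a
#' gap in `a`). With `free_end_gaps` the terminal gap runs carry no penalty.
#'
#' @param a,b nucleotide strings (nonempty).
#' @param scoring an [align_scoring].
#' @return object of class `aligned_pair`: list with `gapped_a`, `gapped_b`,
#'   `score`, and precomputed `stats` (see [alignment_stats]).
#' @examples
#' p <- global_align("ACGTACGT", "ACGT")
#' p$gapped_b
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  a <- clean_sequence(a); b <- clean_sequence(b)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  res <- cpp_align(a, b, scoring$match, scoring$mismatch, scoring$gap_open,
                   scoring$gap_extend, scoring$free_end_gaps,
                   scoring$n_wildcard)
  structure(list(gapped_a = res$gapped_a, gapped_b = res$gapped_b,
                 score = res$score, stats = res$stats),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(x$gapped_a, x$gapped_b, sprintf("score: %g", x$score), sep = "\n")
  invisible(x)
}

#' Column statistics of an aligned pair
#'
#' Counts match columns (`M`), mismatch columns (`X`), and gap columns and
#' runs split into internal and terminal. A gap run is a maximal block of
#' consecutive `-` in one sequence; a run touching the first or last
#' alignment column is terminal. Columns with `N` in either sequence count
#' as matches when `n_wildcard` is `TRUE`. This is a pure R implementation,
#' independent of the C++ path, and is cross-checked against it in the test
#' suite.
#'
#' @param pair an `aligned_pair`, or a list/character vector holding two
#'   equal-length gapped sequences.
#' @param n_wildcard treat `N` columns as matches?
#' @return named numeric vector with elements `M`, `X`, `C_int`, `R_int`,
#'   `C_term`, `R_term`, `overlap` (columns excluding terminal gaps) and
#'   `length` (alignment columns).
#' @export
alignment_stats <- function(pair, n_wildcard = TRUE) {
  if (inherits(pair, "aligned_pair")) {
    ga <- pair$gapped_a; gb <- pair$gapped_b
  } else {
    ga <- pair[[1]]; gb <- pair[[2]]
  }
  if (nchar(ga) != nchar(gb)) stop("gapped sequences have unequal lengths")
  x <- strsplit(ga, "")[[1]]
  y <- strsplit(gb, "")[[1]]
  if (any(x == "-" & y == "-")) stop("alignment contains an all-gap column")
  L <- length(x)
  gap_a <- x == "-"
  gap_b <- y == "-"
  nwild <- if (n_wildcard) (x == "N" | y == "N") else rep(FALSE, L)
  mcol <- !gap_a & !gap_b & (x == y | nwild)
  xcol <- !gap_a & !gap_b & !mcol
  run_counts <- function(g) {
    if (!any(g)) return(list(C_int = 0L, R_int = 0L, C_term = 0L, R_term = 0L))
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    term <- starts[gi] == 1L | ends[gi] == L
    list(C_int = sum(r$lengths[gi][!term]), R_int = sum(!term),
         C_term = sum(r$lengths[gi][term]), R_term = sum(term))
  }
  ra <- run_counts(gap_a)
  rb <- run_counts(gap_b)
  out <- c(M = sum(mcol), X = sum(xcol),
           C_int = ra$C_int + rb$C_int, R_int = ra$R_int + rb$R_int,
           C_term = ra$C_term + rb$C_term, R_term = ra$R_term + rb$R_term)
  out <- c(out, overlap = unname(out["M"] + out["X"] + out["C_int"]),
           length = L)
  out
}

#' Identity definition and terminal-gap policy
#'
#' `definition` selects how gaps enter the identity calculation:
#' `"no_gaps"` excludes them, `"one_gap"` counts each gap run as a single
#' mutational difference, `"each_gap"` counts every gapped nucleotide as a
#' difference. `terminal_policy` selects whether terminal gap runs (length
#' differences, i.e., missing data) are counted like internal ones
#' (`"count"`, the behaviour of the classic tools) or excluded
#' (`"exclude"`).
#'
#' @param definition one of `"no_gaps"`, `"one_gap"`, `"each_gap"`.
#' @param terminal_policy `"count"` or `"exclude"`.
#' @return object of class `identity_config`.
#' @export
identity_config <- function(definition = c("each_gap", "one_gap", "no_gaps"),
                            terminal_policy = c("count", "exclude")) {
  structure(list(definition = match.arg(definition),
                 terminal_policy = match.arg(terminal_policy)),
            class = "identity_config")
}

#' Pairwise identity from alignment statistics
#'
#' Computes the identity fraction under an [identity_config]:
#' * `no_gaps`:  `M / (M + X)`
#' * `one_gap`:  `M / (M + X + R)` with `R` the counted gap runs
#' * `each_gap`: `M / (M + X + C)` with `C` the counted gap columns
#'
#' Terminal runs/columns are included in `R`/`C` only under the `"count"`
#' policy. Divergence is `1 - identity`.
#'
#' @param stats output of [alignment_stats] (or the `stats` element of an
#'   `aligned_pair`).
#' @param cfg an [identity_config].
#' @return identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(stats, cfg = identity_config()) {
  M <- stats[["M"]]; X <- stats[["X"]]
  if (M + X == 0)
    stop("identity undefined: alignment has no comparable columns")
  count_term <- cfg$terminal_policy == "count"
  switch(cfg$definition,
    no_gaps = M / (M + X),
    one_gap = {
      R <- stats[["R_int"]] + if (count_term) stats[["R_term"]] else 0
      M / (M + X + R)
    },
    each_gap = {
      C <- stats[["C_int"]] + if (count_term) stats[["C_term"]] else 0
      M / (M + X + C)
    })
}

#' Pairwise divergence of two unaligned sequences
#'
#' Convenience wrapper: align with [global_align], take [alignment_stats],
#' return `1 - identity` under `cfg`. With free end gaps two highly
#' dissimilar sequences can have an *empty* optimal overlap (all columns
#' terminal gaps), leaving identity undefined; `undefined` selects whether
#' that raises an error or returns the maximal divergence 1 (the sensible
#' reading inside clustering: such a pair never joins one OTU).
#'
#' @inheritParams global_align
#' @param cfg an [identity_config].
#' @param undefined `"error"` or `"max"` for empty-overlap alignments.
#' @return divergence fraction in `[0, 1]`.
#' @export
pair_divergence <- function(a, b, cfg = identity_config(),
                            scoring = align_scoring(),
                            undefined = c("error", "max"),
                            min_coverage = 0) {
  undefined <- match.arg(undefined)
  st <- global_align(a, b, scoring)$stats
  if (st[["M"]] + st[["X"]] == 0 && undefined == "max") return(1)
  if (min_coverage > 0 &&
      st[["overlap"]] < min_coverage * min(nchar(a), nchar(b)))
    return(1)
  1 - seq_identity(st, cfg)
}

# Divergence from precomputed pairwise-alignment stats, for the clustering
# layer: undefined pairs (empty ends-free overlap) and pairs whose aligned
# overlap covers less than `min_coverage` of the shorter sequence are
# maximally divergent. Without the coverage guard, a no-gaps identity of
# 1.0 over a coincidental short exact substring would merge unrelated
# sequences -- an artifact a banded global aligner such as UCLUST's never
# produces.
div_or_max <- function(stats, cfg, min_len = NULL, min_coverage = 0) {
  if (stats[["M"]] + stats[["X"]] == 0) return(1)
  if (min_coverage > 0 && !is.null(min_len) &&
      stats[["overlap"]] < min_coverage * min_len) return(1)
  1 - seq_identity(stats, cfg)
}

#' Identity of two rows of a multiple sequence alignment
#'
#' Columns gapped in both rows are deleted first; the remaining pairwise
#' alignment is scored exactly as [alignment_stats] plus [seq_identity].
#'
#' @param row_i,row_j equal-width gapped sequences from one MSA.
#' @param cfg an [identity_config].
#' @param n_wildcard treat `N` columns as matches?
#' @return identity fraction.
#' @export
msa_pair_identity <- function(row_i, row_j, cfg = identity_config(),
                              n_wildcard = TRUE) {
  if (nchar(row_i) != nchar(row_j)) stop("MSA rows have unequal widths")
  stats <- cpp_msa_pair_stats(toupper(row_i), toupper(row_j), n_wildcard)
  seq_identity(stats, cfg)
}

#' Pairwise divergence matrix
#'
#' Builds the symmetric matrix of divergences (`1 - identity`) between all
#' sequence pairs, either by pairwise global alignment (when `x` is a
#' character vector of sequences or a `unique_set`) or from the rows of a
#' multiple sequence alignment (when `x` is the output of
#' [read_aligned_fasta] or a data.frame with a `gapped_sequence` column).
#'
#' @param x sequences or MSA.
#' @param cfg an [identity_config].
#' @param scoring an [align_scoring] (pairwise route only).
#' @param undefined `"error"` (default: an undefined pair aborts, naming
#'   the pair) or `"max"` (undefined pairs get divergence 1; used by the
#'   clustering layer).
#' @param min_coverage pairwise route only: pairs whose aligned overlap
#'   covers less than this fraction of the shorter sequence are assigned
#'   divergence 1 (guards against coincidental short exact overlaps under
#'   end-gap-free alignment); 0 disables.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(x, cfg = identity_config(),
                            scoring = align_scoring(),
                            undefined = c("error", "max"),
                            min_coverage = 0) {
  undefined <- match.arg(undefined)
  if (is.data.frame(x) && "gapped_sequence" %in% names(x)) {
    dl <- cpp_msa_distances(x$gapped_sequence,
                            cfg$terminal_policy == "count",
                            scoring$n_wildcard, undefined == "max")
    d <- dl[[cfg$definition]]
    dimnames(d) <- list(x$seq_id, x$seq_id)
    return(d)
  }
  seqs <- if (is.data.frame(x)) x$sequence else as.character(x)
  ids <- if (is.data.frame(x) && "uid" %in% names(x)) x$uid
    else if (!is.data.frame(x) && !is.null(names(x))) names(x)
    else as.character(seq_along(seqs))
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      v <- tryCatch(pair_divergence(seqs[i], seqs[j], cfg, scoring,
                                    undefined = undefined,
                                    min_coverage = min_coverage),
                    error = function(e)
                      stop(sprintf("pair (%s, %s): %s", ids[i], ids[j],
                                   conditionMessage(e)), call. = FALSE))
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a distance matrix in mothur phylip lower-triangle format
#'
#' @param d symmetric distance matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_lower <- function(d, path) {
  n <- nrow(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  for (i in seq_len(n)) {
    row <- if (i > 1) paste(formatC(d[i, seq_len(i - 1)], format = "f",
                                    digits = 6), collapse = "\t") else ""
    writeLines(paste(c(rownames(d)[i], row[nzchar(row)]), collapse = "\t"),
               con)
  }
  invisible(path)
}
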