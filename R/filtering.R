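#' The Uni18S forward primer
#'
#' Degenerate forward primer targeting the 18S V4 region
#' (`AGGGCAAKYCTGGTGCCAGC`; `K` = G/T, `Y` = C/T).
#'
#' @return IUPAC primer string.
#' @export
primer_uni18s <- function() "AGGGCAAKYCTGGTGCCAGC"

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

#' Filtering parameters for a regime
#'
#' Bundles the thresholds of the two filtering regimes. The *stringent*
#' regime removes reads shorter than `trim_length` after primer removal,
#' trims survivors to exactly `trim_length`, and rejects reads whose
#' expected number of errors over the trimmed bases exceeds
#' `max_expected_error`. The *relaxed* regime keeps variable-length reads
#' within `[min_length, max_length]` and rejects reads with mean phred
#' quality below `min_avg_quality`. Both regimes reject reads containing
#' ambiguous bases (`N`) unless `allow_ambiguous` is set.
#'
#' @param regime `"stringent"` or `"relaxed"`.
#' @param forward_primer IUPAC primer matched and stripped at the 5' end.
#' @param max_primer_mismatches mismatches tolerated in the primer match.
#' @param trim_length stringent truncation length (nt).
#' @param min_length,max_length relaxed length window (nt); under the
#'   stringent regime `min_length` equals `trim_length`.
#' @param max_expected_error stringent expected-error ceiling.
#' @param min_avg_quality relaxed mean-quality floor (phred units).
#' @param allow_ambiguous keep reads containing `N`?
#' @param strip_reverse_primer also search for and trim a 3' reverse-primer
#'   tail (off by default; reads are assumed to start at the forward end).
#' @param reverse_primer IUPAC reverse primer used when
#'   `strip_reverse_primer` is `TRUE`.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(regime = c("stringent", "relaxed"),
                          forward_primer = primer_uni18s(),
                          max_primer_mismatches = 0L,
                          trim_length = 400L,
                          min_length = NULL,
                          max_length = NULL,
                          max_expected_error = 0.5,
                          min_avg_quality = 20,
                          allow_ambiguous = FALSE,
                          strip_reverse_primer = FALSE,
                          reverse_primer = NULL) {
  regime <- match.arg(regime)
  if (is.null(min_length))
    min_length <- if (regime == "stringent") trim_length else 250L
  if (is.null(max_length))
    max_length <- if (regime == "stringent") Inf else 600L
  stopifnot(min_length <= max_length, max_expected_error > 0,
            max_primer_mismatches >= 0)
  structure(list(regime = regime, forward_primer = toupper(forward_primer),
                 max_primer_mismatches = as.integer(max_primer_mismatches),
                 trim_length = as.integer(trim_length),
                 min_length = min_length, max_length = max_length,
                 max_expected_error = max_expected_error,
                 min_avg_quality = min_avg_quality,
                 allow_ambiguous = isTRUE(allow_ambiguous),
                 strip_reverse_primer = isTRUE(strip_reverse_primer),
                 reverse_primer = reverse_primer),
            class = "filter_params")
}

#' Expected number of sequencing errors of a read
#'
#' The expected-error statistic `sum(10^(-Q/10))` over a read's phred
#' scores: the expected count of erroneous bases if qualities are accurate.
#'
#' @param qualities integer vector of phred scores (may be empty).
#' @return nonnegative numeric scalar.
#' @examples
#' expected_error(c(10, 20, 30))  # 0.1 + 0.01 + 0.001
#' @export
expected_error <- function(qualities) {
  if (!length(qualities)) return(0)
  sum(10^(-qualities / 10))
}

# number of mismatches of each sequence's prefix against an IUPAC pattern;
# returns Inf for sequences shorter than the pattern
iupac_prefix_mismatches <- function(seqs, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  k <- length(pat)
  short <- nchar(seqs) < k
  mm <- rep(Inf, length(seqs))
  if (any(!short)) {
    pre <- substr(seqs[!short], 1L, k)
    mat <- matrix(unlist(strsplit(pre, ""), use.names = FALSE),
                  nrow = k, ncol = sum(!short))
    ok <- matrix(FALSE, nrow = k, ncol = ncol(mat))
    for (i in seq_len(k)) {
      allowed <- IUPAC_SETS[[pat[i]]]
      if (is.null(allowed)) stop("invalid IUPAC code in primer: ", pat[i])
      ok[i, ] <- mat[i, ] %in% allowed
    }
    mm[!short] <- k - colSums(ok)
  }
  mm
}

#' Match and strip the forward primer
#'
#' A read is accepted when its 5' prefix matches `primer` under IUPAC
#' degeneracy with at most `max_mismatches` mismatching positions; the
#' primer bases (and their qualities) are then removed. Reads shorter than
#' the primer are rejected as `too_short_for_primer`.
#'
#' @param reads a [read_set].
#' @param primer IUPAC primer string.
#' @param max_mismatches tolerated mismatch count.
#' @return list with elements `kept` (trimmed [read_set]), `n_mismatch`,
#'   and `n_too_short`.
#' @export
match_and_trim_primer <- function(reads, primer, max_mismatches = 0L) {
  stopifnot(nzchar(primer))
  k <- nchar(primer)
  mm <- iupac_prefix_mismatches(reads$seq, primer)
  too_short <- nchar(reads$seq) < k
  keep <- !too_short & mm <= max_mismatches
  kept <- reads[keep]
  kept$seq <- substring(kept$seq, k + 1L)
  kept$qual <- lapply(kept$qual, function(q) q[-seq_len(min(k, length(q)))])
  list(kept = kept,
       n_mismatch = sum(!keep & !too_short),
       n_too_short = sum(too_short))
}

#' Apply a filtering regime to reads
#'
#' Rules are applied per read in a fixed order: forward primer match/strip,
#' length (with truncation to `trim_length` under the stringent regime),
#' ambiguous bases, then quality (expected error over the retained bases for
#' stringent; mean quality for relaxed). Each read lands in exactly one
#' tally of the report.
#'
#' @param reads a [read_set].
#' @param params a [filter_params].
#' @return list with elements `kept` (a [read_set]) and `report` (named
#'   integer vector of per-reason rejection counts plus `kept`).
#' @export
apply_filter <- function(reads, params) {
  stopifnot(inherits(params, "filter_params"))
  n_in <- length(reads)
  rep0 <- c(primer_mismatch = 0L, too_short_for_primer = 0L,
            too_short = 0L, too_long = 0L, ambiguous_base = 0L,
            expected_error = 0L, avg_quality = 0L, kept = 0L)
  pm <- match_and_trim_primer(reads, params$forward_primer,
                              params$max_primer_mismatches)
  rep0["primer_mismatch"] <- pm$n_mismatch
  rep0["too_short_for_primer"] <- pm$n_too_short
  rs <- pm$kept
  if (isTRUE(params$strip_reverse_primer) && !is.null(params$reverse_primer)) {
    rs <- strip_reverse_tail(rs, params$reverse_primer)
  }
  len <- nchar(rs$seq)
  if (params$regime == "stringent") {
    short <- len < params$trim_length
    rep0["too_short"] <- sum(short)
    rs <- rs[!short]
    rs$seq <- substr(rs$seq, 1L, params$trim_length)
    rs$qual <- lapply(rs$qual, function(q) q[seq_len(params$trim_length)])
  } else {
    short <- len < params$min_length
    long <- !short & len > params$max_length
    rep0["too_short"] <- sum(short)
    rep0["too_long"] <- sum(long)
    rs <- rs[!short & !long]
  }
  if (!params$allow_ambiguous) {
    amb <- grepl("N", rs$seq, fixed = TRUE)
    rep0["ambiguous_base"] <- sum(amb)
    rs <- rs[!amb]
  }
  if (params$regime == "stringent") {
    ee <- vapply(rs$qual, expected_error, numeric(1))
    bad <- ee > params$max_expected_error
    rep0["expected_error"] <- sum(bad)
    rs <- rs[!bad]
  } else {
    aq <- vapply(rs$qual, function(q) if (length(q)) mean(q) else 0,
                 numeric(1))
    bad <- aq < params$min_avg_quality
    rep0["avg_quality"] <- sum(bad)
    rs <- rs[!bad]
  }
  rep0["kept"] <- length(rs)
  stopifnot(sum(rep0) == n_in)  # partition invariant
  list(kept = rs, report = rep0)
}

# Optional 3' tail trimming at the reverse-complemented reverse primer.
# The tail (primer realisation and anything after it) is removed when an
# exact-degeneracy match is found; reads without a match pass unchanged.
strip_reverse_tail <- function(rs, reverse_primer) {
  rcsets <- rev(strsplit(toupper(reverse_primer), "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  rc <- paste(comp[rcsets], collapse = "")
  pat <- paste(vapply(strsplit(rc, "")[[1]], function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1) s else paste0("[", paste(setdiff(s, "N"), collapse = ""), "]")
  }, character(1)), collapse = "")
  hit <- regexpr(pat, rs$seq, perl = TRUE)
  cut <- as.integer(hit)
  keep_len <- ifelse(cut > 0, cut - 1L, nchar(rs$seq))
  rs$seq <- substr(rs$seq, 1L, keep_len)
  rs$qual <- Map(function(q, l) q[seq_len(l)], rs$qual, keep_len)
  rs
}
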