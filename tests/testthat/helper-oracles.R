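# Independent oracles and small generators shared across the test files.
# Oracles deliberately avoid the code paths they check: the alignment-score
# oracle is an explicit-gap-length DP in plain R (no three-state machine),
# the agglomeration oracle recomputes every cluster-pair linkage from the
# original matrix at each step.

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES4, n, replace = TRUE),
                              collapse = "")

rand_read_set <- function(n, len_range = c(30, 60), prefix = "r") {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  read_set(sprintf("%s%03d", prefix, seq_len(n)),
           vapply(lens, rand_seq, character(1)),
           lapply(lens, function(L) sample(2:41, L, replace = TRUE)))
}

# Optimal global alignment score by explicit gap-length enumeration:
# H[i, j] = best score aligning a[1..i] to b[1..j]; each cell considers the
# diagonal and every gap length ending at (i, j). O(n * m * (n + m)).
oracle_align_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = -10, gap_extend = -1,
                               free_end_gaps = TRUE, n_wildcard = TRUE) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(-Inf, n + 1, m + 1)
  H[1, 1] <- 0
  gap_cost <- function(g) gap_open + gap_extend * g
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (x[i] == y[j] || (n_wildcard && (x[i] == "N" || y[j] == "N")))
        match else mismatch
      best <- max(best, H[i, j] + s)
    }
    if (i > 0) for (g in 1:i) {         # gap in b consuming a[(i-g+1)..i]
      cost <- if (j == 0 && free_end_gaps) 0 else gap_cost(g)
      best <- max(best, H[i - g + 1, j + 1] + cost)
    }
    if (j > 0) for (g in 1:j) {         # gap in a consuming b[(j-g+1)..j]
      cost <- if (i == 0 && free_end_gaps) 0 else gap_cost(g)
      best <- max(best, H[i + 1, j - g + 1] + cost)
    }
    H[i + 1, j + 1] <- best
  }
  if (!free_end_gaps) return(H[n + 1, m + 1])
  # trailing gaps free: best over last row and last column
  max(H[n + 1, ], H[, m + 1])
}

# Naive agglomeration: recompute every cluster-pair linkage from the
# original distances at each step; merge the smallest (ties by smallest
# member index) while <= threshold.
oracle_agglomerate <- function(dmat, threshold, linkage = "average") {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- list(d = Inf, i = 0, j = 0, m1 = Inf, m2 = Inf)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      cross <- dmat[clusters[[i]], clusters[[j]], drop = FALSE]
      dv <- switch(linkage, average = mean(cross), furthest = max(cross),
                   nearest = min(cross))
      m1 <- min(min(clusters[[i]]), min(clusters[[j]]))
      m2 <- max(min(clusters[[i]]), min(clusters[[j]]))
      if (dv < best$d ||
          (dv == best$d && (m1 < best$m1 ||
                            (m1 == best$m1 && m2 < best$m2)))) {
        best <- list(d = dv, i = i, j = j, m1 = m1, m2 = m2)
      }
    }
    if (best$d > threshold) break
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- clusters[-c(best$i, best$j)]
    clusters[[length(clusters) + 1L]] <- merged
  }
  out <- integer(n)
  for (i in seq_along(clusters)) out[clusters[[i]]] <- i
  match(out, unique(out))
}

# membership vector of an otu_set in the order of a unique_set's uids
otu_membership <- function(otus, uniques) {
  memb <- setNames(integer(nrow(uniques)), uniques$uid)
  for (i in seq_len(nrow(otus))) memb[otus$members[[i]]$uid] <- i
  unname(memb[uniques$uid])
}

# do two membership vectors describe the same partition?
same_partition <- function(m1, m2) {
  identical(match(m1, unique(m1)), match(m2, unique(m2)))
}

# random gapped pair with no all-gap column, at least one comparable column
rand_gapped_pair <- function(len = 40) {
  repeat {
    kind <- sample(c("M", "X", "GA", "GB"), len, replace = TRUE,
                   prob = c(0.55, 0.15, 0.15, 0.15))
    if (any(kind %in% c("M", "X"))) break
  }
  a <- character(len); b <- character(len)
  for (k in seq_len(len)) {
    if (kind[k] == "M") { bb <- sample(BASES4, 1); a[k] <- bb; b[k] <- bb }
    else if (kind[k] == "X") { bb <- sample(BASES4, 2); a[k] <- bb[1]; b[k] <- bb[2] }
    else if (kind[k] == "GA") { a[k] <- "-"; b[k] <- sample(BASES4, 1) }
    else { a[k] <- sample(BASES4, 1); b[k] <- "-" }
  }
  list(gapped_a = paste(a, collapse = ""), gapped_b = paste(b, collapse = ""))
}
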