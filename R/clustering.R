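#' Clustering configuration
#'
#' @param algorithm `"greedy"` (abundance-ordered centroid clustering,
#'   UCLUST-style) or `"hierarchical"` (agglomeration over a full distance
#'   matrix, mothur-style).
#' @param divergence_threshold divergence cutoff (default 0.03, i.e.,
#'   sequences within 3% divergence join one OTU).
#' @param identity_cfg an [identity_config].
#' @param linkage hierarchical linkage: `"average"` (average neighbor,
#'   default), `"furthest"` or `"nearest"`.
#' @param accept_mode greedy acceptance: `"first_hit"` joins the first
#'   centroid within the threshold (classic maxaccepts = 1), `"best_hit"`
#'   scans all centroids and joins the closest qualifying one.
#' @param max_matrix_size capacity guard for hierarchical mode: more
#'   sequences than this raise an error instead of attempting an all-pairs
#'   matrix.
#' @param min_coverage pairwise-alignment routes only: a candidate pair
#'   whose aligned overlap covers less than this fraction of the shorter
#'   sequence is treated as maximally divergent. This mirrors the query
#'   coverage requirement of greedy clustering tools and prevents a
#'   coincidental short exact overlap from passing as a no-gaps identity
#'   of 1 under end-gap-free alignment.
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(algorithm = c("greedy", "hierarchical"),
                           divergence_threshold = 0.03,
                           identity_cfg = identity_config(),
                           linkage = c("average", "furthest", "nearest"),
                           accept_mode = c("first_hit", "best_hit"),
                           max_matrix_size = 20000L,
                           min_coverage = 0.5) {
  stopifnot(divergence_threshold > 0, divergence_threshold < 1,
            min_coverage >= 0, min_coverage <= 1)
  structure(list(algorithm = match.arg(algorithm),
                 divergence_threshold = divergence_threshold,
                 identity_cfg = identity_cfg,
                 linkage = match.arg(linkage),
                 accept_mode = match.arg(accept_mode),
                 max_matrix_size = as.integer(max_matrix_size),
                 min_coverage = min_coverage),
            class = "cluster_config")
}

# defensive resort: abundance descending, ties by sequence
sort_uniques <- function(uniques) {
  ord <- order(-uniques$abundance, uniques$sequence, method = "radix")
  out <- uniques[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy centroid clustering
#'
#' Processes unique sequences in order of decreasing abundance. The most
#' abundant sequence founds the first cluster; each later sequence is
#' aligned to the existing centroids in centroid-creation order and joins
#' one within the divergence threshold (first qualifying centroid under
#' `first_hit`; minimum-divergence centroid, earliest on ties, under
#' `best_hit`), otherwise it founds a new cluster. Centroids never change
#' after creation.
#'
#' @param uniques a `unique_set` (re-sorted defensively).
#' @param cfg a [cluster_config].
#' @param scoring an [align_scoring].
#' @param stats_fun optional `function(i, j)` returning alignment stats for
#'   rows `i`, `j` of the sorted unique table (used by [compare_workflows]
#'   to share an alignment cache); default aligns on demand.
#' @return an `otu_set` (see [cluster_otus]).
#' @export
greedy_cluster <- function(uniques, cfg = cluster_config(),
                           scoring = align_scoring(), stats_fun = NULL) {
  uniques <- sort_uniques(uniques)
  n <- nrow(uniques)
  if (n == 0) return(make_otu_set(uniques, integer(), integer()))
  if (is.null(stats_fun)) {
    seqs <- uniques$sequence
    stats_fun <- function(i, j)
      cpp_align(seqs[i], seqs[j], scoring$match, scoring$mismatch,
                scoring$gap_open, scoring$gap_extend, scoring$free_end_gaps,
                scoring$n_wildcard)$stats
  }
  thr <- cfg$divergence_threshold
  icfg <- cfg$identity_cfg
  mc <- cfg$min_coverage %||% 0.5
  lens <- nchar(uniques$sequence)
  centroids <- integer(0)          # row indices of founders, creation order
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    if (length(centroids)) {
      if (cfg$accept_mode == "first_hit") {
        for (k in seq_along(centroids)) {
          ck <- centroids[k]
          d <- div_or_max(stats_fun(i, ck), icfg,
                          min_len = min(lens[i], lens[ck]),
                          min_coverage = mc)
          if (d <= thr) { hit <- k; break }
        }
      } else {
        best <- Inf
        for (k in seq_along(centroids)) {
          ck <- centroids[k]
          d <- div_or_max(stats_fun(i, ck), icfg,
                          min_len = min(lens[i], lens[ck]),
                          min_coverage = mc)
          if (d <= thr && d < best) { best <- d; hit <- k }
        }
      }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      assign[i] <- length(centroids)
    } else assign[i] <- hit
  }
  make_otu_set(uniques, assign, centroids)
}

#' Agglomerative clustering of a distance matrix
#'
#' Cuts an agglomeration (Lance-Williams updates) at the divergence
#' threshold: merges with linkage distance at or below the cutoff are
#' applied, none beyond. Merge order is deterministic: smallest linkage
#' distance first, ties resolved by the smallest member index.
#'
#' @param dmat symmetric distance matrix (no `NA`).
#' @param threshold cut height.
#' @param linkage `"average"`, `"furthest"` or `"nearest"`.
#' @return integer membership vector (1-based cluster labels in order of
#'   first appearance).
#' @export
agglomerate <- function(dmat, threshold,
                        linkage = c("average", "furthest", "nearest")) {
  linkage <- match.arg(linkage)
  n <- nrow(dmat)
  if (anyNA(dmat)) stop("distance matrix must be free of NA")
  if (n != ncol(dmat) || max(abs(dmat - t(dmat))) > 1e-12)
    stop("distance matrix must be symmetric")
  if (n == 1) return(1L)
  members <- as.list(seq_len(n))    # cluster slot -> original indices
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  minmem <- seq_len(n)              # smallest original member per cluster
  d <- unname(dmat)
  diag(d) <- Inf
  rowmin <- apply(d, 1, min)        # cached min of each active row
  nn <- apply(d, 1, which.min)      # column achieving it
  while (sum(active) > 1L) {
    mn <- min(rowmin[active])
    if (mn > threshold) break
    # candidate pairs achieving the minimum; ties resolved by the smallest
    # original member index of the pair, then of the partner
    rows <- which(active & rowmin == mn)
    bi <- bj <- 0L; bk1 <- bk2 <- Inf
    for (r in rows) {
      cols <- which(d[r, ] == mn)
      for (cc in cols) {
        a <- min(minmem[r], minmem[cc]); b <- max(minmem[r], minmem[cc])
        if (a < bk1 || (a == bk1 && b < bk2)) {
          bk1 <- a; bk2 <- b
          if (minmem[r] <= minmem[cc]) { bi <- r; bj <- cc }
          else { bi <- cc; bj <- r }
        }
      }
    }
    i <- bi; j <- bj
    # Lance-Williams update of distances to the merged cluster (kept in i)
    drow <- switch(linkage,
      average = (sizes[i] * d[i, ] + sizes[j] * d[j, ]) /
                (sizes[i] + sizes[j]),
      furthest = pmax(d[i, ], d[j, ]),
      nearest = pmin(d[i, ], d[j, ]))
    drow[!active] <- Inf
    drow[c(i, j)] <- Inf
    d[i, ] <- drow
    d[, i] <- drow
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    minmem[i] <- min(minmem[i], minmem[j])
    active[j] <- FALSE
    d[j, ] <- Inf
    d[, j] <- Inf
    rowmin[j] <- Inf
    rowmin[i] <- min(d[i, ])
    nn[i] <- which.min(d[i, ])
    # rows whose cached minimum pointed at a merged cluster are stale;
    # other rows can only improve via the new cluster i
    stale <- which(active & (nn == i | nn == j))
    stale <- setdiff(stale, i)
    for (k in stale) {
      rowmin[k] <- min(d[k, ])
      nn[k] <- which.min(d[k, ])
    }
    better <- which(active & d[, i] < rowmin)
    better <- setdiff(better, i)
    if (length(better)) {
      rowmin[better] <- d[better, i]
      nn[better] <- i
    }
  }
  out <- integer(n)
  lab <- 0L
  for (k in which(active)) {
    lab <- lab + 1L
    out[members[[k]]] <- lab
  }
  match(out, unique(out))  # labels in order of first appearance
}

#' Hierarchical OTU clustering
#'
#' Builds (or accepts) a pairwise divergence matrix and agglomerates it at
#' the divergence threshold. The matrix is derived from a supplied MSA when
#' `msa` is given, otherwise from pairwise global alignments. The OTU
#' centroid is the most abundant member (ties by the abundance-sorted
#' order).
#'
#' @param uniques a `unique_set`.
#' @param cfg a [cluster_config].
#' @param dmat optional precomputed divergence matrix matching the *sorted*
#'   unique table.
#' @param msa optional MSA (`data.frame` with `gapped_sequence`) whose rows
#'   carry `seq_id` equal to the unique ids.
#' @param scoring an [align_scoring] for the pairwise route.
#' @return an `otu_set`.
#' @export
hierarchical_cluster <- function(uniques, cfg = cluster_config("hierarchical"),
                                 dmat = NULL, msa = NULL,
                                 scoring = align_scoring()) {
  uniques <- sort_uniques(uniques)
  n <- nrow(uniques)
  if (n == 0) return(make_otu_set(uniques, integer(), integer()))
  if (n > cfg$max_matrix_size)
    stop(sprintf(
      "capacity: %d sequences exceed max_matrix_size = %d for hierarchical clustering",
      n, cfg$max_matrix_size))
  if (n == 1) return(make_otu_set(uniques, 1L, 1L))
  if (is.null(dmat)) {
    if (!is.null(msa)) {
      idx <- match(uniques$uid, msa$seq_id)
      if (anyNA(idx)) stop("MSA is missing rows for some unique sequences")
      dmat <- distance_matrix(msa[idx, , drop = FALSE], cfg$identity_cfg,
                              scoring, undefined = "max")
    } else {
      dmat <- distance_matrix(uniques, cfg$identity_cfg, scoring,
                              undefined = "max",
                              min_coverage = cfg$min_coverage %||% 0.5)
    }
  }
  memb <- agglomerate(dmat, cfg$divergence_threshold, cfg$linkage)
  # centroid: most abundant member; uniques are abundance-sorted, so the
  # first row of each cluster wins (ties resolved by sort order)
  cent <- vapply(seq_len(max(memb)), function(k) which(memb == k)[1],
                 integer(1))
  make_otu_set(uniques, memb, cent)
}

#' Cluster unique sequences into OTUs
#'
#' Dispatches to [greedy_cluster] or [hierarchical_cluster] according to
#' `cfg$algorithm`. Hierarchical mode uses MSA-derived distances when an
#' MSA is supplied, else pairwise-alignment distances. OTUs are returned in
#' decreasing total-abundance order with ids `OTU_0001`, `OTU_0002`, ...
#'
#' @param uniques a `unique_set`.
#' @param cfg a [cluster_config].
#' @param msa optional MSA for hierarchical mode.
#' @param scoring an [align_scoring].
#' @param stats_fun optional stats cache hook for greedy mode.
#' @return an `otu_set`: data.frame with columns `otu_id`, `centroid`,
#'   `total_abundance`, `n_members`, and list-column `members` (each a
#'   data.frame with `uid`, `sequence`, `abundance`, `member_ids`).
#' @export
cluster_otus <- function(uniques, cfg = cluster_config(), msa = NULL,
                         scoring = align_scoring(), stats_fun = NULL) {
  if (cfg$algorithm == "greedy")
    greedy_cluster(uniques, cfg, scoring, stats_fun)
  else
    hierarchical_cluster(uniques, cfg, msa = msa, scoring = scoring)
}

# assemble the otu_set container from a sorted unique table, a membership
# vector and the centroid row index per cluster
make_otu_set <- function(uniques, assign, centroid_rows) {
  k <- length(centroid_rows)
  if (k == 0) {
    out <- data.frame(otu_id = character(), centroid = character(),
                      total_abundance = integer(), n_members = integer(),
                      stringsAsFactors = FALSE)
    out$members <- list()
    class(out) <- c("otu_set", "data.frame")
    return(out)
  }
  tot <- vapply(seq_len(k), function(c)
    sum(uniques$abundance[assign == c]), numeric(1))
  # order OTUs by decreasing abundance; ties by centroid creation order
  ord <- order(-tot, seq_len(k))
  members <- lapply(ord, function(c) {
    m <- uniques[assign == c, c("uid", "sequence", "abundance", "member_ids"),
                 drop = FALSE]
    rownames(m) <- NULL
    m
  })
  out <- data.frame(otu_id = sprintf("OTU_%04d", seq_len(k)),
                    centroid = uniques$sequence[centroid_rows[ord]],
                    total_abundance = as.integer(tot[ord]),
                    n_members = vapply(members, nrow, integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$members <- members
  class(out) <- c("otu_set", "data.frame")
  out
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("otu_set: %d OTU(s), %d unique sequence(s), %d read(s)\n",
              nrow(x), sum(x$n_members), sum(x$total_abundance)))
  if (nrow(x))
    print(utils::head(as.data.frame(x)[c("otu_id", "total_abundance",
                                         "n_members")], 5))
  invisible(x)
}

#' Write OTU representative sequences as FASTA
#'
#' Headers carry `;size=` total abundances: `>OTU_0001;size=1234`.
#'
#' @param otus an `otu_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_fasta <- function(otus, path) {
  hdr <- sprintf("%s;size=%d", otus$otu_id, otus$total_abundance)
  write_fasta(setNames(otus$centroid, hdr), path)
}

#' Write a mothur-style list line
#'
#' Single line: `label`, the OTU count, then one comma-separated member-id
#' field per OTU, tab-delimited.
#'
#' @param otus an `otu_set`.
#' @param path output path.
#' @param label distance label (default `"0.03"`).
#' @return `path`, invisibly.
#' @export
write_mothur_list <- function(otus, path, label = "0.03") {
  fields <- vapply(otus$members, function(m)
    paste(m$uid, collapse = ","), character(1))
  writeLines(paste(c(label, nrow(otus), fields), collapse = "\t"), path)
  invisible(path)
}

#' Write the OTU membership table
#'
#' TSV with one row per member unique sequence: `otu_id`, `uid`,
#' `abundance`.
#'
#' @param otus an `otu_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_membership <- function(otus, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(otus)), function(i) {
    m <- otus$members[[i]]
    data.frame(otu_id = otus$otu_id[i], uid = m$uid, abundance = m$abundance,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(otu_id = character(), uid = character(),
                       abundance = integer())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
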