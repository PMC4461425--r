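test_that("greedy clustering joins within and splits beyond the threshold", {
  set.seed(41)
  base <- rand_seq(400)
  one_off <- strsplit(base, "")[[1]]
  one_off[200] <- setdiff(BASES4, one_off[200])[1]
  one_off <- paste(one_off, collapse = "")
  # single sequence -> one OTU containing it
  u <- unique_set(base, 5L)
  ot <- greedy_cluster(u)
  expect_equal(nrow(ot), 1)
  expect_equal(ot$centroid, base)
  # divergence 1/400 = 0.0025 < 0.03 -> one OTU, centroid = more abundant
  u <- unique_set(c(base, one_off), c(5L, 3L))
  ot <- greedy_cluster(u)
  expect_equal(nrow(ot), 1)
  expect_equal(ot$centroid, base)
  expect_equal(ot$total_abundance, 8L)
  # 40/400 mismatches -> divergence 0.10 > 0.03 -> two OTUs
  forty <- strsplit(base, "")[[1]]
  pos <- sample(400, 40)
  forty[pos] <- vapply(forty[pos], function(b)
    sample(setdiff(BASES4, b), 1), character(1))
  u <- unique_set(c(base, paste(forty, collapse = "")), c(5L, 3L))
  expect_equal(nrow(greedy_cluster(u)), 2)
  # empty input -> empty output
  expect_equal(nrow(greedy_cluster(dereplicate(read_set()))), 0)
})

test_that("terminal gaps split length variants under each_gap+count only", {
  fx <- fixture_suite()$prefix_pair
  for (alg in c("greedy", "hierarchical")) {
    n_eg <- nrow(cluster_otus(fx, cluster_config(
      alg, identity_cfg = identity_config("each_gap", "count"))))
    n_ex <- nrow(cluster_otus(fx, cluster_config(
      alg, identity_cfg = identity_config("each_gap", "exclude"))))
    n_ng <- nrow(cluster_otus(fx, cluster_config(
      alg, identity_cfg = identity_config("no_gaps"))))
    expect_equal(n_eg, 2)
    expect_equal(n_ex, 1)
    expect_equal(n_ng, 1)
  }
})

test_that("hierarchical clustering follows average-linkage arithmetic", {
  d3 <- function(d12, d13, d23) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- d12; m[1, 3] <- m[3, 1] <- d13
    m[2, 3] <- m[3, 2] <- d23
    m
  }
  expect_equal(max(agglomerate(d3(0.01, 0.01, 0.01), 0.03)), 1)
  expect_equal(max(agglomerate(d3(0.10, 0.10, 0.10), 0.03)), 3)
  # chain case: merge {1,2} at 0.02, then d({1,2},3) = 0.035 > 0.03
  memb <- agglomerate(d3(0.02, 0.05, 0.02), 0.03, "average")
  expect_equal(memb, c(1L, 1L, 2L))
  # nearest linkage would chain them into one cluster
  memb <- agglomerate(d3(0.02, 0.05, 0.02), 0.03, "nearest")
  expect_equal(max(memb), 1)
  expect_error(agglomerate(matrix(c(0, 1, 2, 0), 2, 2), 0.03), "symmetric")
  expect_error(agglomerate(matrix(c(0, NA, NA, 0), 2, 2), 0.03), "NA")
})

test_that("agglomeration agrees with the naive oracle (n <= 50)", {
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(5:50, 1)
    d <- matrix(0, n, n)
    v <- runif(n * (n - 1) / 2, 0, 0.12)
    d[lower.tri(d)] <- v
    d <- d + t(d)
    # continuous distances: ties have probability ~0, all linkages safe
    for (lk in c("average", "furthest", "nearest")) {
      got <- agglomerate(d, 0.05, lk)
      want <- oracle_agglomerate(d, 0.05, lk)
      expect_true(same_partition(got, want),
                  info = sprintf("n=%d linkage=%s", n, lk))
    }
    # tie-heavy matrices exercise the smallest-member rule; restricted to
    # max/min linkages whose merged values are bit-identical on both routes
    # (average linkage accumulates differently and may flip exact ties)
    dt <- matrix(0, n, n)
    dt[lower.tri(dt)] <- round(v, 2)
    dt <- dt + t(dt)
    for (lk in c("furthest", "nearest")) {
      got <- agglomerate(dt, 0.05, lk)
      want <- oracle_agglomerate(dt, 0.05, lk)
      expect_true(same_partition(got, want),
                  info = sprintf("ties n=%d linkage=%s", n, lk))
    }
  }
})

test_that("greedy equals a naive re-implementation on random sets", {
  set.seed(43)
  for (rep in 1:3) {
    base <- rand_seq(120)
    seqs <- unique(vapply(1:12, function(i) {
      ch <- strsplit(base, "")[[1]]
      pos <- sample(120, sample(0:10, 1))
      if (length(pos))
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(BASES4, b), 1), character(1))
      paste(ch, collapse = "")
    }, character(1)))
    u <- unique_set(seqs, sample(1:9, length(seqs), replace = TRUE))
    cfg <- cluster_config("greedy",
                          identity_cfg = identity_config("each_gap"))
    got <- greedy_cluster(u, cfg)
    # naive: same rules, written independently over pair_divergence
    us <- u[order(-u$abundance, u$sequence), ]
    cents <- integer(0); memb <- integer(nrow(us))
    for (i in seq_len(nrow(us))) {
      joined <- FALSE
      for (k in seq_along(cents)) {
        d <- pair_divergence(us$sequence[i], us$sequence[cents[k]],
                             identity_config("each_gap"), undefined = "max")
        if (d <= 0.03) { memb[i] <- k; joined <- TRUE; break }
      }
      if (!joined) { cents <- c(cents, i); memb[i] <- length(cents) }
    }
    expect_true(same_partition(otu_membership(got, us), memb))
  }
})

test_that("greedy and hierarchical agree on well-separated species", {
  set.seed(44)
  comm <- generate_references(community_spec(n_species = 6L,
                                             length_range = c(200L, 260L),
                                             seed = 7L))
  # a few close variants per species (intra <= 1%), no errors
  seqs <- unlist(lapply(comm$references$sequence, function(t) {
    c(t, vapply(1:2, function(i) {
      ch <- strsplit(t, "")[[1]]
      pos <- sample(length(ch), 2)
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(BASES4, b), 1), character(1))
      paste(ch, collapse = "")
    }, character(1)))
  }))
  u <- unique_set(unique(seqs),
                  rev(seq_along(unique(seqs))))
  g <- cluster_otus(u, cluster_config("greedy"))
  h <- cluster_otus(u, cluster_config("hierarchical"))
  us <- otubench:::sort_uniques(u)
  expect_equal(nrow(g), 6)
  expect_true(same_partition(otu_membership(g, us), otu_membership(h, us)))
})

test_that("otu_set respects the partition invariant and ordering", {
  set.seed(45)
  fx <- fixture_suite()
  u <- dereplicate(apply_filter(fx$singleton_community$sim$reads,
                                filter_params("relaxed"))$kept)
  ot <- cluster_otus(u, cluster_config("greedy"))
  expect_equal(sum(ot$total_abundance), sum(u$abundance))
  all_uids <- unlist(lapply(ot$members, `[[`, "uid"))
  expect_setequal(all_uids, u$uid)
  expect_false(anyDuplicated(all_uids) > 0)
  expect_true(all(diff(ot$total_abundance) <= 0))
  expect_equal(ot$otu_id, sprintf("OTU_%04d", seq_len(nrow(ot))))
  # permuting read order leaves the partition unchanged
  perm <- sample(length(fx$singleton_community$sim$reads))
  u2 <- dereplicate(apply_filter(fx$singleton_community$sim$reads[perm],
                                 filter_params("relaxed"))$kept)
  ot2 <- cluster_otus(u2, cluster_config("greedy"))
  expect_equal(ot$centroid, ot2$centroid)
  expect_equal(ot$total_abundance, ot2$total_abundance)
})

test_that("hierarchical guard, threshold monotonicity, OTU count ordering", {
  set.seed(46)
  u <- unique_set(replicate(8, rand_seq(60)), sample(1:5, 8, replace = TRUE))
  expect_error(
    hierarchical_cluster(u, cluster_config("hierarchical",
                                           max_matrix_size = 5L)),
    "capacity")
  d <- distance_matrix(otubench:::sort_uniques(u),
                       identity_config("each_gap"), undefined = "max")
  counts <- vapply(c(0.01, 0.05, 0.2, 0.9), function(h)
    max(agglomerate(d, h)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # elementwise-larger matrices never give fewer clusters (average/furthest)
  d2 <- pmin(d * 1.5, 1)
  for (lk in c("average", "furthest"))
    expect_gte(max(agglomerate(d2, 0.1, lk)), max(agglomerate(d, 0.1, lk)))
})

test_that("best_hit greedy picks the closest qualifying centroid", {
  base <- strsplit(strrep("ACGT", 25), "")[[1]]
  mk <- function(k) {                 # k mismatches vs base
    ch <- base
    if (k > 0) for (p in seq_len(k)) ch[p * 7] <- setdiff(BASES4, ch[p * 7])[1]
    paste(ch, collapse = "")
  }
  # centroid A (abundant), centroid B (2nd), query equidistant-ish: 2 vs 1
  u <- unique_set(c(mk(0), mk(3), mk(2)), c(10L, 8L, 1L))
  cfgF <- cluster_config("greedy", divergence_threshold = 0.025,
                         identity_cfg = identity_config("no_gaps"),
                         accept_mode = "first_hit")
  cfgB <- cluster_config("greedy", divergence_threshold = 0.025,
                         identity_cfg = identity_config("no_gaps"),
                         accept_mode = "best_hit")
  otF <- greedy_cluster(u, cfgF)
  otB <- greedy_cluster(u, cfgB)
  # first_hit: query (2 diffs from A = 0.02 <= 0.025) joins A
  expect_equal(otF$members[[1]]$abundance, c(10L, 1L))
  # best_hit: query is 1 diff from B (0.01) -> joins B
  expect_equal(otB$members[[2]]$abundance, c(8L, 1L))
})
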