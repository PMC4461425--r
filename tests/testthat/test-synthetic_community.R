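test_that("reference generation is deterministic and respects the floor", {
  spec <- community_spec(n_species = 8L, seed = 61L)
  a <- generate_references(spec)
  b <- generate_references(spec)
  expect_identical(a, b)
  lens <- nchar(a$references$sequence)
  expect_true(all(lens >= 400 & lens <= 600))
  # pairwise no-gaps divergence >= 0.06 on full template and 400-prefix
  ng <- identity_config("no_gaps")
  for (i in 1:7) for (j in (i + 1):8) {
    expect_gte(pair_divergence(a$references$sequence[i],
                               a$references$sequence[j], ng,
                               undefined = "max", min_coverage = 0.5),
               0.06)
    expect_gte(pair_divergence(substr(a$references$sequence[i], 1, 400),
                               substr(a$references$sequence[j], 1, 400),
                               ng, undefined = "max", min_coverage = 0.5),
               0.06)
  }
  # copy structure: first copy is the species template
  expect_equal(vapply(a$templates, `[`, character(1), 1),
               setNames(a$references$sequence, a$references$species))
  # single species, single copy
  one <- generate_references(community_spec(n_species = 1L,
                                            copies_per_species = c(1L, 1L),
                                            seed = 62L))
  expect_equal(nrow(one$references), 1)
  expect_length(one$templates[[1]], 1)
})

test_that("read simulation is deterministic and labels every read", {
  comm <- generate_references(community_spec(n_species = 5L, seed = 63L))
  s1 <- simulate_reads(comm, 200, seed = 64L)
  s2 <- simulate_reads(comm, 200, seed = 64L)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$truth), 200)
  expect_setequal(s1$truth$read_id, s1$reads$id)
  expect_error(simulate_reads(comm, 0), "positive")
})

test_that("zero error rates give exact primer + template reads", {
  comm <- generate_references(community_spec(n_species = 4L, seed = 65L,
                                             copies_per_species = c(1L, 1L)))
  err0 <- error_model(sub_rate = 0, indel_rate = 0,
                      homopolymer_slip_prob = 0, chimera_rate = 0)
  sim <- simulate_reads(comm, 50, err = err0, seed = 66L)
  expect_true(all(sim$truth$n_errors == 0))
  expect_false(any(sim$truth$is_chimera))
  tmap <- setNames(comm$references$sequence, comm$references$species)
  stripped <- substring(sim$reads$seq, 21)
  expect_equal(stripped, unname(tmap[sim$truth$species]))
  # and the primer prefix is a valid realisation of the degenerate primer
  mm <- otubench:::iupac_prefix_mismatches(sim$reads$seq, primer_uni18s())
  expect_true(all(mm == 0))
})

test_that("forced homopolymer slippage changes run length by one", {
  template <- paste0(strrep("CT", 10), "AAAA", strrep("GA", 10))
  comm <- list(references = data.frame(species = "sp1",
                                       sequence = template,
                                       stringsAsFactors = FALSE),
               templates = list(sp1 = template))
  err <- error_model(sub_rate = 0, indel_rate = 0,
                     homopolymer_slip_prob = 1, chimera_rate = 0)
  sim <- simulate_reads(comm, 30, err = err, seed = 67L)
  runs <- vapply(substring(sim$reads$seq, 21), function(s) {
    r <- rle(strsplit(s, "")[[1]])
    max(r$lengths[r$values == "A"])
  }, numeric(1), USE.NAMES = FALSE)
  expect_true(all(runs %in% c(3, 5)))
  expect_true(all(sim$truth$n_errors >= 1))
})

test_that("injected error counts match alignment differences (constructed)", {
  set.seed(68)
  template <- rand_seq(300)
  # substitutions only
  err <- error_model(sub_rate = 0.01, indel_rate = 0,
                     homopolymer_slip_prob = 0, chimera_rate = 0)
  comm <- list(references = data.frame(species = "sp1", sequence = template,
                                       stringsAsFactors = FALSE),
               templates = list(sp1 = template))
  # simulate without a primer so the template is the exact pre-error read
  sim <- simulate_reads(comm, 20, err = err, seed = 69L, primer = "")
  for (i in seq_len(20)) {
    st <- global_align(sim$reads$seq[i], template,
                       align_scoring(free_end_gaps = FALSE))$stats
    expect_equal(st[["X"]], sim$truth$n_errors[i])
    expect_equal(st[["C_int"]] + st[["C_term"]], 0)
  }
})

test_that("chimeras are two-parent crossovers, flagged and never filtered", {
  comm <- generate_references(community_spec(n_species = 6L, seed = 70L,
                                             copies_per_species = c(1L, 1L)))
  err <- error_model(sub_rate = 0, indel_rate = 0,
                     homopolymer_slip_prob = 0, chimera_rate = 1)
  sim <- simulate_reads(comm, 10, err = err, seed = 71L)
  expect_true(all(sim$truth$is_chimera))
  expect_true(all(!is.na(sim$truth$parent_a) & !is.na(sim$truth$parent_b)))
  expect_true(all(sim$truth$parent_a != sim$truth$parent_b))
  tmap <- setNames(comm$references$sequence, comm$references$species)
  for (i in 1:10) {
    body <- substring(sim$reads$seq[i], 21)
    pa <- tmap[[sim$truth$parent_a[i]]]
    pb <- tmap[[sim$truth$parent_b[i]]]
    expect_equal(nchar(body), nchar(pb))  # length taken from the 3' parent
    # a crossover point k must exist: body = pa[1..k] + pb[(k+1)..]
    bodyc <- strsplit(body, "")[[1]]
    pac <- strsplit(pa, "")[[1]]; pbc <- strsplit(pb, "")[[1]]
    lo <- min(length(pac), length(bodyc))
    kmax <- which(c(bodyc[seq_len(lo)] != pac[seq_len(lo)], TRUE))[1] - 1
    msuf <- rev(bodyc) != rev(pbc)
    suf_len <- if (any(msuf)) which(msuf)[1] - 1 else length(bodyc)
    expect_gte(kmax + suf_len, nchar(body))
  }
})

test_that("log-normal abundances yield singletons; dropout removes species", {
  fx <- fixture_suite()
  u <- dereplicate(fx$singleton_community$sim$reads)
  expect_gt(sum(u$abundance == 1L), 0)
  comm <- fx$singleton_community$community
  sim <- simulate_reads(comm, 300, seed = 72L, n_dropout_species = 3L)
  expect_lte(length(unique(sim$truth$species[!sim$truth$is_chimera])), 5)
})

test_that("indel-type errors inflate each_gap OTU counts more than one_gap", {
  comm <- generate_references(community_spec(n_species = 8L, seed = 73L))
  low <- error_model(sub_rate = 1e-3, indel_rate = 0,
                     homopolymer_slip_prob = 0, chimera_rate = 0)
  high <- error_model(sub_rate = 1e-3, indel_rate = 0.004,
                      homopolymer_slip_prob = 0.05, chimera_rate = 0)
  count_otus <- function(sim, def) {
    u <- dereplicate(apply_filter(sim$reads,
                                  filter_params("relaxed"))$kept)
    nrow(greedy_cluster(u, cluster_config(
      "greedy", identity_cfg = identity_config(def, "count"))))
  }
  d_eg <- d_og <- 0
  for (s in 1:3) {
    sim_lo <- simulate_reads(comm, 300L, err = low, seed = 740L + s)
    sim_hi <- simulate_reads(comm, 300L, err = high, seed = 740L + s)
    d_eg <- d_eg + count_otus(sim_hi, "each_gap") -
      count_otus(sim_lo, "each_gap")
    d_og <- d_og + count_otus(sim_hi, "one_gap") -
      count_otus(sim_lo, "one_gap")
  }
  # indel and homopolymer errors create gaps; counting every gapped base
  # (each_gap) must inflate OTU numbers at least as much as counting runs
  expect_gte(d_eg, d_og)
  expect_gt(d_eg, 0)
})

test_that("fixture_suite exposes the documented scenarios", {
  fx <- fixture_suite()
  expect_equal(nchar(fx$prefix_pair$sequence), c(440L, 400L))
  expect_equal(substr(fx$prefix_pair$sequence[1], 1, 400),
               fx$prefix_pair$sequence[2])
  d <- pair_divergence(fx$close_species$refs$sequence[1],
                       fx$close_species$refs$sequence[2],
                       identity_config("no_gaps"))
  expect_gt(d, 0.01); expect_lt(d, 0.03)
  d <- pair_divergence(fx$divergent_copies$uniques$sequence[1],
                       fx$divergent_copies$uniques$sequence[2],
                       identity_config("no_gaps"))
  expect_gt(d, 0.03)
  # close species merge at 3%, split at 1%
  expect_equal(nrow(greedy_cluster(fx$close_species$uniques,
                                   cluster_config("greedy", 0.03))), 1)
  expect_equal(nrow(greedy_cluster(fx$close_species$uniques,
                                   cluster_config("greedy", 0.01))), 2)
})
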