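test_that("identity formulas reproduce hand arithmetic", {
  st <- c(M = 390, X = 6, C_int = 4, R_int = 1, C_term = 0, R_term = 0)
  expect_equal(seq_identity(st, identity_config("no_gaps")), 390 / 396)
  expect_equal(seq_identity(st, identity_config("one_gap")), 390 / 397)
  expect_equal(seq_identity(st, identity_config("each_gap")), 390 / 400)
  # prefix pair: M=4, C_term=4, R_term=1
  st <- global_align("ACGTACGT", "ACGT")$stats
  expect_equal(st[["M"]], 4)
  expect_equal(st[["C_term"]], 4)
  expect_equal(st[["R_term"]], 1)
  expect_equal(seq_identity(st, identity_config("each_gap", "count")), 0.5)
  expect_equal(seq_identity(st, identity_config("each_gap", "exclude")), 1)
  expect_equal(seq_identity(st, identity_config("no_gaps")), 1)
  # identical sequences: 1 under every definition and policy
  st <- global_align("ACGTACGT", "ACGTACGT")$stats
  for (d in c("no_gaps", "one_gap", "each_gap"))
    for (p in c("count", "exclude"))
      expect_equal(seq_identity(st, identity_config(d, p)), 1)
  expect_error(seq_identity(c(M = 0, X = 0, C_int = 0, R_int = 0,
                              C_term = 4, R_term = 1),
                            identity_config("no_gaps")), "undefined")
})

test_that("alignment_stats counts columns and runs by hand-checked cases", {
  expect_equal(alignment_stats(c("AC-GT", "ACCGT"))[c("M", "X", "C_int",
                                                      "R_int", "C_term")],
               c(M = 4, X = 0, C_int = 1, R_int = 1, C_term = 0))
  expect_equal(alignment_stats(c("ACGT----", "ACGTACGT"))[c("M", "C_term",
                                                            "R_term",
                                                            "C_int")],
               c(M = 4, C_term = 4, R_term = 1, C_int = 0))
  expect_equal(alignment_stats(c("A--T", "AGCT"))[c("M", "C_int", "R_int")],
               c(M = 2, C_int = 2, R_int = 1))
  # N is a wildcard match by default, a mismatch when disabled
  expect_equal(alignment_stats(c("ANGT", "ACGT"))[["M"]], 4)
  expect_equal(alignment_stats(c("ANGT", "ACGT"), n_wildcard = FALSE)[["X"]],
               1)
  expect_error(alignment_stats(c("A-T", "A-T")), "all-gap")
})

test_that("R and C++ stats agree on random gapped pairs (dual route)", {
  set.seed(31)
  for (rep in 1:50) {
    p <- rand_gapped_pair(sample(10:60, 1))
    expect_equal(
      alignment_stats(p),
      otubench:::cpp_gapped_stats(p$gapped_a, p$gapped_b, TRUE),
      ignore_attr = TRUE)
  }
})

test_that("aligner matches the explicit-gap-length DP oracle on short seqs", {
  set.seed(32)
  for (rep in 1:120) {
    a <- rand_seq(sample(1:12, 1))
    b <- rand_seq(sample(1:12, 1))
    for (free in c(TRUE, FALSE)) {
      got <- global_align(a, b, align_scoring(free_end_gaps = free))
      expect_equal(got$score,
                   oracle_align_score(a, b, free_end_gaps = free),
                   info = sprintf("%s vs %s free=%s", a, b, free))
      # the returned alignment itself must attain the reported score
      st <- alignment_stats(got)
      gap_runs_cost <- function(g) {
        r <- rle(strsplit(g, "")[[1]] == "-")
        runs <- r$lengths[r$values]
        if (!length(runs)) return(0)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
        term <- (starts == 1 | ends == sum(r$lengths))[r$values]
        sum(ifelse(term & free, 0, -10 - runs))
      }
      rescore <- st[["M"]] * 1 + st[["X"]] * -2 +
        gap_runs_cost(got$gapped_a) + gap_runs_cost(got$gapped_b)
      expect_equal(rescore, got$score)
    }
  }
})

test_that("spec example ACGT vs AGT: one internal gap under penalised ends", {
  got <- global_align("ACGT", "AGT", align_scoring(free_end_gaps = FALSE))
  st <- alignment_stats(got)
  expect_equal(st[["M"]], 3)
  expect_equal(st[["X"]], 0)
  expect_equal(st[["C_int"]] + st[["C_term"]], 1)
  # under free end gaps the optimum trades the costly internal gap for a
  # terminal one (score 0 beats -8)
  free <- global_align("ACGT", "AGT")
  expect_equal(free$score, 0)
  expect_equal(alignment_stats(free)[["C_term"]], 1)
})

test_that("identity ordering and policy ordering hold (property)", {
  set.seed(33)
  for (rep in 1:200) {
    st <- alignment_stats(rand_gapped_pair(sample(15:60, 1)))
    ids <- sapply(c("no_gaps", "one_gap", "each_gap"), function(d)
      seq_identity(st, identity_config(d, "count")))
    expect_true(ids[1] >= ids[2] && ids[2] >= ids[3])
    for (d in c("one_gap", "each_gap"))
      expect_gte(seq_identity(st, identity_config(d, "exclude")),
                 seq_identity(st, identity_config(d, "count")))
    expect_equal(seq_identity(st, identity_config("no_gaps", "exclude")),
                 seq_identity(st, identity_config("no_gaps", "count")))
  }
})

test_that("identity is symmetric and definitions coincide without gaps", {
  set.seed(34)
  for (rep in 1:20) {
    a <- rand_seq(40); b <- rand_seq(sample(30:50, 1))
    for (d in c("no_gaps", "one_gap", "each_gap")) {
      cfg <- identity_config(d)
      expect_equal(pair_divergence(a, b, cfg, undefined = "max"),
                   pair_divergence(b, a, cfg, undefined = "max"))
    }
    # gap-free alignment: all three definitions coincide
    m <- rand_seq(40)
    m2 <- strsplit(m, "")[[1]]
    pos <- sample(40, 3)
    m2[pos] <- vapply(m2[pos], function(x)
      sample(setdiff(BASES4, x), 1), character(1))
    m2 <- paste(m2, collapse = "")
    vals <- sapply(c("no_gaps", "one_gap", "each_gap"), function(d)
      pair_divergence(m, m2, identity_config(d)))
    expect_true(all(vals == vals[1]))
  }
})

test_that("msa_pair_identity drops shared gap columns first", {
  expect_equal(msa_pair_identity("AC-GT", "AC-GT"), 1)
  # consistency with the pairwise path on the same implied alignment
  expect_equal(msa_pair_identity("AC-GT", "ACCGT",
                                 identity_config("each_gap")),
               seq_identity(alignment_stats(c("AC-GT", "ACCGT")),
                            identity_config("each_gap")))
  # "A---T" / "-ACGT": no shared gap column; row 1's run (cols 2-4) is
  # internal, row 2's leading gap is terminal; only T/T is comparable
  st <- otubench:::cpp_msa_pair_stats("A---T", "-ACGT", TRUE)
  expect_equal(st[["M"]], 1)
  expect_equal(st[["C_int"]], 3)
  expect_equal(st[["R_int"]], 1)
  expect_equal(st[["C_term"]], 1)
  expect_equal(st[["R_term"]], 1)
  expect_error(msa_pair_identity("AC-GT", "ACGT"), "widths")
  # a run ending at the last retained column is terminal
  st <- otubench:::cpp_msa_pair_stats("ACG--", "ACGTT", TRUE)
  expect_equal(st[["C_term"]], 2)
  expect_equal(st[["C_int"]], 0)
})

test_that("distance_matrix is symmetric, zero-diagonal, def-ordered", {
  expect_equal(distance_matrix(c(a = "ACGTACGT", b = "ACGTACGT")),
               matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  set.seed(35)
  seqs <- replicate(6, paste0(rand_seq(30), strrep("AC", sample(0:8, 1))))
  names(seqs) <- sprintf("s%d", 1:6)
  d_ng <- distance_matrix(seqs, identity_config("no_gaps"), undefined = "max")
  d_og <- distance_matrix(seqs, identity_config("one_gap"), undefined = "max")
  d_eg <- distance_matrix(seqs, identity_config("each_gap"),
                          undefined = "max")
  expect_true(all(d_eg >= d_og - 1e-12) && all(d_og >= d_ng - 1e-12))
  expect_true(all(diag(d_eg) == 0))
  expect_equal(d_eg, t(d_eg))
  # MSA route agrees with direct per-pair computation
  msa <- data.frame(seq_id = c("a", "b"),
                    gapped_sequence = c("AC-GT", "ACCGT"),
                    stringsAsFactors = FALSE)
  dm <- distance_matrix(msa, identity_config("each_gap"))
  expect_equal(dm["a", "b"],
               1 - msa_pair_identity("AC-GT", "ACCGT",
                                     identity_config("each_gap")))
})

test_that("phylip lower-triangle export is readable", {
  d <- matrix(c(0, 0.1, 0.1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  f <- withr::local_tempfile(fileext = ".dist")
  write_phylip_lower(d, f)
  lines <- readLines(f)
  expect_equal(lines[1], "2")
  expect_match(lines[3], "^b\t0\\.100000$")
})
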