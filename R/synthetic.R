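# Seeded generator of mock-community references and error-bearing reads.
# The stated world it emulates: a 454-sequenced, length-variable 18S V4
# amplicon community (~400-600 bp post-primer, conserved flanks around a
# freely expanding/contracting core, intragenomic rRNA copy variants,
# substitution/indel/homopolymer errors, PCR chimeras, skewed abundances).

# evaluate `code` under a temporary RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")

# random sequence with occasional homopolymer runs (3-6 nt), the error
# substrate of pyrosequencing slippage
random_seq_chars <- function(n, hp_prob = 0.08) {
  out <- character(0)
  while (length(out) < n) {
    b <- sample(BASES, 1)
    len <- if (runif(1) < hp_prob) sample(3:6, 1) else 1L
    out <- c(out, rep(b, len))
  }
  out[seq_len(n)]
}

mutate_chars <- function(x, sub_rate = 0, indel_rate = 0) {
  n <- length(x)
  subs <- which(runif(n) < sub_rate)
  if (length(subs))
    x[subs] <- vapply(x[subs], function(b) sample(setdiff(BASES, b), 1),
                      character(1))
  if (indel_rate > 0) {
    u <- runif(n)
    del <- u < indel_rate / 2
    ins <- u >= indel_rate / 2 & u < indel_rate
    pieces <- ifelse(del, "", x)
    insb <- which(ins)
    if (length(insb))
      pieces[insb] <- paste0(x[insb],
                             vapply(insb, function(i) sample(BASES, 1),
                                    character(1)))
    x <- strsplit(paste(pieces, collapse = ""), "")[[1]]
  }
  x
}

#' Specification of a synthetic mock community
#'
#' Defaults describe the benchmark community: 43 reference species (the
#' usable, amplified and distinguishable, fraction of a 61-species mock
#' community), amplicon lengths spanning 400-600 nt after the primer, all
#' species pairs at least 6% diverged (twice the usual 3% clustering
#' threshold), and one to three intragenomic rRNA copies per species
#' carrying slight copy variation.
#'
#' @param n_species number of species.
#' @param length_range post-primer template length window (nt).
#' @param min_interspecies_divergence floor on pairwise *no gaps*
#'   divergence between species templates, enforced both on the full
#'   template and on its leading 400 nt (so stringent trimming cannot erase
#'   distinguishability).
#' @param copies_per_species integer range (length 2) of rRNA copies.
#' @param copy_sub_rate,copy_indel_rate per-base rates of copy variation.
#' @param seed integer seed; generation is deterministic under it.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(n_species = 43L,
                           length_range = c(400L, 600L),
                           min_interspecies_divergence = 0.06,
                           copies_per_species = c(1L, 3L),
                           copy_sub_rate = 0.005,
                           copy_indel_rate = 0.001,
                           seed = 1L) {
  stopifnot(length(length_range) == 2, length_range[1] <= length_range[2],
            n_species >= 1, min_interspecies_divergence > 0,
            length(copies_per_species) == 2)
  structure(list(n_species = as.integer(n_species),
                 length_range = as.integer(length_range),
                 min_interspecies_divergence = min_interspecies_divergence,
                 copies_per_species = as.integer(copies_per_species),
                 copy_sub_rate = copy_sub_rate,
                 copy_indel_rate = copy_indel_rate,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Error model for read simulation
#'
#' 454-like defaults chosen a priori: substitutions 1e-3 per base, indels
#' 5e-4 per base, homopolymer slippage (run length changes by one) at 0.01
#' per run of length >= 3, chimeras in 1% of reads, and a positional
#' quality profile: mean Q35 at the 5' end decaying by `quality_slope`
#' phred units per base (default -1/60, i.e., Q25 at position 600) with
#' per-base jitter. The decay is a function of base *position*, as on the
#' instrument -- a short read's bases are not lower-quality than the same
#' positions of a long read. Qualities are drawn independently of the
#' injected errors (see the methods vignette for what this does and does
#' not test).
#'
#' @param sub_rate per-base substitution probability.
#' @param indel_rate per-base indel probability (split evenly between
#'   insertion and deletion).
#' @param homopolymer_slip_prob per-run probability of a +-1 length change
#'   for mononucleotide runs of length >= 3.
#' @param chimera_rate per-read probability of a two-parent PCR crossover.
#' @param quality_mean5 mean phred at the first base.
#' @param quality_slope mean phred change per base position (negative).
#' @param quality_sd per-base phred jitter (sd).
#' @return object of class `error_model`.
#' @export
error_model <- function(sub_rate = 1e-3, indel_rate = 5e-4,
                        homopolymer_slip_prob = 0.01, chimera_rate = 0.01,
                        quality_mean5 = 35, quality_slope = -1 / 60,
                        quality_sd = 2) {
  rates <- c(sub_rate, indel_rate, homopolymer_slip_prob, chimera_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), quality_slope <= 0)
  structure(list(sub_rate = sub_rate, indel_rate = indel_rate,
                 homopolymer_slip_prob = homopolymer_slip_prob,
                 chimera_rate = chimera_rate,
                 quality_mean5 = quality_mean5,
                 quality_slope = quality_slope,
                 quality_sd = quality_sd),
            class = "error_model")
}

#' Generate mock-community reference sequences and per-species templates
#'
#' Species templates share conserved flanks (mimicking the conserved
#' regions surrounding a hypervariable core) and differ by heavy core
#' substitution plus a species-specific core contraction, which yields the
#' large inter-taxon length differences characteristic of the marker.
#' Pairwise *no gaps* divergences are validated (full template and leading
#' 400 nt) against `spec$min_interspecies_divergence`, re-drawing offenders
#' a bounded number of times. Intragenomic copies are light mutations of
#' the species template (copy 1 is the template itself). Deterministic
#' under `spec$seed`.
#'
#' @param spec a [community_spec].
#' @return list with `references` (data.frame `species`, `sequence` --
#'   copy 1 of each species) and `templates` (named list of character
#'   vectors, one per species, copies in order).
#' @export
generate_references <- function(spec = community_spec()) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    n <- spec$n_species
    minl <- spec$length_range[1]; maxl <- spec$length_range[2]
    flk <- min(120L, max(20L, minl %/% 4L))
    core_max <- maxl - 2L * flk
    if (core_max < 10L) stop("length_range too short for template structure")
    flank5 <- random_seq_chars(flk)
    flank3 <- random_seq_chars(flk)
    anc_core <- random_seq_chars(core_max)
    draw_template <- function(target_len) {
      core_len <- target_len - 2L * flk
      cut <- core_max - core_len
      core <- anc_core
      if (cut > 0) {
        start <- sample(core_max - cut + 1L, 1)
        core <- core[-(start:(start + cut - 1L))]
      }
      core <- mutate_chars(core, sub_rate = 0.15)
      f5 <- mutate_chars(flank5, sub_rate = 0.03)
      f3 <- mutate_chars(flank3, sub_rate = 0.03)
      paste(c(f5, core, f3), collapse = "")
    }
    lens <- sample(seq(minl, maxl), n, replace = TRUE)
    templates <- vapply(lens, draw_template, character(1))
    # divergence validation with bounded re-draws of offending templates
    ng <- identity_config("no_gaps")
    too_close <- function(a, b) {
      # coverage-guarded: a coincidental short exact overlap is not
      # evidence of relatedness (divergence 1, passes the floor)
      d_full <- pair_divergence(a, b, ng, undefined = "max",
                                min_coverage = 0.5)
      if (d_full < spec$min_interspecies_divergence) return(TRUE)
      pa <- substr(a, 1, 400); pb <- substr(b, 1, 400)
      pair_divergence(pa, pb, ng, undefined = "max", min_coverage = 0.5) <
        spec$min_interspecies_divergence
    }
    if (n > 1) {
      for (i in seq(2, n)) {
        tries <- 0L
        repeat {
          bad <- any(vapply(seq_len(i - 1), function(j)
            too_close(templates[i], templates[j]), logical(1)))
          if (!bad) break
          tries <- tries + 1L
          if (tries > 25L)
            stop("could not satisfy divergence/length constraints; ",
                 "relax min_interspecies_divergence or length_range")
          templates[i] <- draw_template(lens[i])
        }
      }
    }
    species <- sprintf("species_%02d", seq_len(n))
    copies <- lapply(seq_len(n), function(i) {
      k <- sample(seq(spec$copies_per_species[1], spec$copies_per_species[2]),
                  1)
      c(templates[i], vapply(seq_len(max(0L, k - 1L)), function(j)
        paste(mutate_chars(strsplit(templates[i], "")[[1]],
                           spec$copy_sub_rate, spec$copy_indel_rate),
              collapse = ""), character(1)))
    })
    names(copies) <- species
    list(references = data.frame(species = species, sequence = templates,
                                 stringsAsFactors = FALSE),
         templates = copies)
  })
}

# one realisation of a degenerate IUPAC primer
realize_primer <- function(primer) {
  ch <- strsplit(toupper(primer), "")[[1]]
  paste(vapply(ch, function(b) {
    s <- setdiff(IUPAC_SETS[[b]], "N")
    if (length(s) == 1) s else sample(s, 1)
  }, character(1)), collapse = "")
}

# apply the error model to one template; returns list(seq, n_errors)
inject_errors <- function(template, err) {
  x <- strsplit(template, "")[[1]]
  n_err <- 0L
  if (err$homopolymer_slip_prob > 0) {
    r <- rle(x)
    idx <- which(r$lengths >= 3L)
    if (length(idx)) {
      slip <- idx[runif(length(idx)) < err$homopolymer_slip_prob]
      if (length(slip)) {
        r$lengths[slip] <- r$lengths[slip] +
          sample(c(-1L, 1L), length(slip), replace = TRUE)
        n_err <- n_err + length(slip)
        x <- inverse.rle(r)
      }
    }
  }
  n <- length(x)
  subs <- which(runif(n) < err$sub_rate)
  if (length(subs)) {
    x[subs] <- vapply(x[subs], function(b) sample(setdiff(BASES, b), 1),
                      character(1))
    n_err <- n_err + length(subs)
  }
  if (err$indel_rate > 0) {
    u <- runif(length(x))
    del <- u < err$indel_rate / 2
    ins <- u >= err$indel_rate / 2 & u < err$indel_rate
    if (any(del) || any(ins)) {
      pieces <- ifelse(del, "", x)
      for (i in which(ins)) pieces[i] <- paste0(x[i], sample(BASES, 1))
      n_err <- n_err + sum(del) + sum(ins)
      x <- strsplit(paste(pieces, collapse = ""), "")[[1]]
    }
  }
  list(seq = paste(x, collapse = ""), n_errors = n_err)
}

#' Simulate error-bearing amplicon reads with ground truth
#'
#' Reads are drawn species-first under the abundance model (log-normal by
#' default, so rare species and singletons arise naturally; uniform mirrors
#' an equal-tissue mock community), then a copy uniformly. With probability
#' `err$chimera_rate` a read is a two-parent crossover at a uniform
#' breakpoint, flagged in the ground truth but never filtered here. A
#' realisation of the degenerate forward primer is prepended before errors
#' are injected, so the primer-matching stage of filtering is exercised
#' (including primer-region errors). Qualities follow the model's 5'->3'
#' decay profile.
#'
#' @param community output of [generate_references].
#' @param n_reads number of reads (> 0).
#' @param err an [error_model].
#' @param abundance `"lognormal"` or `"uniform"`.
#' @param sigma log-normal sd parameter (default 1.2).
#' @param seed integer seed.
#' @param primer IUPAC forward primer prepended to each read.
#' @param n_dropout_species drop this many randomly chosen species from the
#'   read pool (emulating amplification failure); they stay in the
#'   reference set.
#' @return list with `reads` (a [read_set]) and `truth` (data.frame
#'   `read_id`, `species`, `copy_index`, `is_chimera`, `parent_a`,
#'   `parent_b`, `n_errors`).
#' @export
simulate_reads <- function(community, n_reads, err = error_model(),
                           abundance = c("lognormal", "uniform"),
                           sigma = 1.2, seed = 1L,
                           primer = primer_uni18s(),
                           n_dropout_species = 0L) {
  abundance <- match.arg(abundance)
  if (n_reads <= 0) stop("n_reads must be positive")
  tmpl <- community$templates
  n_sp <- length(tmpl)
  species <- names(tmpl)
  with_seed(seed, {
    w <- if (abundance == "lognormal") rlnorm(n_sp, 0, sigma) else
      rep(1, n_sp)
    if (n_dropout_species > 0)
      w[sample(n_sp, min(n_dropout_species, n_sp))] <- 0
    if (all(w == 0)) stop("all species dropped out")
    sp_idx <- sample.int(n_sp, n_reads, replace = TRUE, prob = w)
    is_chi <- runif(n_reads) < err$chimera_rate
    ids <- sprintf("read_%05d", seq_len(n_reads))
    seqs <- character(n_reads)
    quals <- vector("list", n_reads)
    truth <- data.frame(read_id = ids, species = species[sp_idx],
                        copy_index = NA_integer_, is_chimera = is_chi,
                        parent_a = NA_character_, parent_b = NA_character_,
                        n_errors = NA_integer_, stringsAsFactors = FALSE)
    for (i in seq_len(n_reads)) {
      if (is_chi[i]) {
        others <- which(w > 0 & seq_len(n_sp) != sp_idx[i])
        sp_b <- if (length(others)) {
          if (length(others) == 1) others else
            sample(others, 1, prob = w[others])
        } else sp_idx[i]
        ca <- sample(length(tmpl[[sp_idx[i]]]), 1)
        cb <- sample(length(tmpl[[sp_b]]), 1)
        a <- tmpl[[sp_idx[i]]][ca]; b <- tmpl[[sp_b]][cb]
        lo <- min(nchar(a), nchar(b))
        bp <- sample(seq(max(1L, lo %/% 4L), lo - 1L), 1)
        template <- paste0(substr(a, 1, bp), substring(b, bp + 1))
        truth$parent_a[i] <- species[sp_idx[i]]
        truth$parent_b[i] <- species[sp_b]
        truth$copy_index[i] <- ca
      } else {
        ci <- sample(length(tmpl[[sp_idx[i]]]), 1)
        truth$copy_index[i] <- ci
        template <- tmpl[[sp_idx[i]]][ci]
      }
      full <- paste0(realize_primer(primer), template)
      mut <- inject_errors(full, err)
      truth$n_errors[i] <- mut$n_errors
      seqs[i] <- mut$seq
      L <- nchar(mut$seq)
      prof <- err$quality_mean5 + err$quality_slope * (seq_len(L) - 1)
      q <- as.integer(round(prof + rnorm(L, 0, err$quality_sd)))
      quals[[i]] <- pmin(pmax(q, 2L), 41L)
    }
    list(reads = read_set(ids, seqs, quals), truth = truth)
  })
}

#' Curated small fixtures used across the test-suite and examples
#'
#' * `prefix_pair`: a 440 nt sequence and its 400 nt prefix as a two-row
#'   `unique_set` -- the minimal terminal-gap OTU-splitting case.
#' * `close_species`: two reference species ~1% diverged (undersplitting at
#'   a 3% threshold, split at 1%).
#' * `divergent_copies`: one species with two templates ~10% apart
#'   (oversplitting at 3%).
#' * `singleton_community`: a small 8-species community with log-normal
#'   abundances and default errors, yielding singleton unique sequences.
#'
#' All fixtures are generated with fixed internal seeds.
#'
#' @return named list of fixtures.
#' @export
fixture_suite <- function() {
  with_seed(20150513, {
    base <- paste(random_seq_chars(440), collapse = "")
    prefix_pair <- unique_set(c(base, substr(base, 1, 400)), c(5L, 3L))

    sp_a <- paste(random_seq_chars(400), collapse = "")
    ch <- strsplit(sp_a, "")[[1]]
    pos <- sample(400, 4)
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1),
                      character(1))
    sp_b <- paste(ch, collapse = "")
    close_species <- list(
      refs = data.frame(species = c("species_A", "species_B"),
                        sequence = c(sp_a, sp_b), stringsAsFactors = FALSE),
      uniques = unique_set(c(sp_a, sp_b), c(10L, 8L)))

    t1 <- paste(random_seq_chars(400), collapse = "")
    c1 <- strsplit(t1, "")[[1]]
    pos <- sample(400, 40)
    c1[pos] <- vapply(c1[pos], function(b) sample(setdiff(BASES, b), 1),
                      character(1))
    t2 <- paste(c1, collapse = "")
    divergent_copies <- list(
      refs = data.frame(species = "species_C", sequence = t1,
                        stringsAsFactors = FALSE),
      uniques = unique_set(c(t1, t2), c(10L, 6L)))

    comm <- generate_references(community_spec(n_species = 8L, seed = 99L))
    sim <- simulate_reads(comm, n_reads = 600L, seed = 100L)
    list(prefix_pair = prefix_pair, close_species = close_species,
         divergent_copies = divergent_copies,
         singleton_community = list(community = comm, sim = sim))
  })
}
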