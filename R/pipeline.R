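#' Workflow configuration
#'
#' A flat-key description of one complete workflow: filtering regime and
#' thresholds, singleton policy, clustering algorithm/identity definition/
#' threshold, and classification thresholds. Round-trips losslessly through
#' JSON via [write_workflow_config]/[read_workflow_config].
#'
#' @param reads path to a FASTQ file, or a [read_set].
#' @param references path to a reference FASTA, a data.frame
#'   (`species`, `sequence`), or `NULL` for a natural-community run
#'   (classification skipped, only OTU counts reported).
#' @param regime filtering regime, `"stringent"` or `"relaxed"`.
#' @param keep_singletons keep abundance-1 unique sequences?
#' @param algorithm,definition,terminal_policy,threshold,linkage,accept_mode
#'   clustering controls (see [cluster_config] and [identity_config]).
#' @param min_identity,min_overlap classification thresholds.
#' @param filter_overrides named list of [filter_params] arguments
#'   overriding the regime defaults.
#' @param msa optional aligned FASTA path or MSA data.frame for
#'   hierarchical mode.
#' @param out_dir optional directory for artifacts.
#' @param seed integer seed recorded with the run.
#' @return object of class `workflow_config`.
#' @export
workflow_config <- function(reads, references = NULL,
                            regime = c("stringent", "relaxed"),
                            keep_singletons = FALSE,
                            algorithm = c("greedy", "hierarchical"),
                            definition = c("each_gap", "one_gap", "no_gaps"),
                            terminal_policy = c("count", "exclude"),
                            threshold = 0.03,
                            linkage = "average", accept_mode = "first_hit",
                            min_identity = 0.90, min_overlap = 200L,
                            filter_overrides = list(),
                            msa = NULL, out_dir = NULL, seed = 1L) {
  structure(list(reads = reads, references = references,
                 regime = match.arg(regime),
                 keep_singletons = isTRUE(keep_singletons),
                 algorithm = match.arg(algorithm),
                 definition = match.arg(definition),
                 terminal_policy = match.arg(terminal_policy),
                 threshold = threshold, linkage = linkage,
                 accept_mode = accept_mode,
                 min_identity = min_identity,
                 min_overlap = as.integer(min_overlap),
                 filter_overrides = filter_overrides,
                 msa = msa, out_dir = out_dir, seed = as.integer(seed)),
            class = "workflow_config")
}

#' Serialise / restore a workflow configuration
#'
#' Only path-valued `reads`/`references`/`msa` fields can be serialised;
#' in-memory objects raise an error.
#'
#' @param cfg a [workflow_config].
#' @param path JSON file path.
#' @return `path` (write) or a [workflow_config] (read).
#' @export
write_workflow_config <- function(cfg, path) {
  ser <- unclass(cfg)
  for (f in c("reads", "references", "msa"))
    if (!is.null(ser[[f]]) && !is.character(ser[[f]]))
      stop("cannot serialise in-memory '", f, "'; use a file path")
  jsonlite::write_json(ser, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_workflow_config
#' @export
read_workflow_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$filter_overrides <- as.list(x$filter_overrides)
  do.call(workflow_config, x)
}

resolve_reads <- function(x) {
  if (inherits(x, "read_set")) x else read_fastq(x)
}

resolve_refs <- function(x) {
  if (is.null(x) || is.data.frame(x)) x else read_reference_fasta(x)
}

#' Run one complete workflow
#'
#' Stages run in a fixed order: filter, dereplicate, singleton policy,
#' cluster, classify, summarise. Per-stage counts are collected in a
#' structured log; when `out_dir` is set, all intermediate artifacts are
#' written (kept FASTQ, unique FASTA, OTU FASTA, membership TSV,
#' classification TSV, summary JSON, JSON-lines log). An empty post-filter
#' dataset yields an explicit empty result with a warning, not an error.
#'
#' @param cfg a [workflow_config].
#' @return object of class `workflow_result`: list with `summary` (an
#'   `evaluation_summary` or `NULL`), `otus`, `classifications`, `uniques`,
#'   `filter_report`, `log`, `config`.
#' @export
run_workflow <- function(cfg) {
  stopifnot(inherits(cfg, "workflow_config"))
  reads <- resolve_reads(cfg$reads)
  refs <- resolve_refs(cfg$references)
  fp <- do.call(filter_params,
                c(list(regime = cfg$regime), cfg$filter_overrides))
  flt <- apply_filter(reads, fp)
  log <- list(list(stage = "filter", n_in = length(reads),
                   n_out = length(flt$kept),
                   report = as.list(flt$report)))
  uniq <- dereplicate(flt$kept)
  log <- c(log, list(list(stage = "dereplicate", n_in = length(flt$kept),
                          n_out = nrow(uniq))))
  if (!cfg$keep_singletons) {
    n0 <- nrow(uniq)
    uniq <- remove_singletons(uniq)
    log <- c(log, list(list(stage = "remove_singletons", n_in = n0,
                            n_out = nrow(uniq))))
  }
  icfg <- identity_config(cfg$definition, cfg$terminal_policy)
  ccfg <- cluster_config(cfg$algorithm, cfg$threshold, icfg,
                         linkage = cfg$linkage,
                         accept_mode = cfg$accept_mode)
  msa <- cfg$msa
  if (is.character(msa)) msa <- read_aligned_fasta(msa)
  if (nrow(uniq) == 0) {
    warning("no reads survived filtering/singleton removal; empty result")
    otus <- make_otu_set(uniq, integer(), integer())
    cls <- NULL
    summary <- NULL
  } else {
    otus <- cluster_otus(uniq, ccfg, msa = msa)
    log <- c(log, list(list(stage = "cluster", n_in = nrow(uniq),
                            n_out = nrow(otus))))
    if (!is.null(refs)) {
      cls <- classify_otus(otus, refs, cfg$min_identity, cfg$min_overlap)
      summary <- summarize_evaluation(cls, refs, nrow(otus))
      log <- c(log, list(list(stage = "classify", n_in = nrow(otus),
                              n_matched = summary$n_matched_otus)))
    } else {
      cls <- NULL
      summary <- NULL
    }
  }
  res <- structure(list(summary = summary, otus = otus,
                        classifications = cls, uniques = uniq,
                        filter_report = flt$report, log = log,
                        config = cfg),
                   class = "workflow_result")
  if (!is.null(cfg$out_dir)) write_workflow_artifacts(res, cfg$out_dir)
  res
}

#' @export
print.workflow_result <- function(x, ...) {
  cat(sprintf("workflow [%s filter, singletons %s, %s/%s/%s @ %.3g]\n",
              x$config$regime,
              if (x$config$keep_singletons) "included" else "removed",
              x$config$algorithm, x$config$definition,
              x$config$terminal_policy, x$config$threshold))
  cat(sprintf("  %d OTU(s) from %d unique sequence(s)\n",
              nrow(x$otus), nrow(x$uniques)))
  if (!is.null(x$summary)) { cat("  "); print(x$summary) }
  invisible(x)
}

write_workflow_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_uniques_fasta(res$uniques, file.path(dir, "uniques.fasta"))
  write_otu_fasta(res$otus, file.path(dir, "otus.fasta"))
  write_otu_membership(res$otus, file.path(dir, "membership.tsv"))
  if (!is.null(res$classifications))
    utils::write.table(res$classifications,
                       file.path(dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$summary))
    jsonlite::write_json(unclass(res$summary),
                         file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  loglines <- vapply(res$log, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE), character(1))
  writeLines(loglines, file.path(dir, "log.jsonl"))
  invisible(dir)
}

#' Align sequences with MAFFT
#'
#' Thin wrapper over an external `mafft` binary (`--retree 2 --quiet`,
#' deterministic). Used by [compare_workflows] for the distance matrix of
#' hierarchical mode, as hierarchical clustering of amplicons is
#' conventionally run on a multiple sequence alignment.
#'
#' @param seqs named character vector (or `unique_set`) to align.
#' @param mafft path to the mafft executable.
#' @return MSA data.frame (`seq_id`, `gapped_sequence`).
#' @export
align_with_mafft <- function(seqs, mafft = Sys.which("mafft")) {
  if (!nzchar(mafft)) stop("mafft executable not found")
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$uid)
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)))
  write_fasta(seqs, fin)
  status <- system2(mafft, c("--retree", "2", "--quiet", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (!identical(status, 0L)) stop("mafft failed with status ", status)
  read_aligned_fasta(fout)
}

#' Run the factorial workflow grid
#'
#' Crosses filtering regimes, singleton policies, clustering algorithms and
#' identity definitions over one shared set of reads, evaluating each
#' combination against the reference database. Filtering and dereplication
#' are shared per regime; greedy alignments are cached across definitions;
#' hierarchical distances come from one MSA per regime (MAFFT when
#' available, pairwise alignments otherwise), with the singleton-removed
#' arm reusing the induced sub-alignment. Hierarchical combinations whose
#' matrix would exceed `max_matrix_size` are reported as infeasible rather
#' than aborting the grid; other per-combination failures are likewise
#' recorded and the run continues.
#'
#' @param reads FASTQ path or [read_set].
#' @param references reference FASTA path or data.frame (may be `NULL`:
#'   OTU counts only).
#' @param regimes,singletons,algorithms,definitions grid axes.
#' @param threshold divergence threshold.
#' @param terminal_policy terminal-gap policy for all combinations.
#' @param min_identity,min_overlap classification thresholds.
#' @param use_msa `"auto"` (MAFFT when on PATH), `TRUE` or `FALSE`.
#' @param max_matrix_size hierarchical capacity guard.
#' @param filter_overrides named list of per-regime [filter_params]
#'   overrides, e.g. `list(stringent = list(max_expected_error = 1))`.
#' @param verbose print progress?
#' @return data.frame with one row per combination: the axes, `feasible`,
#'   `n_uniques`, `n_otus`, `n_matched_otus`, `n_species_detected`,
#'   `precision`, `species_detection`, and a Table-style `cell`
#'   `"total (matched) detected"`.
#' @export
compare_workflows <- function(reads, references = NULL,
                              regimes = c("stringent", "relaxed"),
                              singletons = c(FALSE, TRUE),
                              algorithms = c("greedy", "hierarchical"),
                              definitions = c("no_gaps", "one_gap",
                                              "each_gap"),
                              threshold = 0.03,
                              terminal_policy = "count",
                              min_identity = 0.90, min_overlap = 200L,
                              use_msa = "auto",
                              max_matrix_size = 20000L,
                              filter_overrides = list(),
                              verbose = FALSE) {
  reads <- resolve_reads(reads)
  refs <- resolve_refs(references)
  scoring <- align_scoring()
  if (identical(use_msa, "auto")) use_msa <- nzchar(Sys.which("mafft"))
  say <- function(...) if (verbose) message(sprintf(...))

  # per-regime shared preprocessing
  prep <- list()
  for (rg in regimes) {
    fp <- do.call(filter_params,
                  c(list(regime = rg), filter_overrides[[rg]]))
    flt <- apply_filter(reads, fp)
    uniq <- sort_uniques(dereplicate(flt$kept))
    prep[[rg]] <- list(uniques = uniq,
                       nosing = remove_singletons(uniq),
                       report = flt$report,
                       greedy_cache = new.env(parent = emptyenv()),
                       msa_dists = NULL)
    say("regime %s: %d reads kept, %d uniques (%d without singletons)",
        rg, sum(flt$report["kept"]), nrow(uniq), nrow(prep[[rg]]$nosing))
  }

  classify_cache <- new.env(parent = emptyenv())
  classify_cached <- function(otus) {
    if (is.null(refs)) return(NULL)
    rows <- lapply(seq_len(nrow(otus)), function(i) {
      key <- otus$centroid[i]
      hit <- get0(key, envir = classify_cache, inherits = FALSE)
      if (is.null(hit)) {
        hit <- classify_otus(otus[i, , drop = FALSE], refs, min_identity,
                             min_overlap, scoring)
        assign(key, hit, envir = classify_cache)
      }
      hit$otu_id <- otus$otu_id[i]
      hit
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }

  msa_distances_for <- function(rg) {
    pr <- prep[[rg]]
    if (!is.null(pr$msa_dists)) return(pr$msa_dists)
    u <- pr$uniques
    say("regime %s: computing %s distances for %d sequences", rg,
        if (use_msa) "MSA" else "pairwise", nrow(u))
    if (use_msa && nrow(u) >= 2) {
      msa <- align_with_mafft(u)
      idx <- match(u$uid, msa$seq_id)
      dl <- cpp_msa_distances(msa$gapped_sequence[idx],
                              terminal_policy == "count",
                              scoring$n_wildcard, TRUE)
    } else {
      # pairwise-alignment route: one stats pass feeds all three matrices
      n <- nrow(u)
      dng <- dog <- deg <- matrix(0, n, n)
      count_term <- terminal_policy == "count"
      if (n >= 2) {
        for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
          st <- cpp_align(u$sequence[i], u$sequence[j], scoring$match,
                          scoring$mismatch, scoring$gap_open,
                          scoring$gap_extend, scoring$free_end_gaps,
                          scoring$n_wildcard)$stats
          M <- st[["M"]]; X <- st[["X"]]
          short <- min(nchar(u$sequence[i]), nchar(u$sequence[j]))
          if (M + X == 0 || st[["overlap"]] < 0.5 * short) {
            # empty or low-coverage ends-free overlap: maximally diverged
            dng[i, j] <- dng[j, i] <- 1
            dog[i, j] <- dog[j, i] <- 1
            deg[i, j] <- deg[j, i] <- 1
            next
          }
          R <- st[["R_int"]] + if (count_term) st[["R_term"]] else 0
          C <- st[["C_int"]] + if (count_term) st[["C_term"]] else 0
          dng[i, j] <- dng[j, i] <- 1 - M / (M + X)
          dog[i, j] <- dog[j, i] <- 1 - M / (M + X + R)
          deg[i, j] <- deg[j, i] <- 1 - M / (M + X + C)
        }
      }
      dl <- list(no_gaps = dng, one_gap = dog, each_gap = deg)
    }
    for (def in names(dl)) dimnames(dl[[def]]) <- list(pr$uniques$uid,
                                                       pr$uniques$uid)
    prep[[rg]]$msa_dists <<- dl
    dl
  }

  grid <- expand.grid(definition = definitions, algorithm = algorithms,
                      keep_singletons = singletons, regime = regimes,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    rg <- grid$regime[g]; keep <- grid$keep_singletons[g]
    alg <- grid$algorithm[g]; def <- grid$definition[g]
    u <- if (keep) prep[[rg]]$uniques else prep[[rg]]$nosing
    icfg <- identity_config(def, terminal_policy)
    row <- data.frame(regime = rg, keep_singletons = keep, algorithm = alg,
                      definition = def, feasible = TRUE,
                      n_uniques = nrow(u), n_otus = NA_integer_,
                      n_matched_otus = NA_integer_,
                      n_species_detected = NA_integer_,
                      precision = NA_real_, species_detection = NA_real_,
                      cell = NA_character_, note = "",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      if (nrow(u) == 0) stop("no sequences to cluster")
      if (alg == "hierarchical") {
        if (nrow(u) > max_matrix_size)
          stop(sprintf("capacity: %d sequences exceed max_matrix_size = %d",
                       nrow(u), max_matrix_size))
        dl <- msa_distances_for(rg)
        d <- dl[[def]][u$uid, u$uid, drop = FALSE]
        ccfg <- cluster_config("hierarchical", threshold, icfg,
                               max_matrix_size = max_matrix_size)
        hierarchical_cluster(u, ccfg, dmat = d)
      } else {
        cache <- prep[[rg]]$greedy_cache
        full <- prep[[rg]]$uniques
        pos <- match(u$uid, full$uid)
        sfun <- function(i, j) {
          ii <- pos[i]; jj <- pos[j]
          key <- if (ii < jj) paste0(ii, "_", jj) else paste0(jj, "_", ii)
          st <- get0(key, envir = cache, inherits = FALSE)
          if (is.null(st)) {
            st <- cpp_align(full$sequence[ii], full$sequence[jj],
                            scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend,
                            scoring$free_end_gaps, scoring$n_wildcard)$stats
            assign(key, st, envir = cache)
          }
          st
        }
        ccfg <- cluster_config("greedy", threshold, icfg)
        greedy_cluster(u, ccfg, scoring, stats_fun = sfun)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$feasible <- FALSE
      row$note <- conditionMessage(res)
      say("%s/%s/%s/singletons=%s: infeasible (%s)", rg, alg, def, keep,
          row$note)
    } else {
      row$n_otus <- nrow(res)
      if (!is.null(refs)) {
        cls <- classify_cached(res)
        s <- summarize_evaluation(cls, refs, nrow(res))
        row$n_matched_otus <- s$n_matched_otus
        row$n_species_detected <- s$n_species_detected
        row$precision <- s$precision
        row$species_detection <- s$species_detection
        row$cell <- sprintf("%d (%d) %d", s$n_otus, s$n_matched_otus,
                            s$n_species_detected)
      } else {
        row$cell <- sprintf("%d", row$n_otus)
      }
      say("%s/%s/%s/singletons=%s: %s", rg, alg, def, keep, row$cell)
    }
    rows[[g]] <- row
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("workflow_grid", "data.frame")
  out
}

#' Format a workflow grid like a results table
#'
#' Rows are identity definitions, columns are regime x singleton policy x
#' algorithm; cells read `"total (matched) detected"`, or `"-"` for
#' infeasible combinations.
#'
#' @param grid output of [compare_workflows].
#' @return data.frame in wide format.
#' @export
format_grid <- function(grid) {
  grid$col <- paste(grid$regime,
                    ifelse(grid$keep_singletons, "+singletons",
                           "-singletons"),
                    grid$algorithm, sep = "|")
  defs <- unique(grid$definition)
  cols <- unique(grid$col)
  out <- data.frame(definition = defs, stringsAsFactors = FALSE)
  for (cc in cols) {
    out[[cc]] <- vapply(defs, function(d) {
      r <- grid[grid$definition == d & grid$col == cc, ]
      if (!nrow(r) || !r$feasible[1]) "-" else r$cell[1]
    }, character(1))
  }
  out
}
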