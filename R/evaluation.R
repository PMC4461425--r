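#' Read a reference database FASTA
#'
#' Headers are taken as species names (first whitespace-delimited token).
#'
#' @param path FASTA path.
#' @return data.frame with columns `species` and `sequence`.
#' @export
read_reference_fasta <- function(path) {
  x <- read_fasta(path)
  if (anyDuplicated(x$seq_id)) stop("reference species names must be unique")
  data.frame(species = x$seq_id, sequence = x$sequence,
             stringsAsFactors = FALSE)
}

#' Validate a reference database against a clustering threshold
#'
#' Checks that all reference pairs diverge beyond the clustering threshold,
#' mirroring the curation step of removing species that a divergence cutoff
#' cannot distinguish. Offending pairs raise a warning (not an error) and
#' are returned so the caller can drop them.
#'
#' @param refs data.frame with `species`, `sequence`.
#' @param divergence_threshold clustering threshold the references must
#'   exceed pairwise.
#' @param cfg [identity_config] used for the divergence computation.
#' @param scoring an [align_scoring].
#' @return data.frame of offending pairs (`species_a`, `species_b`,
#'   `divergence`), zero rows when the database is clean.
#' @export
validate_references <- function(refs, divergence_threshold = 0.03,
                                cfg = identity_config("no_gaps"),
                                scoring = align_scoring()) {
  n <- nrow(refs)
  bad <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        dv <- pair_divergence(refs$sequence[i], refs$sequence[j], cfg, scoring)
        if (dv <= divergence_threshold)
          bad[[length(bad) + 1L]] <- data.frame(
            species_a = refs$species[i], species_b = refs$species[j],
            divergence = dv, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(bad)) do.call(rbind, bad) else
    data.frame(species_a = character(), species_b = character(),
               divergence = numeric(), stringsAsFactors = FALSE)
  if (nrow(out))
    warning(sprintf(
      "%d reference pair(s) within the %.3g divergence threshold (e.g. %s vs %s)",
      nrow(out), divergence_threshold, out$species_a[1], out$species_b[1]))
  out
}

#' Classify OTU centroids against a reference database
#'
#' Each centroid is aligned (end-gap-free global alignment) to every
#' reference sequence; the best hit is the reference with maximal identity
#' computed as matches over the aligned overlap (gap columns excluded, the
#' *no gaps* definition), approximating BLAST percent identity. Only hits
#' whose overlap reaches `min_overlap` compete for the best hit (an
#' unrelated reference can align a handful of bases at 100% identity under
#' end-gap-free alignment; BLAST-style ranking would never prefer such a
#' hit over a full-length one). Ties go to the larger overlap, then the
#' alphabetically first species, and are flagged. A positive
#' identification additionally requires `best_identity >= min_identity`;
#' otherwise the OTU is `UNCLASSIFIED`.
#'
#' @param otus an `otu_set` (or data.frame with `otu_id`, `centroid`).
#' @param refs reference data.frame (`species`, `sequence`).
#' @param min_identity identity threshold (default 0.90).
#' @param min_overlap minimum alignment length in nucleotides (default 200).
#' @param scoring an [align_scoring].
#' @param overlap_counts `"non_terminal"` counts match, mismatch and
#'   internal-gap columns as the alignment length; `"all_columns"` counts
#'   every column including terminal gaps.
#' @return data.frame with `otu_id`, `best_species` (or `"UNCLASSIFIED"`),
#'   `best_identity`, `alignment_overlap`, `tie`.
#' @export
classify_otus <- function(otus, refs, min_identity = 0.90,
                          min_overlap = 200L, scoring = align_scoring(),
                          overlap_counts = c("non_terminal", "all_columns")) {
  overlap_counts <- match.arg(overlap_counts)
  if (is.null(refs) || nrow(refs) == 0) stop("empty reference set")
  ord <- order(refs$species, method = "radix")  # alphabetical tie-break
  refs <- refs[ord, , drop = FALSE]
  ng <- identity_config("no_gaps")
  out <- lapply(seq_len(nrow(otus)), function(i) {
    best_id <- -1; best_sp <- NA_character_; best_ov <- 0L; tie <- FALSE
    any_id <- -1; any_ov <- 0L   # best hit ignoring the overlap rule
    for (r in seq_len(nrow(refs))) {
      st <- global_align(otus$centroid[i], refs$sequence[r], scoring)$stats
      if (st[["M"]] + st[["X"]] == 0) next
      idv <- seq_identity(st, ng)
      ov <- if (overlap_counts == "non_terminal")
        as.integer(st[["overlap"]]) else as.integer(st[["length"]])
      if (idv > any_id || (idv == any_id && ov > any_ov)) {
        any_id <- idv; any_ov <- ov
      }
      if (ov < min_overlap) next   # too short to compete for the best hit
      if (idv > best_id || (idv == best_id && ov > best_ov)) {
        tie <- idv == best_id
        best_id <- idv; best_sp <- refs$species[r]; best_ov <- ov
      } else if (idv == best_id && ov == best_ov) tie <- TRUE
    }
    if (is.na(best_sp)) {          # no qualifying overlap: report the best
      best_id <- any_id; best_ov <- any_ov   # raw hit, leave unclassified
    }
    ok <- !is.na(best_sp) && best_id >= min_identity &&
      best_ov >= min_overlap
    data.frame(otu_id = otus$otu_id[i],
               best_species = if (ok) best_sp else "UNCLASSIFIED",
               best_identity = best_id, alignment_overlap = best_ov,
               tie = tie, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Summarise a classified workflow
#'
#' Computes the mock-community accuracy metrics: `n_matched_otus` (OTUs
#' classified to any reference species), `n_species_detected` (distinct
#' species hit), `precision = n_species_detected / n_otus`, and
#' `species_detection = n_species_detected / nrow(refs)`.
#'
#' @param classifications output of [classify_otus].
#' @param refs the reference data.frame used for classification.
#' @param n_otus total OTU count of the workflow (defaults to
#'   `nrow(classifications)`).
#' @return object of class `evaluation_summary`.
#' @export
summarize_evaluation <- function(classifications, refs,
                                 n_otus = nrow(classifications)) {
  if (n_otus == 0) stop("precision undefined: no OTUs were produced")
  matched <- classifications$best_species != "UNCLASSIFIED"
  n_matched <- sum(matched)
  n_species <- length(unique(classifications$best_species[matched]))
  structure(list(n_otus = as.integer(n_otus),
                 n_matched_otus = as.integer(n_matched),
                 n_species_detected = as.integer(n_species),
                 n_reference_species = nrow(refs),
                 precision = n_species / n_otus,
                 species_detection = n_species / nrow(refs)),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf(
    "%d OTUs (%d matched); %d/%d species detected; precision %.3f; detection %.3f\n",
    x$n_otus, x$n_matched_otus, x$n_species_detected, x$n_reference_species,
    x$precision, x$species_detection))
  invisible(x)
}

#' Audit OTUs against simulator ground truth
#'
#' Uses the per-read labels of the simulator to score each OTU by the
#' origin of its member reads: the majority species claims the OTU;
#' chimera-majority OTUs are tallied separately. A species with two or more
#' OTUs contributes its excess as oversplitting events; an OTU containing
#' reads of two or more (non-chimeric) species counts as one undersplitting
#' event.
#'
#' @param otus an `otu_set` whose members carry read ids.
#' @param ground_truth data.frame from [simulate_reads] with columns
#'   `read_id`, `species`, `is_chimera`.
#' @return list with `per_species` (data.frame `species`, `n_otus`),
#'   `oversplit` and `undersplit` event counts, `chimera_otus`, and
#'   `otu_species` (majority species per OTU).
#' @export
ground_truth_audit <- function(otus, ground_truth) {
  lab <- setNames(ground_truth$species, ground_truth$read_id)
  chi <- setNames(ground_truth$is_chimera, ground_truth$read_id)
  undersplit <- 0L
  chimera_otus <- 0L
  otu_species <- character(nrow(otus))
  for (i in seq_len(nrow(otus))) {
    ids <- unlist(otus$members[[i]]$member_ids, use.names = FALSE)
    if (anyNA(lab[ids])) stop("reads lacking ground-truth labels")
    is_chi <- chi[ids]
    sp <- lab[ids][!is_chi]
    if (!length(sp)) {            # all member reads are chimeras
      chimera_otus <- chimera_otus + 1L
      otu_species[i] <- "CHIMERA"
      next
    }
    tab <- sort(table(sp), decreasing = TRUE)
    if (sum(is_chi) > length(sp)) chimera_otus <- chimera_otus + 1L
    otu_species[i] <- names(tab)[1]
    if (length(tab) >= 2L) undersplit <- undersplit + 1L
  }
  counts <- table(otu_species[otu_species != "CHIMERA"])
  per_species <- data.frame(species = names(counts),
                            n_otus = as.integer(counts),
                            stringsAsFactors = FALSE)
  oversplit <- sum(pmax(per_species$n_otus - 1L, 0L))
  list(per_species = per_species, oversplit = oversplit,
       undersplit = undersplit, chimera_otus = chimera_otus,
       otu_species = otu_species)
}
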