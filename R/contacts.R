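#' Read a docking pose ensemble
#'
#' Loads an ensemble of rigid-body antigen-antibody poses from either a
#' directory of two-chain PDB files (taken in lexicographic filename
#' order) or a single multi-model PDB file (model order). An optional
#' score table attaches a docking score to every pose; scores are
#' all-or-none — an ensemble in which only some poses are scored is
#' rejected, because score-based filtering would silently change the
#' counted population.
#'
#' @param source Directory of PDB files, or one multi-model PDB file.
#' @param antigen_chain,antibody_chain Chain identifiers of the two
#'   binding partners in every pose.
#' @param score_table Optional: path to a TSV with columns
#'   `pose_id`, `score`, or an equivalent data frame. Lower score =
#'   better (docking-energy convention). Scores for unknown pose ids are
#'   dropped with a warning; a pose without a score is an error.
#' @return A `pose_ensemble`: tibble with columns `pose_id`, `structure`
#'   (list of [structure_model()]), `score` (`NA` when unscored), with
#'   the chain mapping in attributes.
#' @export
read_pose_ensemble <- function(source, antigen_chain = "A", antibody_chain = "B",
                               score_table = NULL) {
  if (dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.pdb$", full.names = TRUE))
    if (length(files) == 0L) abort(sprintf("no .pdb files in %s", source))
    ids <- sub("\\.pdb$", "", basename(files))
    models <- lapply(files, function(f) read_pdb_models(f)[[1]])
  } else if (file.exists(source)) {
    models <- read_pdb_models(source)
    ids <- sprintf("model_%04d", seq_along(models))
  } else {
    abort(sprintf("no such file or directory: %s", source))
  }
  for (i in seq_along(models)) {
    ch <- unique(models[[i]]$chain)
    miss <- setdiff(c(antigen_chain, antibody_chain), ch)
    if (length(miss) > 0L)
      abort(sprintf("pose '%s' is missing chain(s) %s", ids[i],
                    paste(miss, collapse = ", ")))
  }
  scores <- rep(NA_real_, length(models))
  if (!is.null(score_table)) {
    st <- if (is.data.frame(score_table)) as_tibble(score_table)
          else readr::read_tsv(score_table, col_types = "cd", progress = FALSE)
    if (!all(c("pose_id", "score") %in% names(st)))
      abort("score table must have columns pose_id, score")
    unknown <- setdiff(st$pose_id, ids)
    if (length(unknown) > 0L)
      warn(sprintf("scores for unknown pose(s) dropped: %s",
                   paste(unknown, collapse = ", ")))
    hit <- match(ids, st$pose_id)
    if (anyNA(hit))
      abort(sprintf("score table must cover every pose; missing: %s",
                    paste(ids[is.na(hit)], collapse = ", ")))
    scores <- st$score[hit]
  }
  ens <- tibble(pose_id = ids, structure = models, score = scores)
  structure(ens, antigen_chain = antigen_chain, antibody_chain = antibody_chain,
            class = c("pose_ensemble", class(ens)))
}

#' Antigen residues in contact with the antibody CDR region
#'
#' An antigen residue counts as a contact when at least one of its heavy
#' atoms lies within `cutoff` (inclusive) of any heavy atom of the
#' antibody's complementarity-determining region. Hydrogens are ignored
#' on both sides; the CDR is supplied explicitly as antibody residue
#' numbers.
#'
#' @param pose A [structure_model()] holding both chains.
#' @param cdr Integer vector of antibody-chain residue numbers forming
#'   the CDR region.
#' @param antigen_chain,antibody_chain Chain identifiers.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 5.0,
#'   inclusive).
#' @return Sorted integer vector of antigen residue numbers.
#' @export
contact_residues <- function(pose, cdr, antigen_chain = "A",
                             antibody_chain = "B", cutoff = 5.0) {
  check_scalar_number(cutoff, "cutoff", positive = TRUE)
  s <- as_tibble(pose)
  ag <- s[s$chain == antigen_chain & s$heavy, , drop = FALSE]
  ab <- s[s$chain == antibody_chain & s$heavy &
            s$resno %in% as.integer(cdr), , drop = FALSE]
  if (nrow(ab) == 0L)
    abort("no CDR heavy atoms in pose: CDR definition does not intersect the antibody chain")
  if (nrow(ag) == 0L) return(integer(0))
  A <- as.matrix(ag[, c("x", "y", "z")])
  B <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  min_d2 <- apply(d2, 1, min)
  hit <- tapply(min_d2, ag$resno, min) <= cutoff^2 + 1e-9
  sort(as.integer(names(hit)[hit]))
}

#' Per-residue contact frequency over a pose ensemble
#'
#' Counts, for every antigen residue, the fraction of poses in which it
#' contacts the antibody CDR region (see [contact_residues()]). With
#' `score_top_fraction < 1` only the best-scoring (lowest-score)
#' `ceiling(fraction * n)` poses are counted, which requires every pose
#' to carry a score.
#'
#' @param ensemble A `pose_ensemble` from [read_pose_ensemble()] (or an
#'   equivalent tibble with chain attributes).
#' @param cdr CDR residue numbers on the antibody chain.
#' @param cutoff Heavy-atom cutoff in Angstrom, inclusive (default 5.0).
#' @param score_top_fraction Fraction in (0, 1] of best-scoring poses to
#'   keep (default 1 = no filtering).
#' @return A `contact_profile` tibble: `residue`, `count`, `frequency`,
#'   `n_poses_used`, covering every antigen residue seen in the counted
#'   poses.
#' @export
contact_frequency <- function(ensemble, cdr, cutoff = 5.0,
                              score_top_fraction = 1.0) {
  if (!is.numeric(score_top_fraction) || score_top_fraction <= 0 ||
      score_top_fraction > 1)
    abort("`score_top_fraction` must be in (0, 1]")
  ag_chain <- attr(ensemble, "antigen_chain") %||% "A"
  ab_chain <- attr(ensemble, "antibody_chain") %||% "B"
  ens <- as_tibble(ensemble)
  if (score_top_fraction < 1) {
    if (anyNA(ens$score))
      abort("score-based filtering requested but not every pose carries a score")
    keep_n <- ceiling(score_top_fraction * nrow(ens))
    ord <- order(ens$score, ens$pose_id)   # pose_id tie-break for determinism
    ens <- ens[sort(ord[seq_len(keep_n)]), , drop = FALSE]
  }
  sets <- lapply(ens$structure, contact_residues, cdr = cdr,
                 antigen_chain = ag_chain, antibody_chain = ab_chain,
                 cutoff = cutoff)
  universe <- sort(unique(unlist(lapply(ens$structure, function(s)
    s$resno[s$chain == ag_chain]))))
  counts <- vapply(universe, function(r)
    sum(vapply(sets, function(x) r %in% x, logical(1))), integer(1))
  out <- tibble(residue = universe, count = counts,
                frequency = counts / nrow(ens), n_poses_used = nrow(ens))
  structure(out, cutoff = cutoff,
            class = c("contact_profile", class(out)))
}

#' Docking-derived epitope from a contact profile
#'
#' @param profile A `contact_profile` from [contact_frequency()].
#' @param min_frequency Minimum contact frequency for epitope membership
#'   (default 0.5).
#' @param name Name for the resulting set.
#' @return An [epitope_set()] with provenance `"docking"`, or `NULL` when
#'   no residue reaches `min_frequency`.
#' @export
docking_epitope <- function(profile, min_frequency = 0.5,
                            name = "docking_epitope") {
  res <- profile$residue[profile$frequency >= min_frequency]
  if (length(res) == 0L) return(NULL)
  epitope_set(res, name, "docking")
}
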