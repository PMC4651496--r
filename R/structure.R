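#' Construct a structure model from an atom table
#'
#' A `structure_model` is a flat atom table: one row per atom with its
#' chain, author residue number, 3-letter residue type, atom name,
#' element symbol, coordinates in Angstrom and a heavy-atom flag.
#' Hydrogen (and deuterium) atoms are flagged non-heavy and ignored by
#' all distance- and surface-based operations.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`,
#'   `elety`, `elesy`, `x`, `y`, `z`; optional `eleno`, `o`, `b`.
#' @return A `structure_model` tibble.
#' @export
structure_model <- function(atoms) {
  atoms <- as_tibble(atoms)
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    abort(sprintf("atom table must have columns %s", paste(need, collapse = ", ")))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    abort("atom coordinates must be finite")
  atoms$resno <- as.integer(atoms$resno)
  if (!"eleno" %in% names(atoms)) atoms$eleno <- seq_len(nrow(atoms))
  if (!"o" %in% names(atoms)) atoms$o <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  atoms$heavy <- !(toupper(atoms$elesy) %in% c("H", "D"))
  no_heavy <- dplyr::summarise(dplyr::group_by(atoms, .data$chain, .data$resno),
                               any_heavy = any(.data$heavy), .groups = "drop")
  if (any(!no_heavy$any_heavy))
    abort("every residue must contain at least one heavy atom")
  structure(atoms, class = c("structure_model", class(atoms)))
}

#' Read a protein structure from a PDB file
#'
#' Parses one model of a PDB file into a [structure_model()]. Alternate
#' locations are resolved to the highest-occupancy copy of each atom.
#' Files with insertion codes are rejected: insertion codes make author
#' residue numbering ambiguous for per-residue score maps.
#'
#' For NMR ensembles the convention throughout this package is to work
#' with the first conformer (`model_index = 1`).
#'
#' @param path Path to a PDB file.
#' @param model_index 1-based model to extract (multi-model files).
#' @return A `structure_model` tibble.
#' @export
read_structure <- function(path, model_index = 1) {
  models <- read_pdb_models(path)
  if (model_index < 1 || model_index > length(models))
    abort(sprintf("model_index %d out of range (file has %d model(s))",
                  model_index, length(models)))
  models[[model_index]]
}

# parse every model of a PDB file into a list of structure_model
read_pdb_models <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  keep <- pdb$atom$type %in% c("ATOM", "HETATM")
  at <- pdb$atom[keep, , drop = FALSE]
  ins <- at$insert
  bad_ins <- !is.na(ins) & ins != "" & ins != " "
  if (any(bad_ins))
    abort(sprintf("insertion codes present (e.g. residue %s%s); renumber first",
                  at$resno[which(bad_ins)][1], ins[which(bad_ins)][1]))
  elesy <- at$elesy
  blank <- is.na(elesy) | elesy == "" | elesy == " "
  if (any(blank)) elesy[blank] <- bio3d::atom2ele(at$elety[blank])
  lapply(seq_len(nrow(pdb$xyz)), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
    tbl <- tibble(
      chain = ifelse(is.na(at$chain), "A", at$chain),
      resno = as.integer(at$resno), resid = at$resid,
      eleno = as.integer(at$eleno), elety = at$elety,
      elesy = toupper(elesy),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      o = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b)
    )
    # altlocs: keep the highest-occupancy copy of each (chain, residue, atom)
    tbl <- tbl |>
      dplyr::group_by(.data$chain, .data$resno, .data$elety) |>
      dplyr::slice_max(.data$o, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$eleno)
    structure_model(tbl)
  })
}

#' Write a structure model to a PDB file
#'
#' @param structure A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  s <- as_tibble(structure)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
                   resno = s$resno, resid = s$resid, eleno = s$eleno,
                   elety = s$elety, chain = s$chain, o = s$o, b = s$b,
                   elesy = s$elesy)
  invisible(path)
}

#' Paint per-residue scores into the B-factor column
#'
#' Writes a copy of the structure in which every atom's B-factor holds
#' its residue's score (CSP, contact frequency, epitope membership, ...),
#' the standard trick for colouring structures by an external quantity in
#' molecular viewers. Scores are matched by author residue number across
#' all chains; residues without a score get `default`. Values outside the
#' PDB B-factor field range are clamped to `[-99.99, 999.99]` with a
#' warning (the column is fixed-width `%6.2f`).
#'
#' @param structure A `structure_model`.
#' @param scores Named numeric vector (names = residue numbers) or a data
#'   frame with columns `residue` and `score`.
#' @param path Output PDB path.
#' @param default Score for unlisted residues (default 0).
#' @return The annotated `structure_model`, invisibly; the file is
#'   written as a side effect.
#' @export
annotate_structure <- function(structure, scores, path, default = 0) {
  if (is.data.frame(scores))
    scores <- setNames(scores$score, scores$residue)
  scores <- unlist(scores)
  if (length(scores) > 0 && any(!is.finite(scores)))
    abort("scores must be finite")
  res_nums <- as.integer(names(scores))
  missing <- setdiff(res_nums, unique(structure$resno))
  if (length(missing) > 0L)
    warn(sprintf("scores for residues absent from structure skipped: %s",
                 paste(missing, collapse = ", ")))
  s <- as_tibble(structure)
  b <- rep(default, nrow(s))
  hit <- match(s$resno, res_nums)
  b[!is.na(hit)] <- scores[hit[!is.na(hit)]]
  clamp <- b < -99.99 | b > 999.99
  if (any(clamp)) {
    warn(sprintf("%d B-factor value(s) clamped to [-99.99, 999.99]", sum(clamp)))
    b <- pmin(pmax(b, -99.99), 999.99)
  }
  s$b <- b
  out <- structure_model(s)
  write_structure(out, path)
  invisible(out)
}
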