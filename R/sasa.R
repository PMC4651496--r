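# Element van der Waals radii (Angstrom) for SASA; unknown elements fall
# back to 1.8 A with a warning.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# Theoretical maximum accessibilities of residue X in Gly-X-Gly tripeptides
# (Tien et al. 2013), Angstrom^2; denominators for relative accessibility.
MAX_ACC_GXG <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
                 CYS = 167.0, GLN = 225.0, GLU = 223.0, GLY = 104.0,
                 HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
                 MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
                 THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# deterministic quasi-uniform points on the unit sphere (Fibonacci spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes atomic SASA by the Shrake-Rupley rolling-probe method: each
#' heavy atom's solvent-accessible sphere (van der Waals radius plus
#' probe radius) is sampled with a deterministic quasi-uniform point set,
#' and the accessible fraction is the fraction of points outside every
#' neighbouring atom's accessible sphere. Atomic areas are summed per
#' residue; relative accessibility divides by the residue's theoretical
#' maximum in a Gly-X-Gly tripeptide, and residues with relative
#' accessibility of at least `exposed_threshold` are called exposed.
#' Hydrogens are ignored.
#'
#' @param structure A [structure_model()].
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4,
#'   a water molecule).
#' @param n_sphere_points Sample points per atom (default 960; accuracy
#'   improves roughly with the square root of the count).
#' @param exposed_threshold Relative-accessibility cutoff for the
#'   `exposed` call (default 0.2).
#' @return Tibble `chain`, `residue`, `resid`, `sasa` (A^2), `rel_acc`
#'   (`NA` for residue types without a reference value), `exposed`.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 960,
                         exposed_threshold = 0.2) {
  check_scalar_number(probe_radius, "probe_radius", positive = TRUE)
  s <- as_tibble(structure)
  s <- s[s$heavy, , drop = FALSE]
  ele <- toupper(s$elesy)
  radii <- VDW_RADII[ele]
  if (anyNA(radii)) {
    warn(sprintf("unknown element(s) %s assigned default vdW radius 1.8 A",
                 paste(unique(ele[is.na(radii)]), collapse = ", ")))
    radii[is.na(radii)] <- 1.8
  }
  r_acc <- unname(radii) + probe_radius
  xyz <- as.matrix(s[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_sphere_points)
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    # candidate occluders: accessible spheres that intersect atom i's
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
          (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r_acc[i] + r_acc)^2 & seq_len(n) != i)
    p <- pts * r_acc[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
             (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 > r_acc[j]^2
    }
    atom_sasa[i] <- 4 * pi * r_acc[i]^2 * sum(acc) / n_sphere_points
  }
  s$atom_sasa <- atom_sasa
  s |>
    dplyr::group_by(chain = .data$chain, residue = .data$resno,
                    resid = .data$resid) |>
    dplyr::summarise(sasa = sum(.data$atom_sasa), .groups = "drop") |>
    dplyr::mutate(
      rel_acc = .data$sasa / unname(MAX_ACC_GXG[.data$resid]),
      exposed = .data$rel_acc >= exposed_threshold
    )
}
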