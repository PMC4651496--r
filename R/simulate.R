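#' Default planted epitope for the synthetic antigen
#'
#' Twenty-nine residues on a 108-residue parvalbumin-like antigen,
#' distributed as five at the N-terminus, sixteen in the region spanning
#' the AB/CD inter-motif axis and the CD calcium-binding site, five
#' around residue 80 and three at the C-terminus. The set contains the
#' conformational core 7, 8, 11, 12, 15, 29-33, 36 and 108.
#'
#' @return Sorted integer vector of residue numbers.
#' @export
default_planted_epitope <- function() {
  sort(c(7L, 8L, 11L, 12L, 15L,
         29:33, 36L, 38L, 41L, 44L,
         51L, 53L, 54L, 56L, 57L, 59L, 61L,
         76L, 78L, 80L, 82L, 84L,
         102L, 106L, 108L))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators, with defaults
#' chosen to emulate the mapped antigen:antibody system: a 108-residue
#' antigen, a planted 29-residue epitope of which two CD-site residues
#' lose their signals on complex formation (so 27 residues carry a
#' measurable significant CSP), a planted CSP effect of 0.05 ppm against
#' 0.002 ppm noise, a 2000-pose docking ensemble with contact
#' probability 0.9 inside / 0.05 outside the epitope, and a six-sequence
#' family alignment whose epitope columns are conserved verbatim.
#'
#' @param seed Integer seed; every generator derives its own stream from
#'   it, so identical configs give byte-identical outputs.
#' @param n_residues Antigen length (default 108).
#' @param planted_epitope Planted epitope residues.
#' @param disappeared_residues Planted residues whose bound-state rows
#'   are dropped (exchange-broadened signals).
#' @param csp_effect Planted CSP at full saturation, ppm.
#' @param csp_noise_sigma Gaussian noise sd on the 1H shift, ppm; the
#'   15N shift receives 10x this (its larger dispersion).
#' @param n_poses Number of docking poses.
#' @param p_contact_in,p_contact_out Per-pose contact probability for
#'   planted / non-planted residues.
#' @param n_probe_residues Residues of the toy antibody probe.
#' @param cdr CDR residue numbers on the probe.
#' @param n_sequences Sequences in the synthetic family alignment.
#' @param substitution_rate Per-site substitution probability outside
#'   conserved columns.
#' @param gap_rate Per-site gap probability outside conserved columns,
#'   non-reference sequences only.
#' @param decay_noise Relative (fraction of I0) Gaussian noise on decay
#'   intensities.
#' @param r2_complex_scale Factor by which complex-state R2 exceeds the
#'   free-state value (slow tumbling of the large complex).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_residues = 108L,
                              planted_epitope = default_planted_epitope(),
                              disappeared_residues = c(57L, 61L),
                              csp_effect = 0.05,
                              csp_noise_sigma = 0.002,
                              n_poses = 2000L,
                              p_contact_in = 0.9,
                              p_contact_out = 0.05,
                              n_probe_residues = 10L,
                              cdr = 3:8,
                              n_sequences = 6L,
                              substitution_rate = 0.1,
                              gap_rate = 0.02,
                              decay_noise = 0.01,
                              r2_complex_scale = 3) {
  planted_epitope <- sort(unique(as.integer(planted_epitope)))
  if (any(planted_epitope < 1L) || any(planted_epitope > n_residues))
    abort("planted epitope residues must lie in [1, n_residues]")
  if (!all(disappeared_residues %in% c(integer(0), planted_epitope)))
    abort("`disappeared_residues` must be a subset of the planted epitope")
  for (p in c(p_contact_in, p_contact_out, substitution_rate, gap_rate))
    if (p < 0 || p > 1) abort("probabilities must lie in [0, 1]")
  if (csp_effect <= 3 * csp_noise_sigma)
    abort("`csp_effect` must exceed 3 * `csp_noise_sigma` for recoverability")
  structure(
    list(seed = as.integer(seed), n_residues = as.integer(n_residues),
         planted_epitope = planted_epitope,
         disappeared_residues = as.integer(disappeared_residues),
         csp_effect = csp_effect, csp_noise_sigma = csp_noise_sigma,
         n_poses = as.integer(n_poses), p_contact_in = p_contact_in,
         p_contact_out = p_contact_out,
         n_probe_residues = as.integer(n_probe_residues),
         cdr = as.integer(cdr), n_sequences = as.integer(n_sequences),
         substitution_rate = substitution_rate, gap_rate = gap_rate,
         decay_noise = decay_noise, r2_complex_scale = r2_complex_scale),
    class = "simulation_config")
}

#' Simulate free and bound amide shift tables
#'
#' Draws free-state amide shifts from realistic HSQC ranges, then builds
#' bound-state tables for a two-point titration (molar ratios 2:1 and
#' 1:1, i.e. bound fractions 0.5 and 1.0 under tight fast-exchange
#' binding): planted residues move by `csp_effect * bound_fraction`
#' (split between the 1H and 15N dimensions with random direction so the
#' composite CSP equals the planted value), Gaussian noise is added
#' everywhere, and planted `disappeared_residues` are dropped from every
#' bound table. The synthetic sequence is proline-free so every residue
#' is observable.
#'
#' @param config A [simulation_config()].
#' @return List with `free` (a [shift_table()]), `bound` (named list of
#'   shift tables, increasing saturation), `titration` (tibble of point
#'   metadata) and `manifest` (planted truth).
#' @export
simulate_shift_tables <- function(config) {
  with_seed(config$seed + 101L, {
    n <- config$n_residues
    aa <- sample(setdiff(AA1, "P"), n, replace = TRUE)
    free <- tibble(residue = seq_len(n), aa = aa,
                   dH = runif(n, 7.0, 9.5), dN = runif(n, 105, 130))
    planted <- config$planted_epitope
    e <- config$csp_effect
    # direction of the planted shift, fixed per residue across the titration
    sH <- sample(c(-1, 1), n, replace = TRUE)
    sN <- sample(c(-1, 1), n, replace = TRUE)
    eff <- rep(0, n); eff[planted] <- e
    titration <- tibble(
      point = c("bound_40uM", "bound_70uM"),
      molar_ratio = c("2:1", "1:1"),
      concentration_uM = c(40, 70),
      bound_fraction = c(0.5, 1.0))
    sig <- config$csp_noise_sigma
    bound <- lapply(seq_len(nrow(titration)), function(i) {
      bf <- titration$bound_fraction[i]
      b <- free
      # CSP = |d_dH| + 0.1 |d_dN| = (0.6 + 0.1 * 4) * eff * bf = eff * bf
      b$dH <- b$dH + sH * 0.6 * eff * bf + rnorm(n, 0, sig)
      b$dN <- b$dN + sN * 4.0 * eff * bf + rnorm(n, 0, 10 * sig)
      b <- b[!(b$residue %in% config$disappeared_residues), ]
      shift_table(b, titration$point[i])
    })
    names(bound) <- titration$point
    list(free = shift_table(free, "free"), bound = bound,
         titration = titration,
         manifest = list(planted_epitope = planted,
                         disappeared_residues = config$disappeared_residues,
                         csp_effect = e, csp_noise_sigma = sig,
                         bound_fractions = titration$bound_fraction))
  })
}

# idealized extended antigen: CA along x at 3.8 A spacing, CB offset -y
build_toy_antigen <- function(n_residues, chain = "A") {
  res <- seq_len(n_residues)
  structure_model(tibble(
    chain = chain,
    resno = rep(res, each = 2),
    resid = "ALA",
    eleno = seq_len(2 * n_residues),
    elety = rep(c("CA", "CB"), n_residues),
    elesy = "C",
    x = rep(3.8 * res, each = 2),
    y = rep(c(0, -1.5), n_residues),
    z = 0, o = 1, b = 0))
}

#' Simulate a docking pose ensemble with planted contacts
#'
#' Builds a toy extended antigen (CA/CB pseudo-atoms at 3.8 A spacing)
#' and, for each pose, places atoms of the probe antibody's CDR residues
#' 4 A above a sampled subset of antigen residues — each planted residue
#' is sampled with `p_contact_in`, all others with `p_contact_out` — so
#' that the 5 A heavy-atom contact criterion is realized for exactly the
#' sampled set (neighbouring residues stay >5.5 A away). Non-CDR probe
#' residues sit 30 A from the antigen. Docking scores are drawn lower
#' (better) for poses contacting more planted residues.
#'
#' @param config A [simulation_config()].
#' @return List with `ensemble` (a `pose_ensemble`), `antigen`
#'   (the toy antigen [structure_model()]), `scores` (tibble
#'   `pose_id`, `score`) and `manifest` (planted truth including each
#'   pose's realized contact set).
#' @export
simulate_pose_ensemble <- function(config) {
  with_seed(config$seed + 303L, {
    n <- config$n_residues
    antigen <- build_toy_antigen(n)
    planted <- config$planted_epitope
    p <- rep(config$p_contact_out, n)
    p[planted] <- config$p_contact_in
    cdr <- config$cdr
    n_probe <- config$n_probe_residues
    poses <- vector("list", config$n_poses)
    contact_sets <- vector("list", config$n_poses)
    scores <- numeric(config$n_poses)
    # constant topology across poses (a valid multi-model ensemble):
    # a 10-residue scaffold 30 A above the antigen plus one candidate
    # contact atom per antigen residue, owned round-robin by CDR residues;
    # per pose, sampled residues' atoms drop to 4 A above their target
    # (realizing the <= 5 A criterion), the rest stay parked at 30 A.
    scaffold <- tibble(
      chain = "B", resno = seq_len(n_probe), resid = "GLY",
      elety = "CA", elesy = "C",
      x = 3.8 * seq_len(n_probe), y = 30, z = 0)
    candidates <- tibble(
      chain = "B", resno = cdr[(seq_len(n) - 1L) %% length(cdr) + 1L],
      resid = "GLY", elety = sprintf("C%d", seq_len(n)), elesy = "C",
      x = 3.8 * seq_len(n), y = 30, z = 0)
    for (k in seq_len(config$n_poses)) {
      sampled <- which(runif(n) < p)
      probe <- candidates
      probe$y[sampled] <- 4.0
      pose_atoms <- dplyr::bind_rows(as_tibble(antigen)[, names(probe)],
                                     scaffold, probe)
      pose_atoms$eleno <- seq_len(nrow(pose_atoms))
      poses[[k]] <- structure_model(pose_atoms)
      contact_sets[[k]] <- sampled
      scores[k] <- -sum(sampled %in% planted) + rnorm(1, 0, 0.3)
    }
    # ids match multi-model reading order so score tables key both ways
    ids <- sprintf("model_%04d", seq_len(config$n_poses))
    ens <- tibble(pose_id = ids, structure = poses, score = scores)
    ens <- structure(ens, antigen_chain = "A", antibody_chain = "B",
                     class = c("pose_ensemble", class(ens)))
    list(ensemble = ens, antigen = antigen,
         scores = tibble(pose_id = ids, score = scores),
         manifest = list(planted_epitope = planted,
                         p_contact_in = config$p_contact_in,
                         p_contact_out = config$p_contact_out,
                         cdr = cdr, n_poses = config$n_poses,
                         pose_contacts = setNames(contact_sets, ids)))
  })
}

#' Simulate a family alignment with conserved epitope columns
#'
#' Generates a random reference sequence and `n_sequences - 1` homologs:
#' planted conserved columns (by default the planted epitope positions)
#' are copied verbatim into every sequence, other positions are
#' substituted with probability `substitution_rate` (always to a
#' different residue) or gapped with probability `gap_rate`. The
#' reference itself is never mutated, so reference residue i sits in
#' alignment column i.
#'
#' @param config A [simulation_config()].
#' @param conserved_columns Columns copied verbatim; default the planted
#'   epitope.
#' @return List with `alignment` (a `multiple_alignment`),
#'   `reference_id` and `manifest`.
#' @export
simulate_alignment <- function(config, conserved_columns = config$planted_epitope) {
  if (config$n_sequences < 2L) abort("need at least 2 sequences")
  with_seed(config$seed + 404L, {
    n <- config$n_residues
    ref <- sample(AA1, n, replace = TRUE)
    seqs <- list(reference = paste(ref, collapse = ""))
    for (i in seq_len(config$n_sequences - 1L)) {
      s <- ref
      for (j in setdiff(seq_len(n), conserved_columns)) {
        u <- runif(1)
        if (u < config$gap_rate) {
          s[j] <- "-"
        } else if (u < config$gap_rate + config$substitution_rate) {
          s[j] <- sample(setdiff(AA1, ref[j]), 1)
        }
      }
      seqs[[sprintf("homolog_%d", i + 1L)]] <- paste(s, collapse = "")
    }
    aln <- multiple_alignment(tibble(id = names(seqs), seq = unlist(seqs)))
    list(alignment = aln, reference_id = "reference",
         manifest = list(conserved_columns = sort(unique(as.integer(conserved_columns))),
                         substitution_rate = config$substitution_rate,
                         gap_rate = config$gap_rate,
                         n_sequences = config$n_sequences))
  })
}

#' Simulate relaxation decay series
#'
#' Draws per-residue R1 and R2 rates for the free antigen and scales the
#' complex-state R2 up by `r2_complex_scale` (the ~40 kDa complex tumbles
#' far more slowly than the ~12 kDa free antigen; R1 decreases mildly).
#' For each residue and rate, intensities `I0 exp(-R t)` are generated on
#' a nine-point delay grid spanning `R t` from 0.05 to 2 (delays chosen
#' relative to the rate, as an experimenter would), with additive
#' Gaussian noise of sd `decay_noise * I0`.
#'
#' @param config A [simulation_config()].
#' @param rates Optional tibble `residue`, `R1_free`, `R2_free`,
#'   `R1_complex`, `R2_complex` overriding the drawn rates.
#' @return List with `decays` (named list of tibbles `residue`,
#'   `delay_s`, `intensity`: `r1_free`, `r2_free`, `r1_complex`,
#'   `r2_complex`), `rates` and `manifest`.
#' @export
simulate_decay_curves <- function(config, rates = NULL) {
  with_seed(config$seed + 202L, {
    n <- config$n_residues
    if (is.null(rates)) {
      rates <- tibble(
        residue = seq_len(n),
        R1_free = runif(n, 1.1, 1.5),
        R2_free = runif(n, 7, 9))
      rates$R1_complex <- rates$R1_free * 0.8
      rates$R2_complex <- rates$R2_free * config$r2_complex_scale
    }
    if (any(rates[, -1] <= 0)) abort("relaxation rates must be positive")
    grid0 <- c(0.05, 0.1, 0.2, 0.35, 0.5, 0.7, 1.0, 1.4, 2.0)
    I0 <- 100
    gen <- function(R) {
      purrr::map(seq_along(R), function(i) {
        t <- grid0 / R[i]
        tibble(residue = rates$residue[i], delay_s = t,
               intensity = pmax(I0 * exp(-R[i] * t) +
                                rnorm(length(t), 0, config$decay_noise * I0),
                                1e-6))
      }) |> purrr::list_rbind()
    }
    decays <- list(r1_free = gen(rates$R1_free),
                   r2_free = gen(rates$R2_free),
                   r1_complex = gen(rates$R1_complex),
                   r2_complex = gen(rates$R2_complex))
    list(decays = decays, rates = rates,
         manifest = list(rates = rates, decay_noise = config$decay_noise,
                         r2_complex_scale = config$r2_complex_scale))
  })
}

#' Write a shift table to TSV
#'
#' @param tbl A [shift_table()] (or compatible tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(tbl, path) {
  readr::write_tsv(as_tibble(tbl)[, c("residue", "aa", "dH", "dN")], path,
                   progress = FALSE)
  invisible(path)
}

# multi-model PDB: single-model writes concatenated under MODEL/ENDMDL
write_multimodel_pdb <- function(models, path) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_along(models)) {
    write_structure(models[[i]], tmp)
    lines <- readLines(tmp)
    lines <- lines[!grepl("^END", lines)]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Generate the full synthetic input bundle on disk
#'
#' Runs every generator and writes the complete set of pipeline inputs
#' to a directory: free/bound shift TSVs, relaxation decay TSVs, the toy
#' antigen PDB, the pose ensemble as a multi-model PDB with a score TSV,
#' the family alignment as aligned FASTA, and `truth.json`, a manifest
#' of all planted ground truth sufficient to score recovery without
#' re-running the generator.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return List with `paths` (named file paths), `manifest` and `config`,
#'   invisibly.
#' @export
simulate_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  shifts <- simulate_shift_tables(config)
  decays <- simulate_decay_curves(config)
  poses <- simulate_pose_ensemble(config)
  aln <- simulate_alignment(config)

  paths <- list(free = p("free.tsv"))
  write_shift_table(shifts$free, paths$free)
  for (nm in names(shifts$bound)) {
    paths[[nm]] <- p(paste0(nm, ".tsv"))
    write_shift_table(shifts$bound[[nm]], paths[[nm]])
  }
  for (nm in names(decays$decays)) {
    key <- paste0("decay_", nm)
    paths[[key]] <- p(paste0(key, ".tsv"))
    readr::write_tsv(decays$decays[[nm]], paths[[key]], progress = FALSE)
  }
  paths$antigen <- p("antigen.pdb")
  write_structure(poses$antigen, paths$antigen)
  paths$poses <- p("poses.pdb")
  write_multimodel_pdb(poses$ensemble$structure, paths$poses)
  paths$scores <- p("scores.tsv")
  readr::write_tsv(poses$scores, paths$scores, progress = FALSE)
  paths$alignment <- p("alignment.afa")
  writeLines(paste0(">", aln$alignment$id, "\n", aln$alignment$seq),
             paths$alignment)

  manifest <- list(
    config = unclass(config),
    shifts = shifts$manifest,
    relaxation = decays$manifest,
    docking = poses$manifest,
    conservation = aln$manifest)
  paths$truth <- p("truth.json")
  jsonlite::write_json(manifest, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, manifest = manifest, config = config))
}
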