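test_that("generators are pure functions of the config", {
  cfg <- simulation_config(seed = 42, n_poses = 6)
  a <- simulate_shift_tables(cfg); b <- simulate_shift_tables(cfg)
  expect_identical(a, b)
  pa <- simulate_pose_ensemble(cfg); pb <- simulate_pose_ensemble(cfg)
  expect_identical(pa$manifest, pb$manifest)
  expect_identical(pa$ensemble$score, pb$ensemble$score)
  la <- simulate_alignment(cfg); lb <- simulate_alignment(cfg)
  expect_identical(la, lb)
  da <- simulate_decay_curves(cfg); db <- simulate_decay_curves(cfg)
  expect_identical(da, db)
  # different seed, different data
  expect_false(identical(
    simulate_shift_tables(simulation_config(seed = 43))$free$dH, a$free$dH))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(planted_epitope = c(1, 200)), "n_residues")
  expect_error(simulation_config(p_contact_in = 1.2), "probabilities")
  expect_error(simulation_config(csp_effect = 0.005, csp_noise_sigma = 0.002),
               "recoverability")
  expect_error(simulation_config(disappeared_residues = 99L), "subset")
})

test_that("noise-free shift tables perturb exactly the planted residues", {
  cfg <- simulation_config(seed = 1, n_residues = 30,
                           planted_epitope = c(10, 20),
                           disappeared_residues = integer(0),
                           csp_noise_sigma = 1e-12)
  st <- simulate_shift_tables(cfg)
  csp <- compute_csp(st$free, st$bound$bound_70uM)
  nz <- csp$residue[csp$csp > 1e-6]
  expect_equal(nz, c(10L, 20L))
  expect_equal(csp$csp[csp$residue %in% c(10, 20)], rep(cfg$csp_effect, 2),
               tolerance = 1e-6)
})

test_that("default-noise classification recovers the planted set across seeds", {
  hits <- vapply(1:100, function(s) {
    cfg <- simulation_config(seed = s)
    st <- simulate_shift_tables(cfg)
    cls <- classify_perturbed(compute_csp(st$free, st$bound$bound_70uM))
    setequal(cls$epitope$residues,
             setdiff(cfg$planted_epitope, cfg$disappeared_residues)) &&
      setequal(cls$disappeared, cfg$disappeared_residues)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("pose manifests agree exactly with contact_residues on every pose", {
  cfg <- simulation_config(seed = 13, n_poses = 25)
  pe <- simulate_pose_ensemble(cfg)
  for (k in seq_len(25))
    expect_equal(contact_residues(pe$ensemble$structure[[k]], cfg$cdr),
                 as.integer(pe$manifest$pose_contacts[[k]]))
})

test_that("degenerate contact probabilities give all-or-nothing frequencies", {
  cfg <- simulation_config(seed = 2, n_poses = 10,
                           p_contact_in = 1, p_contact_out = 0)
  pe <- simulate_pose_ensemble(cfg)
  prof <- contact_frequency(pe$ensemble, cfg$cdr)
  expect_true(all(prof$frequency[prof$residue %in% cfg$planted_epitope] == 1))
  expect_true(all(prof$frequency[!prof$residue %in% cfg$planted_epitope] == 0))
})

test_that("score filtering enriches planted-residue contact frequency", {
  cfg <- simulation_config(seed = 23, n_poses = 200)
  pe <- simulate_pose_ensemble(cfg)
  unfiltered <- contact_frequency(pe$ensemble, cfg$cdr)
  top <- contact_frequency(pe$ensemble, cfg$cdr, score_top_fraction = 0.1)
  planted <- cfg$planted_epitope
  expect_gt(mean(top$frequency[top$residue %in% planted]),
            mean(unfiltered$frequency[unfiltered$residue %in% planted]))
})

test_that("alignment generator plants conservation and respects rate = 0", {
  cfg0 <- simulation_config(seed = 3, substitution_rate = 0, gap_rate = 0)
  sym0 <- conservation_symbols(simulate_alignment(cfg0)$alignment)
  expect_true(all(sym0 == "*"))

  # conserved columns are more often invariant than mutated ones
  frac_in <- numeric(0); frac_out <- numeric(0)
  for (s in 1:20) {
    cfg <- simulation_config(seed = s, substitution_rate = 0.3, n_sequences = 5)
    sim <- simulate_alignment(cfg)
    sym <- conservation_symbols(sim$alignment)
    planted <- sim$manifest$conserved_columns
    frac_in <- c(frac_in, mean(sym[planted] == "*"))
    frac_out <- c(frac_out, mean(sym[-planted] == "*"))
  }
  expect_true(all(frac_in == 1))
  expect_gt(mean(frac_in), mean(frac_out))
})

test_that("decay generator supports exact and noisy rate recovery", {
  cfg0 <- simulation_config(seed = 4, n_residues = 5, planted_epitope = 2L,
                            disappeared_residues = integer(0), decay_noise = 0)
  sim0 <- simulate_decay_curves(cfg0)
  fit0 <- fit_relaxation(sim0$decays$r2_free, "R2")
  expect_equal(fit0$rate, sim0$rates$R2_free, tolerance = 1e-6)

  # complex R2 planted at 3x free: ratio separation in every simulation
  for (s in 1:5) {
    cfg <- simulation_config(seed = s, n_residues = 10, planted_epitope = 2L,
                             disappeared_residues = integer(0))
    sim <- simulate_decay_curves(cfg)
    free_ratio <- sim$rates$R2_free / sim$rates$R1_free
    complex_ratio <- sim$rates$R2_complex / sim$rates$R1_complex
    expect_gt(mean(complex_ratio), mean(free_ratio))
  }
})

test_that("the bundle writes every input plus a truth manifest", {
  dir <- tempfile()
  cfg <- simulation_config(seed = 55, n_poses = 8, n_residues = 20,
                           planted_epitope = c(3, 9, 15),
                           disappeared_residues = integer(0))
  b <- simulate_bundle(cfg, dir)
  expect_true(all(file.exists(unlist(b$paths))))
  truth <- jsonlite::read_json(b$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$shifts$planted_epitope, c(3, 9, 15))
  expect_equal(length(truth$docking$pose_contacts), 8L)
  # manifest alone suffices to score recovery of the docking stage
  ens <- read_pose_ensemble(b$paths$poses)
  for (k in seq_len(8))
    expect_equal(contact_residues(ens$structure[[k]], cfg$cdr),
                 as.integer(truth$docking$pose_contacts[[k]]))
})
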