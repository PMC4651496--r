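two_chain_pose <- function(ab_offset) {
  # antigen: residue 1 at origin; antibody residue 1 single atom at offset
  structure_model(tibble::tibble(
    chain = c("A", "B"), resno = c(1L, 1L), resid = "GLY",
    elety = "CA", elesy = "C",
    x = c(0, ab_offset), y = 0, z = 0))
}

test_that("contact criterion is inclusive at the cutoff", {
  expect_equal(contact_residues(two_chain_pose(4.9), cdr = 1), 1L)
  expect_equal(contact_residues(two_chain_pose(5.0), cdr = 1), 1L)
  expect_equal(contact_residues(two_chain_pose(8.0), cdr = 1), integer(0))
})

test_that("hydrogens are ignored and an empty CDR intersection errors", {
  pose <- structure_model(tibble::tibble(
    chain = c("A", "A", "B"), resno = c(1L, 1L, 1L), resid = "GLY",
    elety = c("CA", "H", "CA"), elesy = c("C", "H", "C"),
    x = c(0, 5.5, 6), y = 0, z = 0))
  # H at 0.5 A from the antibody atom must not create a contact
  expect_equal(contact_residues(pose, cdr = 1), integer(0))
  expect_error(contact_residues(pose, cdr = 99), "CDR")
})

test_that("contact_residues equals the brute-force all-pairs oracle", {
  set.seed(123)
  for (i in 1:30) {
    pose <- random_pose(n_ag = 30, n_ab = 8, with_h = (i %% 3 == 0))
    cdr <- sort(sample(1:8, sample(2:5, 1)))
    cutoff <- runif(1, 3, 8)
    expect_equal(contact_residues(pose, cdr, cutoff = cutoff),
                 brute_force_contacts(pose, cdr, cutoff = cutoff))
  }
})

test_that("chain scan order does not change the contact set", {
  set.seed(5)
  for (i in 1:5) {
    pose <- random_pose()
    swapped <- structure_model(dplyr::mutate(
      tibble::as_tibble(pose), chain = ifelse(chain == "A", "B", "A")))
    a <- contact_residues(pose, cdr = 1:8)
    # scanning from the other side: antigen residues via the swapped labels
    b <- contact_residues(swapped, cdr = 1:8, antigen_chain = "B",
                          antibody_chain = "A")
    expect_equal(a, b)
  }
})

test_that("growing the cutoff never removes contacts", {
  set.seed(8)
  pose <- random_pose()
  prev <- integer(0)
  for (cutoff in c(3, 4, 5, 6, 8, 10)) {
    cur <- contact_residues(pose, cdr = 1:8, cutoff = cutoff)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("contact frequency counts poses and score filtering is all-or-none", {
  cfg <- simulation_config(seed = 17, n_poses = 4, n_residues = 12,
                           planted_epitope = c(2, 5), disappeared_residues = integer(0),
                           p_contact_in = 1, p_contact_out = 0)
  pe <- simulate_pose_ensemble(cfg)
  prof <- contact_frequency(pe$ensemble, cfg$cdr)
  expect_s3_class(prof, "contact_profile")
  expect_equal(prof$frequency[prof$residue %in% c(2, 5)], c(1, 1))
  expect_true(all(prof$frequency[!prof$residue %in% c(2, 5)] == 0))
  expect_equal(prof$n_poses_used, rep(4L, nrow(prof)))
  expect_true(all(prof$frequency == prof$count / prof$n_poses_used))

  # score_top_fraction = 1 is exactly unfiltered counting
  expect_equal(contact_frequency(pe$ensemble, cfg$cdr, score_top_fraction = 1),
               prof)
  unscored <- pe$ensemble
  unscored$score <- NA_real_
  expect_error(contact_frequency(unscored, cfg$cdr, score_top_fraction = 0.5),
               "score")
})

test_that("pose ensembles read deterministically from dir and multi-model file", {
  cfg <- simulation_config(seed = 19, n_poses = 4, n_residues = 10,
                           planted_epitope = c(3, 6), disappeared_residues = integer(0))
  pe <- simulate_pose_ensemble(cfg)
  d <- tempfile(); dir.create(d)
  # write files in shuffled name order: reading must sort lexicographically
  for (k in c(3, 1, 4, 2))
    write_structure(pe$ensemble$structure[[k]],
                    file.path(d, sprintf("pose_%d.pdb", k)))
  ens_dir <- read_pose_ensemble(d)
  expect_equal(ens_dir$pose_id, sprintf("pose_%d", 1:4))

  mm <- tempfile(fileext = ".pdb")
  epimapr:::write_multimodel_pdb(pe$ensemble$structure, mm)
  ens_mm <- read_pose_ensemble(mm)
  expect_equal(nrow(ens_mm), 4L)
  # same ensemble, either packaging: identical contact profile
  expect_equal(contact_frequency(ens_dir, cfg$cdr)[, c("count", "frequency")],
               contact_frequency(ens_mm, cfg$cdr)[, c("count", "frequency")])

  # partial score coverage is a hard error; unknown ids only a warning
  st <- tibble::tibble(pose_id = sprintf("pose_%d", 1:3), score = 1:3)
  expect_error(read_pose_ensemble(d, score_table = st), "every pose")
  st4 <- tibble::tibble(pose_id = c(sprintf("pose_%d", 1:4), "ghost"),
                        score = 1:5)
  expect_warning(ens_s <- read_pose_ensemble(d, score_table = st4), "unknown")
  expect_equal(ens_s$score, 1:4)

  # a pose missing a chain is named in the error
  write_structure(structure_model(tibble::tibble(
    chain = "A", resno = 1L, resid = "GLY", elety = "CA", elesy = "C",
    x = 0, y = 0, z = 0)), file.path(d, "pose_5.pdb"))
  expect_error(read_pose_ensemble(d), "pose_5")
})
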