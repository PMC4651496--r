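test_that("shift tables parse, reject duplicates, and drop bad rows", {
  p <- write_tsv_text(c("residue\taa\tdH\tdN",
                        "1\tA\t8.10\t120.5",
                        "2\tK\t7.95\t118.2",
                        "3\tF\t9.01\t125.0"))
  tbl <- read_shift_table(p, "free")
  expect_s3_class(tbl, "shift_table")
  expect_equal(nrow(tbl), 3L)
  expect_equal(attr(tbl, "state_label"), "free")

  dup <- write_tsv_text(c("residue\taa\tdH\tdN",
                          "42\tA\t8.1\t120", "42\tA\t8.2\t121"))
  expect_error(read_shift_table(dup), "duplicate residue 42")

  empty <- write_tsv_text("residue\taa\tdH\tdN")
  expect_error(read_shift_table(empty), "empty")

  blank <- write_tsv_text(c("residue\taa\tdH\tdN",
                            "1\tA\t\t120.5", "2\tK\t7.95\t118.2"))
  expect_warning(tbl2 <- read_shift_table(blank), "non-numeric")
  expect_equal(nrow(tbl2), 1L)
  expect_equal(tbl2$residue, 2L)
})

test_that("CSP follows |ddH| + w|ddN| and classifies statuses", {
  free <- make_shift_tbl(1:4, dH = c(8.0, 8.0, 7.5, 9.0),
                         dN = c(120, 115, 110, 125), label = "free")
  bound <- make_shift_tbl(c(1, 2, 5), dH = c(8.10, 8.0, 7.0),
                          dN = c(120.5, 115, 112), label = "bound")
  csp <- compute_csp(free, bound)
  expect_equal(csp$csp[csp$residue == 1], 0.10 + 0.1 * 0.50, tolerance = 1e-12)
  expect_equal(csp$csp[csp$residue == 2], 0)
  expect_equal(csp$status[csp$residue == 3], "disappeared")
  expect_true(is.na(csp$csp[csp$residue == 3]))
  expect_equal(csp$status[csp$residue == 5], "missing_in_free")
  full <- compute_csp(free, bound, n_residues = 6)
  expect_equal(full$status[full$residue == 6], "missing_in_both")
  expect_error(compute_csp(free, bound, nitrogen_weight = -0.1), ">= 0")
})

test_that("CSP is invariant under sign flips and monotone in shift size", {
  set.seed(42)
  for (i in 1:20) {
    dH <- runif(1, -0.3, 0.3); dN <- runif(1, -3, 3)
    f <- make_shift_tbl(1, 8, 120)
    b_pos <- make_shift_tbl(1, 8 + dH, 120 + dN)
    b_neg <- make_shift_tbl(1, 8 - dH, 120 - dN)
    expect_equal(compute_csp(f, b_pos)$csp, compute_csp(f, b_neg)$csp)
    b_big <- make_shift_tbl(1, 8 + 2 * dH, 120 + 2 * dN)
    expect_gte(compute_csp(f, b_big)$csp, compute_csp(f, b_pos)$csp)
  }
})

test_that("self-comparison yields an empty significant set", {
  set.seed(7)
  t1 <- make_shift_tbl(1:50, dH = runif(50, 7, 10), dN = runif(50, 105, 135))
  cls <- classify_perturbed(compute_csp(t1, t1))
  expect_null(cls$epitope)
  expect_length(cls$disappeared, 0)
})

test_that("significance threshold is strict and disappeared stay separate", {
  free <- make_shift_tbl(1:3, dH = c(8, 8, 8), dN = c(120, 120, 120))
  # residue 1: csp exactly 0.028; residue 2: 0.03; residue 3 disappears
  bound <- make_shift_tbl(1:2, dH = c(8.028, 8.03), dN = c(120, 120))
  cls <- classify_perturbed(compute_csp(free, bound), threshold = 0.028)
  expect_equal(cls$epitope$residues, 2L)
  expect_equal(cls$disappeared, 3L)
  expect_equal(cls$epitope$provenance, "csp")
  expect_error(classify_perturbed(compute_csp(free, bound), threshold = 0),
               "> 0")
})

test_that("classification matches a brute-force filter on planted data", {
  set.seed(11)
  planted <- sort(sample(1:80, 12))
  dH <- runif(80, 7, 10); dN <- runif(80, 105, 135)
  f <- make_shift_tbl(1:80, dH, dN)
  dH2 <- dH; dH2[planted] <- dH2[planted] + 0.05
  b <- make_shift_tbl(1:80, dH2, dN)
  csp <- compute_csp(f, b)
  cls <- classify_perturbed(csp, 0.028)
  oracle <- csp$residue[!is.na(csp$csp) & csp$csp > 0.028]
  expect_equal(cls$epitope$residues, sort(oracle))
  expect_equal(cls$epitope$residues, planted)
})

test_that("region segmentation counts partition the epitope", {
  sch <- region_scheme(c("n_term", "c_term"), c(1, 95), c(15, 109))
  seg <- segment_regions(epitope_set(c(2, 3, 100)), sch)
  expect_equal(seg$counts$n, c(2L, 1L))
  expect_length(seg$unassigned, 0)

  seg0 <- segment_regions(integer(0), sch)
  expect_true(all(seg0$counts$n == 0))

  seg50 <- segment_regions(epitope_set(50), sch)
  expect_true(all(seg50$counts$n == 0))
  expect_equal(seg50$unassigned, 50L)

  # counts + unassigned always partition the set
  set.seed(3)
  for (i in 1:10) {
    epi <- sort(sample(1:120, 25))
    seg <- segment_regions(epi, default_region_scheme())
    expect_equal(sum(seg$counts$n) + length(seg$unassigned), length(epi))
  }
  expect_error(region_scheme(c("a", "b"), c(1, 10), c(12, 20)), "overlap")
})

test_that("titration CSPs are non-decreasing with bound fraction", {
  cfg <- simulation_config(seed = 21, csp_noise_sigma = 1e-4, csp_effect = 0.06)
  st <- simulate_shift_tables(cfg)
  per <- csp_titration(st$free, st$bound)
  wide <- tidyr::pivot_wider(per[per$status == "measured", c("residue", "point", "csp")],
                             names_from = "point", values_from = "csp")
  planted <- setdiff(cfg$planted_epitope, cfg$disappeared_residues)
  on_planted <- wide[wide$residue %in% planted, ]
  expect_true(all(on_planted$bound_70uM >= on_planted$bound_40uM))
})
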