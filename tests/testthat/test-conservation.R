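test_that("aligned FASTA parses, validates and upper-cases", {
  p <- tempfile(fileext = ".afa")
  writeLines(c(">s1", "acdefghiklmnpqrstvwy", ">s2", "ACDEFGHIKLMNPQRSTVWY",
               ">s3", "ACDEFGHIKLMNPQRSTVW-"), p)
  aln <- read_alignment(p)
  expect_equal(nrow(aln), 3L)
  expect_equal(nchar(aln$seq), rep(20L, 3))
  expect_equal(aln$seq[1], aln$seq[2])

  ragged <- tempfile(fileext = ".afa")
  writeLines(c(">a", "ACDE", ">b", "ACD"), ragged)
  expect_error(read_alignment(ragged), "ragged|unequal")

  expect_error(multiple_alignment(data.frame(id = c("a", "b"),
                                             seq = c("ACXE", "ACDE"))),
               "invalid symbol 'X' at position 3")
})

test_that("Clustal conservation lines are recomputed, not trusted, on input", {
  p <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "s1              MIDE",
               "s2              MLDE",
               "s3              MVDE",
               "                *.**"),  # deliberately wrong symbol at column 2
             p)
  aln <- read_alignment(p)
  expect_equal(nrow(aln), 3L)
  sym <- conservation_symbols(aln)
  expect_equal(sym, c("*", ":", "*", "*"))  # I/L/V is a strong group
})

test_that("conservation symbols follow the Clustal group tables", {
  mk <- function(...) multiple_alignment(
    data.frame(id = paste0("s", seq_along(list(...))), seq = unlist(list(...))))
  expect_equal(conservation_symbols(mk("D", "D", "D")), "*")
  expect_equal(conservation_symbols(mk("I", "L", "V")), ":")
  expect_equal(conservation_symbols(mk("C", "S", "A")), ".")
  expect_equal(conservation_symbols(mk("D", "K", "A")), " ")
  expect_equal(conservation_symbols(mk("A", "-", "A")), " ")  # gap column
  # permutation invariance over sequence order
  a1 <- mk("MIDKW", "MLEKW", "MVQRF")
  a2 <- mk("MVQRF", "MIDKW", "MLEKW")
  expect_equal(conservation_symbols(a1), conservation_symbols(a2))
})

test_that("conservation symbols match mafft's Clustal output on toy alignments", {
  set.seed(61)
  total <- 0L; agree <- 0L
  for (i in 1:20) {
    toy <- random_toy_alignment(n_seq = 4, len = 60, rate = 0.15)
    ref <- mafft_clustal_symbols(toy$id, toy$seq)
    if (is.null(ref) || !identical(unname(ref$seqs), toy$seq))
      next  # mafft realigned or emitted an unparseable block; incomparable
    ours <- conservation_symbols(multiple_alignment(toy))
    total <- total + length(ours)
    agree <- agree + sum(ours == ref$symbols)
  }
  expect_gt(total, 0)
  expect_gte(agree / total, 0.95)
})

test_that("epitope residues map through gaps onto the right columns", {
  aln <- multiple_alignment(data.frame(
    id = c("ref", "hom"), seq = c("A-CD", "AKCD")))
  m <- map_epitope_columns(epitope_set(2), "ref", aln)
  expect_equal(m$column, 3L)
  expect_equal(m$ref_aa, "C")
  expect_equal(m$symbol, "*")
  expect_equal(m$identical_fraction, 1)

  # inverse composition: every non-gap reference position round-trips
  cols <- epimapr:::ungapped_to_columns("A-CD")
  chars <- strsplit("A-CD", "")[[1]]
  expect_equal(chars[cols], c("A", "C", "D"))

  expect_error(map_epitope_columns(epitope_set(9), "ref", aln), "beyond")
  expect_error(map_epitope_columns(epitope_set(1), "nope", aln), "not in alignment")
})

test_that("planted conserved columns report * for every epitope residue", {
  cfg <- simulation_config(seed = 77)
  sim <- simulate_alignment(cfg)
  m <- map_epitope_columns(epitope_set(cfg$planted_epitope), "reference",
                           sim$alignment)
  expect_true(all(m$symbol == "*"))
  expect_true(all(m$identical_fraction == 1))
})

test_that("overlap report counts interval intersections and Jaccard", {
  epi <- epitope_set(c(29, 30, 31, 32, 33, 36))
  lit <- tibble::tibble(name = "axis", start = 28L, end = 45L, source = "x")
  rep1 <- epitope_overlap_report(epi, lit)
  expect_equal(rep1$overlap, 6L)
  expect_equal(rep1$interval_size, 18L)
  expect_equal(rep1$jaccard, 6 / 18)

  rep2 <- epitope_overlap_report(epitope_set(108),
                                 tibble::tibble(name = "cterm", start = 95L,
                                                end = 109L, source = "y"))
  expect_equal(rep2$overlap, 1L)

  empty <- epitope_overlap_report(epi, tibble::tibble(name = character(),
                                                      start = integer(),
                                                      end = integer()))
  expect_equal(nrow(empty), 0L)

  # packaged literature intervals include the canonical parvalbumin regions
  lit_all <- literature_epitopes()
  expect_true(all(c(28, 95, 75) %in% lit_all$start))
})
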