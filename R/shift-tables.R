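#' Read an amide shift table
#'
#' Reads per-residue backbone amide chemical shifts for one state of the
#' antigen (free, or bound at one titration point) from a TSV file with
#' header columns `residue`, `aa`, `dH`, `dN` (1-based residue numbers,
#' one-letter amino acid codes, shifts in ppm). One row per assigned
#' amide; prolines and unassigned residues are simply absent.
#'
#' Rows whose `dH` or `dN` cannot be parsed as a number are dropped with a
#' warning. Duplicate residue numbers are a hard error.
#'
#' @param path Path to the TSV file.
#' @param state_label Label for the state, e.g. `"free"` or `"bound_70uM"`.
#' @return A `shift_table`: a tibble with columns `residue`, `aa`, `dH`,
#'   `dN`, sorted by residue, with the state label in
#'   `attr(, "state_label")`.
#' @export
read_shift_table <- function(path, state_label = "state") {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) abort(sprintf("empty shift table: %s", path))
  need <- c("residue", "aa", "dH", "dN")
  if (!all(need %in% names(raw)))
    abort(sprintf("shift table must have columns %s", paste(need, collapse = ", ")))
  dH <- suppressWarnings(as.numeric(raw$dH))
  dN <- suppressWarnings(as.numeric(raw$dN))
  bad <- !is.finite(dH) | !is.finite(dN)
  if (any(bad)) {
    warn(sprintf("dropping %d row(s) with non-numeric shifts (residues %s)",
                 sum(bad), paste(raw$residue[bad], collapse = ", ")))
  }
  res <- suppressWarnings(as.integer(raw$residue))
  if (anyNA(res)) abort("non-integer residue numbers in shift table")
  tbl <- tibble(residue = res, aa = toupper(raw$aa), dH = dH, dN = dN)[!bad, ]
  if (nrow(tbl) == 0L) abort(sprintf("no usable rows in shift table: %s", path))
  shift_table(tbl, state_label)
}

#' Construct a shift table from a data frame
#'
#' @param entries Data frame with columns `residue`, `aa`, `dH`, `dN`.
#' @param state_label State label (free / bound at a titration point).
#' @return A validated `shift_table` tibble sorted by residue.
#' @export
shift_table <- function(entries, state_label = "state") {
  entries <- as_tibble(entries)[, c("residue", "aa", "dH", "dN")]
  entries$residue <- as.integer(entries$residue)
  dup <- entries$residue[duplicated(entries$residue)]
  if (length(dup) > 0L)
    abort(sprintf("duplicate residue %s in shift table",
                  paste(sort(unique(dup)), collapse = ", ")))
  if (any(entries$residue < 1L)) abort("residue numbers must be >= 1")
  if (!all(is.finite(entries$dH)) || !all(is.finite(entries$dN)))
    abort("shifts must be finite")
  entries <- dplyr::arrange(entries, .data$residue)
  structure(entries, state_label = state_label,
            class = c("shift_table", class(entries)))
}

#' Compute per-residue chemical shift perturbations
#'
#' For every residue in the union of the free and bound shift tables,
#' computes the composite amide CSP
#' \deqn{CSP = |\Delta\delta_H| + w \, |\Delta\delta_N|}
#' with nitrogen weight \eqn{w} (default 0.1, reflecting the roughly
#' ten-fold larger spectral dispersion of the 15N dimension). Residues
#' present in the free spectrum but absent from the bound one are flagged
#' `disappeared` (signal lost on complex formation, typically by exchange
#' broadening); residues absent from the free table cannot be compared and
#' are flagged `missing_in_free`. When `n_residues` is given, residues of
#' the full construct observed in neither state are included as
#' `missing_in_both` (prolines, unassigned).
#'
#' @param free,bound `shift_table` objects for the free and complexed state.
#' @param nitrogen_weight Non-negative weight on `|ddN|`; default 0.1.
#' @param n_residues Optional construct length, to enumerate residues
#'   missing from both tables.
#' @return A tibble of CSP records: `residue`, `aa`, `d_dH`, `d_dN`,
#'   `csp` (ppm; `NA` unless status is `measured`) and
#'   `status` (`measured` / `disappeared` / `missing_in_free` /
#'   `missing_in_both`).
#' @examples
#' free  <- shift_table(data.frame(residue = 1:2, aa = "A",
#'                                 dH = c(8.0, 8.5), dN = c(120, 115)), "free")
#' bound <- shift_table(data.frame(residue = 1:2, aa = "A",
#'                                 dH = c(8.1, 8.5), dN = c(120.5, 115)), "bound")
#' compute_csp(free, bound)  # residue 1: |0.1| + 0.1*|0.5| = 0.15 ppm
#' @export
compute_csp <- function(free, bound, nitrogen_weight = 0.1, n_residues = NULL) {
  if (!is.numeric(nitrogen_weight) || nitrogen_weight < 0)
    abort("`nitrogen_weight` must be >= 0")
  f <- as_tibble(free)[, c("residue", "aa", "dH", "dN")]
  b <- as_tibble(bound)[, c("residue", "dH", "dN")]
  all_res <- sort(union(f$residue, b$residue))
  if (!is.null(n_residues)) all_res <- sort(union(all_res, seq_len(n_residues)))
  out <- tibble(residue = as.integer(all_res)) |>
    dplyr::left_join(dplyr::rename(f, dH_f = "dH", dN_f = "dN"), by = "residue") |>
    dplyr::left_join(dplyr::rename(b, dH_b = "dH", dN_b = "dN"), by = "residue") |>
    dplyr::mutate(
      in_free  = !is.na(.data$dH_f),
      in_bound = !is.na(.data$dH_b),
      status = dplyr::case_when(
        .data$in_free & .data$in_bound   ~ "measured",
        .data$in_free & !.data$in_bound  ~ "disappeared",
        !.data$in_free & .data$in_bound  ~ "missing_in_free",
        TRUE                             ~ "missing_in_both"
      ),
      d_dH = ifelse(.data$status == "measured", .data$dH_b - .data$dH_f, NA_real_),
      d_dN = ifelse(.data$status == "measured", .data$dN_b - .data$dN_f, NA_real_),
      csp  = abs(.data$d_dH) + nitrogen_weight * abs(.data$d_dN)
    ) |>
    dplyr::select("residue", "aa", "d_dH", "d_dN", "csp", "status")
  out
}

#' Classify significantly perturbed residues
#'
#' Splits CSP records into a CSP-derived epitope set (residues whose
#' measured CSP is strictly greater than the significance threshold) and
#' the list of residues whose signals disappeared on complex formation.
#' Disappeared residues are strong qualitative evidence of involvement
#' but carry no CSP value, so they are reported separately and never
#' merged into the significant set.
#'
#' @param csps Tibble of CSP records from [compute_csp()].
#' @param threshold Significance threshold in ppm (default 0.028);
#'   comparison is strict (`csp > threshold`). A CSP within 1e-9 ppm of
#'   the threshold counts as equal to it (and is therefore not
#'   significant), so the strict boundary is immune to floating-point
#'   representation of shift differences.
#' @param name Name for the resulting epitope set.
#' @return A list with elements `epitope` (an [epitope_set()] with
#'   provenance `"csp"`, or `NULL` when no residue passes), `disappeared`
#'   (integer vector) and `threshold`.
#' @export
classify_perturbed <- function(csps, threshold = 0.028, name = "csp_epitope") {
  check_scalar_number(threshold, "threshold", positive = TRUE)
  if (nrow(csps) == 0L) abort("`csps` must be non-empty")
  sig <- csps$residue[csps$status == "measured" & csps$csp > threshold + 1e-9]
  disappeared <- sort(csps$residue[csps$status == "disappeared"])
  epi <- if (length(sig) > 0L) epitope_set(sig, name, "csp") else NULL
  list(epitope = epi, disappeared = as.integer(disappeared),
       threshold = threshold)
}

#' Count epitope residues per sequence region
#'
#' @param epitope An [epitope_set()] (or integer vector of residues).
#' @param scheme A region scheme tibble, see [region_scheme()];
#'   default [default_region_scheme()].
#' @return A list with `counts` (tibble `region`, `n`) and `unassigned`
#'   (residues covered by no interval). Counts plus unassigned always
#'   partition the epitope.
#' @export
segment_regions <- function(epitope, scheme = default_region_scheme()) {
  residues <- if (inherits(epitope, "epitope_set")) epitope$residues
              else sort(unique(as.integer(epitope)))
  scheme <- region_scheme(scheme$region, scheme$start, scheme$end)
  counts <- purrr::pmap_int(scheme, function(region, start, end)
    sum(residues >= start & residues <= end))
  assigned <- purrr::pmap(scheme, function(region, start, end)
    residues[residues >= start & residues <= end])
  counts_tbl <- tibble(region = scheme$region, n = counts)
  list(counts = counts_tbl,
       unassigned = setdiff(residues, unlist(assigned)))
}

#' Compute CSPs across a titration series
#'
#' Convenience wrapper: computes CSP records against the free state for
#' each bound-state shift table of a titration series and stacks them
#' with a `point` label. The headline epitope of a study is conventionally
#' taken from the highest-concentration point; this keeps the per-point
#' record available.
#'
#' @param free Free-state `shift_table`.
#' @param bound_list Named list of bound-state `shift_table`s, ordered by
#'   increasing saturation.
#' @param nitrogen_weight Passed to [compute_csp()].
#' @return A tibble of CSP records with an extra `point` column.
#' @export
csp_titration <- function(free, bound_list, nitrogen_weight = 0.1) {
  if (is.null(names(bound_list)))
    names(bound_list) <- paste0("point_", seq_along(bound_list))
  purrr::imap(bound_list, function(b, nm)
    dplyr::mutate(compute_csp(free, b, nitrogen_weight), point = nm)) |>
    purrr::list_rbind()
}
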