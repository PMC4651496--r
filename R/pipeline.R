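#' Pipeline configuration
#'
#' Collects every input path and tunable parameter of the full analysis
#' in one validated list. All stages except the CSP stage are optional:
#' a missing structure skips accessibility and structure annotation, a
#' missing pose source skips the docking stage, a missing alignment
#' skips conservation — each with a warning, never silently.
#'
#' @param shift_free Path to the free-state shift TSV.
#' @param shift_bound Named character vector of bound-state shift TSVs,
#'   ordered by increasing saturation; the last is the headline point.
#' @param decays Optional named list/vector of decay TSV paths with names
#'   among `r1_free`, `r2_free`, `r1_complex`, `r2_complex`.
#' @param structure Optional antigen PDB path.
#' @param poses Optional pose-ensemble source (directory or multi-model
#'   PDB); requires `cdr`.
#' @param scores Optional pose score TSV.
#' @param alignment Optional aligned FASTA / Clustal path.
#' @param reference_id Reference sequence id in the alignment.
#' @param literature Literature epitope intervals (tibble or TSV path);
#'   default [literature_epitopes()].
#' @param csp_threshold CSP significance threshold, ppm (default 0.028,
#'   strict).
#' @param nitrogen_weight 15N weight in the CSP formula (default 0.1).
#' @param contact_cutoff Heavy-atom contact cutoff, Angstrom (default 5).
#' @param region_scheme Region scheme tibble (default
#'   [default_region_scheme()]).
#' @param cdr CDR residue numbers on the antibody chain.
#' @param antigen_chain,antibody_chain Chain ids in the poses.
#' @param score_top_fraction Fraction of best-scoring poses counted
#'   (default 1 = all).
#' @param docking_min_frequency Contact frequency defining the
#'   docking-derived epitope (default 0.5).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(shift_free, shift_bound,
                            decays = NULL, structure = NULL,
                            poses = NULL, scores = NULL,
                            alignment = NULL, reference_id = "reference",
                            literature = literature_epitopes(),
                            csp_threshold = 0.028, nitrogen_weight = 0.1,
                            contact_cutoff = 5.0,
                            region_scheme = default_region_scheme(),
                            cdr = NULL, antigen_chain = "A",
                            antibody_chain = "B",
                            score_top_fraction = 1.0,
                            docking_min_frequency = 0.5) {
  check_scalar_number(csp_threshold, "csp_threshold", positive = TRUE)
  check_scalar_number(contact_cutoff, "contact_cutoff", positive = TRUE)
  if (nitrogen_weight < 0) abort("`nitrogen_weight` must be >= 0")
  if (length(shift_bound) < 1L) abort("at least one bound shift table is required")
  if (is.null(names(shift_bound)))
    names(shift_bound) <- paste0("point_", seq_along(shift_bound))
  if (!is.null(poses) && is.null(cdr))
    abort("docking stage requires a CDR definition (`cdr`)")
  if (is.character(literature) && length(literature) == 1L)
    literature <- readr::read_tsv(literature, col_types = readr::cols(),
                                  progress = FALSE)
  structure(
    list(shift_free = shift_free, shift_bound = shift_bound, decays = decays,
         structure = structure, poses = poses, scores = scores,
         alignment = alignment, reference_id = reference_id,
         literature = literature, csp_threshold = csp_threshold,
         nitrogen_weight = nitrogen_weight, contact_cutoff = contact_cutoff,
         region_scheme = region_scheme, cdr = cdr,
         antigen_chain = antigen_chain, antibody_chain = antibody_chain,
         score_top_fraction = score_top_fraction,
         docking_min_frequency = docking_min_frequency),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [pipeline_config()]; relative input paths are resolved against the
#' YAML file's directory. Overrides passed as `...` replace the file's
#' values.
#'
#' @param path YAML file.
#' @param ... Named overrides of config keys.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  cfg[names(dots)] <- dots
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  for (key in c("shift_free", "structure", "poses", "scores", "alignment"))
    cfg[[key]] <- rel(cfg[[key]])
  if (!is.null(cfg$shift_bound)) {
    nm <- names(cfg$shift_bound)
    cfg$shift_bound <- setNames(rel(unlist(cfg$shift_bound)), nm)
  }
  if (!is.null(cfg$decays))
    cfg$decays <- lapply(cfg$decays, rel)
  if (!is.null(cfg$region_scheme))
    cfg$region_scheme <- as_tibble(lapply(
      list(region = "region", start = "start", end = "end"),
      function(k) sapply(cfg$region_scheme, `[[`, k)))
  do.call(pipeline_config, cfg)
}

#' Run the full epitope-mapping analysis
#'
#' Executes the stages in dependency order: CSP titration analysis and
#' significance classification, region segmentation, relaxation fitting,
#' solvent accessibility, docking contact frequencies, and conservation
#' mapping, then joins everything into one per-residue table and an
#' agreement summary (Jaccard index between the CSP- and docking-derived
#' epitopes — a repository-defined synthesis metric, not a standard
#' statistic). Deterministic: the same inputs give identical reports.
#'
#' @param config A [pipeline_config()].
#' @return An `analysis_report` list; see [write_report()] for
#'   serialization.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, code) tryCatch(code, error = function(e)
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))

  ## --- CSP stage (always) -------------------------------------------------
  csp_stage <- stage("csp", {
    free <- read_shift_table(config$shift_free, "free")
    bound <- purrr::imap(as.list(config$shift_bound), read_shift_table)
    per_point <- csp_titration(free, bound, config$nitrogen_weight)
    headline_point <- names(bound)[length(bound)]
    headline <- dplyr::filter(per_point, .data$point == headline_point)
    cls <- classify_perturbed(headline, config$csp_threshold)
    mapped <- sort(union(if (is.null(cls$epitope)) integer(0) else
      cls$epitope$residues, cls$disappeared))
    regions_sig <- segment_regions(
      if (is.null(cls$epitope)) integer(0) else cls$epitope,
      config$region_scheme)
    regions_mapped <- segment_regions(mapped, config$region_scheme)
    list(free = free, per_point = per_point, headline_point = headline_point,
         headline = headline, classification = cls, mapped = mapped,
         regions_significant = regions_sig, regions_mapped = regions_mapped)
  })
  n_res <- max(csp_stage$per_point$residue)

  ## --- relaxation stage ---------------------------------------------------
  relax_stage <- NULL
  if (!is.null(config$decays)) {
    relax_stage <- stage("relaxation", {
      d <- lapply(config$decays, function(p)
        readr::read_tsv(p, col_types = "idd", progress = FALSE))
      fit <- function(nm, mode) if (is.null(d[[nm]])) NULL else
        fit_relaxation(d[[nm]], mode)
      f_r1 <- fit("r1_free", "R1"); f_r2 <- fit("r2_free", "R2")
      c_r1 <- fit("r1_complex", "R1"); c_r2 <- fit("r2_complex", "R2")
      rates <- dplyr::bind_rows(
        if (!is.null(f_r1) && !is.null(f_r2))
          dplyr::mutate(relaxation_rates(f_r1, f_r2), state = "free"),
        if (!is.null(c_r1) && !is.null(c_r2))
          dplyr::mutate(relaxation_rates(c_r1, c_r2), state = "complex"))
      summary <- rates |>
        dplyr::group_by(.data$state) |>
        dplyr::summarise(median_R1 = median(.data$R1),
                         median_R2 = median(.data$R2),
                         median_ratio = median(.data$ratio_R2_over_R1),
                         .groups = "drop")
      list(rates = rates, summary = summary)
    })
  }

  ## --- structure / accessibility stage ------------------------------------
  struct_stage <- NULL
  if (!is.null(config$structure)) {
    struct_stage <- stage("structure", {
      s <- read_structure(config$structure)
      ag <- s[s$chain == config$antigen_chain | length(unique(s$chain)) == 1L, ]
      mismatch <- setdiff(unique(csp_stage$per_point$residue), unique(ag$resno))
      if (length(mismatch) > 0L)
        abort(sprintf("shift-table residues absent from structure: %s",
                      paste(mismatch, collapse = ", ")))
      acc <- compute_sasa(s)
      list(structure = s, accessibility = acc)
    })
  } else {
    warn("no structure supplied: skipping accessibility stage")
  }

  ## --- docking stage -------------------------------------------------------
  dock_stage <- NULL
  if (!is.null(config$poses)) {
    dock_stage <- stage("docking", {
      ens <- read_pose_ensemble(config$poses, config$antigen_chain,
                                config$antibody_chain, config$scores)
      prof <- contact_frequency(ens, config$cdr, config$contact_cutoff,
                                config$score_top_fraction)
      epi <- docking_epitope(prof, config$docking_min_frequency)
      list(profile = prof, epitope = epi)
    })
  } else {
    warn("no pose ensemble supplied: skipping docking stage")
  }

  ## --- conservation stage --------------------------------------------------
  cons_stage <- NULL
  if (!is.null(config$alignment)) {
    cons_stage <- stage("conservation", {
      aln <- read_alignment(config$alignment)
      sym <- conservation_symbols(aln)
      epi <- csp_stage$classification$epitope
      emap <- if (is.null(epi)) NULL else
        map_epitope_columns(epi, config$reference_id, aln)
      overlap <- epitope_overlap_report(
        if (is.null(epi)) integer(0) else epi, config$literature)
      list(alignment = aln, symbols = sym, epitope_columns = emap,
           overlap = overlap)
    })
  } else {
    warn("no alignment supplied: skipping conservation stage")
  }

  ## --- combined per-residue table ------------------------------------------
  sig_res <- if (is.null(csp_stage$classification$epitope)) integer(0) else
    csp_stage$classification$epitope$residues
  combined <- csp_stage$headline |>
    dplyr::select("residue", "aa", "csp", "status") |>
    dplyr::mutate(significant = .data$residue %in% sig_res)
  if (!is.null(dock_stage))
    combined <- dplyr::left_join(
      combined, dplyr::select(as_tibble(dock_stage$profile), "residue",
                              contact_frequency = "frequency"),
      by = "residue")
  else combined$contact_frequency <- NA_real_
  if (!is.null(struct_stage))
    combined <- dplyr::left_join(
      combined, dplyr::select(struct_stage$accessibility, "residue",
                              "sasa", "rel_acc", "exposed"),
      by = "residue")
  else combined <- dplyr::mutate(combined, sasa = NA_real_,
                                 rel_acc = NA_real_, exposed = NA)
  if (!is.null(cons_stage)) {
    ref <- cons_stage$alignment$seq[cons_stage$alignment$id == config$reference_id]
    cols <- ungapped_to_columns(ref)
    combined$conservation <- ifelse(
      combined$residue <= length(cols),
      cons_stage$symbols[cols[pmin(combined$residue, length(cols))]],
      NA_character_)
  } else combined$conservation <- NA_character_

  jac <- if (!is.null(dock_stage) && !is.null(dock_stage$epitope) &&
             length(sig_res) > 0L)
    epitope_jaccard(sig_res, dock_stage$epitope) else NA_real_

  structure(
    list(schema_version = "1.0",
         params = list(csp_threshold = config$csp_threshold,
                       nitrogen_weight = config$nitrogen_weight,
                       contact_cutoff = config$contact_cutoff,
                       score_top_fraction = config$score_top_fraction,
                       docking_min_frequency = config$docking_min_frequency,
                       headline_point = csp_stage$headline_point),
         csp = csp_stage, relaxation = relax_stage, structure = struct_stage,
         docking = dock_stage, conservation = cons_stage,
         combined = combined,
         agreement = list(jaccard_csp_docking = jac)),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cls <- x$csp$classification
  n_sig <- if (is.null(cls$epitope)) 0L else length(cls$epitope)
  cat("<analysis_report>\n")
  cat(sprintf("  CSP: %d significant (> %g ppm), %d disappeared [%s]\n",
              n_sig, cls$threshold, length(cls$disappeared),
              x$params$headline_point))
  rc <- x$csp$regions_mapped$counts
  cat(sprintf("  regions (mapped): %s\n",
              paste(sprintf("%s=%d", rc$region, rc$n), collapse = ", ")))
  if (!is.null(x$docking))
    cat(sprintf("  docking epitope: %d residues; Jaccard vs CSP = %.3f\n",
                if (is.null(x$docking$epitope)) 0L else length(x$docking$epitope),
                x$agreement$jaccard_csp_docking))
  if (!is.null(x$relaxation)) {
    s <- x$relaxation$summary
    cat(sprintf("  median R2/R1: %s\n",
                paste(sprintf("%s=%.2f", s$state, s$median_ratio),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `analysis_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.analysis_report <- function(x, ...) {
  cls <- x$csp$classification
  tibble(
    n_significant = if (is.null(cls$epitope)) 0L else length(cls$epitope),
    n_disappeared = length(cls$disappeared),
    csp_threshold = cls$threshold,
    n_docking_epitope = if (is.null(x$docking) || is.null(x$docking$epitope))
      NA_integer_ else length(x$docking$epitope),
    jaccard_csp_docking = x$agreement$jaccard_csp_docking)
}

# fix doubles to 6 significant digits for stable TSV output
signif_cols <- function(df, digits = 6) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                  function(x) signif(x, digits)))
}

#' Serialize an analysis report
#'
#' Writes the report as a bundle of TSV tables (one per stage plus the
#' combined per-residue table), as a single JSON document containing
#' every number printed in any TSV (stages that did not run are present
#' as `null`, keeping the schema stable), or both. Doubles in TSVs are
#' fixed to 6 significant digits so reruns are byte-identical.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param format `"both"` (default), `"tsv_bundle"` or `"json"`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, format = c("both", "tsv_bundle", "json")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    f <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(signif_cols(df), f, progress = FALSE, na = "")
    paths[[name]] <<- f
  }
  cls <- report$csp$classification
  epitopes <- list()
  if (!is.null(cls$epitope))
    epitopes$csp <- list(name = cls$epitope$name, provenance = "csp",
                         residues = cls$epitope$residues)
  if (!is.null(report$docking) && !is.null(report$docking$epitope))
    epitopes$docking <- list(name = report$docking$epitope$name,
                             provenance = "docking",
                             residues = report$docking$epitope$residues)

  if (format %in% c("both", "tsv_bundle")) {
    emit(dplyr::mutate(report$csp$per_point,
                       significant = .data$status == "measured" &
                         .data$csp > cls$threshold), "csp_records")
    emit(report$csp$regions_significant$counts, "region_counts_significant")
    emit(report$csp$regions_mapped$counts, "region_counts_mapped")
    emit(report$combined, "per_residue")
    if (!is.null(report$relaxation)) emit(report$relaxation$rates, "relaxation")
    if (!is.null(report$structure))
      emit(report$structure$accessibility, "accessibility")
    if (!is.null(report$docking))
      emit(as_tibble(report$docking$profile), "contact_profile")
    if (!is.null(report$conservation)) {
      if (!is.null(report$conservation$epitope_columns))
        emit(report$conservation$epitope_columns, "conservation_epitope")
      emit(report$conservation$overlap, "overlap_report")
    }
  }
  if (format %in% c("both", "json")) {
    j <- list(
      schema_version = report$schema_version,
      params = report$params,
      epitopes = epitopes,
      disappeared = cls$disappeared,
      region_counts_significant = report$csp$regions_significant$counts,
      region_counts_mapped = report$csp$regions_mapped$counts,
      agreement = report$agreement,
      per_residue = signif_cols(report$combined),
      relaxation = if (is.null(report$relaxation)) NULL else
        list(summary = report$relaxation$summary,
             rates = signif_cols(report$relaxation$rates)),
      accessibility = if (is.null(report$structure)) NULL else
        signif_cols(report$structure$accessibility),
      contact_profile = if (is.null(report$docking)) NULL else
        signif_cols(as_tibble(report$docking$profile)),
      conservation = if (is.null(report$conservation)) NULL else
        list(symbols = paste(report$conservation$symbols, collapse = ""),
             epitope_columns = report$conservation$epitope_columns,
             overlap = signif_cols(report$conservation$overlap)))
    f <- file.path(dir, "report.json")
    jsonlite::write_json(j, f, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    paths[["report_json"]] <- f
  }
  invisible(unlist(paths))
}
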