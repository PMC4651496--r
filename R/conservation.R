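# ClustalW-convention residue groups: a gap-free column is ':' when all its
# residues fall in one strong group, '.' when in one weak group.
STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                   "HY", "FYW")
WEAK_GROUPS <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SDEENK",
                 "NDEQHK", "NEQHRK", "FVLIM", "HFY")

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA (`.afa`/`.fasta`) or Clustal (`.aln`) file into
#' a validated alignment tibble. Sequences are upper-cased; a Clustal
#' conservation line, if present, is ignored on input (symbols are always
#' recomputed by [conservation_symbols()]). At least two sequences of
#' equal aligned length over the 20 amino acids plus `-` are required.
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (sniff: Clustal header vs FASTA), `"fasta"` or
#'   `"clustal"`.
#' @return A `multiple_alignment`: tibble with columns `id`, `seq`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal"
              else "fasta"
  }
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) abort(sprintf(
      "not a valid %s alignment (ragged lengths or malformed file): %s",
      format, conditionMessage(e))))
  seqs <- toupper(as.character(aln))
  multiple_alignment(tibble(id = names(seqs), seq = unname(seqs)))
}

#' Construct and validate a multiple alignment
#'
#' @param records Data frame with columns `id` (unique sequence ids) and
#'   `seq` (aligned sequences, gaps as `-`).
#' @return A `multiple_alignment` tibble.
#' @export
multiple_alignment <- function(records) {
  records <- as_tibble(records)[, c("id", "seq")]
  if (nrow(records) < 2L) abort("an alignment needs at least 2 sequences")
  if (anyDuplicated(records$id)) abort("sequence ids must be unique")
  records$seq <- toupper(records$seq)
  len <- nchar(records$seq)
  if (length(unique(len)) != 1L)
    abort(sprintf("ragged alignment: lengths %s",
                  paste(unique(len), collapse = ", ")))
  ok <- c(AA1, "-")
  for (i in seq_len(nrow(records))) {
    ch <- strsplit(records$seq[i], "")[[1]]
    bad <- which(!(ch %in% ok))
    if (length(bad) > 0L)
      abort(sprintf("invalid symbol '%s' at position %d of sequence '%s'",
                    ch[bad[1]], bad[1], records$id[i]))
  }
  structure(records, class = c("multiple_alignment", class(records)))
}

# alignment as a character matrix, sequences in rows
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$id
  m
}

#' Clustal-style conservation symbols per alignment column
#'
#' Annotates each column with the ClustalW conservation symbol:
#' `*` all residues identical (and no gap), `:` all residues in one
#' strong substitution group, `.` all in one weak group, and a blank
#' otherwise. Any gap in a column yields a blank.
#'
#' @param aln A `multiple_alignment`.
#' @return Character vector of symbols, one per alignment column.
#' @examples
#' a <- multiple_alignment(data.frame(id = c("s1", "s2"),
#'                                    seq = c("ILDE", "VLDQ")))
#' conservation_symbols(a)  # ":", "*", "*", ":"
#' @export
conservation_symbols <- function(aln) {
  m <- aln_matrix(aln)
  apply(m, 2, function(col) {
    if (any(col == "-")) return(" ")
    u <- unique(col)
    if (length(u) == 1L) return("*")
    in_group <- function(groups) any(vapply(groups, function(g)
      all(u %in% strsplit(g, "")[[1]]), logical(1)))
    if (in_group(STRONG_GROUPS)) return(":")
    if (in_group(WEAK_GROUPS)) return(".")
    " "
  })
}

# column index of each ungapped position of one aligned sequence
ungapped_to_columns <- function(aligned_seq) {
  which(strsplit(aligned_seq, "")[[1]] != "-")
}

#' Map epitope residues onto alignment columns
#'
#' Maps each epitope residue (numbered on the ungapped reference
#' sequence) to its alignment column and reports, per residue, the
#' residue shown by every sequence in that column, the Clustal
#' conservation symbol, and the fraction of sequences identical to the
#' reference there — the quantitative basis for arguing that an antibody
#' recognising those residues should cross-react within the family.
#'
#' @param epitope An [epitope_set()] (or integer vector), numbered on the
#'   ungapped reference.
#' @param reference_id Sequence id of the reference in the alignment.
#' @param aln A `multiple_alignment`.
#' @return Tibble `residue`, `column`, `ref_aa`, `symbol`,
#'   `per_sequence_residues` (concatenated column characters in sequence
#'   order), `identical_fraction`.
#' @export
map_epitope_columns <- function(epitope, reference_id, aln) {
  residues <- if (inherits(epitope, "epitope_set")) epitope$residues
              else sort(unique(as.integer(epitope)))
  if (!reference_id %in% aln$id)
    abort(sprintf("reference id '%s' not in alignment", reference_id))
  ref <- aln$seq[aln$id == reference_id]
  cols <- ungapped_to_columns(ref)
  if (any(residues > length(cols)))
    abort(sprintf("epitope residue(s) beyond ungapped reference length %d: %s",
                  length(cols),
                  paste(residues[residues > length(cols)], collapse = ", ")))
  m <- aln_matrix(aln)
  sym <- conservation_symbols(aln)
  purrr::map(residues, function(r) {
    col <- cols[r]
    chars <- m[, col]
    ref_aa <- chars[aln$id == reference_id]
    tibble(residue = r, column = col, ref_aa = unname(ref_aa),
           symbol = sym[col],
           per_sequence_residues = paste(chars, collapse = ""),
           identical_fraction = mean(chars == ref_aa))
  }) |>
    purrr::list_rbind()
}

#' Published IgE-epitope intervals for beta-parvalbumins
#'
#' Inclusive residue intervals (Gad m 1 numbering) of IgE-binding regions
#' reported for related parvalbumin allergens: the AB/CD inter-motif axis
#' peptide 28-45 (Gad c 1, Sal s 1), the C-terminal peptide 95-109
#' (Gad m 1), the region around residue 80 (Cyp c 1), and the broader
#' 30-40 and 50-60 windows. Users can supply their own table in the same
#' shape.
#'
#' @return Tibble `name`, `start`, `end`, `source`.
#' @export
literature_epitopes <- function() {
  tibble(
    name   = c("ab_cd_axis_28_45", "c_terminus_95_109", "around_80_75_85",
               "window_30_40", "window_50_60"),
    start  = c(28L, 95L, 75L, 30L, 50L),
    end    = c(45L, 109L, 85L, 40L, 60L),
    source = c("Gad c 1 / Sal s 1 peptide mapping",
               "Gad m 1 overlapping peptides",
               "Cyp c 1 mapping", "multi-allergen IgE window",
               "Gad m 1 / Gad c 1 IgE window")
  )
}

#' Overlap of a mapped epitope with literature intervals
#'
#' @param epitope An [epitope_set()] or integer vector of residues.
#' @param literature Tibble of inclusive intervals with columns `name`,
#'   `start`, `end` (and optionally `source`), on the same reference
#'   numbering; default [literature_epitopes()].
#' @return Tibble `name`, `start`, `end`, `interval_size`, `overlap`
#'   (residues of the epitope inside the interval) and `jaccard`
#'   (epitope vs the expanded interval set). Empty `literature` gives an
#'   empty report.
#' @export
epitope_overlap_report <- function(epitope, literature = literature_epitopes()) {
  residues <- if (inherits(epitope, "epitope_set")) epitope$residues
              else sort(unique(as.integer(epitope)))
  literature <- as_tibble(literature)
  if (nrow(literature) == 0L)
    return(tibble(name = character(), start = integer(), end = integer(),
                  interval_size = integer(), overlap = integer(),
                  jaccard = double()))
  if (any(literature$start > literature$end))
    abort("literature intervals must satisfy start <= end")
  literature |>
    dplyr::mutate(
      interval_size = .data$end - .data$start + 1L,
      overlap = purrr::map2_int(.data$start, .data$end, function(s, e)
        sum(residues >= s & residues <= e)),
      jaccard = purrr::map2_dbl(.data$start, .data$end, function(s, e)
        epitope_jaccard(residues, seq.int(s, e)))
    ) |>
    dplyr::select("name", "start", "end", "interval_size", "overlap", "jaccard")
}
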