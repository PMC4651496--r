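#' Create an epitope set
#'
#' An epitope set is a named collection of antigen residue numbers together
#' with a provenance tag recording how it was derived: from chemical shift
#' perturbation mapping (`"csp"`), from a docking pose ensemble
#' (`"docking"`), or from published epitope intervals (`"literature"`).
#'
#' @param residues Integer vector of 1-based residue numbers (non-empty,
#'   duplicates removed, returned sorted).
#' @param name Label for the set.
#' @param provenance One of `"csp"`, `"docking"`, `"literature"`.
#' @param seq_length Optional sequence length; when given, residues must lie
#'   in `[1, seq_length]`.
#' @return An object of class `epitope_set`.
#' @examples
#' epitope_set(c(7, 8, 11, 12, 15, 29:33, 36, 108), "scFv epitope", "csp")
#' @export
epitope_set <- function(residues, name = "epitope",
                        provenance = c("csp", "docking", "literature"),
                        seq_length = NULL) {
  provenance <- match.arg(provenance)
  residues <- as.integer(residues)
  if (length(residues) == 0L || anyNA(residues))
    abort("`residues` must be a non-empty integer vector without NA")
  if (any(residues < 1L))
    abort("residue numbers are 1-based and must be >= 1")
  if (!is.null(seq_length) && any(residues > seq_length))
    abort(sprintf("residues beyond sequence length %d: %s", seq_length,
                  paste(residues[residues > seq_length], collapse = ", ")))
  structure(
    list(name = name, provenance = provenance,
         residues = sort(unique(residues))),
    class = "epitope_set"
  )
}

#' @export
print.epitope_set <- function(x, ...) {
  cat(sprintf("<epitope_set> %s (%s): %d residues\n", x$name, x$provenance,
              length(x$residues)))
  cat(" ", paste(x$residues, collapse = " "), "\n")
  invisible(x)
}

#' @export
length.epitope_set <- function(x) length(x$residues)

#' Jaccard index between two epitope sets
#'
#' @param a,b `epitope_set` objects (or bare integer vectors of residues).
#' @return A number in `[0, 1]`; 0 for two empty sets by convention.
#' @export
epitope_jaccard <- function(a, b) {
  ra <- if (inherits(a, "epitope_set")) a$residues else as.integer(a)
  rb <- if (inherits(b, "epitope_set")) b$residues else as.integer(b)
  u <- length(union(ra, rb))
  if (u == 0L) return(0)
  length(intersect(ra, rb)) / u
}

#' Define a named residue-interval scheme
#'
#' A region scheme partitions (part of) the antigen sequence into named,
#' non-overlapping, inclusive residue intervals used to summarise where
#' mapped residues fall (N-terminus, the axis joining the AB and CD
#' motifs, the CD calcium-binding site, the region around residue 80, and
#' the C-terminus for a parvalbumin-like antigen).
#'
#' @param region Character vector of region names.
#' @param start,end Integer vectors of inclusive interval bounds.
#' @param seq_length Optional sequence length to validate against.
#' @return A tibble with columns `region`, `start`, `end`.
#' @export
region_scheme <- function(region, start, end, seq_length = NULL) {
  if (length(region) != length(start) || length(start) != length(end))
    abort("`region`, `start` and `end` must have equal length")
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < start))
    abort("intervals must satisfy 1 <= start <= end")
  if (!is.null(seq_length) && any(end > seq_length))
    abort(sprintf("interval end beyond sequence length %d", seq_length))
  if (anyDuplicated(region)) abort("region names must be unique")
  sch <- tibble(region = as.character(region), start = start, end = end)
  sch <- dplyr::arrange(sch, start)
  if (nrow(sch) > 1L && any(sch$start[-1] <= sch$end[-nrow(sch)]))
    abort("region intervals must not overlap")
  sch
}

#' Default parvalbumin region scheme
#'
#' Intervals chosen to reflect the sequence regions conventionally
#' discussed for beta-parvalbumin allergens (Gad m 1 numbering):
#' the N-terminus, the AB/CD inter-motif axis, the CD calcium-binding
#' site, the region around residue 80 and the C-terminus.
#'
#' @return A region scheme tibble (see [region_scheme()]).
#' @export
default_region_scheme <- function() {
  region_scheme(
    region = c("n_terminus", "ab_cd_axis", "cd_site", "around_80", "c_terminus"),
    start  = c(1L, 28L, 51L, 75L, 95L),
    end    = c(15L, 45L, 62L, 85L, 109L)
  )
}
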