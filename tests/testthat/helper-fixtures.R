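# fixtures and independent oracles used across the suite

make_shift_tbl <- function(residue, dH, dN, aa = "A", label = "state") {
  shift_table(data.frame(residue = residue, aa = aa, dH = dH, dN = dN), label)
}

write_tsv_text <- function(text, path = tempfile(fileext = ".tsv")) {
  writeLines(text, path)
  path
}

# random two-chain pose: antigen chain A with n_ag residues x 3 heavy atoms,
# antibody chain B with n_ab residues x 3 heavy atoms, coords in a box
random_pose <- function(n_ag = 30, n_ab = 8, box = 25, with_h = FALSE) {
  mk <- function(chain, n, x0) {
    k <- 3L
    tibble::tibble(
      chain = chain, resno = rep(seq_len(n), each = k), resid = "ALA",
      elety = rep(c("N", "CA", "CB"), n), elesy = rep(c("N", "C", "C"), n),
      x = runif(n * k, 0, box) + x0, y = runif(n * k, 0, box),
      z = runif(n * k, 0, box))
  }
  atoms <- dplyr::bind_rows(mk("A", n_ag, 0), mk("B", n_ab, 10))
  if (with_h) {
    h <- atoms[atoms$chain == "A", ][1:5, ]
    h$elety <- "H"; h$elesy <- "H"
    # hydrogens planted right next to chain B so counting them would show
    h$x <- mean(atoms$x[atoms$chain == "B"])
    h$y <- mean(atoms$y[atoms$chain == "B"])
    h$z <- mean(atoms$z[atoms$chain == "B"])
    atoms <- dplyr::bind_rows(atoms, h)
  }
  structure_model(atoms)
}

# plain O(N*M) double-loop distance scan, no matrix algebra: the
# independent oracle for contact_residues
brute_force_contacts <- function(pose, cdr, antigen_chain = "A",
                                 antibody_chain = "B", cutoff = 5) {
  s <- tibble::as_tibble(pose)
  ag <- s[s$chain == antigen_chain & s$heavy, ]
  ab <- s[s$chain == antibody_chain & s$heavy & s$resno %in% cdr, ]
  out <- integer(0)
  for (r in unique(ag$resno)) {
    ra <- ag[ag$resno == r, ]
    hit <- FALSE
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(ab))) {
        d <- sqrt((ra$x[i] - ab$x[j])^2 + (ra$y[i] - ab$y[j])^2 +
                    (ra$z[i] - ab$z[j])^2)
        if (d <= cutoff) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) out <- c(out, r)
  }
  sort(out)
}

# grid-search oracle for the mono-exponential rate: for each candidate R
# the optimal I0 is linear; returns the R minimizing the residual sum
grid_search_rate <- function(delay, intensity, r_max = 20, step = 1e-3) {
  grid <- seq(step, r_max, by = step)
  sse <- vapply(grid, function(R) {
    e <- exp(-R * delay)
    I0 <- sum(intensity * e) / sum(e * e)
    sum((intensity - I0 * e)^2)
  }, numeric(1))
  grid[which.min(sse)]
}

# reference Clustal implementation: mafft --clustalout on (already aligned,
# gap-free, low-divergence) sequences; returns list(seqs, symbols) or NULL
# when the output cannot be compared column-to-column
mafft_clustal_symbols <- function(ids, seqs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(paste0(">", ids, "\n", seqs), fa)
  out <- suppressWarnings(
    system2("mafft", c("--retree", "1", "--clustalout", fa),
            stdout = TRUE, stderr = FALSE))
  if (!is.character(out) || length(out) == 0) return(NULL)
  body <- out[-1]
  aln <- setNames(rep("", length(ids)), ids)
  cons <- ""
  i <- 1
  while (i <= length(body)) {
    if (!nzchar(trimws(body[i]))) { i <- i + 1; next }
    # a block: one line per sequence, then the conservation line
    start <- NULL
    for (id in ids) {
      m <- regmatches(body[i], regexec("^(\\S+\\s+)(\\S+)\\s*$", body[i]))[[1]]
      if (length(m) == 0 || m[2 + 1] == "") return(NULL)
      if (is.null(start)) start <- nchar(m[2]) + 1
      aln[trimws(m[2])] <- paste0(aln[trimws(m[2])], m[3])
      i <- i + 1
    }
    chunk_len <- nchar(aln[[1]]) - nchar(cons)
    cons_line <- if (i <= length(body) && !grepl("^\\S", body[i])) body[i] else ""
    cons_chunk <- substr(paste0(cons_line, strrep(" ", start + chunk_len)),
                         start, start + chunk_len - 1)
    cons <- paste0(cons, cons_chunk)
    if (nzchar(cons_line)) i <- i + 1
  }
  if (!all(ids %in% names(aln))) return(NULL)
  list(seqs = aln[ids], symbols = strsplit(cons, "")[[1]])
}

# low-divergence gap-free toy alignment for the reference comparison
random_toy_alignment <- function(n_seq = 4, len = 60, rate = 0.15) {
  ref <- sample(epimapr:::AA1, len, replace = TRUE)
  seqs <- vapply(seq_len(n_seq), function(i) {
    s <- ref
    if (i > 1) {
      mut <- runif(len) < rate
      s[mut] <- vapply(s[mut], function(a)
        sample(setdiff(epimapr:::AA1, a), 1), character(1))
    }
    paste(s, collapse = "")
  }, character(1))
  tibble::tibble(id = sprintf("s%02d", seq_len(n_seq)), seq = seqs)
}
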