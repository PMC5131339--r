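# In-code fixtures shared across the suite.

# minimal 3-residue single-chain PDB: Gly1-Pro2-Cys3 on chain A
gpc_pdb <- function(with_water = FALSE) {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  PRO A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  CYS A   3       7.600   0.000   0.000  1.00  0.00           C")
  if (with_water) {
    lines <- c(lines,
      "HETATM    4  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O")
  }
  paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
}

# a propensity matrix built directly from per-cell values (bypasses the
# ddg transform, for exact-value tests)
matrix_from_u <- function(u_by_row, wt = NULL, chain = "A") {
  n <- length(u_by_row)
  wt <- wt %||% rep("A", n)
  rows <- lapply(seq_len(n), function(i) {
    u <- u_by_row[[i]]
    stopifnot(length(u) == 20)
    wt_i <- wt[i]
    tibble::tibble(chain = chain, position = i, wt = wt_i,
                   mut = amino_acids(),
                   is_identity = amino_acids() == wt_i,
                   ddg = NA_real_, u = u)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "rt") <- default_rt()
  attr(out, "source") <- "test"
  class(out) <- c("ums_matrix", class(out))
  out
}

# one matrix row as a vector of 20 u-values: identity cell at u0, the 19
# substitutions at usub
row_u <- function(wt, usub, u0 = 0.5) {
  u <- rep(usub, 20)
  u[amino_acids() == wt] <- u0
  u
}

`%||%` <- rlang::`%||%`
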