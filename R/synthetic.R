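# Seeded synthetic fixtures: toy structures, planted-ddG tables and
# noisy experimental/computed propensity pairs.

#' Generate a toy helical structure as PDB text
#'
#' A single chain A with an ideal alpha-helix alpha-carbon trace (radius
#' 2.3 Angstrom, rise 1.5 Angstrom per residue, 100 degree turn) and
#' residue types drawn uniformly from the 20 standard amino acids under
#' the given seed. Output is valid PDB ATOM text, parseable by
#' [read_structure()]. Deterministic: the same `n_residues` and `seed`
#' always give byte-identical text.
#'
#' @param n_residues Number of residues (>= 1).
#' @param seed Integer seed for the residue-type draw.
#' @return Character scalar of PDB text.
#' @export
#' @examples
#' cat(make_toy_structure(3, seed = 1))
make_toy_structure <- function(n_residues, seed = 1) {
  if (!is.numeric(n_residues) || length(n_residues) != 1 || n_residues < 1) {
    abort("`n_residues` must be a single integer >= 1.")
  }
  n <- as.integer(n_residues)
  set.seed(seed)
  aa1 <- sample(amino_acids(), n, replace = TRUE)
  aa3 <- unname(.aa_one_to_three[aa1])

  radius <- 2.3
  rise <- 1.5
  turn <- 100 * pi / 180
  i <- seq_len(n)
  x <- radius * cos((i - 1) * turn)
  y <- radius * sin((i - 1) * turn)
  z <- (i - 1) * rise

  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    i, aa3, i, x, y, z, 1, 0)
  paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
}

#' Consecutive alpha-carbon spacing of the toy helix
#'
#' Closed-form chord length between consecutive CA atoms of the generator's
#' helix: \eqn{\sqrt{2 r^2 (1 - \cos\theta) + \Delta z^2}} with r = 2.3,
#' turn 100 degrees and rise 1.5 Angstrom.
#'
#' @return Chord length in Angstrom (about 3.83).
#' @export
toy_helix_ca_spacing <- function() {
  radius <- 2.3
  rise <- 1.5
  turn <- 100 * pi / 180
  sqrt(2 * radius^2 * (1 - cos(turn)) + rise^2)
}

#' Synthetic ddG table with planted critical residues
#'
#' Covers all 20 x N mutations of a structure. Identity mutations get
#' \eqn{\Delta\Delta G} exactly 0; all 19 substitutions at planted
#' positions get `ddg_high` (default 4 kcal/mol, far above the
#' saturation point RT ln(9) of the 0.9 propensity threshold); all other
#' substitutions draw from a clipped Normal background. With the default
#' background clip at 1.2 kcal/mol (below RT ln(9) = 1.302 at the default
#' RT), planted and background positions are analytically separable:
#' planted foldability is 19 x u(ddg_high) > 17.1 while background
#' foldability is exactly 0.
#'
#' @param structure An `ums_structure`.
#' @param planted Integer positions (in any chain) whose substitutions all
#'   get `ddg_high`.
#' @param ddg_high Planted ddG (kcal/mol); default 4.
#' @param background_sd SD of the Normal(0, sd) background; default 0.5.
#' @param background_clip Background values clipped to +/- this bound
#'   (kcal/mol); default 1.2.
#' @param seed Integer seed.
#' @return List with `ddg` (tibble: `chain`, `position`, `wt`, `mut`,
#'   `ddg`, `source`) and `truth` (the planted positions).
#' @export
#' @examples
#' s <- read_structure(make_toy_structure(10, seed = 1))
#' syn <- make_synthetic_ddg(s, planted = c(2, 7), seed = 7)
make_synthetic_ddg <- function(structure, planted = integer(),
                               ddg_high = 4.0, background_sd = 0.5,
                               background_clip = 1.2, seed = 1) {
  validate_ums_structure(structure)
  planted <- as.integer(planted)
  if (!all(planted %in% structure$position)) {
    abort(sprintf("Planted position(s) absent from structure: %s",
                  paste(setdiff(planted, structure$position), collapse = ", ")))
  }
  specs <- enumerate_mutations(structure)
  set.seed(seed)
  bg <- rnorm(nrow(specs), mean = 0, sd = background_sd)
  bg <- pmin(pmax(bg, -background_clip), background_clip)
  ddg <- ifelse(specs$position %in% planted, ddg_high, bg)
  ddg[specs$is_identity] <- 0
  tbl <- specs |>
    dplyr::mutate(ddg = ddg, source = "synthetic") |>
    dplyr::select("chain", "position", "wt", "mut", "ddg", "source")
  list(ddg = tbl, truth = sort(unique(planted)))
}

#' Synthetic experimental/computed propensity pairs
#'
#' Draws experimental propensities uniformly on \[0, 1\] and perturbs them
#' with additive Uniform(-epsilon, epsilon) noise, clipped back into
#' \[0, 1\], to emulate the discrepancy between measured and computed
#' unfolding values. By construction `fit_score(pairs) <= epsilon`, with
#' expectation about epsilon/2 away from the clipping edges.
#'
#' @param n_pairs Number of pairs (for a full scan of an N-residue
#'   protein, use 20 x N).
#' @param epsilon Noise half-width in \[0, 0.5).
#' @param seed Integer seed.
#' @return Tibble of class `ums_pairs` with `id`, `u_exp`, `u_calc`.
#' @export
#' @examples
#' make_validation_pairs(10, epsilon = 0.05, seed = 1)
make_validation_pairs <- function(n_pairs, epsilon = 0.05, seed = 1) {
  stopifnot(is.numeric(n_pairs), length(n_pairs) == 1, n_pairs >= 1)
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon < 0 || epsilon >= 0.5) {
    abort("`epsilon` must lie in [0, 0.5).")
  }
  n <- as.integer(n_pairs)
  set.seed(seed)
  u_exp <- runif(n)
  noise <- if (epsilon == 0) rep(0, n) else runif(n, -epsilon, epsilon)
  u_calc <- pmin(pmax(u_exp + noise, 0), 1)
  out <- tibble::tibble(id = seq_len(n), u_exp = u_exp, u_calc = u_calc)
  attr(out, "epsilon") <- epsilon
  attr(out, "seed") <- seed
  class(out) <- c("ums_pairs", class(out))
  out
}
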