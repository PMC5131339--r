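# The ddG -> unfolding-propensity transform and effect classification.

#' Default thermal energy scale of the unfolding curve
#'
#' RT at 298.15 K in kcal/mol. The single tunable of the two-state
#' transform: it sets how steeply the unfolding curve rises around the
#' folding-unfolding equilibrium.
#'
#' @return `0.5926` (kcal/mol).
#' @export
default_rt <- function() 0.5926

#' Convert free-energy changes to unfolding propensities
#'
#' Places each mutation on the two-state sigmoidal unfolding curve:
#' \deqn{U = \frac{1}{1 + e^{-\Delta\Delta G / RT}}}
#' so that \eqn{U} is the implied fraction of unfolded molecules. The
#' propensity ranges 0-1: values below 0.5 are stabilizing, above 0.5
#' destabilizing, and exactly 0.5 is the folding-unfolding equilibrium
#' (no change in stability, as for an identity mutation with
#' \eqn{\Delta\Delta G = 0}).
#'
#' @param ddg Numeric vector of free-energy changes (kcal/mol),
#'   destabilizing-positive.
#' @param rt Thermal energy scale RT (kcal/mol); must be positive.
#' @return Numeric vector of propensities in \[0, 1\].
#' @export
#' @examples
#' ddg_to_propensity(0)                   # 0.5, the equilibrium
#' ddg_to_propensity(c(-3, 0, 3))         # stabilizing .. destabilizing
ddg_to_propensity <- function(ddg, rt = default_rt()) {
  stopifnot(is.numeric(rt), length(rt) == 1, rt > 0)
  if (!is.numeric(ddg) || any(!is.finite(ddg))) {
    abort("`ddg` must be finite numeric (kcal/mol).")
  }
  stats::plogis(ddg / rt)
}

#' Invert the propensity transform
#'
#' @param u Propensities in (0, 1).
#' @param rt Thermal energy scale (kcal/mol).
#' @return \eqn{\Delta\Delta G} in kcal/mol.
#' @export
propensity_to_ddg <- function(u, rt = default_rt()) {
  stopifnot(is.numeric(rt), length(rt) == 1, rt > 0)
  if (any(!is.finite(u)) || any(u <= 0 | u >= 1)) {
    abort("`u` must lie strictly inside (0, 1) to invert the transform.")
  }
  stats::qlogis(u) * rt
}

#' Classify a propensity as stabilizing / equilibrium / destabilizing
#'
#' The ternary scheme bins propensities as stabilizing (0-0.4),
#' folding-unfolding equilibrium (0.4-0.6) and destabilizing (0.6-1.0);
#' the overlapping bin edges 0.4 and 0.6 are assigned to the equilibrium
#' bin. The binary scheme splits at 0.5, with exactly 0.5 still reported
#' as equilibrium.
#'
#' @param u Numeric propensities in \[0, 1\].
#' @param scheme `"ternary"` (default) or `"binary"`.
#' @return Factor with levels `stabilizing`, `equilibrium`, `destabilizing`.
#' @export
#' @examples
#' classify_effect(c(0.3, 0.5, 0.95))
classify_effect <- function(u, scheme = c("ternary", "binary")) {
  scheme <- rlang::arg_match(scheme)
  if (!is.numeric(u) || any(!is.finite(u)) || any(u < 0 | u > 1)) {
    abort("Propensities must be finite and in [0, 1].")
  }
  lev <- c("stabilizing", "equilibrium", "destabilizing")
  cls <- if (scheme == "ternary") {
    ifelse(u < 0.4, "stabilizing", ifelse(u > 0.6, "destabilizing", "equilibrium"))
  } else {
    ifelse(u < 0.5, "stabilizing", ifelse(u > 0.5, "destabilizing", "equilibrium"))
  }
  factor(cls, levels = lev)
}

#' Weights of the toy ddG estimator
#'
#' @param hydropathy kcal/mol per (contact x Kyte-Doolittle unit) for the
#'   burial-weighted hydrophobicity change.
#' @param volume kcal/mol per (contact x 100 cubic Angstrom) for the
#'   burial-weighted side-chain volume change.
#' @param glycine,proline,cysteine Fixed penalties (kcal/mol) for mutating
#'   these conformationally or covalently special residues away from
#'   wild type.
#' @return Named list of weights.
#' @export
toy_weights <- function(hydropathy = 0.08, volume = 0.4,
                        glycine = 2.0, proline = 2.5, cysteine = 3.0) {
  list(hydropathy = hydropathy, volume = volume,
       glycine = glycine, proline = proline, cysteine = cysteine)
}

#' Toy empirical ddG estimator
#'
#' A deterministic, clearly-labelled toy stand-in for a physics-based
#' energy function, so the scan runs end-to-end self-contained. For each
#' substitution it combines (i) burial (alpha-carbon contact count within
#' 10 Angstrom, excluding self) times the Kyte-Doolittle hydrophobicity
#' loss, (ii) burial times the absolute side-chain volume change, and
#' (iii) a fixed penalty for mutating glycine, proline or cysteine away
#' from wild type. Identity mutations score exactly 0 kcal/mol, so the
#' internal control sits at the folding-unfolding equilibrium by
#' construction. Scores are for plumbing and testing, not for real
#' stability prediction.
#'
#' @param structure An `ums_structure`.
#' @param specs Mutation specs; defaults to the full saturation scan.
#' @param weights Term weights from [toy_weights()].
#' @return `specs` with columns `burial` (contact count) and `ddg`
#'   (kcal/mol, destabilizing-positive) added, plus `source = "toy"`.
#' @export
#' @examples
#' s <- read_structure(make_toy_structure(6, seed = 1))
#' estimate_ddg_toy(s)
estimate_ddg_toy <- function(structure, specs = enumerate_mutations(structure),
                             weights = toy_weights()) {
  validate_ums_structure(structure)
  key <- paste(structure$chain, structure$position)
  spec_key <- paste(specs$chain, specs$position)
  if (!all(spec_key %in% key)) {
    abort(sprintf("Mutation spec(s) at position(s) absent from structure: %s",
                  paste(unique(spec_key[!spec_key %in% key]), collapse = ", ")))
  }
  .check_aa(specs$wt, "wild-type")
  .check_aa(specs$mut, "mutant")

  co <- as.matrix(structure[, c("x", "y", "z")])
  d <- as.matrix(dist(co))
  burial <- rowSums(d <= 10) - 1L # exclude self
  burial <- setNames(burial, key)

  b <- unname(burial[spec_key])
  dh <- .aa_hydropathy[specs$wt] - .aa_hydropathy[specs$mut]
  dv <- abs(.aa_volume[specs$wt] - .aa_volume[specs$mut]) / 100
  penalty <- dplyr::case_when(
    specs$wt == specs$mut ~ 0,
    specs$wt == "G" ~ weights$glycine,
    specs$wt == "P" ~ weights$proline,
    specs$wt == "C" ~ weights$cysteine,
    .default = 0
  )
  ddg <- weights$hydropathy * b * unname(dh) +
    weights$volume * b * unname(dv) + penalty
  ddg[specs$wt == specs$mut] <- 0 # identity is exactly neutral

  dplyr::mutate(tibble::as_tibble(specs), burial = b, ddg = ddg,
                source = "toy")
}
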