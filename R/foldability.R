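# Per-residue foldability, critical residues, and the internal control.

#' Per-residue foldability profile
#'
#' For each residue position, foldability is the sum of unfolding
#' propensities over the 19 non-identity substitutions whose propensity
#' exceeds the saturation threshold (default 0.9, the region of the
#' unfolding curve where a mutation can be considered to cause unfolding
#' outright). It therefore ranges 0-19: 0 when no substitution is severe,
#' 19 when every substitution unfolds the protein completely. Unlike an
#' average, the gated sum tallies severe mutations without being diluted
#' by benign ones. Missing cells contribute nothing and are counted in
#' `n_missing`; rows with more than two missing substitutions are marked
#' not `comparable`, since their attainable maximum falls materially below
#' the 0-19 scale.
#'
#' @param matrix An `ums_matrix` from [build_propensity_matrix()].
#' @param threshold Saturation threshold in (0, 1); default 0.9.
#' @return Tibble of class `ums_foldability` with columns `chain`,
#'   `position`, `wt`, `foldability`, `n_severe`, `n_missing`,
#'   `comparable`; attribute `threshold`.
#' @export
#' @examples
#' s <- read_structure(make_toy_structure(5, seed = 1))
#' m <- build_propensity_matrix(estimate_ddg_toy(s), s)
#' foldability_profile(m)
foldability_profile <- function(matrix, threshold = 0.9) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single value in (0, 1).")
  }
  out <- tibble::as_tibble(matrix) |>
    dplyr::filter(!.data$is_identity) |>
    dplyr::summarise(
      foldability = sum(.data$u[.data$u > threshold], na.rm = TRUE),
      n_severe = sum(.data$u > threshold, na.rm = TRUE),
      n_missing = sum(is.na(.data$u)),
      .by = c("chain", "position", "wt")) |>
    dplyr::mutate(comparable = .data$n_missing <= 2)
  attr(out, "threshold") <- threshold
  class(out) <- c("ums_foldability", class(out))
  out
}

#' Critical residues of a foldability profile
#'
#' Residues whose foldability strictly exceeds the cutoff — by default
#' 17.1 = 19 mutations x the 0.9 saturation threshold, i.e. positions
#' where essentially every substitution unfolds the protein. Rows with
#' more than two missing substitution cells are excluded (their
#' foldability is not comparable to the 0-19 scale) and reported via a
#' warning.
#'
#' @param profile An `ums_foldability` tibble.
#' @param cutoff Critical-residue cutoff; default 17.1.
#' @return Tibble with `chain`, `position`, `wt`, `foldability`, in
#'   structure order.
#' @export
critical_residues <- function(profile, cutoff = 17.1) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, is.finite(cutoff))
  excluded <- dplyr::filter(profile, !.data$comparable)
  if (nrow(excluded) > 0) {
    warn(sprintf(
      "%d residue(s) excluded from critical calls (>2 missing cells): %s",
      nrow(excluded),
      paste(sprintf("%s:%d", excluded$chain, excluded$position), collapse = ", ")))
  }
  profile |>
    dplyr::filter(.data$comparable, .data$foldability > cutoff) |>
    dplyr::select("chain", "position", "wt", "foldability") |>
    tibble::as_tibble()
}

#' Internal control: identity mutations as a stereochemistry check
#'
#' Every residue mutated to itself should sit exactly at the
#' folding-unfolding equilibrium (propensity 0.5); systematic deviation
#' signals poor stereochemistry of the input model (strained rotamers make
#' the "wild-type" structure disagree with its own sequence). The control
#' reports the mean, SD, t-based 95% confidence interval and the p-value
#' of a one-sample t-test against 0.5 over all identity-cell propensities.
#' The verdict is driven by the confidence interval — "pass" iff the CI
#' half-width is at most `tolerance` and the CI contains 0.5 — because a
#' tiny p-value alone cannot certify closeness to 0.5.
#'
#' @param matrix An `ums_matrix` with at least two identity cells.
#' @param tolerance Maximum admissible CI half-width; default 0.05.
#' @param conf_level Confidence level of the interval; default 0.95.
#' @return Object of class `ums_control`: a list with `n`, `mean`, `sd`,
#'   `conf_low`, `conf_high`, `p_value`, `tolerance`, `verdict`.
#' @export
#' @examples
#' s <- read_structure(make_toy_structure(10, seed = 1))
#' m <- build_propensity_matrix(estimate_ddg_toy(s), s)
#' internal_control(m)
internal_control <- function(matrix, tolerance = 0.05, conf_level = 0.95) {
  u <- tibble::as_tibble(matrix) |>
    dplyr::filter(.data$is_identity, !is.na(.data$u)) |>
    dplyr::pull("u")
  if (length(u) < 2) {
    abort("Internal control needs at least 2 identity cells (SD undefined below that).")
  }
  m <- mean(u)
  s <- sd(u)
  n <- length(u)
  if (s == 0) {
    ci <- c(m, m)
    p <- if (m == 0.5) 1 else 0
  } else {
    tt <- stats::t.test(u, mu = 0.5, conf.level = conf_level)
    ci <- unname(tt$conf.int)
    p <- unname(tt$p.value)
  }
  half_width <- (ci[2] - ci[1]) / 2
  verdict <- if (half_width <= tolerance && ci[1] <= 0.5 && 0.5 <= ci[2]) {
    "pass"
  } else {
    "fail"
  }
  structure(
    list(n = n, mean = m, sd = s, conf_low = ci[1], conf_high = ci[2],
         conf_level = conf_level, p_value = p, tolerance = tolerance,
         verdict = verdict),
    class = "ums_control")
}

#' @export
print.ums_control <- function(x, ...) {
  cat("Internal control (identity mutations)\n")
  cat(sprintf("  n = %d, mean = %.4f, sd = %.4f\n", x$n, x$mean, x$sd))
  cat(sprintf("  %d%% CI [%.4f, %.4f], t-test vs 0.5: p = %.3g\n",
              round(100 * x$conf_level), x$conf_low, x$conf_high, x$p_value))
  cat(sprintf("  verdict: %s (CI half-width tolerance %.3f)\n",
              x$verdict, x$tolerance))
  invisible(x)
}

#' @method tidy ums_control
#' @export
tidy.ums_control <- function(x, ...) {
  tibble::tibble(n = x$n, mean = x$mean, sd = x$sd,
                 conf_low = x$conf_low, conf_high = x$conf_high,
                 p_value = x$p_value, verdict = x$verdict)
}

#' @method glance ums_control
#' @export
glance.ums_control <- function(x, ...) tidy(x)

#' @method tidy ums_foldability
#' @export
tidy.ums_foldability <- function(x, ...) tibble::as_tibble(x)
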