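# Experimental-vs-computed validation: pairing, match matrices,
# percent matching and the fit score.

#' Pair experimental and computed unfolding propensities
#'
#' Transforms experimental \eqn{\Delta\Delta G} values (already normalised
#' to destabilizing-positive at read time) to propensities on the same
#' unfolding curve as the scan, and joins them with the computed matrix
#' cells by mutation key (chain, position, mut). Records present on only
#' one side are not dropped silently: they are attached as the
#' `unmatched_exp` / `unmatched_calc` attributes.
#'
#' @param exp_table Experimental ddG tibble (e.g. from
#'   [read_experimental_table()]) with `chain`, `position`, `mut`, `ddg`.
#' @param matrix The computed `ums_matrix`.
#' @param rt Thermal energy scale used to transform the experimental
#'   values; defaults to the matrix's own RT.
#' @return Tibble of class `ums_pairs` with `chain`, `position`, `wt`,
#'   `mut`, `u_exp`, `u_calc`.
#' @export
pair_propensities <- function(exp_table, matrix, rt = NULL) {
  rt <- rt %||% attr(matrix, "rt") %||% default_rt()
  exp_table <- tibble::as_tibble(exp_table) |>
    dplyr::mutate(u_exp = ddg_to_propensity(.data$ddg, rt))
  calc <- tibble::as_tibble(matrix) |>
    dplyr::filter(!is.na(.data$u)) |>
    dplyr::select("chain", "position", "wt", "mut", u_calc = "u")
  pairs <- dplyr::inner_join(
    dplyr::select(exp_table, "chain", "position", "mut", "u_exp"),
    calc, by = c("chain", "position", "mut")) |>
    dplyr::select("chain", "position", "wt", "mut", "u_exp", "u_calc")
  if (nrow(pairs) == 0) {
    abort("No overlapping mutation keys between experimental table and matrix.")
  }
  key <- function(d) paste(d$chain, d$position, d$mut)
  attr(pairs, "unmatched_exp") <-
    dplyr::filter(exp_table, !key(exp_table) %in% key(pairs))
  attr(pairs, "unmatched_calc") <-
    dplyr::filter(calc, !key(calc) %in% key(pairs))
  class(pairs) <- c("ums_pairs", class(pairs))
  pairs
}

#' Cross-tabulate experimental vs computed effect classes
#'
#' Classifies both propensities of each pair with the ternary scheme
#' (stabilizing 0-0.4, equilibrium 0.4-0.6, destabilizing 0.6-1) and
#' cross-tabulates: rows are the experimental class, columns the computed
#' class, so the diagonal counts matches.
#'
#' @param pairs Tibble with `u_exp` and `u_calc` columns.
#' @return 3x3 integer matrix of class `ums_match_matrix`.
#' @export
#' @examples
#' p <- make_validation_pairs(5, epsilon = 0.02, seed = 1)
#' match_matrix(p)
match_matrix <- function(pairs) {
  if (nrow(pairs) == 0) abort("No validation pairs.")
  mm <- table(experimental = classify_effect(pairs$u_exp),
              computed = classify_effect(pairs$u_calc))
  mm <- unclass(mm)
  storage.mode(mm) <- "integer"
  class(mm) <- c("ums_match_matrix", class(mm))
  mm
}

#' Percent of pairs whose effect classes match
#'
#' @param mm A match matrix from [match_matrix()].
#' @return Percentage in \[0, 100\]: `100 * trace / total`.
#' @export
percent_matching <- function(mm) {
  total <- sum(mm)
  if (total == 0) abort("Empty match matrix.")
  100 * sum(diag(mm)) / total
}

#' Fit score between experimental and computed propensities
#'
#' The mean absolute difference
#' \deqn{\frac{1}{N}\sum_i |U_{exp,i} - U_{calc,i}|}
#' over all paired mutations: 0 is a perfect fit, 1 the worst possible
#' given propensities live in \[0, 1\]. Kept as a single replaceable
#' function so an alternative discrepancy can be swapped in.
#'
#' @param pairs Tibble with `u_exp` and `u_calc`, or a numeric vector
#'   (then `u_calc` must be supplied).
#' @param u_calc Computed propensities when `pairs` is a numeric vector of
#'   experimental propensities.
#' @return Fit score in \[0, 1\].
#' @export
#' @examples
#' fit_score(c(0.2, 0.8), c(0.3, 0.6)) # 0.15
fit_score <- function(pairs, u_calc = NULL) {
  if (is.numeric(pairs)) {
    u_exp <- pairs
    stopifnot(is.numeric(u_calc), length(u_calc) == length(u_exp))
  } else {
    u_exp <- pairs$u_exp
    u_calc <- pairs$u_calc
  }
  if (length(u_exp) == 0) abort("No validation pairs.")
  if (any(u_exp < 0 | u_exp > 1 | u_calc < 0 | u_calc > 1)) {
    abort("Propensities must lie in [0, 1].")
  }
  mean(abs(u_exp - u_calc))
}

#' Per-protein validation report
#'
#' Runs the full comparison for each protein in an experimental table:
#' match matrix, percent matching/mismatching, fit score and mutation
#' count — the same summary layout as a stability-benchmark table.
#'
#' @param exp_table Experimental tibble from [read_experimental_table()]
#'   (with `protein_id`), or a plain ddG tibble treated as one protein.
#' @param matrix The computed `ums_matrix` (a single structure's scan) or
#'   a named list of matrices keyed by `protein_id`.
#' @param rt Optional RT override for the experimental transform.
#' @return Object of class `ums_validation`: tibble with one row per
#'   protein (`protein_id`, `fit_score`, `pct_matching`, `pct_mismatching`,
#'   `n_mutations`) and the match matrices in the `match_matrices`
#'   attribute.
#' @export
validate_unfolding <- function(exp_table, matrix, rt = NULL) {
  exp_table <- tibble::as_tibble(exp_table)
  if (!"protein_id" %in% names(exp_table)) exp_table$protein_id <- "protein"
  ids <- unique(exp_table$protein_id)
  get_matrix <- function(id) {
    if (inherits(matrix, "ums_matrix")) return(matrix)
    if (is.list(matrix) && id %in% names(matrix)) return(matrix[[id]])
    abort(sprintf("No propensity matrix supplied for protein '%s'.", id))
  }
  rows <- purrr::map(ids, function(id) {
    pairs <- pair_propensities(
      dplyr::filter(exp_table, .data$protein_id == id), get_matrix(id), rt = rt)
    mm <- match_matrix(pairs)
    pm <- percent_matching(mm)
    tibble::tibble(protein_id = id, fit_score = fit_score(pairs),
                   pct_matching = pm, pct_mismatching = 100 - pm,
                   n_mutations = nrow(pairs),
                   match_matrix = list(mm))
  })
  out <- dplyr::bind_rows(rows)
  report <- dplyr::select(out, -"match_matrix")
  attr(report, "match_matrices") <- setNames(out$match_matrix, ids)
  class(report) <- c("ums_validation", class(report))
  report
}

#' @export
print.ums_validation <- function(x, ...) {
  cat("Experimental-vs-computed unfolding validation\n")
  NextMethod()
}

#' @method tidy ums_validation
#' @export
tidy.ums_validation <- function(x, ...) {
  out <- x
  attr(out, "match_matrices") <- NULL
  class(out) <- setdiff(class(out), "ums_validation")
  tibble::as_tibble(out)
}

#' @method glance ums_validation
#' @export
glance.ums_validation <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_mutations = sum(x$n_mutations),
    mean_pct_matching = mean(x$pct_matching),
    sd_pct_matching = sd(x$pct_matching),
    mean_fit_score = mean(x$fit_score))
}

#' Write a validation report as TSV
#'
#' @param report An `ums_validation` report.
#' @param path Optional output file.
#' @return TSV text (invisibly when `path` is given).
#' @export
write_validation_report <- function(report, path = NULL) {
  text <- readr::format_tsv(tidy(report))
  if (!is.null(path)) {
    readr::write_tsv(tidy(report), path)
    return(invisible(text))
  }
  text
}
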