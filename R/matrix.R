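# The position x amino-acid propensity matrix.

new_ums_matrix <- function(df, rt, source = "unknown") {
  df <- tibble::as_tibble(df)
  attr(df, "rt") <- rt
  attr(df, "source") <- source
  class(df) <- c("ums_matrix", setdiff(class(df), "ums_matrix"))
  df
}

#' Assemble the propensity matrix for a scanned structure
#'
#' Joins a \eqn{\Delta\Delta G} table onto the full enumerated mutation
#' list of the structure and converts each record to an unfolding
#' propensity with [ddg_to_propensity()]. The result is a long tibble with
#' one row per (residue, mutant) cell — conceptually a positions x 20
#' matrix whose columns are the amino acids in alphabetical order. Cells
#' without a ddG record are kept as `NA` (rendered grey, excluded from
#' foldability), never imputed. A record whose wild-type residue disagrees
#' with the structure is a consistency error: it flags either a corrupted
#' table or a homology model whose sequence drifted from the intended one.
#'
#' @param ddg ddG tibble from [read_ddg_table()], [estimate_ddg_toy()] or
#'   [make_synthetic_ddg()].
#' @param structure The `ums_structure` that was scanned.
#' @param rt Thermal energy scale RT (kcal/mol).
#' @param on_missing `"na"` keeps uncovered cells as missing; `"error"`
#'   requires full 20 x N coverage.
#' @return Tibble of class `ums_matrix` with columns `chain`, `position`,
#'   `wt`, `mut`, `is_identity`, `ddg`, `u`; attributes `rt` and `source`.
#' @export
#' @examples
#' s <- read_structure(make_toy_structure(4, seed = 1))
#' m <- build_propensity_matrix(estimate_ddg_toy(s), s)
build_propensity_matrix <- function(ddg, structure, rt = default_rt(),
                                    on_missing = c("na", "error")) {
  on_missing <- rlang::arg_match(on_missing)
  validate_ums_structure(structure)
  specs <- enumerate_mutations(structure)

  ddg <- tibble::as_tibble(ddg)
  joined <- dplyr::left_join(
    specs,
    dplyr::select(ddg, "chain", "position", wt_ddg = "wt", "mut", "ddg"),
    by = c("chain", "position", "mut"))

  mismatch <- joined |>
    dplyr::filter(!is.na(.data$wt_ddg), .data$wt_ddg != .data$wt) |>
    dplyr::distinct(.data$chain, .data$position, .data$wt, .data$wt_ddg)
  if (nrow(mismatch) > 0) {
    abort(sprintf(
      "Wild-type mismatch between ddG table and structure at position(s): %s",
      paste(sprintf("%s:%d (structure %s, table %s)", mismatch$chain,
                    mismatch$position, mismatch$wt, mismatch$wt_ddg),
            collapse = "; ")))
  }
  if (on_missing == "error" && anyNA(joined$ddg)) {
    abort(sprintf("%d of %d cells have no ddG record.",
                  sum(is.na(joined$ddg)), nrow(joined)))
  }

  out <- joined |>
    dplyr::mutate(u = ifelse(is.na(.data$ddg), NA_real_,
                             ddg_to_propensity(dplyr::coalesce(.data$ddg, 0), rt))) |>
    dplyr::select("chain", "position", "wt", "mut", "is_identity", "ddg", "u")
  src <- if ("source" %in% names(ddg)) paste(unique(ddg$source), collapse = "+") else "unknown"
  new_ums_matrix(out, rt = rt, source = src)
}

#' @export
print.ums_matrix <- function(x, ...) {
  cat(sprintf(
    "# Unfolding propensity matrix: %d residue(s) x 20 amino acids (RT = %g kcal/mol, source: %s)\n",
    nrow(x) / 20L, attr(x, "rt"), attr(x, "source")))
  NextMethod()
}

#' Widen a propensity matrix to positions x amino acids
#'
#' @param matrix An `ums_matrix`.
#' @return Tibble with a `residue` label column (`chain:position:wt`) and
#'   one column per amino acid in alphabetical order.
#' @export
propensity_wide <- function(matrix) {
  tibble::as_tibble(matrix) |>
    dplyr::mutate(residue = sprintf("%s:%d:%s", .data$chain, .data$position,
                                    .data$wt)) |>
    dplyr::select("residue", "mut", "u") |>
    tidyr::pivot_wider(names_from = "mut", values_from = "u") |>
    dplyr::select("residue", dplyr::all_of(amino_acids()))
}

#' Serialise / read a propensity matrix as TSV
#'
#' The wide layout: a `residue` label column (`chain:position:wt`) followed
#' by the 20 amino-acid columns. Round-trip safe with
#' [read_propensity_matrix()].
#'
#' @param matrix An `ums_matrix`.
#' @param path Optional output file.
#' @return TSV text (invisibly when `path` is given).
#' @export
write_propensity_matrix <- function(matrix, path = NULL) {
  wide <- propensity_wide(matrix)
  text <- readr::format_tsv(wide)
  if (!is.null(path)) {
    readr::write_tsv(wide, path)
    return(invisible(text))
  }
  text
}

#' @rdname write_propensity_matrix
#' @param text TSV text or file path produced by [write_propensity_matrix()].
#' @param rt RT recorded on the rebuilt matrix.
#' @export
read_propensity_matrix <- function(text, rt = default_rt()) {
  text <- .slurp(text)
  wide <- readr::read_tsv(I(text), show_col_types = FALSE)
  if (!identical(setdiff(names(wide), "residue"), amino_acids())) {
    abort("Matrix TSV must have a 'residue' column plus the 20 amino-acid columns.")
  }
  parts <- strsplit(wide$residue, ":", fixed = TRUE)
  long <- wide |>
    dplyr::mutate(chain = vapply(parts, `[[`, "", 1),
                  position = as.integer(vapply(parts, `[[`, "", 2)),
                  wt = vapply(parts, `[[`, "", 3)) |>
    tidyr::pivot_longer(dplyr::all_of(amino_acids()), names_to = "mut",
                        values_to = "u") |>
    dplyr::mutate(is_identity = .data$wt == .data$mut, ddg = NA_real_) |>
    dplyr::select("chain", "position", "wt", "mut", "is_identity", "ddg", "u")
  new_ums_matrix(long, rt = rt, source = "tsv")
}
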