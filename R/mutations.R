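# Saturation-mutagenesis enumeration and the mutation/ddG table formats.

#' Enumerate the full saturation-mutagenesis list
#'
#' Generates 20 variants per residue: the 19 possible missense substitutions
#' plus one identity mutation (residue mutated to itself), yielding
#' 20 x (number of residues) specs. Residues follow structure order; mutant
#' residues follow alphabetical one-letter order.
#'
#' @param structure An `ums_structure` tibble from [read_structure()].
#' @return A tibble with columns `chain`, `position`, `wt`, `mut`,
#'   `is_identity`.
#' @export
#' @examples
#' s <- read_structure(make_toy_structure(3, seed = 1))
#' enumerate_mutations(s) # 60 rows
enumerate_mutations <- function(structure) {
  validate_ums_structure(structure)
  tibble::as_tibble(structure) |>
    dplyr::select("chain", "position", "wt") |>
    tidyr::crossing(mut = amino_acids()) |>
    dplyr::arrange(factor(.data$chain, levels = unique(structure$chain)),
                   .data$position, .data$mut) |>
    dplyr::mutate(is_identity = .data$wt == .data$mut) |>
    dplyr::select("chain", "position", "wt", "mut", "is_identity")
}

#' Write a mutation list
#'
#' Serialises mutation specs either in the FoldX `individual_list` dialect
#' (one `<wt><chain><position><mut>;` token per line, e.g. `PA23H;`) or as a
#' TSV with columns `chain`, `position`, `wt`, `mut`.
#'
#' @param specs Tibble of mutation specs ([enumerate_mutations()] output or
#'   compatible).
#' @param dialect `"foldx_individual"` or `"tsv"`.
#' @param path Optional file to write; the text is always returned
#'   (invisibly when `path` is given).
#' @return Character scalar of formatted text.
#' @export
write_mutation_list <- function(specs, dialect = c("foldx_individual", "tsv"),
                                path = NULL) {
  if (nrow(specs) == 0) abort("Empty mutation list.")
  dialect <- rlang::arg_match(dialect)
  text <- switch(dialect,
    foldx_individual = paste0(
      paste0(specs$wt, specs$chain, specs$position, specs$mut, ";",
             collapse = "\n"), "\n"),
    tsv = readr::format_tsv(dplyr::select(specs, "chain", "position", "wt", "mut"))
  )
  if (!is.null(path)) {
    writeLines(sub("\n$", "", text), path)
    return(invisible(text))
  }
  text
}

#' Read a mutation list written by [write_mutation_list()]
#'
#' @param text Character scalar of list text, or a file path.
#' @param dialect `"foldx_individual"` or `"tsv"`.
#' @return Tibble with `chain`, `position`, `wt`, `mut`, `is_identity`.
#' @export
read_mutation_list <- function(text, dialect = c("foldx_individual", "tsv")) {
  dialect <- rlang::arg_match(dialect)
  text <- .slurp(text)
  if (dialect == "tsv") {
    out <- readr::read_tsv(I(text), show_col_types = FALSE,
                           col_types = readr::cols(
                             chain = "c", position = "i", wt = "c", mut = "c"))
  } else {
    lines <- strsplit(text, "\n")[[1]]
    lines <- trimws(sub(";\\s*$", "", lines))
    lines <- lines[nzchar(lines)]
    m <- regmatches(lines, regexec("^([A-Z])([A-Za-z0-9])([0-9]+)([A-Z])$", lines))
    bad <- vapply(m, length, 1L) != 5L
    if (any(bad)) {
      abort(sprintf("Unparseable mutation token(s): %s",
                    paste(head(lines[bad], 3), collapse = ", ")))
    }
    out <- tibble::tibble(
      chain = vapply(m, `[[`, "", 3),
      position = as.integer(vapply(m, `[[`, "", 4)),
      wt = vapply(m, `[[`, "", 2),
      mut = vapply(m, `[[`, "", 5)
    )
  }
  dplyr::mutate(out, is_identity = .data$wt == .data$mut)
}

# read a character scalar that is either inline text or a path
.slurp <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  if (!grepl("\n", x) && file.exists(x)) {
    return(paste(readr::read_lines(x), collapse = "\n"))
  }
  x
}

#' Read a per-mutation free-energy table
#'
#' Ingests \eqn{\Delta\Delta G} values (kcal/mol) keyed by
#' (chain, position, wt, mut). All values are normalised internally to the
#' destabilizing-positive convention: with
#' `sign_convention = "destabilizing_negative"` every value is negated on
#' ingest. The `"foldx_dif"` dialect parses FoldX BuildModel difference
#' output (`Dif_*.fxout`), pairing the i-th energy with the i-th mutation of
#' an accompanying mutation list.
#'
#' @param text TSV text or a file path. The TSV dialect requires a header
#'   with columns `chain`, `position`, `wt`, `mut`, `ddg_kcal_mol`.
#' @param dialect `"tsv"` or `"foldx_dif"`.
#' @param sign_convention `"destabilizing_positive"` (default) or
#'   `"destabilizing_negative"`.
#' @param mutation_list For `"foldx_dif"`: the mutation list (text or tibble)
#'   the FoldX run was driven by, in run order.
#' @return A tibble with columns `chain`, `position`, `wt`, `mut`, `ddg`
#'   (kcal/mol, destabilizing-positive) and `source`.
#' @export
read_ddg_table <- function(text,
                           dialect = c("tsv", "foldx_dif"),
                           sign_convention = c("destabilizing_positive",
                                               "destabilizing_negative"),
                           mutation_list = NULL) {
  dialect <- rlang::arg_match(dialect)
  sign_convention <- rlang::arg_match(sign_convention)
  text <- .slurp(text)
  if (!nzchar(trimws(text))) abort("Empty ddG table.")

  if (dialect == "tsv") {
    tbl <- readr::read_tsv(I(text), show_col_types = FALSE,
                           col_types = readr::cols(
                             chain = "c", position = "i", wt = "c",
                             mut = "c", ddg_kcal_mol = "c"))
    need <- c("chain", "position", "wt", "mut", "ddg_kcal_mol")
    missing_cols <- setdiff(need, names(tbl))
    if (length(missing_cols) > 0) {
      abort(sprintf("ddG table missing column(s): %s",
                    paste(missing_cols, collapse = ", ")))
    }
    ddg <- suppressWarnings(as.numeric(tbl$ddg_kcal_mol))
    if (anyNA(ddg)) {
      # +1 for the header row
      abort(sprintf("Non-numeric ddG value at line %d: '%s'",
                    which(is.na(ddg))[1] + 1L,
                    tbl$ddg_kcal_mol[which(is.na(ddg))[1]]))
    }
    out <- tibble::tibble(chain = tbl$chain, position = tbl$position,
                          wt = tbl$wt, mut = tbl$mut, ddg = ddg,
                          source = "tsv")
  } else {
    if (is.null(mutation_list)) {
      abort("dialect = 'foldx_dif' requires `mutation_list`.")
    }
    specs <- if (is.data.frame(mutation_list)) {
      mutation_list
    } else {
      read_mutation_list(mutation_list, dialect = "foldx_individual")
    }
    lines <- strsplit(text, "\n")[[1]]
    energy_lines <- grep("\\t", lines, value = TRUE)
    energy_lines <- energy_lines[grepl("^\\S+\\.pdb\\t", energy_lines)]
    vals <- suppressWarnings(
      as.numeric(vapply(strsplit(energy_lines, "\t"), `[[`, "", 2)))
    if (length(vals) == 0 || anyNA(vals)) {
      abort("Could not parse energies from FoldX difference output.")
    }
    if (length(vals) != nrow(specs)) {
      abort(sprintf("FoldX output has %d energies but mutation list has %d specs.",
                    length(vals), nrow(specs)))
    }
    out <- tibble::tibble(chain = specs$chain, position = specs$position,
                          wt = specs$wt, mut = specs$mut, ddg = vals,
                          source = "foldx_dif")
  }

  if (sign_convention == "destabilizing_negative") out$ddg <- -out$ddg
  if (!all(is.finite(out$ddg))) abort("Non-finite ddG value in table.")

  dup <- out |>
    dplyr::count(.data$chain, .data$position, .data$mut) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate ddG record(s) for key(s): %s",
                  paste(sprintf("%s:%d:%s", dup$chain, dup$position, dup$mut),
                        collapse = ", ")))
  }
  out
}

#' Write a ddG table in the TSV dialect
#'
#' @param ddg Tibble with `chain`, `position`, `wt`, `mut`, `ddg`
#'   (destabilizing-positive kcal/mol).
#' @param path Optional output file.
#' @return TSV text (invisibly when `path` is given).
#' @export
write_ddg_table <- function(ddg, path = NULL) {
  out <- ddg |>
    dplyr::transmute(.data$chain, .data$position, .data$wt, .data$mut,
                     ddg_kcal_mol = .data$ddg)
  text <- readr::format_tsv(out)
  if (!is.null(path)) {
    readr::write_tsv(out, path)
    return(invisible(text))
  }
  text
}

#' Read an experimental (ProTherm-like) stability table
#'
#' Experimental \eqn{\Delta\Delta G} records for validation. The layout is
#' TSV with columns `protein_id`, `chain`, `position`, `wt`, `mut`,
#' `ddg_kcal_mol`, and optionally `sign_convention`
#' (`destabilizing_positive` / `destabilizing_negative`, per row) and
#' `source_note`. ProTherm reports stability changes with the opposite sign
#' to this package's convention, so the default for rows without an explicit
#' convention is `destabilizing_negative` (values are negated on ingest).
#' Multiple measurements of the same mutation are averaged after sign
#' normalisation, with the number of observations retained in `n_obs`.
#'
#' @param text TSV text or a file path.
#' @param default_sign_convention Convention assumed when the table has no
#'   `sign_convention` column.
#' @return Tibble with `protein_id`, `chain`, `position`, `wt`, `mut`,
#'   `ddg` (destabilizing-positive), `n_obs`.
#' @export
read_experimental_table <- function(text,
                                    default_sign_convention = c(
                                      "destabilizing_negative",
                                      "destabilizing_positive")) {
  default_sign_convention <- rlang::arg_match(default_sign_convention)
  text <- .slurp(text)
  tbl <- readr::read_tsv(I(text), show_col_types = FALSE)
  need <- c("protein_id", "chain", "position", "wt", "mut", "ddg_kcal_mol")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("Experimental table missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"sign_convention" %in% names(tbl)) {
    tbl$sign_convention <- default_sign_convention
  }
  bad <- setdiff(unique(tbl$sign_convention),
                 c("destabilizing_positive", "destabilizing_negative"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown sign convention(s): %s", paste(bad, collapse = ", ")))
  }
  tbl |>
    dplyr::mutate(
      position = as.integer(.data$position),
      ddg = ifelse(.data$sign_convention == "destabilizing_negative",
                   -.data$ddg_kcal_mol, .data$ddg_kcal_mol)) |>
    dplyr::summarise(ddg = mean(.data$ddg), n_obs = dplyr::n(),
                     .by = c("protein_id", "chain", "position", "wt", "mut"))
}
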