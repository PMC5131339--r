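# Reading protein structures into residue-level tibbles.

new_ums_structure <- function(df, id = "structure") {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("chain", "position", "wt", "x", "y", "z") %in% names(df)))
  attr(df, "id") <- id
  class(df) <- c("ums_structure", class(df))
  df
}

validate_ums_structure <- function(structure) {
  if (nrow(structure) == 0) {
    abort("Structure has no residues.")
  }
  .check_aa(structure$wt, "wild-type residue")
  inc <- structure |>
    dplyr::summarise(ok = all(diff(.data$position) > 0), .by = "chain")
  if (!all(inc$ok)) {
    abort(sprintf("Residue positions not strictly increasing in chain(s): %s",
                  paste(inc$chain[!inc$ok], collapse = ", ")))
  }
  invisible(structure)
}

#' Read a protein structure from PDB
#'
#' Parses ATOM records into one row per residue (the alpha-carbon trace),
#' preserving the file's author residue numbering so downstream mutation
#' names (e.g. P23H) match clinical nomenclature. HETATM records and
#' residues without a standard parent amino acid are skipped with a warning;
#' common modified residues (e.g. selenomethionine) are mapped to their
#' standard parent. Alternate locations resolve to the first encountered;
#' insertion codes are rejected.
#'
#' @param pdb Path to a PDB file, or a character scalar of PDB text
#'   (recognised by embedded newlines / leading ATOM records).
#' @param chain Optional single chain identifier to keep; all chains by
#'   default.
#' @param id Identifier stored on the result; defaults to the file name.
#' @return A tibble of class `ums_structure` with columns `chain`,
#'   `position`, `wt` (one-letter code) and alpha-carbon coordinates
#'   `x`, `y`, `z` (Angstrom).
#' @export
#' @examples
#' pdb <- make_toy_structure(5, seed = 1)
#' read_structure(pdb)
read_structure <- function(pdb, chain = NULL, id = NULL) {
  stopifnot(is.character(pdb), length(pdb) == 1)
  if (grepl("\n", pdb) || grepl("^(ATOM|HETATM|HEADER|MODEL)", pdb)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(pdb, path)
    id <- id %||% "structure"
  } else {
    path <- pdb
    if (!file.exists(path)) abort(sprintf("No such PDB file: %s", path))
    id <- id %||% sub("\\.pdb$", "", basename(path))
  }

  parsed <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) abort(paste0("No parsable ATOM records: ", conditionMessage(e)))
  )
  atoms <- tibble::as_tibble(parsed$atom)
  if (!any(atoms$type == "ATOM")) {
    abort("No parsable ATOM records in input.")
  }
  if (any(atoms$type == "HETATM")) {
    warn(sprintf("Skipping %d HETATM record(s).", sum(atoms$type == "HETATM")))
  }

  ca <- atoms |>
    dplyr::filter(.data$type == "ATOM", .data$elety == "CA")
  if (nrow(ca) == 0) abort("No CA atoms found among ATOM records.")

  if (any(!is.na(ca$insert) & ca$insert != "")) {
    abort("Residues with insertion codes are not supported.")
  }

  # alternate locations: first encountered wins (file order)
  ca <- ca |> dplyr::distinct(.data$chain, .data$resno, .keep_all = TRUE)

  resid3 <- toupper(ca$resid)
  wt <- unname(.aa_three_to_one[resid3])
  parent <- unname(.aa_nonstandard_parent[resid3])
  mapped <- is.na(wt) & !is.na(parent)
  if (any(mapped)) {
    warn(sprintf("Mapped %d non-standard residue(s) to standard parents: %s",
                 sum(mapped),
                 paste(unique(resid3[mapped]), collapse = ", ")))
    wt[mapped] <- parent[mapped]
  }
  unknown <- is.na(wt)
  if (any(unknown)) {
    warn(sprintf("Skipped %d residue(s) with no standard parent: %s",
                 sum(unknown),
                 paste(unique(resid3[unknown]), collapse = ", ")))
  }

  res <- tibble::tibble(
    chain = ca$chain, position = ca$resno, wt = wt,
    x = ca$x, y = ca$y, z = ca$z
  ) |>
    dplyr::filter(!is.na(.data$wt))

  if (!is.null(chain)) {
    stopifnot(length(chain) == 1)
    if (!chain %in% res$chain) {
      abort(sprintf("Chain '%s' not present in structure (chains: %s).",
                    chain, paste(unique(res$chain), collapse = ", ")))
    }
    res <- dplyr::filter(res, .data$chain == !!chain)
  }

  out <- new_ums_structure(res, id = id)
  validate_ums_structure(out)
  out
}

#' @export
print.ums_structure <- function(x, ...) {
  cat(sprintf("# Protein structure '%s': %d residue(s), %d chain(s)\n",
              attr(x, "id"), nrow(x), dplyr::n_distinct(x$chain)))
  NextMethod()
}
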