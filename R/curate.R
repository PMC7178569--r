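# Corpus reading, curation and writing.
#
# Molecule datasets are plain data.frames with the columns
#   raw_smiles, canonical_smiles, label, class_id, is_augmented
# (label/class_id NA when absent). Original records satisfy
# raw_smiles == canonical_smiles; augmented enumeration variants carry the
# variant text in raw_smiles.

#' Construct a set of molecule records from SMILES
#'
#' Canonicalizes the inputs and attaches optional regression labels or
#' integer class ids. Invalid SMILES abort with an error: silently dropping
#' rows of a labelled dataset would corrupt the label alignment.
#'
#' @param smiles Character vector of SMILES.
#' @param label Optional numeric labels (regression).
#' @param class_id Optional integer class ids (classification).
#' @return A data.frame of molecule records.
#' @export
molecule_records <- function(smiles, label = NULL, class_id = NULL) {
  smiles <- as.character(smiles)
  n <- length(smiles)
  if (!is.null(label) && length(label) != n) {
    stop("`label` must align with `smiles`", call. = FALSE)
  }
  if (!is.null(class_id) && length(class_id) != n) {
    stop("`class_id` must align with `smiles`", call. = FALSE)
  }
  can <- canonicalize_all(smiles)
  if (anyNA(can)) {
    bad <- smiles[is.na(can)]
    stop("invalid SMILES in labelled input: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  data.frame(raw_smiles = can,
             canonical_smiles = can,
             label = if (is.null(label)) rep(NA_real_, n) else as.numeric(label),
             class_id = if (is.null(class_id)) rep(NA_integer_, n)
                        else as.integer(class_id),
             is_augmented = rep(FALSE, n),
             stringsAsFactors = FALSE)
}

#' Curate a corpus of raw SMILES
#'
#' Applies, in order: a parse/validity filter, a mixture filter (more than
#' one disconnected fragment), a heavy-atom filter (strictly more than
#' `max_heavy_atoms` heavy atoms removed), standardization +
#' canonicalization, and optional duplicate removal on the canonical form
#' (first occurrence kept). Unparsable entries are counted in the report,
#' never raised.
#'
#' @param smiles Character vector of raw SMILES.
#' @param max_heavy_atoms Heavy-atom threshold (default 50).
#' @param deduplicate Remove canonical duplicates? Default `TRUE`.
#' @return A list with `records` (data.frame of retained molecule records)
#'   and `report` (a `curation_report`).
#' @export
curate_corpus <- function(smiles, max_heavy_atoms = 50L, deduplicate = TRUE) {
  stopifnot(max_heavy_atoms >= 1L)
  smiles <- as.character(smiles)
  n_input <- length(smiles)
  report <- list(n_input = n_input, n_removed_invalid = 0L,
                 n_removed_mixture = 0L, n_removed_heavy_atoms = 0L,
                 n_removed_duplicate = 0L, n_retained = 0L)
  if (n_input == 0L) {
    return(list(records = molecule_records(character(0)),
                report = structure(report, class = "curation_report")))
  }
  can <- canonicalize_all(smiles)
  graphs <- lapply(smiles, function(s) {
    tryCatch(smiles_parse(s), error = function(e) NULL)
  })
  valid <- !is.na(can) & !vapply(graphs, is.null, TRUE)
  report$n_removed_invalid <- sum(!valid)

  mixture <- valid & vapply(seq_along(graphs), function(i) {
    valid[i] && max(mol_components(graphs[[i]])) > 1L
  }, TRUE)
  report$n_removed_mixture <- sum(mixture)
  ok <- valid & !mixture

  heavy <- ok & vapply(seq_along(graphs), function(i) {
    ok[i] && sum(graphs[[i]]$element != "H") > max_heavy_atoms
  }, TRUE)
  report$n_removed_heavy_atoms <- sum(heavy)
  ok <- ok & !heavy

  can_ok <- can[ok]
  if (deduplicate) {
    dup <- duplicated(can_ok)
    report$n_removed_duplicate <- sum(dup)
    can_ok <- can_ok[!dup]
  }
  report$n_retained <- length(can_ok)
  records <- data.frame(raw_smiles = can_ok, canonical_smiles = can_ok,
                        label = rep(NA_real_, length(can_ok)),
                        class_id = rep(NA_integer_, length(can_ok)),
                        is_augmented = rep(FALSE, length(can_ok)),
                        stringsAsFactors = FALSE)
  list(records = records,
       report = structure(report, class = "curation_report"))
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report:\n")
  for (f in names(x)) cat(sprintf("  %-22s %d\n", f, x[[f]]))
  invisible(x)
}

#' Write a curation report as JSON
#' @param report A `curation_report`.
#' @param path Output path.
#' @param meta Optional named list of extra metadata (e.g. the seed of the
#'   run that produced the corpus).
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(report, path, meta = NULL) {
  x <- unclass(report)
  if (!is.null(meta)) x <- c(x, list(meta = meta))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a .smi file (one SMILES per line, optional whitespace-separated id)
#' @param path Input path.
#' @return A data.frame with columns `smiles` and `id`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  data.frame(smiles = vapply(parts, `[`, "", 1L),
             id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, ""),
             stringsAsFactors = FALSE)
}

#' Write SMILES to a .smi file
#' @param smiles Character vector of SMILES (or a molecule-record
#'   data.frame, whose `raw_smiles` column is written).
#' @param path Output path.
#' @param id Optional id column.
#' @return `path`, invisibly.
#' @export
write_smi <- function(smiles, path, id = NULL) {
  if (is.data.frame(smiles)) smiles <- smiles$raw_smiles
  lines <- if (is.null(id)) smiles else paste(smiles, id)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a labelled QSAR dataset from CSV
#'
#' The file must have a header. Invalid SMILES abort with an error.
#'
#' @param path CSV path (UTF-8).
#' @param smiles_col Name of the SMILES column.
#' @param label_col Optional name of the numeric label column.
#' @param class_col Optional name of the class-id column.
#' @return A data.frame of molecule records.
#' @export
read_qsar_csv <- function(path, smiles_col = "smiles", label_col = NULL,
                          class_col = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        check.names = FALSE)
  for (col in c(smiles_col, label_col, class_col)) {
    if (!is.null(col) && !col %in% names(df)) {
      stop("column ", sQuote(col), " not found in ", path, call. = FALSE)
    }
  }
  molecule_records(
    df[[smiles_col]],
    label = if (!is.null(label_col)) as.numeric(df[[label_col]]),
    class_id = if (!is.null(class_col)) as.integer(df[[class_col]]))
}
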