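#' Read a per-program score table
#'
#' Reads one docking program's flat score table (delimited text, one row per
#' molecule) into the long tidy form used throughout the package: a tibble
#' with columns `molecule_id`, `program`, `score` and `direction`.
#'
#' Docking programs emit scores in program-native units; for all common
#' engines a more negative score is better, so the default direction is
#' `"lower"`. Duplicate molecule ids (e.g. tautomers exported as separate
#' rows) are an error unless `collapse = "best"`, in which case the best score
#' under the table's direction is kept per id — the convention used when a
#' dataset contains several tautomers of one parent molecule.
#'
#' @param path Path to a delimited text file.
#' @param program_id Identifier for the docking program (used as the `program`
#'   column).
#' @param direction `"lower"` (default; more negative = better, the convention
#'   of docking energy scores) or `"higher"`.
#' @param structure_id Optional receptor structure identifier; adds a
#'   `structure` column for ensemble workflows.
#' @param collapse `"error"` (default) or `"best"`: policy for duplicated
#'   molecule ids.
#' @param col_molecule,col_score Column names in the file. Defaults
#'   `"molecule_id"` and `"score"`.
#' @param delim Field delimiter; default `","`.
#' @return A tibble with columns `molecule_id`, `program`, `score`,
#'   `direction` (and `structure` if `structure_id` was given).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("molecule_id,score", "A,-9.1", "B,-7.2", "C,-8.0"), f)
#' read_score_table(f, program_id = "vina")
read_score_table <- function(path, program_id,
                             direction = c("lower", "higher"),
                             structure_id = NULL,
                             collapse = c("error", "best"),
                             col_molecule = "molecule_id",
                             col_score = "score",
                             delim = ",") {
  direction <- match.arg(direction)
  collapse <- match.arg(collapse)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) abort(sprintf("empty score table: %s", path))
  for (col in c(col_molecule, col_score)) {
    if (!col %in% names(raw)) {
      abort(sprintf('column "%s" missing from %s', col, path))
    }
  }
  score_raw <- raw[[col_score]]
  score <- suppressWarnings(as.numeric(score_raw))
  bad <- which(!is.finite(score))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric or non-finite score at data row %d of %s (value %s)",
                  bad[1], path, deparse(as.character(score_raw[bad[1]]))))
  }
  out <- tibble::tibble(
    molecule_id = as.character(raw[[col_molecule]]),
    program = program_id,
    score = score,
    direction = direction
  )
  if (!is.null(structure_id)) out$structure <- structure_id
  if (anyDuplicated(out$molecule_id)) {
    if (collapse == "error") {
      dup <- out$molecule_id[duplicated(out$molecule_id)][1]
      abort(sprintf('duplicated molecule id "%s" in %s (set collapse = "best" to keep the best score)',
                    dup, path))
    }
    out <- collapse_variants(out)
  }
  assert_scores(out)
}

#' Read a ligand/decoy label table
#'
#' @param path Delimited file with columns `molecule_id` and `label`, where
#'   label is `"ligand"` or `"decoy"`.
#' @param delim Field delimiter.
#' @return A tibble with columns `molecule_id`, `label`.
#' @export
read_labels <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  labels <- tibble::tibble(molecule_id = as.character(raw$molecule_id),
                           label = as.character(raw$label))
  assert_labels(labels)
  labels
}

#' Collapse molecular variants to their parent molecule
#'
#' When a dataset lists several variants (tautomers, protomers, duplicate
#' poses) of one parent molecule, each program's table is reduced to one entry
#' per parent holding the best score among its variants under the table's
#' direction.
#'
#' @param scores A scores tibble (`molecule_id`, `program`, `score`,
#'   `direction`).
#' @param parent_map Optional tibble with columns `variant_id` and
#'   `molecule_id` mapping variants to parents. Ids absent from the map pass
#'   through as their own parent. With `parent_map = NULL` the molecule ids
#'   themselves are deduplicated (best score per id).
#' @return A scores tibble with one row per parent molecule per program.
#' @export
#' @examples
#' tbl <- tibble::tibble(molecule_id = c("t1", "t2"), program = "icm",
#'                       score = c(-8, -9.5), direction = "lower")
#' collapse_variants(tbl, tibble::tibble(variant_id = c("t1", "t2"),
#'                                       molecule_id = c("M", "M")))
collapse_variants <- function(scores, parent_map = NULL) {
  if (!is.null(parent_map)) {
    idx <- match(scores$molecule_id, parent_map$variant_id)
    mapped <- parent_map$molecule_id[idx]
    scores$molecule_id <- ifelse(is.na(idx), scores$molecule_id, mapped)
  }
  grouping <- c("program", "direction", "molecule_id",
                intersect("structure", names(scores)))
  out <- scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      score = if (.data$direction[1] == "lower") min(.data$score) else max(.data$score),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(c("molecule_id", "program",
                                  intersect("structure", names(scores)),
                                  "score", "direction"))) |>
    dplyr::arrange(.data$program, .data$molecule_id)
  assert_scores(out)
}

#' Convert scores to per-program ordinal ranks
#'
#' Within each program (and structure, if present) the best score under the
#' table's direction receives rank 1. Raw-score ties are broken
#' deterministically by ascending molecule id, so each table's ranks are
#' always a strict permutation of 1..N.
#'
#' @param scores A scores tibble.
#' @return A tibble with columns `molecule_id`, `program` (and `structure` if
#'   present), `rank`.
#' @export
#' @examples
#' tbl <- tibble::tibble(molecule_id = c("A", "B", "C"), program = "vina",
#'                       score = c(-9, -7, -8), direction = "lower")
#' score_to_ranks(tbl)
score_to_ranks <- function(scores) {
  assert_scores(scores)
  grouping <- c("program", intersect("structure", names(scores)))
  out <- scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::mutate(rank = ordinal_rank(.data$score, .data$molecule_id,
                                      .data$direction[1])) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("molecule_id", grouping, "rank"))) |>
    dplyr::arrange(.data$program, .data$rank)
  assert_ranks(out)
}
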