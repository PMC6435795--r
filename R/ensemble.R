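#' Merging and shrinking over receptor structures, rank variant
#'
#' Combines one docking program's results over several receptor structures by
#' keeping, for each molecule, its best (minimum) rank across structures,
#' then re-ranking ascending on that key. Key ties are broken by ascending
#' molecule id so the output is again a strict permutation of 1..N. Because
#' ranks are unitless, this variant is immune to score offset/scale
#' differences between structures and is the one to pair with rank-based
#' consensus strategies.
#'
#' @param ranks A ranks tibble for one program with a `structure` column
#'   covering at least two structures, all over the same molecule set.
#' @return A ranks tibble (`molecule_id`, `program`, `rank`) with the merged
#'   ranking; the best-rank key is kept in a `best_rank` column.
#' @export
#' @examples
#' ranks <- tibble::tibble(
#'   molecule_id = rep(c("A", "B", "C"), 2),
#'   program = "vina",
#'   structure = rep(c("s1", "s2"), each = 3),
#'   rank = c(1L, 4L, 2L, 7L, 1L, 3L))
#' merge_shrink_rank(ranks)
merge_shrink_rank <- function(ranks) {
  if (!"structure" %in% names(ranks)) {
    abort("`ranks` needs a `structure` column for merging")
  }
  # per-structure ranks may be slices of a larger screen (e.g. after molecule
  # alignment), so only positivity is required of the inputs; the merged
  # output is re-ranked to a strict permutation
  if (!all(ranks$rank >= 1) || !all(ranks$rank == as.integer(ranks$rank))) {
    abort("`rank` must hold positive integers")
  }
  if (dplyr::n_distinct(ranks$structure) < 2L) {
    abort("merging needs at least two structures")
  }
  if (dplyr::n_distinct(ranks$program) != 1L) {
    abort("merge tables one program at a time")
  }
  sets <- split(ranks$molecule_id, ranks$structure)
  if (!all(vapply(sets, setequal, logical(1), y = sets[[1]]))) {
    abort("structures cover different molecule sets; align them first")
  }
  out <- ranks |>
    dplyr::group_by(.data$molecule_id, .data$program) |>
    dplyr::summarise(best_rank = min(.data$rank), .groups = "drop") |>
    dplyr::mutate(rank = ordinal_rank(.data$best_rank, .data$molecule_id,
                                      "lower")) |>
    dplyr::select(dplyr::all_of(c("molecule_id", "program", "rank",
                                  "best_rank"))) |>
    dplyr::arrange(.data$rank)
  assert_ranks(out)
}

#' Merging and shrinking over receptor structures, score variant
#'
#' Keeps, for each molecule, the best raw score across structures under the
#' shared score direction. Structure-specific score offsets are *not*
#' corrected: if one structure's scores are systematically lower, the merged
#' table will be dominated by that structure regardless of its quality. This
#' hazard is inherent to score-level merging; it is why the rank variant is
#' preferred with rank-based consensus and the score variant is reserved for
#' score-based consensus strategies.
#'
#' @param scores A scores tibble for one program with a `structure` column
#'   (at least two structures, one direction).
#' @return A scores tibble (`molecule_id`, `program`, `score`, `direction`)
#'   holding each molecule's best score.
#' @export
merge_shrink_score <- function(scores) {
  if (!"structure" %in% names(scores)) {
    abort("`scores` needs a `structure` column for merging")
  }
  assert_scores(scores)
  if (dplyr::n_distinct(scores$structure) < 2L) {
    abort("merging needs at least two structures")
  }
  if (dplyr::n_distinct(scores$program) != 1L) {
    abort("merge tables one program at a time")
  }
  sets <- split(scores$molecule_id, scores$structure)
  if (!all(vapply(sets, setequal, logical(1), y = sets[[1]]))) {
    abort("structures cover different molecule sets; align them first")
  }
  dir <- single_direction(scores)
  out <- scores |>
    dplyr::group_by(.data$molecule_id, .data$program) |>
    dplyr::summarise(
      score = if (dir == "lower") min(.data$score) else max(.data$score),
      .groups = "drop"
    ) |>
    dplyr::mutate(direction = dir) |>
    dplyr::arrange(.data$molecule_id)
  assert_scores(out)
}
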