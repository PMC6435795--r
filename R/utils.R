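# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

DIRECTIONS <- c("lower", "higher")

#' Canonical strategy labels
#'
#' The six consensus strategies, grouped by what they consume: rank-based
#' strategies use only each program's ordering, score-based strategies use the
#' (possibly rescaled) raw scores.
#' @return A named list with elements `rank` and `score`, each a character
#'   vector of strategy labels.
#' @export
#' @examples
#' strategy_groups()
strategy_groups <- function() {
  list(rank = c("RbR", "RbV", "ECR"), score = c("AASS", "RbN", "Zscore"))
}

check_direction <- function(direction) {
  if (!is.character(direction) || length(direction) != 1L ||
      !direction %in% DIRECTIONS) {
    abort('`direction` must be "lower" or "higher"')
  }
  direction
}

# A scores tibble has columns molecule_id, program, score, direction
# (optionally structure). Validates invariants: finite scores, unique
# molecule per (program, structure), single direction per program.
assert_scores <- function(scores, arg = "scores") {
  needed <- c("molecule_id", "program", "score", "direction")
  missing_cols <- setdiff(needed, names(scores))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` lacks column(s): %s", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(scores) == 0L) abort(sprintf("`%s` is empty", arg))
  if (!all(is.finite(scores$score))) {
    abort(sprintf("`%s` contains non-finite scores", arg))
  }
  if (!all(scores$direction %in% DIRECTIONS)) {
    abort(sprintf('`%s` has directions outside {"lower","higher"}', arg))
  }
  keys <- if ("structure" %in% names(scores)) {
    paste(scores$program, scores$structure, scores$molecule_id, sep = "\r")
  } else {
    paste(scores$program, scores$molecule_id, sep = "\r")
  }
  if (anyDuplicated(keys)) {
    abort(sprintf("`%s` has duplicated molecule ids within a table", arg))
  }
  ndir <- dplyr::n_distinct(paste(scores$program, scores$direction))
  if (ndir != dplyr::n_distinct(scores$program)) {
    abort(sprintf("`%s` mixes directions within one program", arg))
  }
  invisible(scores)
}

assert_ranks <- function(ranks, arg = "ranks") {
  needed <- c("molecule_id", "program", "rank")
  missing_cols <- setdiff(needed, names(ranks))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` lacks column(s): %s", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(ranks) == 0L) abort(sprintf("`%s` is empty", arg))
  grp <- if ("structure" %in% names(ranks)) {
    paste(ranks$program, ranks$structure, sep = "\r")
  } else {
    ranks$program
  }
  ok <- vapply(split(ranks$rank, grp), function(r) {
    length(r) > 0 && setequal(r, seq_along(r))
  }, logical(1))
  if (!all(ok)) {
    abort(sprintf("`%s`: ranks in table(s) %s are not a permutation of 1..N",
                  arg, paste(names(ok)[!ok], collapse = ", ")))
  }
  invisible(ranks)
}

# Every program must cover exactly the same molecule set (call align_programs
# first if not).
assert_aligned <- function(tbl, arg = "input") {
  sets <- split(tbl$molecule_id, tbl$program)
  ref <- sort(sets[[1]])
  same <- vapply(sets, function(s) identical(sort(s), ref), logical(1))
  if (!all(same)) {
    abort(sprintf(
      "programs in `%s` cover different molecule sets; run align_programs() first",
      arg))
  }
  invisible(tbl)
}

single_direction <- function(scores) {
  dirs <- unique(scores$direction)
  if (length(dirs) != 1L) {
    abort("tables mix score directions; negate scores to a common direction first")
  }
  dirs
}

# Ordinal ranking of a score vector under a direction, ties broken by
# ascending molecule id, so the result is always a permutation of 1..N.
ordinal_rank <- function(score, molecule_id, direction) {
  key <- if (direction == "lower") score else -score
  ord <- order(key, molecule_id, method = "radix")
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  rank
}

assert_labels <- function(labels) {
  if (!all(c("molecule_id", "label") %in% names(labels))) {
    abort('`labels` needs columns "molecule_id" and "label"')
  }
  if (!all(labels$label %in% c("ligand", "decoy"))) {
    abort('labels must be "ligand" or "decoy"')
  }
  if (anyDuplicated(labels$molecule_id)) {
    abort("duplicated molecule ids in `labels`")
  }
  invisible(labels)
}
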