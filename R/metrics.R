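# Evaluation metrics for a final ranking plus ligand/decoy labels.

# Normalizes the many ranking-shaped inputs to one tibble:
# molecule_id, final_rank, tie_group (singleton groups for strict rankings).
as_ranking <- function(x) {
  if (inherits(x, "consensus_result")) {
    return(tibble::as_tibble(x)[c("molecule_id", "final_rank", "tie_group")])
  }
  if (is.data.frame(x)) {
    if (all(c("molecule_id", "final_rank") %in% names(x))) {
      out <- tibble::tibble(molecule_id = x$molecule_id,
                            final_rank = as.integer(x$final_rank))
    } else if (all(c("molecule_id", "rank") %in% names(x))) {
      if ("program" %in% names(x) && dplyr::n_distinct(x$program) > 1L) {
        abort("ranking covers several programs; pass one program or a consensus result")
      }
      out <- tibble::tibble(molecule_id = x$molecule_id,
                            final_rank = as.integer(x$rank))
    } else {
      abort("cannot interpret `ranking`: need consensus_result or molecule_id + rank")
    }
    if (!setequal(out$final_rank, seq_len(nrow(out)))) {
      abort("ranking is not a permutation of 1..N")
    }
    out <- dplyr::arrange(out, .data$final_rank)
    out$tie_group <- if ("tie_group" %in% names(x)) {
      as.integer(x$tie_group[order(x$final_rank)])
    } else {
      out$final_rank
    }
    return(out)
  }
  abort("`ranking` must be a data frame or consensus_result")
}

join_labels <- function(ranking, labels) {
  assert_labels(labels)
  idx <- match(ranking$molecule_id, labels$molecule_id)
  if (anyNA(idx)) {
    abort(sprintf("unlabelled molecule(s), e.g. %s",
                  ranking$molecule_id[which(is.na(idx))[1]]))
  }
  ranking$label <- labels$label[idx]
  ranking
}

top_n_count <- function(x, n) max(1L, as.integer(floor(x / 100 * n)))

#' Enrichment factor
#'
#' The enrichment factor at x% is the ratio of the ligand fraction in the top
#' x% of the ranked list to the ligand fraction in the whole dataset:
#' EFx = (Hits_x / N_x) * (N / Hits_total), with N_x = max(1, floor(x/100 *
#' N)). EF is 1 in expectation for a random ranking and bounded above by
#' min(N_x, Hits)/N_x * N/Hits; EF at 100% is exactly 1.
#'
#' Tied consensus scores are resolved by the ranking's deterministic
#' provisional order (ascending molecule id within a tie group); use
#' [shuffle_evaluate()] for the tie-induced uncertainty.
#'
#' @param ranking A `consensus_result`, or a tibble with `molecule_id` and
#'   `rank`/`final_rank` forming a permutation of 1..N.
#' @param labels Tibble with `molecule_id` and `label` ("ligand"/"decoy")
#'   covering every ranked molecule.
#' @param x Percent threshold(s) in (0, 100].
#' @return A tibble with one row per threshold: `percent`, `n_top`, `hits`,
#'   `ef`.
#' @export
enrichment_factor <- function(ranking, labels, x = c(1, 2, 5)) {
  if (any(x <= 0 | x > 100)) abort("`x` must be in (0, 100]")
  rk <- join_labels(as_ranking(ranking), labels)
  n <- nrow(rk)
  hits_total <- sum(rk$label == "ligand")
  if (hits_total == 0L) abort("no ligands among ranked molecules")
  is_hit <- rk$label[order(rk$final_rank)] == "ligand"
  cum_hits <- cumsum(is_hit)
  out <- purrr::map(x, function(xx) {
    n_top <- top_n_count(xx, n)
    hits <- cum_hits[n_top]
    ef <- (hits / n_top) * (n / hits_total)
    tibble::tibble(percent = xx, n_top = n_top, hits = hits, ef = ef)
  }) |> purrr::list_rbind()
  bound <- (pmin(out$n_top, hits_total) / out$n_top) * (n / hits_total)
  stopifnot(all(out$ef <= bound + 1e-9))
  out
}

#' Enrichment curve
#'
#' Percentage of all ligands recovered as a function of the percentage of the
#' ranked dataset screened. The returned curve passes through (0, 0) and
#' (100, 100). The same top-list size rule as [enrichment_factor()] is used,
#' so at thresholds where x/100*N is a whole number the identity
#' recovered(x) = EFx * x * (Hits/N) * (100/Hits) = EFx * x holds.
#'
#' @inheritParams enrichment_factor
#' @param grid Percent thresholds to evaluate; default 0.5% steps.
#' @return A tibble of class `enrichment_curve` with columns
#'   `percent_screened` and `percent_ligands`.
#' @export
enrichment_curve <- function(ranking, labels, grid = seq(0.5, 100, by = 0.5)) {
  if (any(grid <= 0 | grid > 100)) abort("`grid` must be in (0, 100]")
  rk <- join_labels(as_ranking(ranking), labels)
  n <- nrow(rk)
  hits_total <- sum(rk$label == "ligand")
  if (hits_total == 0L) abort("no ligands among ranked molecules")
  is_hit <- rk$label[order(rk$final_rank)] == "ligand"
  cum_hits <- cumsum(is_hit)
  grid <- sort(unique(grid))
  rec <- vapply(grid, function(xx) {
    100 * cum_hits[top_n_count(xx, n)] / hits_total
  }, numeric(1))
  out <- tibble::tibble(percent_screened = c(0, grid),
                        percent_ligands = c(0, rec))
  structure(out, class = c("enrichment_curve", class(tibble::tibble())))
}

#' ROC curve and AUC for a ranking
#'
#' Sweeps a threshold down the ranked list, plotting the true positive rate
#' (recovered ligand fraction) against the false positive rate (accepted
#' decoy fraction). All members of a tie group enter at a single threshold
#' step, which draws a diagonal segment through the group and makes the
#' trapezoidal AUC equal to the pairwise-comparison statistic with ties
#' counted 1/2 — the standard Wilcoxon/Mann-Whitney convention.
#'
#' @inheritParams enrichment_factor
#' @return A tibble of class `roc_curve` with columns `fpr` and `tpr` and an
#'   `auc` attribute (retrieve with [roc_auc()]).
#' @export
roc_curve <- function(ranking, labels) {
  rk <- join_labels(as_ranking(ranking), labels)
  n_lig <- sum(rk$label == "ligand")
  n_dec <- sum(rk$label == "decoy")
  if (n_lig == 0L || n_dec == 0L) {
    abort("ROC needs both ligands and decoys in `labels`")
  }
  rk <- dplyr::arrange(rk, .data$final_rank)
  by_group <- rk |>
    dplyr::group_by(.data$tie_group) |>
    dplyr::summarise(tp = sum(.data$label == "ligand"),
                     fp = sum(.data$label == "decoy"), .groups = "drop") |>
    dplyr::arrange(.data$tie_group)
  tpr <- c(0, cumsum(by_group$tp) / n_lig)
  fpr <- c(0, cumsum(by_group$fp) / n_dec)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  out <- tibble::tibble(fpr = fpr, tpr = tpr)
  structure(out, class = c("roc_curve", class(tibble::tibble())), auc = auc)
}

#' @rdname roc_curve
#' @return `roc_auc()` returns the area under the ROC curve as a bare number.
#' @export
roc_auc <- function(ranking, labels) {
  attr(roc_curve(ranking, labels), "auc")
}

#' Count best-strategy successes across screening contexts
#'
#' Summarizes a set of screening contexts (individual receptor structures
#' and merged ensembles) by awarding, within each context, one point to every
#' consensus strategy attaining the maximal enrichment factor — ties share
#' points. Individual-structure contexts compare all six strategies jointly
#' (`group = "all"`); merged-ensemble contexts are scored separately for the
#' score-based triple AASS/RbN/Zscore (`group = "score"`) and the rank-based
#' triple RbR/RbV/ECR (`group = "rank"`), since score-level merging feeds
#' only score-based consensus and rank-level merging only rank-based
#' consensus.
#'
#' @param ef_table Tibble with columns `context`, `group` (one of `"all"`,
#'   `"score"`, `"rank"`), `strategy`, `ef`. Every (context, group) cell must
#'   carry its full strategy set.
#' @return A tibble `strategy`, `points` with one row per strategy seen.
#' @export
#' @examples
#' success_count(tibble::tibble(
#'   context = "s1", group = "all",
#'   strategy = c("AASS", "RbN", "Zscore", "RbR", "RbV", "ECR"),
#'   ef = c(7, 7, 6, 7, 6.8, 6)))
success_count <- function(ef_table) {
  needed <- c("context", "group", "strategy", "ef")
  if (!all(needed %in% names(ef_table))) {
    abort(sprintf("`ef_table` needs columns %s", paste(needed, collapse = ", ")))
  }
  required <- list(all = unlist(strategy_groups(), use.names = FALSE),
                   score = strategy_groups()$score,
                   rank = strategy_groups()$rank)
  if (!all(ef_table$group %in% names(required))) {
    abort('`group` must be "all", "score" or "rank"')
  }
  cells <- split(ef_table, paste(ef_table$context, ef_table$group, sep = "\r"))
  winners <- purrr::map(cells, function(cell) {
    want <- required[[cell$group[1]]]
    if (!setequal(cell$strategy, want) || anyDuplicated(cell$strategy)) {
      abort(sprintf('context "%s" (%s) must carry exactly: %s',
                    cell$context[1], cell$group[1],
                    paste(want, collapse = ", ")))
    }
    if (anyNA(cell$ef)) {
      abort(sprintf('missing EF value in context "%s"', cell$context[1]))
    }
    cell$strategy[cell$ef == max(cell$ef)]
  })
  all_strategies <- unique(ef_table$strategy)
  points <- table(factor(unlist(winners), levels = all_strategies))
  tibble::tibble(strategy = all_strategies,
                 points = as.integer(points[all_strategies]))
}

#' Published benchmark EF2 values for the six consensus strategies
#'
#' EF2 values for the six consensus strategies over the four benchmark
#' systems CDK2, ESR1, ADRB2 and CAH2 — eight individual receptor structures
#' plus the four merged (score- and rank-level) ensembles — shipped as a
#' plain-text table. Formatted as [success_count()] input.
#'
#' @return A tibble with columns `context`, `group`, `strategy`, `ef`.
#' @export
benchmark_ef2 <- function() {
  path <- system.file("extdata", "benchmark_ef2.csv", package = "ecrank",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "cccd", progress = FALSE)
}
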