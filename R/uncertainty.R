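#' Tie-shuffling uncertainty for enrichment metrics
#'
#' Consensus scores can coincide for many molecules — massively so for
#' rank-by-vote, whose score is a small integer vote count, and for the
#' poorly-ranked tail of ECR, where all exponential terms vanish together.
#' The internal order of such a tie group is arbitrary, so any metric that
#' cuts the list at a threshold inherits an uncertainty. This protocol
#' shuffles the order within every tie group uniformly at random (cross-group
#' order stays fixed by consensus score), recomputes the metrics for each
#' shuffle, and reports their mean and standard deviation over `n_shuffles`
#' draws (20 by default).
#'
#' Metrics whose threshold no tie group straddles are unaffected and report
#' a standard deviation of exactly 0.
#'
#' @param result A `consensus_result` (carries the tie groups).
#' @param labels Ligand/decoy label tibble.
#' @param ef Percent thresholds for enrichment factors.
#' @param ep_grid Optional grid of percents: also report the enrichment-curve
#'   recovery at these points.
#' @param auc If `TRUE`, also report the ROC-AUC of each shuffled (strict)
#'   ranking.
#' @param n_shuffles Number of shuffles, at least 2.
#' @param seed Integer seed making the draw reproducible.
#' @return A tibble of class `shuffle_report` with columns `metric`, `mean`,
#'   `sd`; the per-shuffle value matrix is kept in attribute `per_shuffle`.
#' @export
shuffle_evaluate <- function(result, labels, ef = c(1, 2, 5), ep_grid = NULL,
                             auc = FALSE, n_shuffles = 20, seed) {
  if (n_shuffles < 2) abort("`n_shuffles` must be at least 2")
  rk <- join_labels(as_ranking(result), labels)
  rk <- dplyr::arrange(rk, .data$final_rank)
  n <- nrow(rk)
  hits_total <- sum(rk$label == "ligand")
  if (hits_total == 0L) abort("no ligands among ranked molecules")
  is_hit <- rk$label == "ligand"
  group_idx <- split(seq_len(n), rk$tie_group)
  metric_names <- c(paste0("EF", ef),
                    if (!is.null(ep_grid)) paste0("EP", ep_grid),
                    if (auc) "AUC")
  n_top_ef <- vapply(ef, top_n_count, integer(1), n = n)
  n_top_ep <- if (!is.null(ep_grid)) {
    vapply(ep_grid, top_n_count, integer(1), n = n)
  }
  n_dec <- n - hits_total

  one_draw <- function(perm_hits) {
    cum_hits <- cumsum(perm_hits)
    vals <- (cum_hits[n_top_ef] / n_top_ef) * (n / hits_total)
    if (!is.null(ep_grid)) {
      vals <- c(vals, 100 * cum_hits[n_top_ep] / hits_total)
    }
    if (auc) {
      # strict ranking: AUC = P(ligand above decoy) via rank-sum
      if (n_dec == 0L) abort("AUC needs decoys")
      lig_pos <- which(perm_hits)
      auc_val <- 1 - (sum(lig_pos) - hits_total * (hits_total + 1) / 2) /
        (hits_total * n_dec)
      vals <- c(vals, auc_val)
    }
    vals
  }

  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      perm <- seq_len(n)
      for (idx in group_idx) {
        if (length(idx) > 1L) perm[idx] <- idx[sample.int(length(idx))]
      }
      one_draw(is_hit[perm])
    }, numeric(length(metric_names)))
  })
  draws <- matrix(draws, nrow = length(metric_names),
                  dimnames = list(metric_names, NULL))
  out <- tibble::tibble(
    metric = metric_names,
    mean = unname(apply(draws, 1, mean)),
    sd = unname(apply(draws, 1, sd))
  )
  structure(out, class = c("shuffle_report", class(tibble::tibble())),
            per_shuffle = t(draws), n_shuffles = n_shuffles, seed = seed,
            strategy = attr(result, "strategy"))
}
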