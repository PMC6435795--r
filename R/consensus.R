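#' Threshold specifications for ECR and rank-by-vote
#'
#' `sigma_pct(x)` expresses the threshold as a percentage of the dataset size;
#' `sigma_abs(v)` gives it directly in molecules. For ECR the resolved value
#' is the expected value of the exponential kernel, sigma = max(1,
#' round(x/100 * N)) in percent mode; for rank-by-vote the vote cutoff is
#' k = max(1, floor(x/100 * N)).
#'
#' @param value Positive number: percent of the dataset (`sigma_pct`) or an
#'   absolute count of molecules (`sigma_abs`). `sigma_abs` also accepts a
#'   named per-program vector for ECR.
#' @return A `sigma_spec` object.
#' @export
#' @examples
#' sigma_pct(5)   # the conventional 5%-of-dataset threshold
#' sigma_abs(100)
sigma_pct <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || value <= 0) {
    abort("`value` must be a single positive number")
  }
  structure(list(mode = "percent", value = value), class = "sigma_spec")
}

#' @rdname sigma_pct
#' @export
sigma_abs <- function(value) {
  if (!is.numeric(value) || any(value <= 0)) {
    abort("`value` must be positive")
  }
  structure(list(mode = "absolute", value = value), class = "sigma_spec")
}

#' @export
print.sigma_spec <- function(x, ...) {
  unit <- if (x$mode == "percent") "% of dataset" else " molecules"
  cat(sprintf("<sigma_spec> %s%s\n", paste(x$value, collapse = ", "), unit))
  invisible(x)
}

resolve_sigma <- function(sigma, n) {
  if (is.numeric(sigma)) sigma <- sigma_abs(sigma)
  if (!inherits(sigma, "sigma_spec")) {
    abort("`sigma` must be sigma_pct(), sigma_abs(), or a positive number")
  }
  out <- if (sigma$mode == "percent") {
    max(1, round(sigma$value / 100 * n))
  } else {
    sigma$value
  }
  if (any(out <= 0)) abort("resolved sigma must be positive")
  out
}

resolve_vote_cutoff <- function(threshold, n) {
  if (is.numeric(threshold)) threshold <- sigma_pct(threshold)
  k <- if (threshold$mode == "percent") {
    max(1L, as.integer(floor(threshold$value / 100 * n)))
  } else {
    as.integer(threshold$value[1])
  }
  min(k, n)
}

#' Align per-program rank tables on a common molecule set
#'
#' Docking programs occasionally fail to score some molecules, so their rank
#' tables may cover different molecule sets. `align_programs()` reconciles
#' them under one of two policies: `"worst_rank"` (default) keeps the union of
#' molecules and appends each program's missing molecules at the bottom of its
#' ranking (ranks N_j+1, N_j+2, ... in molecule-id order); `"intersect"` keeps
#' only molecules scored by every program and re-ranks within each program.
#'
#' @param ranks A ranks tibble (`molecule_id`, `program`, `rank`).
#' @param policy `"worst_rank"` or `"intersect"`.
#' @param quiet Suppress the message reporting imputed/dropped counts.
#' @return A ranks tibble in which every program ranks the same molecule set.
#' @export
align_programs <- function(ranks, policy = c("worst_rank", "intersect"),
                           quiet = FALSE) {
  policy <- match.arg(policy)
  assert_ranks(ranks)
  sets <- split(ranks$molecule_id, ranks$program)
  if (policy == "intersect") {
    common <- Reduce(intersect, sets)
    if (length(common) == 0L) abort("empty molecule intersection across programs")
    dropped <- length(unique(ranks$molecule_id)) - length(common)
    if (!quiet && dropped > 0) {
      message(sprintf("align_programs: dropped %d molecule(s) not scored by every program",
                      dropped))
    }
    out <- ranks |>
      dplyr::filter(.data$molecule_id %in% common) |>
      dplyr::group_by(.data$program) |>
      dplyr::mutate(rank = ordinal_rank(.data$rank, .data$molecule_id, "lower")) |>
      dplyr::ungroup()
  } else {
    universe <- sort(unique(ranks$molecule_id))
    imputed <- 0L
    out <- purrr::map(names(sets), function(p) {
      tbl <- ranks[ranks$program == p, c("molecule_id", "program", "rank")]
      missing <- setdiff(universe, tbl$molecule_id)
      if (length(missing) > 0) {
        imputed <<- imputed + length(missing)
        tbl <- dplyr::bind_rows(tbl, tibble::tibble(
          molecule_id = sort(missing), program = p,
          rank = nrow(tbl) + seq_along(missing)))
      }
      tbl
    }) |> purrr::list_rbind()
    if (!quiet && imputed > 0) {
      message(sprintf("align_programs: imputed worst ranks for %d missing entries",
                      imputed))
    }
  }
  out <- dplyr::arrange(out, .data$program, .data$rank)
  assert_ranks(out)
}

# ---- consensus result container ----------------------------------------

# Groups molecules whose consensus scores coincide (relative tolerance for
# real-valued scores, exact for integer vote counts) into maximal tie groups.
# `scores_sorted` must already be in final-rank order.
tie_group_ids <- function(scores_sorted, tol = 1e-12) {
  n <- length(scores_sorted)
  if (n == 1L) return(1L)
  d <- abs(diff(scores_sorted))
  scale <- pmax(abs(scores_sorted[-n]), abs(scores_sorted[-1]))
  new_group <- d > tol * pmax(scale, .Machine$double.xmin)
  cumsum(c(TRUE, new_group))
}

new_consensus_result <- function(molecule_id, consensus_score, strategy,
                                 score_direction, params = list(),
                                 tie_exact = FALSE) {
  key <- if (score_direction == "higher") -consensus_score else consensus_score
  ord <- order(key, molecule_id, method = "radix")
  sorted_scores <- consensus_score[ord]
  grp <- if (tie_exact) {
    cumsum(c(TRUE, diff(sorted_scores) != 0))
  } else {
    tie_group_ids(sorted_scores)
  }
  out <- tibble::tibble(
    molecule_id = unname(molecule_id[ord]),
    consensus_score = unname(sorted_scores),
    final_rank = seq_along(ord),
    tie_group = as.integer(grp)
  )
  structure(out,
            class = c("consensus_result", class(tibble::tibble())),
            strategy = strategy,
            score_direction = score_direction,
            params = params)
}

#' @export
print.consensus_result <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<consensus_result> strategy=%s  n=%d  tie groups=%d\n",
              attr(x, "strategy"), nrow(x), max(x$tie_group)))
  if (length(p) > 0) {
    cat("  params:", paste(names(p), unlist(lapply(p, paste, collapse = ",")),
                           sep = "=", collapse = "  "), "\n")
  }
  NextMethod()
}

# wide molecule x program rank matrix from a long aligned ranks tibble
rank_matrix <- function(ranks) {
  assert_ranks(ranks)
  assert_aligned(ranks, "ranks")
  wide <- tidyr::pivot_wider(ranks[c("molecule_id", "program", "rank")],
                             names_from = "program", values_from = "rank")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$molecule_id
  m
}

score_matrix <- function(scores) {
  assert_scores(scores)
  assert_aligned(scores, "scores")
  wide <- tidyr::pivot_wider(scores[c("molecule_id", "program", "score")],
                             names_from = "program", values_from = "score")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$molecule_id
  m
}

# ---- rank-based strategies ---------------------------------------------

#' Exponential consensus ranking (ECR)
#'
#' Scores each molecule by a sum of exponential kernels of its per-program
#' ranks: P(i) = (1/sigma) * sum_j exp(-r_ij / sigma), where r_ij is the rank
#' of molecule i in program j and sigma is the expected value of the
#' exponential kernel, i.e. how deep into each program's ranking the consensus
#' effectively looks. A molecule ranked near the top by *any* program earns a
#' large term from that program alone, so ECR behaves as a conditional "or"
#' across programs — in contrast to averaging strategies, which a single poor
#' rank can sink. Higher P(i) is better; exact score coincidences (typically
#' the poorly-ranked tail, where all kernels underflow together) are recorded
#' as tie groups.
#'
#' @param ranks An aligned ranks tibble (`molecule_id`, `program`, `rank`).
#' @param sigma A [sigma_pct()] / [sigma_abs()] spec (default 5% of the
#'   dataset) or a bare number of molecules. `sigma_abs()` accepts a named
#'   per-program vector for program-specific kernels.
#' @return A `consensus_result` tibble: `molecule_id`, `consensus_score`,
#'   `final_rank`, `tie_group`, with strategy metadata in attributes.
#' @export
#' @examples
#' ranks <- tibble::tibble(
#'   molecule_id = rep(c("A", "B", "C"), 2),
#'   program = rep(c("p1", "p2"), each = 3),
#'   rank = c(1L, 2L, 3L, 3L, 1L, 2L))
#' consensus_ecr(ranks, sigma = sigma_abs(1))
consensus_ecr <- function(ranks, sigma = sigma_pct(5)) {
  m <- rank_matrix(ranks)
  n <- nrow(m)
  s <- resolve_sigma(sigma, n)
  if (length(s) == 1L) {
    sig <- rep(s, ncol(m))
  } else {
    if (is.null(names(s)) || !setequal(names(s), colnames(m))) {
      abort("per-program sigma must be named by program")
    }
    sig <- s[colnames(m)]
  }
  p <- sweep(exp(sweep(m, 2, -1 / sig, `*`)), 2, 1 / sig, `*`)
  new_consensus_result(rownames(m), rowSums(p), "ECR", "higher",
                       params = list(sigma = unname(s),
                                     n_programs = ncol(m)))
}

#' Rank-by-rank consensus (average rank)
#'
#' The consensus score is the arithmetic mean of each molecule's per-program
#' ranks; lower is better. A single very poor rank drags the average down, so
#' unlike ECR this strategy acts as a soft conditional "and".
#'
#' @inheritParams consensus_ecr
#' @return A `consensus_result` tibble.
#' @export
consensus_rbr <- function(ranks) {
  m <- rank_matrix(ranks)
  new_consensus_result(rownames(m), rowMeans(m), "RbR", "lower",
                       params = list(n_programs = ncol(m)))
}

#' Rank-by-vote consensus
#'
#' Each molecule receives one vote from every program that ranks it within
#' the top x% of the dataset; the consensus score is the vote count (0..n
#' programs), higher is better. Because the score takes only n+1 values,
#' large tie groups are expected and the tie-shuffling protocol
#' ([shuffle_evaluate()]) matters most for this strategy.
#'
#' @inheritParams consensus_ecr
#' @param threshold Vote threshold as a [sigma_pct()] spec (default 5% of the
#'   dataset) or a bare percentage. The cutoff rank is
#'   `max(1, floor(x/100 * N))`.
#' @return A `consensus_result` tibble.
#' @export
consensus_rbv <- function(ranks, threshold = sigma_pct(5)) {
  m <- rank_matrix(ranks)
  k <- resolve_vote_cutoff(threshold, nrow(m))
  votes <- rowSums(m <= k)
  new_consensus_result(rownames(m), votes, "RbV", "higher",
                       params = list(cutoff = k, n_programs = ncol(m)),
                       tie_exact = TRUE)
}

# ---- score-based strategies --------------------------------------------

#' Rank-by-number consensus (average raw score)
#'
#' Averages each molecule's raw scores across programs. Raw docking scores
#' carry program-specific units, scales and offsets, so this strategy is
#' biased toward programs whose scores are numerically more negative — the
#' classic failure mode the rescaled and rank-based strategies avoid.
#'
#' @param scores An aligned scores tibble sharing one direction.
#' @return A `consensus_result` tibble.
#' @export
consensus_rbn <- function(scores) {
  dir <- single_direction(scores)
  m <- score_matrix(scores)
  new_consensus_result(rownames(m), rowMeans(m), "RbN", dir,
                       params = list(n_programs = ncol(m)))
}

#' Average of auto-scaled scores (AASS)
#'
#' Rescales each program's scores to [0, 1] using that program's minimum and
#' maximum, then averages across programs. Invariant to per-program positive
#' affine transforms of the scores, which removes unit/offset bias; sensitive
#' to outliers since min and max set the scale.
#'
#' @inheritParams consensus_rbn
#' @return A `consensus_result` tibble. Under a `"lower"` direction the best
#'   possible consensus score is 0.
#' @export
consensus_aass <- function(scores) {
  dir <- single_direction(scores)
  m <- score_matrix(scores)
  rng <- apply(m, 2, range)
  if (any(rng[2, ] == rng[1, ])) {
    abort("a program has constant scores; auto-scaling is undefined")
  }
  scaled <- sweep(sweep(m, 2, rng[1, ], `-`), 2, rng[2, ] - rng[1, ], `/`)
  # after (s - min)/(max - min), small is best iff direction is "lower"
  new_consensus_result(rownames(m), rowMeans(scaled), "AASS", dir,
                       params = list(n_programs = ncol(m)))
}

#' Z-score consensus
#'
#' Standardizes each program's scores by that program's mean and population
#' standard deviation, then averages the standardized scores across programs.
#' Like AASS this is invariant to per-program positive affine transforms.
#'
#' @inheritParams consensus_rbn
#' @return A `consensus_result` tibble.
#' @export
consensus_zscore <- function(scores) {
  dir <- single_direction(scores)
  m <- score_matrix(scores)
  mu <- colMeans(m)
  sig <- sqrt(colMeans(sweep(m, 2, mu)^2))  # population sd
  if (any(sig == 0)) abort("a program has zero score variance")
  z <- sweep(sweep(m, 2, mu), 2, sig, `/`)
  new_consensus_result(rownames(m), rowMeans(z), "Zscore", dir,
                       params = list(n_programs = ncol(m)))
}

#' Random scoring function (RSF)
#'
#' A synthetic "docking program" assigning i.i.d. standard-normal scores to
#' each molecule. It models an engine with no discriminative power (expected
#' ROC-AUC 0.5) and serves as a negative control when assessing how consensus
#' strategies cope with a broken program.
#'
#' @param molecule_ids Character vector of molecule ids.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @param program_id Program label, default `"RSF"`.
#' @return A scores tibble with direction `"lower"`.
#' @export
random_scoring_function <- function(molecule_ids, seed, program_id = "RSF") {
  if (length(molecule_ids) == 0L) abort("`molecule_ids` is empty")
  if (anyDuplicated(molecule_ids)) abort("duplicated molecule ids")
  score <- withr::with_seed(seed, rnorm(length(molecule_ids)))
  tibble::tibble(molecule_id = as.character(molecule_ids),
                 program = program_id, score = score, direction = "lower")
}

#' Run one consensus strategy by name
#'
#' Dispatch helper used by the pipeline and CLI: rank-based strategies
#' (`"ecr"`, `"rbr"`, `"rbv"`) consume ranks computed from `scores`;
#' score-based strategies (`"rbn"`, `"aass"`, `"zscore"`) consume the scores
#' directly.
#'
#' @param scores An aligned scores tibble.
#' @param strategy One of `"ecr"`, `"rbr"`, `"rbv"`, `"rbn"`, `"aass"`,
#'   `"zscore"`.
#' @param sigma,threshold Passed to [consensus_ecr()] / [consensus_rbv()].
#' @return A `consensus_result` tibble.
#' @export
run_strategy <- function(scores, strategy, sigma = sigma_pct(5),
                         threshold = sigma_pct(5)) {
  strategy <- match.arg(tolower(strategy),
                        c("ecr", "rbr", "rbv", "rbn", "aass", "zscore"))
  if (strategy %in% c("ecr", "rbr", "rbv")) {
    ranks <- score_to_ranks(scores)
    switch(strategy,
           ecr = consensus_ecr(ranks, sigma = sigma),
           rbr = consensus_rbr(ranks),
           rbv = consensus_rbv(ranks, threshold = threshold))
  } else {
    switch(strategy,
           rbn = consensus_rbn(scores),
           aass = consensus_aass(scores),
           zscore = consensus_zscore(scores))
  }
}
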