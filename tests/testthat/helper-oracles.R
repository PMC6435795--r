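# Independent brute-force oracles, written straight from the definitions with
# explicit loops. They deliberately share no code with the package internals.

# ordinal ranks: best score first under `direction`, ties by ascending id
oracle_ranks <- function(score, ids, direction = "lower") {
  key <- if (direction == "lower") score else -score
  ord <- order(key, ids)
  r <- integer(length(ids))
  r[ord] <- seq_along(ids)
  names(r) <- ids
  r
}

# final ordering of ids by a consensus score vector (ties by id)
oracle_order <- function(score, ids, higher_better) {
  key <- if (higher_better) -score else score
  ids[order(key, ids)]
}

oracle_ecr <- function(rank_mat, sigma) {
  p <- numeric(nrow(rank_mat))
  for (i in seq_len(nrow(rank_mat))) {
    for (j in seq_len(ncol(rank_mat))) {
      p[i] <- p[i] + exp(-rank_mat[i, j] / sigma) / sigma
    }
  }
  names(p) <- rownames(rank_mat)
  p
}

oracle_rbr <- function(rank_mat) {
  out <- numeric(nrow(rank_mat))
  for (i in seq_len(nrow(rank_mat))) out[i] <- mean(rank_mat[i, ])
  names(out) <- rownames(rank_mat)
  out
}

oracle_rbv <- function(rank_mat, k) {
  out <- numeric(nrow(rank_mat))
  for (i in seq_len(nrow(rank_mat))) out[i] <- sum(rank_mat[i, ] <= k)
  names(out) <- rownames(rank_mat)
  out
}

oracle_rbn <- function(score_mat) {
  out <- numeric(nrow(score_mat))
  for (i in seq_len(nrow(score_mat))) out[i] <- mean(score_mat[i, ])
  names(out) <- rownames(score_mat)
  out
}

oracle_aass <- function(score_mat) {
  out <- numeric(nrow(score_mat))
  for (i in seq_len(nrow(score_mat))) {
    acc <- 0
    for (j in seq_len(ncol(score_mat))) {
      smin <- min(score_mat[, j]); smax <- max(score_mat[, j])
      acc <- acc + (score_mat[i, j] - smin) / (smax - smin)
    }
    out[i] <- acc / ncol(score_mat)
  }
  names(out) <- rownames(score_mat)
  out
}

oracle_zscore <- function(score_mat) {
  out <- numeric(nrow(score_mat))
  for (i in seq_len(nrow(score_mat))) {
    acc <- 0
    for (j in seq_len(ncol(score_mat))) {
      mu <- mean(score_mat[, j])
      sig <- sqrt(mean((score_mat[, j] - mu)^2))  # population sd
      acc <- acc + (score_mat[i, j] - mu) / sig
    }
    out[i] <- acc / ncol(score_mat)
  }
  names(out) <- rownames(score_mat)
  out
}

# AUC as the fraction of (ligand, decoy) pairs ordered correctly, ties 1/2.
# `score` is a consensus score where higher_better says which end is best.
oracle_pairwise_auc <- function(score, is_ligand, higher_better = FALSE) {
  lig <- which(is_ligand); dec <- which(!is_ligand)
  total <- 0
  for (i in lig) {
    for (d in dec) {
      better <- if (higher_better) score[i] > score[d] else score[i] < score[d]
      equal <- score[i] == score[d]
      total <- total + if (equal) 0.5 else as.numeric(better)
    }
  }
  total / (length(lig) * length(dec))
}

# Expected EFx over all equally-likely orderings within tie groups, by full
# enumeration. `groups` is a list of character vectors (tie groups) in final
# score order; labels is a named label vector.
oracle_tie_ef_expectation <- function(groups, labels, x) {
  n <- length(unlist(groups))
  hits_total <- sum(labels == "ligand")
  n_top <- max(1, floor(x / 100 * n))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  per_group <- lapply(groups, perms)
  idx <- lapply(per_group, seq_along)
  grid <- expand.grid(idx)
  efs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ordering <- character(0)
    for (k in seq_along(groups)) {
      ordering <- c(ordering, per_group[[k]][[grid[g, k]]])
    }
    hits <- sum(labels[ordering[seq_len(n_top)]] == "ligand")
    efs[g] <- (hits / n_top) * (n / hits_total)
  }
  mean(efs)
}
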