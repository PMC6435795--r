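test_that("sigma and vote thresholds resolve with the documented rounding", {
  # percent-mode sigma: max(1, round(x/100 * N)); vote cutoff: max(1, floor())
  expect_equal(ecrank:::resolve_sigma(sigma_pct(5), 2000), 100)
  expect_equal(ecrank:::resolve_sigma(sigma_pct(5), 9), 1)   # round(0.45) -> 0 -> floor at 1
  expect_equal(ecrank:::resolve_sigma(sigma_abs(7), 2000), 7)
  expect_equal(ecrank:::resolve_vote_cutoff(sigma_pct(5), 100), 5L)
  expect_equal(ecrank:::resolve_vote_cutoff(sigma_pct(5), 119), 5L)
  expect_equal(ecrank:::resolve_vote_cutoff(sigma_pct(0.01), 100), 1L)
  expect_error(consensus_ecr(make_ranks(p = c(A = 1, B = 2)), sigma = -1),
               "positive")
})

test_that("align_programs applies intersect and worst-rank policies", {
  rks <- make_ranks(p1 = c(A = 1, B = 2, C = 3, D = 4),
                    p2 = c(A = 2, B = 1, C = 3))
  ints <- suppressMessages(align_programs(rks, "intersect"))
  expect_false("D" %in% ints$molecule_id)
  expect_setequal(ints$rank[ints$program == "p1"], 1:3)
  worst <- suppressMessages(align_programs(rks, "worst_rank"))
  expect_equal(worst$rank[worst$program == "p2" & worst$molecule_id == "D"], 4L)
  # identical sets pass through unchanged
  same <- make_ranks(p1 = c(A = 1, B = 2), p2 = c(A = 2, B = 1))
  expect_equal(dplyr::arrange(align_programs(same), program, molecule_id),
               dplyr::arrange(same, program, molecule_id))
  disjoint <- make_ranks(p1 = c(A = 1), p2 = c(B = 1))
  expect_error(align_programs(disjoint, "intersect"), "empty")
})

test_that("ECR matches hand-computed exponential sums", {
  rks <- make_ranks(p1 = c(A = 1, B = 2, C = 3), p2 = c(A = 3, B = 1, C = 2))
  res <- consensus_ecr(rks, sigma = sigma_abs(1))
  scores <- setNames(res$consensus_score, res$molecule_id)
  expect_equal(scores[["A"]], exp(-1) + exp(-3), tolerance = 1e-12)
  expect_equal(scores[["B"]], exp(-2) + exp(-1), tolerance = 1e-12)
  expect_equal(scores[["C"]], exp(-3) + exp(-2), tolerance = 1e-12)
  expect_equal(res$molecule_id, c("B", "A", "C"))
})

test_that("ECR acts as a conditional 'or' where averaging strategies do not", {
  # X is top-ranked by three of four programs but bottom-ranked by the fourth;
  # Y is uniformly mediocre. With sigma = 10 ECR prefers X, RbR prefers Y.
  ids <- c("X", "Y", paste0("F", sprintf("%03d", 1:998)))
  rks <- purrr::map(1:4, function(j) {
    others <- setdiff(ids, c("X", "Y"))
    if (j < 4) {
      r <- c(X = 1, Y = 10,
             setNames(setdiff(seq_len(1000), c(1, 10)), others))
    } else {
      r <- c(X = 1000, Y = 10,
             setNames(setdiff(seq_len(1000), c(1000, 10)), others))
    }
    tibble::tibble(molecule_id = names(r), program = paste0("p", j),
                   rank = as.integer(r))
  }) |> purrr::list_rbind()
  ecr <- consensus_ecr(rks, sigma = sigma_abs(10))
  rbr <- consensus_rbr(rks)
  sx <- ecr$consensus_score[ecr$molecule_id == "X"]
  sy <- ecr$consensus_score[ecr$molecule_id == "Y"]
  expect_equal(sx * 10, 3 * exp(-0.1) + exp(-100), tolerance = 1e-12)
  expect_equal(sy * 10, 4 * exp(-1), tolerance = 1e-12)
  expect_lt(ecr$final_rank[ecr$molecule_id == "X"],
            ecr$final_rank[ecr$molecule_id == "Y"])
  mx <- rbr$consensus_score[rbr$molecule_id == "X"]
  expect_equal(mx, 250.75)
  expect_lt(rbr$final_rank[rbr$molecule_id == "Y"],
            rbr$final_rank[rbr$molecule_id == "X"])
})

test_that("RbV counts votes at the resolved cutoff and degenerates gracefully", {
  # N = 100, x = 5 -> cutoff 5; ranks (3, 80) earn exactly one vote
  ids <- sprintf("m%03d", 1:100)
  r1 <- setNames(seq_len(100), ids)                       # m001 ranked 3 via swap
  r1[c("m001", "m003")] <- c(3L, 1L)
  r2 <- setNames(seq_len(100), ids)
  r2[c("m001", "m080")] <- c(80L, 1L)
  rks <- make_ranks(p1 = r1, p2 = r2)
  res <- consensus_rbv(rks, threshold = sigma_pct(5))
  expect_equal(res$consensus_score[res$molecule_id == "m001"], 1)
  # every program ranking a molecule first gives it the full n votes
  top <- res$molecule_id[res$final_rank == 1]
  expect_equal(consensus_rbv(make_ranks(p1 = c(A = 1, B = 2), p2 = c(A = 1, B = 2)),
                             sigma_pct(50))$consensus_score[1], 2)
  # cutoff = N collapses everything into one global tie group
  all_votes <- consensus_rbv(rks, threshold = sigma_pct(100))
  expect_equal(unique(all_votes$consensus_score), 2)
  expect_equal(unique(all_votes$tie_group), 1L)
})

test_that("single-program consensus reduces to the input ordering", {
  rks <- make_ranks(p = c(C = 1, A = 2, B = 3))
  for (res in list(consensus_ecr(rks, sigma_abs(2)), consensus_rbr(rks))) {
    expect_equal(res$molecule_id[res$final_rank], c("C", "A", "B"))
  }
  tbl <- make_scores(p = c(C = -9, A = -5, B = -1))
  for (res in list(consensus_rbn(tbl), consensus_zscore(tbl))) {
    expect_equal(res$molecule_id[res$final_rank], c("C", "A", "B"))
  }
})

test_that("Z-score uses the population standard deviation", {
  tbl <- make_scores(p = c(A = -1, B = 0, C = 1))
  res <- consensus_zscore(tbl)
  scores <- setNames(res$consensus_score, res$molecule_id)
  expect_equal(scores[["A"]], -1 / sqrt(2 / 3), tolerance = 1e-12)  # -1.2247
  expect_equal(scores[["B"]], 0, tolerance = 1e-12)
  expect_equal(scores[["C"]], 1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_error(consensus_zscore(make_scores(p1 = c(A = 1, B = 1),
                                            p2 = c(A = 0, B = 1))), "variance")
})

test_that("AASS rescales each program to [0, 1] by its min and max", {
  tbl <- make_scores(p = c(A = -12, B = -7, C = -2))
  res <- consensus_aass(tbl)
  expect_equal(res$consensus_score[res$molecule_id == "B"], 0.5)
  expect_equal(res$consensus_score[res$molecule_id == "A"], 0)
  expect_equal(res$final_rank[res$molecule_id == "A"], 1L)
  expect_error(consensus_aass(make_scores(p1 = c(A = 1, B = 1),
                                          p2 = c(A = 0, B = 1))), "constant")
})

test_that("RbN averages raw scores and is dominated by a shifted program", {
  tbl <- make_scores(p1 = c(A = -10, B = -2), p2 = c(A = -8, B = -4))
  res <- consensus_rbn(tbl)
  expect_equal(res$consensus_score[res$molecule_id == "A"], -9)
  # shift one program by -1000: its ordering now decides the consensus
  base <- make_scores(p1 = c(A = -1, B = -2, C = -3),   # prefers C
                      p2 = c(A = -3, B = -2, C = -1))   # prefers A
  shifted <- dplyr::mutate(base, score = ifelse(program == "p2",
                                                score - 1000, score))
  res_shift <- consensus_rbn(shifted)
  expect_equal(res_shift$molecule_id[res_shift$final_rank], c("A", "B", "C"))
  expect_error(consensus_rbn(dplyr::mutate(base, direction =
    ifelse(program == "p2", "higher", "lower"))), "direction")
})

test_that("each strategy's final ranking equals brute-force recomputation", {
  cases <- expand.grid(n_mol = c(3, 5, 6), n_prog = c(1, 2, 3), seed = 1:4)
  for (case in seq_len(nrow(cases))) {
    inst <- random_instance(cases$n_mol[case], cases$n_prog[case],
                            seed = 1000 + case)
    ids <- sort(names(inst[[1]]))
    tbl <- do.call(make_scores, inst)
    rank_mat <- sapply(inst, function(v) oracle_ranks(v, names(v))[ids])
    rank_mat <- matrix(rank_mat, nrow = length(ids),
                       dimnames = list(ids, names(inst)))
    score_mat <- sapply(inst, function(v) v[ids])
    score_mat <- matrix(score_mat, nrow = length(ids),
                        dimnames = list(ids, names(inst)))
    rks <- score_to_ranks(tbl)
    sigma <- 2; k <- 2
    got <- list(
      ECR = consensus_ecr(rks, sigma_abs(sigma)),
      RbR = consensus_rbr(rks),
      RbV = consensus_rbv(rks, sigma_abs(k)),
      RbN = consensus_rbn(tbl),
      AASS = consensus_aass(tbl),
      Zscore = consensus_zscore(tbl))
    want <- list(
      ECR = oracle_order(oracle_ecr(rank_mat, sigma), ids, TRUE),
      RbR = oracle_order(oracle_rbr(rank_mat), ids, FALSE),
      RbV = oracle_order(oracle_rbv(rank_mat, k), ids, TRUE),
      RbN = oracle_order(oracle_rbn(score_mat), ids, FALSE),
      AASS = oracle_order(oracle_aass(score_mat), ids, FALSE),
      Zscore = oracle_order(oracle_zscore(score_mat), ids, FALSE))
    for (s in names(got)) {
      expect_equal(got[[s]]$molecule_id, want[[s]],
                   label = sprintf("%s case %d", s, case))
    }
  }
})

test_that("rank-based strategies ignore monotone score transforms; rescaled score strategies ignore affine ones", {
  for (seed in 1:5) {
    inst <- random_instance(7, 3, seed = 2000 + seed)
    tbl <- do.call(make_scores, inst)
    # strictly monotone per-program transform (exp is monotone increasing)
    warped <- tbl |>
      dplyr::group_by(program) |>
      dplyr::mutate(score = exp(score) * match(program[1], names(inst))) |>
      dplyr::ungroup()
    affine <- tbl |>
      dplyr::group_by(program) |>
      dplyr::mutate(score = score * (1 + match(program[1], names(inst))) - 10) |>
      dplyr::ungroup()
    for (f in list(function(x) consensus_ecr(score_to_ranks(x), sigma_abs(2)),
                   function(x) consensus_rbr(score_to_ranks(x)),
                   function(x) consensus_rbv(score_to_ranks(x), sigma_abs(2)))) {
      expect_equal(f(warped)$molecule_id, f(tbl)$molecule_id)
    }
    for (f in list(consensus_aass, consensus_zscore)) {
      expect_equal(f(affine)$molecule_id, f(tbl)$molecule_id)
      expect_equal(f(affine)$consensus_score, f(tbl)$consensus_score,
                   tolerance = 1e-10)
    }
  }
  # witness: RbN is not affine-invariant (see the shifted-program test above)
})

test_that("dropping the 1/sigma prefactor never changes the ECR ranking", {
  for (seed in 1:5) {
    inst <- random_instance(8, 3, seed = 3000 + seed)
    rks <- score_to_ranks(do.call(make_scores, inst))
    res <- consensus_ecr(rks, sigma_abs(3))
    m <- ecrank:::rank_matrix(rks)
    noprefactor <- rowSums(exp(-m / 3))
    ids <- names(sort(-noprefactor))
    # resolve exact ties as the package does: descending score, then id
    ord <- order(-noprefactor, rownames(m))
    expect_equal(res$molecule_id, rownames(m)[ord])
  }
})

test_that("random scoring function is seed-reproducible and uninformative", {
  ids <- sprintf("m%04d", 1:400)
  a <- random_scoring_function(ids, seed = 42)
  b <- random_scoring_function(ids, seed = 42)
  expect_identical(a, b)
  c <- random_scoring_function(ids, seed = 43)
  expect_false(identical(a$score, c$score))
  # on labelled screens RSF hovers at AUC 0.5
  aucs <- vapply(1:10, function(s) {
    scr <- synthetic_screen(n_molecules = 400, seed = s)
    rsf <- random_scoring_function(scr$labels$molecule_id, seed = 100 + s)
    roc_auc(score_to_ranks(rsf), scr$labels)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("ECR ties are confined to coinciding/underflowed scores while RbV ties span the list", {
  scr <- synthetic_screen(n_molecules = 1500, seed = 11)
  rks <- score_to_ranks(scr$scores)
  # at the practical 5%-of-dataset sigma every molecule is distinguishable
  ecr <- consensus_ecr(rks, sigma_pct(5))
  expect_equal(max(table(ecr$tie_group)), 1L)
  # an extreme sigma = 1 molecule underflows the whole poorly-ranked tail to
  # an exact zero score: one tie group at the very bottom of the list
  tiny <- consensus_ecr(rks, sigma_abs(1))
  zero <- tidy(tiny)[tiny$consensus_score == 0, ]
  expect_gt(nrow(zero), 50)
  expect_equal(dplyr::n_distinct(zero$tie_group), 1L)
  expect_gt(min(zero$final_rank), 0.8 * nrow(tiny))
  # RbV at the same threshold: votes take at most n_programs + 1 values and
  # a single vote count covers most of the dataset
  rbv <- consensus_rbv(rks, sigma_pct(5))
  sizes <- table(rbv$tie_group)
  expect_lte(length(sizes), 7)
  expect_gt(max(sizes), nrow(rbv) / 2)
})
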