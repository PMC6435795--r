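#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML (or equivalent list) naming the per-program,
#' per-structure score tables, the label table, the strategies to run and
#' their thresholds. See [run_pipeline()] for the recognized fields.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, base_dir = dirname(path))
}

validate_run_config <- function(cfg, base_dir = ".") {
  fail <- function(field, msg) abort(sprintf("config field `%s`: %s", field, msg))
  if (is.null(cfg$seed)) fail("seed", "required")
  if (is.null(cfg$labels)) fail("labels", "required")
  if (is.null(cfg$programs) || length(cfg$programs) == 0) {
    fail("programs", "at least one program required")
  }
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  cfg$labels <- resolve(cfg$labels)
  for (i in seq_along(cfg$programs)) {
    prog <- cfg$programs[[i]]
    if (is.null(prog$id)) fail(sprintf("programs[%d].id", i), "required")
    if (is.null(prog$tables) || length(prog$tables) == 0) {
      fail(sprintf("programs[%d].tables", i),
           "map of structure id to score-table path required")
    }
    cfg$programs[[i]]$direction <- prog$direction %||% "lower"
    check_direction(cfg$programs[[i]]$direction)
    cfg$programs[[i]]$tables <- lapply(prog$tables, resolve)
  }
  cfg$strategies <- tolower(cfg$strategies %||%
                              c("ecr", "rbr", "rbv", "rbn", "aass", "zscore"))
  bad <- setdiff(cfg$strategies, c("ecr", "rbr", "rbv", "rbn", "aass", "zscore"))
  if (length(bad) > 0) fail("strategies", paste("unknown:", paste(bad, collapse = ", ")))
  cfg$sigma_percent <- cfg$sigma_percent %||% 5
  cfg$vote_percent <- cfg$vote_percent %||% 5
  cfg$ms_mode <- match.arg(cfg$ms_mode %||% "auto", c("auto", "rank", "score"))
  cfg$missing <- match.arg(cfg$missing %||% "worst_rank",
                           c("worst_rank", "intersect"))
  cfg$ef <- cfg$ef %||% c(1, 2, 5)
  cfg$shuffle_n <- cfg$shuffle_n %||% 20
  cfg$output_dir <- cfg$output_dir %||% "ecrank-out"
  structure(cfg, class = "run_config")
}

# rank route: per-structure ranks -> within-program alignment -> rank-MS ->
# cross-program alignment. Returns an aligned long ranks tibble.
prepare_rank_route <- function(tables, missing, quiet = TRUE) {
  per_program <- purrr::imap(tables, function(scores, id) {
    ranks <- score_to_ranks(scores)
    if ("structure" %in% names(ranks) &&
        dplyr::n_distinct(ranks$structure) > 1L) {
      # align structures within the program, reusing the cross-program policy
      as_prog <- dplyr::transmute(ranks, molecule_id = .data$molecule_id,
                                  program = .data$structure, rank = .data$rank)
      aligned <- align_programs(as_prog, policy = missing, quiet = quiet)
      merged <- merge_shrink_rank(tibble::tibble(
        molecule_id = aligned$molecule_id, program = id,
        structure = aligned$program, rank = aligned$rank))
      merged[c("molecule_id", "program", "rank")]
    } else {
      ranks[c("molecule_id", "program", "rank")]
    }
  })
  align_programs(purrr::list_rbind(per_program), policy = missing, quiet = quiet)
}

# score route: score-MS within program (best score over structures where the
# molecule was scored), then cross-program restriction to the policy set.
prepare_score_route <- function(tables, missing, quiet = TRUE) {
  per_program <- purrr::map(tables, function(scores) {
    if ("structure" %in% names(scores) &&
        dplyr::n_distinct(scores$structure) > 1L) {
      sets <- split(scores$molecule_id, scores$structure)
      common <- Reduce(intersect, sets)
      if (missing == "intersect") {
        scores <- scores[scores$molecule_id %in% common, ]
      }
      # best score over the structures that scored the molecule
      scores |>
        dplyr::group_by(.data$molecule_id, .data$program, .data$direction) |>
        dplyr::summarise(score = if (.data$direction[1] == "lower") {
          min(.data$score)
        } else {
          max(.data$score)
        }, .groups = "drop") |>
        dplyr::select(dplyr::all_of(c("molecule_id", "program", "score",
                                      "direction")))
    } else {
      scores[c("molecule_id", "program", "score", "direction")]
    }
  })
  long <- purrr::list_rbind(per_program)
  sets <- split(long$molecule_id, long$program)
  keep <- Reduce(intersect, sets)
  if (length(keep) == 0L) abort("empty molecule intersection across programs")
  dropped <- length(unique(long$molecule_id)) - length(keep)
  if (!quiet && dropped > 0) {
    message(sprintf("score route: dropped %d molecule(s) lacking a score in some program",
                    dropped))
  }
  long[long$molecule_id %in% keep, ]
}

#' Run the full consensus screening workflow
#'
#' Executes the recommended ensemble-docking consensus workflow end to end:
#' read per-program (and per-structure) score tables, merge receptor
#' ensembles by the merging-and-shrinking procedure, compute the requested
#' consensus strategies, and evaluate each against the ligand/decoy labels
#' (enrichment factors with tie-shuffle mean and standard deviation, and
#' ROC-AUC). Rank-level merging feeds the rank-based strategies (RbR, RbV,
#' ECR) and score-level merging the score-based ones (RbN, AASS, Z-score);
#' `ms_mode = "auto"` applies this pairing, while forcing `"rank"` or
#' `"score"` restricts the run to the compatible strategy group when
#' ensembles are present.
#'
#' @param config A `run_config` (from [read_run_config()]), a path to a YAML
#'   config, or a plain list with the same fields: `seed`, `labels`,
#'   `programs` (each with `id`, `direction`, `tables` = structure-to-path
#'   map), and optionally `strategies`, `sigma_percent`, `vote_percent`,
#'   `ms_mode`, `missing`, `ef`, `shuffle_n`, `output_dir`.
#' @param output_dir Overrides the config's output directory; `NULL` disables
#'   writing and returns results invisibly only.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list with `consensus` (named list of
#'   `consensus_result`s), `metrics` (long tibble: strategy, metric, value,
#'   sd), `resolved` (resolved thresholds) and `paths` (written files).
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  labels <- read_labels(config$labels)
  tables <- purrr::map(config$programs, function(prog) {
    tbls <- purrr::imap(prog$tables, function(path, structure_id) {
      read_score_table(path, program_id = prog$id,
                       direction = prog$direction,
                       structure_id = structure_id, collapse = "best")
    })
    purrr::list_rbind(tbls)
  })
  names(tables) <- vapply(config$programs, `[[`, "", "id")
  has_ensemble <- any(vapply(tables, function(t) {
    "structure" %in% names(t) && dplyr::n_distinct(t$structure) > 1L
  }, logical(1)))

  groups <- strategy_groups()
  rank_strats <- intersect(config$strategies, tolower(groups$rank))
  score_strats <- intersect(config$strategies, tolower(groups$score))
  if (has_ensemble && config$ms_mode == "rank" && length(score_strats) > 0) {
    abort("ms_mode = 'rank' cannot feed score-based strategies; drop them or use auto")
  }
  if (has_ensemble && config$ms_mode == "score" && length(rank_strats) > 0) {
    abort("ms_mode = 'score' cannot feed rank-based strategies; drop them or use auto")
  }

  results <- list()
  if (length(rank_strats) > 0) {
    ranks <- prepare_rank_route(tables, config$missing, quiet = quiet)
    if (has_ensemble) say("rank-level merging and shrinking applied (%s strategies)",
                          paste(rank_strats, collapse = ", "))
    n <- dplyr::n_distinct(ranks$molecule_id)
    say("sigma resolved to %d molecules; vote cutoff %d of %d",
        resolve_sigma(sigma_pct(config$sigma_percent), n),
        resolve_vote_cutoff(sigma_pct(config$vote_percent), n), n)
    for (s in rank_strats) {
      results[[s]] <- switch(s,
        ecr = consensus_ecr(ranks, sigma = sigma_pct(config$sigma_percent)),
        rbr = consensus_rbr(ranks),
        rbv = consensus_rbv(ranks, threshold = sigma_pct(config$vote_percent)))
    }
  }
  if (length(score_strats) > 0) {
    scores <- prepare_score_route(tables, config$missing, quiet = quiet)
    if (has_ensemble) say("score-level merging and shrinking applied (%s strategies)",
                          paste(score_strats, collapse = ", "))
    for (s in score_strats) {
      results[[s]] <- switch(s,
        rbn = consensus_rbn(scores),
        aass = consensus_aass(scores),
        zscore = consensus_zscore(scores))
    }
  }

  metrics <- purrr::imap(results, function(res, s) {
    rep <- shuffle_evaluate(res, labels, ef = config$ef, auc = TRUE,
                            n_shuffles = config$shuffle_n, seed = config$seed)
    dplyr::mutate(tibble::as_tibble(rep), strategy = s, .before = 1)
  }) |> purrr::list_rbind()

  out_dir <- if (missing(output_dir)) config$output_dir else output_dir
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(results)) {
      p <- file.path(out_dir, sprintf("consensus_%s.csv", s))
      readr::write_csv(tidy(results[[s]]), p)
      paths <- c(paths, p)
    }
    p <- file.path(out_dir, "metrics.csv")
    readr::write_csv(metrics, p)
    paths <- c(paths, p)
    summary <- list(
      seed = config$seed,
      strategies = config$strategies,
      sigma_percent = config$sigma_percent,
      vote_percent = config$vote_percent,
      ms_mode = config$ms_mode,
      missing = config$missing,
      n_shuffles = config$shuffle_n,
      metrics = metrics
    )
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
    say("wrote %d file(s) to %s", length(paths), out_dir)
  }
  invisible(list(consensus = results, metrics = metrics, paths = paths,
                 labels = labels))
}
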