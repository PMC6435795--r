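# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a consensus result
#'
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @return The underlying tibble (`molecule_id`, `consensus_score`,
#'   `final_rank`, `tie_group`) plus a `strategy` column.
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$strategy <- attr(x, "strategy")
  out
}

#' One-row summary of a consensus result
#'
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @return A one-row tibble: strategy, number of molecules and programs,
#'   number of tie groups and the size of the largest one, plus resolved
#'   sigma / vote cutoff where applicable.
#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    strategy = attr(x, "strategy"),
    n_molecules = nrow(x),
    n_programs = p$n_programs %||% NA_integer_,
    n_tie_groups = max(x$tie_group),
    max_tie_group = max(table(x$tie_group)),
    sigma = if (!is.null(p$sigma)) p$sigma[1] else NA_real_,
    vote_cutoff = p$cutoff %||% NA_integer_
  )
}

#' @method tidy shuffle_report
#' @export
tidy.shuffle_report <- function(x, ...) tibble::as_tibble(x)

#' @method glance shuffle_report
#' @export
glance.shuffle_report <- function(x, ...) {
  tibble::tibble(strategy = attr(x, "strategy") %||% NA_character_,
                 n_shuffles = attr(x, "n_shuffles"),
                 seed = attr(x, "seed"))
}

#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_points = nrow(x))
}

#' Plot an enrichment curve
#'
#' Percentage of ligands recovered against percentage of the ranked dataset
#' screened; the dotted diagonal is the random-screening expectation.
#'
#' @param object An `enrichment_curve` (see [enrichment_curve()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_curve
#' @export
autoplot.enrichment_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$percent_screened,
                               y = .data$percent_ligands)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "% of dataset screened", y = "% of ligands recovered") +
    ggplot2::coord_cartesian(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_curve` (see [roc_curve()]); the AUC is shown in the
#'   subtitle.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot the consensus score profile of a ranking
#'
#' Consensus score against final rank, with tie groups of more than one
#' molecule highlighted — a quick visual of where a strategy's ranking is
#' actually undetermined (for rank-by-vote this typically covers the whole
#' list; for ECR only the tail).
#'
#' @param object A `consensus_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$tied <- duplicated(df$tie_group) | duplicated(df$tie_group, fromLast = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$final_rank,
                                   y = .data$consensus_score,
                                   colour = .data$tied)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 name = "in tie group") +
    ggplot2::labs(x = "Final rank", y = "Consensus score",
                  title = attr(object, "strategy")) +
    ggplot2::theme_minimal()
}
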