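#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a classification outcome
#'
#' One row per repetition with its test accuracy.
#'
#' @param x a `classification_outcome`.
#' @param ... unused.
#' @return tibble: `approach`, `condition`, `band`, `repetition`,
#'   `accuracy`.
#' @export
tidy.classification_outcome <- function(x, ...) {
  tibble::tibble(approach = x$approach, condition = x$condition,
                 band = x$band %||% NA_character_,
                 repetition = seq_along(x$accuracies),
                 accuracy = x$accuracies)
}

#' One-row summary of a classification outcome
#'
#' @param x a `classification_outcome`.
#' @param ... unused.
#' @return tibble: mean/sd accuracy, repetitions, chance level.
#' @export
glance.classification_outcome <- function(x, ...) {
  tibble::tibble(approach = x$approach, condition = x$condition,
                 band = x$band %||% NA_character_,
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = stats::sd(x$accuracies),
                 n_repetitions = length(x$accuracies),
                 chance = 1 / x$n_classes)
}

#' Tidy an ICA decomposition
#'
#' @param x a `decomposition`.
#' @param ... unused.
#' @return tibble: `component`, `variance_share`.
#' @export
tidy.decomposition <- function(x, ...) {
  tibble::tibble(component = seq_along(x$variance_share),
                 variance_share = x$variance_share)
}

#' Tidy a CSP result
#'
#' @param x a `csp_result`.
#' @param ... unused.
#' @return tibble: `filter`, `class` (the one-vs-rest problem it came
#'   from), `variance_ratio`.
#' @export
tidy.csp_result <- function(x, ...) {
  tibble::tibble(filter = seq_along(x$eigenvalues), class = x$classes,
                 variance_ratio = x$eigenvalues)
}

#' Tidy an experiment report
#'
#' @param x an `experiment_report`.
#' @param ... unused.
#' @return the per-participant accuracy tibble.
#' @export
tidy.experiment_report <- function(x, ...) x$accuracies

#' Condition-level summary of an experiment report
#'
#' @param x an `experiment_report`.
#' @param ... unused.
#' @return tibble: approach, condition, mean accuracy across participants.
#' @export
glance.experiment_report <- function(x, ...) {
  x$accuracies |>
    dplyr::group_by(.data$approach, .data$condition) |>
    dplyr::summarise(mean_accuracy = mean(.data$mean_accuracy),
                     n_participants = dplyr::n(), .groups = "drop")
}
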