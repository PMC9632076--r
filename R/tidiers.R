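#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ABC model-choice result
#'
#' @param x An `abc_result`.
#' @param ... Unused.
#' @return Tibble with one row per model: `model`, `n_accepted`,
#'   `posterior`.
#' @method tidy abc_result
#' @export
tidy.abc_result <- function(x, ...) x$posterior

#' @rdname tidy.abc_result
#' @method glance abc_result
#' @export
glance.abc_result <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_accepted = x$n_accepted,
                 tolerance = x$tolerance, n_models = nrow(x$posterior),
                 best_model = abc_best_model(x),
                 max_posterior = max(x$posterior$posterior))
}

#' Tidy an ABC cross-validation confusion matrix
#'
#' @param x An `abc_cv`.
#' @param ... Unused.
#' @return Long tibble `true_model`, `assigned_model`, `n`, `rate`.
#' @method tidy abc_cv
#' @export
tidy.abc_cv <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$rate <- out$n / attr(x, "n_pseudo")
  out
}

#' @rdname tidy.abc_cv
#' @method glance abc_cv
#' @export
glance.abc_cv <- function(x, ...) {
  correct <- sum(x$n[as.character(x$true_model) ==
                       as.character(x$assigned_model)])
  tibble::tibble(n_pseudo = attr(x, "n_pseudo"),
                 tolerance = attr(x, "tolerance"),
                 n_models = length(unique(x$true_model)),
                 accuracy = correct / sum(x$n))
}

#' Posterior bar chart for an ABC result
#'
#' @param object An `abc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abc_result
#' @export
autoplot.abc_result <- function(object, ...) {
  ggplot2::ggplot(object$posterior,
                  ggplot2::aes(x = .data$model, y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "demographic scenario",
                  y = "posterior model probability",
                  title = paste0("Rejection ABC (tolerance ",
                                 object$tolerance, ", ",
                                 object$n_accepted, "/", object$n_total,
                                 " rows accepted)")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heat map for ABC cross-validation
#'
#' @param object An `abc_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abc_cv
#' @export
autoplot.abc_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$assigned_model,
                                   y = .data$true_model,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "assigned model", y = "generating model",
                  fill = "rate") +
    ggplot2::theme_minimal()
}
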