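#' Standardize a reference table against an observed vector
#'
#' Centers and scales every statistic by the reference table's mean and SD
#' (MAD optionally, as a robust alternative). Statistics with zero scale
#' carry no distance information and are dropped from the comparison; they
#' are listed in the scaling report rather than silently discarded.
#'
#' @param table A `reference_table` (or any data frame containing the
#'   statistic columns).
#' @param observed Named numeric vector or one-row data frame of observed
#'   statistics; its names define which columns are compared.
#' @param scale_fun `"sd"` (default) or `"mad"`.
#' @return List with `table_scaled` (matrix, used statistics only),
#'   `observed_scaled` (numeric), and `scaling` (tibble `stat`, `center`,
#'   `scale`, `used`).
#' @export
abc_standardize <- function(table, observed, scale_fun = c("sd", "mad")) {
  scale_fun <- match.arg(scale_fun)
  obs <- as_stat_vector(observed)
  stat_cols <- intersect(names(obs), names(table))
  if (!length(stat_cols))
    stop("observed vector shares no statistic names with the table",
         call. = FALSE)
  x <- as.matrix(as.data.frame(table)[, stat_cols, drop = FALSE])
  ctr <- colMeans(x)
  scl <- if (scale_fun == "sd") {
    apply(x, 2, stats::sd)
  } else {
    apply(x, 2, stats::mad)
  }
  used <- is.finite(scl) & scl > 0
  if (!any(used))
    stop("all statistics have zero scale in the reference table",
         call. = FALSE)
  scaling <- tibble::tibble(stat = stat_cols, center = ctr, scale = scl,
                            used = used)
  xs <- sweep(sweep(x[, used, drop = FALSE], 2, ctr[used]), 2, scl[used], "/")
  os <- (obs[stat_cols][used] - ctr[used]) / scl[used]
  list(table_scaled = xs, observed_scaled = os, scaling = scaling)
}

#' Invert a standardization
#'
#' @param scaled Named numeric vector of standardized statistics.
#' @param scaling Scaling report from [abc_standardize()].
#' @return Numeric vector on the original scale.
#' @export
abc_unstandardize <- function(scaled, scaling) {
  i <- match(names(scaled), scaling$stat)
  scaled * scaling$scale[i] + scaling$center[i]
}

as_stat_vector <- function(observed) {
  if (is.data.frame(observed)) {
    stopifnot(nrow(observed) == 1)
    observed <- observed[, vapply(observed, is.numeric, TRUE), drop = FALSE]
    obs <- as.numeric(observed[1, ])
    names(obs) <- names(observed)
    obs
  } else {
    stopifnot(is.numeric(observed), !is.null(names(observed)))
    observed
  }
}

#' Rejection-ABC model choice
#'
#' Computes Euclidean distances between the observed summary vector and
#' every reference-table row on standardized statistics, accepts the
#' `ceiling(tolerance * n)` nearest rows (ties broken stably by row index),
#' and estimates each model's posterior probability as its frequency among
#' the accepted rows.
#'
#' @param table A `reference_table`.
#' @param observed Observed summary vector (one-row data frame from
#'   [summarize_alignment()] or named numeric).
#' @param tolerance Retained fraction, in (0, 1].
#' @param scale_fun Passed to [abc_standardize()].
#' @return Object of class `abc_result`: list with `tolerance`,
#'   `n_accepted`, `n_total`, `posterior` (tibble `model`, `n_accepted`,
#'   `posterior`), `accepted` (tibble: `row`, `model`, `distance`, parameter
#'   columns; distance non-decreasing), and `scaling`.
#' @examples
#' models <- lapply(c("constant", "lgm"), build_model)
#' ref <- build_reference_table(models, n_sims = 20, master_seed = 1)
#' obs <- ref[1, attr(ref, "stat_cols")]
#' fit <- abc_reject(ref, obs, tolerance = 0.25)
#' tidy(fit)
#' @export
abc_reject <- function(table, observed, tolerance = 0.05,
                       scale_fun = c("sd", "mad")) {
  if (!nrow(table)) stop("empty reference table", call. = FALSE)
  if (!is.numeric(tolerance) || tolerance <= 0 || tolerance > 1)
    stop("tolerance must lie in (0, 1]", call. = FALSE)
  std <- abc_standardize(table, observed, scale_fun)
  dif <- sweep(std$table_scaled, 2, std$observed_scaled)
  distance <- sqrt(rowSums(dif^2))
  k <- as.integer(ceiling(tolerance * nrow(table)))
  ord <- order(distance)                      # stable: ties keep row order
  acc <- ord[seq_len(k)]

  model_levels <- unique(table$model)
  acc_models <- factor(table$model[acc], levels = model_levels)
  counts <- as.integer(table(acc_models))
  posterior <- tibble::tibble(model = model_levels,
                              n_accepted = counts,
                              posterior = counts / k)
  param_cols <- intersect(attr(table, "param_cols") %||% character(0),
                          names(table))
  accepted <- dplyr::bind_cols(
    tibble::tibble(row = acc, model = table$model[acc],
                   distance = distance[acc]),
    as.data.frame(table)[acc, param_cols, drop = FALSE])
  structure(list(tolerance = tolerance, n_accepted = k,
                 n_total = nrow(table), posterior = posterior,
                 accepted = tibble::as_tibble(accepted),
                 scaling = std$scaling),
            class = "abc_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Best-supported model of an ABC fit
#'
#' @param result An `abc_result`.
#' @return Model name with the highest posterior probability (ties broken by
#'   table model order).
#' @export
abc_best_model <- function(result) {
  stopifnot(inherits(result, "abc_result"))
  result$posterior$model[which.max(result$posterior$posterior)]
}

#' Leave-one-out cross-validation of ABC model choice
#'
#' Draws `n_pseudo` rows per model as pseudo-observed datasets; each is
#' removed from the table, classified by the model with the highest
#' rejection posterior (ties broken by table model order), and tallied into
#' a confusion matrix.
#'
#' @param table A `reference_table` with at least `n_pseudo + 1` rows per
#'   model.
#' @param n_pseudo Pseudo-observed replicates per model.
#' @param tolerance Rejection tolerance.
#' @param seed Optional seed for the pseudo-observation draw.
#' @return Object of class `abc_cv`: tibble `true_model`, `assigned_model`,
#'   `n` (complete model grid; each true-model row group sums to
#'   `n_pseudo`), with attributes `n_pseudo` and `tolerance`.
#' @export
abc_cross_validate <- function(table, n_pseudo, tolerance = 0.05,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model_levels <- unique(table$model)
  per <- table(factor(table$model, levels = model_levels))
  if (any(per < n_pseudo + 1))
    stop("each model needs at least n_pseudo + 1 rows; have ",
         paste(per, collapse = ", "), call. = FALSE)
  stat_cols <- attr(table, "stat_cols") %||%
    grep("^(S_|pi_|fst_)", names(table), value = TRUE)
  assigned <- character(0)
  truth <- character(0)
  for (m in model_levels) {
    idx <- sample(which(table$model == m), n_pseudo)
    for (i in idx) {
      obs <- as.numeric(as.data.frame(table)[i, stat_cols])
      names(obs) <- stat_cols
      sub <- table[-i, , drop = FALSE]
      attr(sub, "param_cols") <- attr(table, "param_cols")
      res <- abc_reject(sub, obs, tolerance)
      assigned <- c(assigned, abc_best_model(res))
      truth <- c(truth, m)
    }
  }
  out <- tidyr::complete(
    dplyr::count(tibble::tibble(
      true_model = factor(truth, levels = model_levels),
      assigned_model = factor(assigned, levels = model_levels)),
      .data$true_model, .data$assigned_model, name = "n"),
    .data$true_model, .data$assigned_model, fill = list(n = 0L))
  out$n <- as.integer(out$n)
  class(out) <- c("abc_cv", class(out))
  attr(out, "n_pseudo") <- n_pseudo
  attr(out, "tolerance") <- tolerance
  out
}

#' Write an ABC result as a JSON report plus accepted-rows CSV
#'
#' The JSON report carries the tolerance, acceptance count, model posterior
#' probabilities and per-model accepted-parameter quantiles; the accepted
#' rows (model, distance, parameters) go to a companion CSV.
#'
#' @param result An `abc_result`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return The report list, invisibly.
#' @export
write_abc_report <- function(result, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(result, "abc_result"))
  param_cols <- setdiff(names(result$accepted),
                        c("row", "model", "distance"))
  quantiles <- lapply(split(result$accepted, result$accepted$model),
    function(df) {
      lapply(stats::setNames(param_cols, param_cols), function(pc) {
        v <- df[[pc]]
        v <- v[is.finite(v)]
        if (!length(v)) return(NULL)
        as.list(stats::quantile(v, c(0.025, 0.5, 0.975), names = TRUE))
      })
    })
  report <- list(
    tolerance = result$tolerance,
    n_total = result$n_total,
    n_accepted = result$n_accepted,
    best_model = abc_best_model(result),
    posterior = stats::setNames(as.list(result$posterior$posterior),
                                result$posterior$model),
    accepted_parameter_quantiles = quantiles)
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (!is.null(csv_path))
    readr::write_csv(result$accepted, csv_path)
  invisible(report)
}

#' @export
print.abc_result <- function(x, ...) {
  cat("<abc_result> tolerance ", x$tolerance, ": accepted ", x$n_accepted,
      " of ", x$n_total, " rows\n", sep = "")
  print(x$posterior)
  invisible(x)
}
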