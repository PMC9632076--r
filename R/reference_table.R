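#' Build an ABC reference table by simulation
#'
#' For each model runs `n_sims` independent replicates of the full chain
#' draw parameters -> simulate genealogy -> drop mutations -> summarize,
#' and stacks the rows (model id, flattened parameter draws, summary-statistic
#' vector) into one tibble. All models must share the deme layout so the
#' statistic vectors align column-for-column.
#'
#' Reproducibility: per-replicate seeds are drawn once from the master seed's
#' stream (`sample.int(2^31 - 2)`) and indexed by (model, replicate), so the
#' whole table — and any single row — is bit-identically regenerable from
#' `master_seed`, including under out-of-order or parallel execution.
#'
#' @param models List of `demographic_model` objects (e.g. the four
#'   scenarios built from one configuration).
#' @param n_sims Number of simulated rows per model (>= 1).
#' @param master_seed Integer master seed; required, no silent
#'   nondeterminism.
#' @return A tibble of class `reference_table` with columns `model`, the
#'   flattened parameter draws (`lgm_time_years_bp`, `lgm_severity`,
#'   `eemian_time_years_bp`, `eemian_severity`; `NA` where a scenario lacks
#'   the parameter), and the statistics of [summary_vector_names()].
#'   Attributes: `stat_cols`, `param_cols`, `master_seed`, `n_sims`.
#' @examples
#' models <- lapply(c("constant", "lgm"), build_model)
#' ref <- build_reference_table(models, n_sims = 3, master_seed = 1)
#' dim(ref)
#' @export
build_reference_table <- function(models, n_sims, master_seed) {
  stopifnot(is.list(models), length(models) >= 1, n_sims >= 1)
  if (missing(master_seed) || !is.numeric(master_seed))
    stop("master_seed is required", call. = FALSE)
  lay <- lapply(models, function(m)
    m$demes[, c("deme_id", "age_years_bp", "n_samples")])
  for (m in models[-1]) {
    if (!identical(lay[[1]], m$demes[, c("deme_id", "age_years_bp",
                                         "n_samples")]))
      stop("all models must share the same deme layout", call. = FALSE)
  }
  deme_order <- models[[1]]$demes$deme_id
  stat_cols <- summary_vector_names(deme_order)
  labels <- unique(unlist(lapply(models, function(m)
    vapply(m$bottlenecks, `[[`, "", "label"))))
  param_cols <- if (length(labels)) {
    as.vector(rbind(paste0(tolower(labels), "_time_years_bp"),
                    paste0(tolower(labels), "_severity")))
  } else character(0)

  n_models <- length(models)
  set.seed(as.integer(master_seed))
  seeds <- sample.int(2147483645L, n_models * n_sims)

  n_rows <- n_models * n_sims
  vals <- matrix(NA_real_, n_rows, length(param_cols) + length(stat_cols),
                 dimnames = list(NULL, c(param_cols, stat_cols)))
  model_id <- character(n_rows)
  r <- 0L
  for (mi in seq_len(n_models)) {
    model <- models[[mi]]
    for (j in seq_len(n_sims)) {
      r <- r + 1L
      set.seed(seeds[(mi - 1L) * n_sims + j])
      params <- draw_params(model)
      gen <- simulate_genealogy(model, params)
      aln <- drop_mutations(gen)
      sv <- summarize_alignment(aln, deme_order = deme_order)
      model_id[r] <- model$name
      if (nrow(params$bottlenecks)) {
        lab <- tolower(params$bottlenecks$label)
        vals[r, paste0(lab, "_time_years_bp")] <-
          params$bottlenecks$time_years_bp
        vals[r, paste0(lab, "_severity")] <- params$bottlenecks$severity
      }
      vals[r, stat_cols] <- as.numeric(sv[1, stat_cols])
    }
  }
  out <- tibble::as_tibble(as.data.frame(vals))
  out <- dplyr::bind_cols(tibble::tibble(model = model_id), out)
  class(out) <- c("reference_table", class(out))
  attr(out, "stat_cols") <- stat_cols
  attr(out, "param_cols") <- param_cols
  attr(out, "master_seed") <- as.integer(master_seed)
  attr(out, "n_sims") <- n_sims
  out
}

#' Read / write a reference table as CSV
#'
#' The CSV has a header `model`, parameter columns, then statistic columns.
#' Statistic columns are recognised on read as those matching the
#' [summary_vector_names()] patterns (`S_*`, `pi_*`, `fst_*`).
#'
#' @param table A `reference_table`.
#' @param path File path.
#' @return `read_reference_table()` returns a `reference_table`.
#' @export
write_reference_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  nm <- names(out)
  stat_cols <- nm[grepl("^(S_|pi_|fst_)", nm)]
  param_cols <- setdiff(nm, c("model", stat_cols))
  class(out) <- c("reference_table", class(out))
  attr(out, "stat_cols") <- stat_cols
  attr(out, "param_cols") <- param_cols
  out
}
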