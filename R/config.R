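#' Packaged default model configuration
#'
#' Returns the default study configuration emulating a temporally structured
#' mitogenome sampling design for a cold-adapted rodent: 13 demes ("populations"
#' in the ABC sense: temporal sampling points of maternal clades) spread over
#' 5 clades, 113 samples in total (59 ancient, 54 modern), sampling ages
#' spanning 0--50 ka BP, and a ~16.3 kb mitogenome.
#'
#' The deme sizes are the female effective population size `N_ef` (mtDNA is
#' maternally inherited, so the haploid coalescent runs on the number of
#' females). The default of 30,000 females per deme is a placeholder chosen
#' so that per-site diversity 2 N mu matches the few-per-thousand scale
#' typical of rodent mitogenomes, and so that the species-wide female
#' effective size is of skyline scale when a handful of demes coexist at any
#' one time; override it when a study-specific table is available. Join times default to published clade
#' TMRCA estimates (clade 5 at 27 ka BP, clades 1 and 3 at 56.5 ka BP, root at
#' 100 ka BP); between-clade join times are package defaults. Everything is
#' user-overridable, either by editing the returned list or via a YAML file
#' ([read_model_config()]).
#'
#' The clock converts calendar time to coalescent time at 2 generations per
#' year, with a per-generation per-site mutation rate of
#' 2.07e-7 / 2 = 1.035e-7 (a substitution-rate anchor of 2.07e-7
#' substitutions/site/year divided by the generation rate).
#'
#' @return A list of class `coal_config` with elements:
#' \describe{
#'   \item{demes}{tibble: `deme_id`, `clade`, `age_years_bp`, `n_samples`,
#'     `size_females`.}
#'   \item{joins}{tibble: `time_years_bp`, `source`, `dest`; backward in time
#'     all lineages of `source` move into `dest`.}
#'   \item{bottlenecks}{named list (`lgm`, `eemian`) of bottleneck
#'     specifications: `label`, `timing_prior`, `severity_prior`,
#'     `duration_years`.}
#'   \item{clock}{list: `generations_per_year`, `mu_per_site_per_gen`,
#'     `seq_length`.}
#'   \item{options}{list: `bottleneck_scope` ("all" demes extant during the
#'     epoch, or "ancestral" for the root deme only) and `shared_severity`
#'     (draw one severity shared by both bottlenecks).}
#' }
#' @examples
#' cfg <- default_model_config()
#' cfg$demes
#' @export
default_model_config <- function() {
  demes <- tibble::tribble(
    ~deme_id, ~clade, ~age_years_bp, ~n_samples,
    "c1_50",  "1",    50000,         5,
    "c1_40",  "1",    40000,         5,
    "c1_30",  "1",    30000,         5,
    "c2_45",  "2",    45000,         5,
    "c2_35",  "2",    35000,         5,
    "c3_48",  "3",    48000,         5,
    "c3_38",  "3",    38000,         5,
    "c3_28",  "3",    28000,         5,
    "c4_30",  "4",    30000,         5,
    "c4_20",  "4",    20000,         5,
    "c5_15",  "5",    15000,         5,
    "c5_05",  "5",     5000,         4,
    "c5_00",  "5",        0,        54
  )
  demes$size_females <- 30000

  joins <- tibble::tribble(
    ~time_years_bp, ~source,  ~dest,
    44000,          "c1_30",  "c1_40",
    56500,          "c1_40",  "c1_50",
    50000,          "c2_35",  "c2_45",
    42000,          "c3_28",  "c3_38",
    56500,          "c3_38",  "c3_48",
    40000,          "c4_20",  "c4_30",
    8000,           "c5_00",  "c5_05",
    27000,          "c5_05",  "c5_15",
    70000,          "c2_45",  "c1_50",
    75000,          "c4_30",  "c3_48",
    85000,          "c3_48",  "c1_50",
    100000,         "c5_15",  "c1_50"
  )

  bottlenecks <- list(
    lgm = list(
      label          = "LGM",
      timing_prior   = prior_log_uniform(20000, 30000),
      severity_prior = prior_uniform(0.2, 0.6),
      duration_years = 8600
    ),
    eemian = list(
      label          = "Eemian",
      timing_prior   = prior_log_uniform(115000, 130000),
      severity_prior = prior_uniform(0.2, 0.6),
      duration_years = 15000
    )
  )

  clock <- list(
    generations_per_year = 2,
    mu_per_site_per_gen  = 2.07e-7 / 2,
    seq_length           = 16300
  )

  model_config(demes = demes, joins = joins, bottlenecks = bottlenecks,
               clock = clock)
}

#' Build a model configuration
#'
#' Assembles (and lightly checks) the configuration consumed by
#' [build_model()]. See [default_model_config()] for the packaged default and
#' the meaning of each component.
#'
#' @param demes Data frame with columns `deme_id`, `clade`, `age_years_bp`,
#'   `n_samples`, `size_females`.
#' @param joins Data frame with columns `time_years_bp`, `source`, `dest`.
#'   May have zero rows for a single-deme configuration.
#' @param bottlenecks Named list of bottleneck specifications (see
#'   [default_model_config()]). The `lgm` and `eemian` entries are picked up
#'   by the corresponding scenarios.
#' @param clock List with `generations_per_year`, `mu_per_site_per_gen`,
#'   `seq_length`.
#' @param options List with `bottleneck_scope` ("all" or "ancestral") and
#'   `shared_severity` (logical).
#' @return A `coal_config` list.
#' @export
model_config <- function(demes, joins,
                         bottlenecks = list(),
                         clock = list(generations_per_year = 2,
                                      mu_per_site_per_gen = 1.035e-7,
                                      seq_length = 16300),
                         options = list(bottleneck_scope = "all",
                                        shared_severity = FALSE)) {
  demes <- tibble::as_tibble(demes)
  joins <- tibble::as_tibble(joins)
  need_d <- c("deme_id", "clade", "age_years_bp", "n_samples", "size_females")
  if (!all(need_d %in% names(demes)))
    stop("demes must have columns: ", paste(need_d, collapse = ", "),
         call. = FALSE)
  need_j <- c("time_years_bp", "source", "dest")
  if (!all(need_j %in% names(joins)))
    stop("joins must have columns: ", paste(need_j, collapse = ", "),
         call. = FALSE)
  demes$n_samples <- as.integer(demes$n_samples)
  demes$age_years_bp <- as.numeric(demes$age_years_bp)
  demes$size_females <- as.numeric(demes$size_females)
  options$bottleneck_scope <- match.arg(options$bottleneck_scope,
                                        c("all", "ancestral"))
  structure(list(demes = demes, joins = joins, bottlenecks = bottlenecks,
                 clock = clock, options = options),
            class = "coal_config")
}

#' Read / write a model configuration as YAML
#'
#' The on-disk schema mirrors the in-memory configuration: top-level sections
#' `demes` (list of records), `joins`, `bottlenecks` (each with a
#' `timing_prior`/`severity_prior` record of `kind`, `lower`, `upper`),
#' `clock` and `options`. `write_model_config()` followed by
#' `read_model_config()` round-trips exactly.
#'
#' @param path File path.
#' @param config A `coal_config` object.
#' @return `read_model_config()` returns a `coal_config`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  demes <- dplyr::bind_rows(lapply(raw$demes, tibble::as_tibble))
  joins <- if (length(raw$joins)) {
    dplyr::bind_rows(lapply(raw$joins, tibble::as_tibble))
  } else {
    tibble::tibble(time_years_bp = numeric(), source = character(),
                   dest = character())
  }
  bns <- lapply(raw$bottlenecks, function(b) {
    list(label          = b$label,
         timing_prior   = rebuild_prior(b$timing_prior),
         severity_prior = rebuild_prior(b$severity_prior),
         duration_years = b$duration_years)
  })
  model_config(demes = demes, joins = joins, bottlenecks = bns,
               clock = raw$clock, options = raw$options)
}

rebuild_prior <- function(p) {
  switch(p$kind,
    "log-uniform" = prior_log_uniform(p$lower, p$upper),
    "uniform"     = prior_uniform(p$lower, p$upper),
    "fixed"       = prior_fixed(p$lower),
    stop("unknown prior kind in config: '", p$kind, "'", call. = FALSE))
}

#' @rdname read_model_config
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "coal_config"))
  raw <- list(
    demes = apply(config$demes, 1, as.list, simplify = FALSE),
    joins = apply(config$joins, 1, as.list, simplify = FALSE),
    bottlenecks = lapply(config$bottlenecks, function(b) {
      list(label          = b$label,
           timing_prior   = unclass(b$timing_prior),
           severity_prior = unclass(b$severity_prior),
           duration_years = b$duration_years)
    }),
    clock = config$clock,
    options = config$options
  )
  # apply() stringifies mixed rows; rebuild records type-faithfully instead
  raw$demes <- purrr::pmap(config$demes, list)
  raw$joins <- purrr::pmap(config$joins, list)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @export
print.coal_config <- function(x, ...) {
  cat("<coal_config> ", nrow(x$demes), " demes, ",
      length(unique(x$demes$clade)), " clades, ",
      sum(x$demes$n_samples), " samples, ",
      nrow(x$joins), " joins, L = ", x$clock$seq_length, "\n", sep = "")
  invisible(x)
}
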