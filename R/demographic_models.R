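#' Demographic scenarios
#'
#' Four competing demographic histories for a structured, temporally sampled
#' mitochondrial dataset:
#' \describe{
#'   \item{constant}{constant population size through time (bottleneck
#'     severity implicitly 1.0);}
#'   \item{lgm}{a bottleneck during the Last Glacial Maximum, onset drawn
#'     log-uniformly on 20--30 ka BP;}
#'   \item{eemian}{a bottleneck during the Eemian interglacial, onset drawn
#'     log-uniformly on 115--130 ka BP;}
#'   \item{lgm_eemian}{both bottlenecks.}
#' }
#' During a bottleneck epoch every deme's size is multiplied by a severity
#' factor `b` drawn from its prior (default uniform on 0.2--0.6); the epoch
#' spans `[onset, onset + duration]` years BP, i.e. the drawn time is the
#' recent edge of the window and the window extends back in time by the
#' configured duration (LGM 8.6 ka, Eemian 15 ka by default).
#'
#' @name scenarios
NULL

scenario_names <- c("constant", "lgm", "eemian", "lgm_eemian")

#' Build a demographic model for one scenario
#'
#' Instantiates and validates one of the four scenarios from a configuration
#' (see [default_model_config()]). The returned model carries the deme layout,
#' the join (population-merge) events, the scenario's bottleneck
#' specifications with their priors, and the mutational clock.
#'
#' @param name One of `"constant"`, `"lgm"`, `"eemian"`, `"lgm_eemian"`.
#' @param config A `coal_config`, by default [default_model_config()].
#' @return An object of class `demographic_model`.
#' @examples
#' m <- build_model("lgm_eemian")
#' m
#' @seealso [draw_params()], [simulate_genealogy()], [validate_model()]
#' @export
build_model <- function(name, config = default_model_config()) {
  if (!is.character(name) || length(name) != 1 || !name %in% scenario_names)
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; expected one of: ", paste(scenario_names, collapse = ", "),
         call. = FALSE)
  stopifnot(inherits(config, "coal_config"))
  bns <- switch(name,
    constant   = list(),
    lgm        = list(config$bottlenecks$lgm),
    eemian     = list(config$bottlenecks$eemian),
    lgm_eemian = list(config$bottlenecks$lgm, config$bottlenecks$eemian)
  )
  if (name != "constant" && any(vapply(bns, is.null, TRUE)))
    stop("configuration lacks the bottleneck specification required by '",
         name, "'", call. = FALSE)
  model <- structure(
    list(name = name, demes = config$demes, joins = config$joins,
         bottlenecks = bns, clock = config$clock, options = config$options),
    class = "demographic_model")
  bad <- validate_model(model)
  if (length(bad))
    stop("invalid model: ", paste(bad, collapse = "; "), call. = FALSE)
  model
}

#' Validate a demographic model
#'
#' Checks every structural invariant of a model and returns a character
#' vector of human-readable violations (empty when the model is valid):
#' unique positive-sized demes, a join set forming a tree that connects all
#' demes into a single ancestral (root) deme, join times later than the
#' sampling times of the demes involved and consistently ordered along join
#' chains, bottleneck priors with positive bounds and severity support within
#' (0, 1], and a strictly positive clock.
#'
#' @param model A `demographic_model` (or a hand-built list with the same
#'   fields; nothing is assumed valid).
#' @return Character vector of violation descriptions; `character(0)` if the
#'   model is valid.
#' @export
validate_model <- function(model) {
  bad <- character()
  d <- model$demes
  j <- model$joins

  if (anyDuplicated(d$deme_id))
    bad <- c(bad, paste0("duplicated deme_id: ",
                         paste(unique(d$deme_id[duplicated(d$deme_id)]),
                               collapse = ", ")))
  if (any(!is.finite(d$age_years_bp) | d$age_years_bp < 0))
    bad <- c(bad, "age_years_bp must be finite and >= 0")
  if (any(d$n_samples < 1))
    bad <- c(bad, "n_samples must be >= 1 for every deme")
  if (any(!is.finite(d$size_females) | d$size_females <= 0))
    bad <- c(bad, "size_females must be > 0 for every deme")

  ck <- model$clock
  # mu = 0 is allowed (mutation-free runs); the other clock fields must be > 0
  if (!is.numeric(ck$generations_per_year) || ck$generations_per_year <= 0)
    bad <- c(bad, "clock: generations_per_year must be > 0")
  if (!is.numeric(ck$mu_per_site_per_gen) || ck$mu_per_site_per_gen < 0)
    bad <- c(bad, "clock: mu_per_site_per_gen must be >= 0")
  if (!is.numeric(ck$seq_length) || ck$seq_length < 1)
    bad <- c(bad, "clock: seq_length must be >= 1")

  nd <- nrow(d)
  if (nd > 1 || nrow(j) > 0) {
    if (nrow(j) != nd - 1)
      bad <- c(bad, sprintf("expected %d join events for %d demes, got %d",
                            nd - 1, nd, nrow(j)))
    unknown <- setdiff(c(j$source, j$dest), d$deme_id)
    if (length(unknown))
      bad <- c(bad, paste0("join references unknown deme: ",
                           paste(unique(unknown), collapse = ", ")))
    if (any(j$source == j$dest))
      bad <- c(bad, "join with source == dest")
    if (anyDuplicated(j$source))
      bad <- c(bad, paste0("deme joined away more than once: ",
                           paste(unique(j$source[duplicated(j$source)]),
                                 collapse = ", ")))
    if (!length(unknown) && !anyDuplicated(j$source) &&
        nrow(j) == nd - 1 && all(j$source != j$dest)) {
      roots <- setdiff(d$deme_id, j$source)
      if (length(roots) != 1) {
        bad <- c(bad, "join events do not leave exactly one root deme")
      } else {
        # every deme must reach the root by following source -> dest
        nxt <- stats::setNames(j$dest, j$source)
        for (dm in d$deme_id) {
          cur <- dm; steps <- 0
          while (cur %in% names(nxt) && steps <= nd) {
            cur <- nxt[[cur]]; steps <- steps + 1
          }
          if (cur != roots) {
            bad <- c(bad, paste0("deme ", dm,
                                 " is not connected to the root deme"))
            break
          }
        }
      }
      # join time must postdate the sampling of both demes involved
      age <- stats::setNames(d$age_years_bp, d$deme_id)
      late <- j$time_years_bp <= pmax(age[j$source], age[j$dest])
      if (any(late))
        bad <- c(bad, paste0("join at ", j$time_years_bp[late],
                             " years BP does not postdate sampling of ",
                             j$source[late], " or ", j$dest[late]))
      # a deme must not receive lineages after it has itself joined away
      src_time <- stats::setNames(j$time_years_bp, j$source)
      into_dead <- j$dest %in% j$source &
        j$time_years_bp >= src_time[j$dest]
      into_dead[is.na(into_dead)] <- FALSE
      if (any(into_dead))
        bad <- c(bad, paste0("join into ", j$dest[into_dead],
                             " at ", j$time_years_bp[into_dead],
                             " years BP occurs after that deme joined away"))
    }
  }

  for (b in model$bottlenecks) {
    if (is.null(b)) { bad <- c(bad, "NULL bottleneck specification"); next }
    for (pn in c("timing_prior", "severity_prior")) {
      p <- b[[pn]]
      if (!inherits(p, "abc_prior")) {
        bad <- c(bad, paste0(b$label, ": ", pn, " is not a prior"))
        next
      }
      if (p$lower <= 0 && pn == "timing_prior")
        bad <- c(bad, paste0(b$label, ": timing prior bounds must be > 0"))
    }
    sp <- b$severity_prior
    if (inherits(sp, "abc_prior") && (sp$lower <= 0 || sp$upper > 1))
      bad <- c(bad, paste0(b$label, ": severity support must lie in (0, 1]"))
    if (!is.numeric(b$duration_years) || b$duration_years <= 0)
      bad <- c(bad, paste0(b$label, ": duration_years must be > 0"))
  }
  if (model$name == "constant" && length(model$bottlenecks) != 0)
    bad <- c(bad, "constant scenario must carry no bottlenecks")
  if (model$name == "lgm_eemian" && length(model$bottlenecks) != 2)
    bad <- c(bad, "lgm_eemian scenario must carry exactly two bottlenecks")
  bad
}

#' Draw one concrete parameter set from a model's priors
#'
#' Draws each bottleneck's onset time and severity independently from their
#' priors (one shared severity draw if the configuration sets
#' `shared_severity`), and resolves the per-deme female effective sizes. The
#' constant scenario has no free parameters: its implied severity is 1.0.
#' Uses the current R random number stream.
#'
#' @param model A validated `demographic_model`.
#' @return Object of class `model_params`: list with `model` (scenario name),
#'   `bottlenecks` (tibble: `label`, `time_years_bp`, `severity`,
#'   `duration_years`) and `sizes` (named numeric, females per deme).
#' @examples
#' set.seed(1)
#' draw_params(build_model("lgm"))
#' @export
draw_params <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  bns <- model$bottlenecks
  if (length(bns)) {
    times <- vapply(bns, function(b) draw_prior(b$timing_prior), numeric(1))
    if (isTRUE(model$options$shared_severity) && length(bns) > 1) {
      sev <- rep(draw_prior(bns[[1]]$severity_prior), length(bns))
    } else {
      sev <- vapply(bns, function(b) draw_prior(b$severity_prior), numeric(1))
    }
    draws <- tibble::tibble(
      label          = vapply(bns, `[[`, "", "label"),
      time_years_bp  = times,
      severity       = sev,
      duration_years = vapply(bns, `[[`, numeric(1), "duration_years"))
  } else {
    draws <- tibble::tibble(label = character(), time_years_bp = numeric(),
                            severity = numeric(), duration_years = numeric())
  }
  structure(list(model = model$name, bottlenecks = draws,
                 sizes = stats::setNames(model$demes$size_females,
                                         model$demes$deme_id)),
            class = "model_params")
}

#' Calendar / coalescent time conversion
#'
#' Years BP and generations BP are related exactly and invertibly through the
#' clock's `generations_per_year` (default 2 generations per year).
#'
#' @param years_bp,generations_bp Times to convert.
#' @param clock A clock list (see [default_model_config()]).
#' @return Numeric vector of converted times.
#' @export
years_to_generations <- function(years_bp, clock) {
  years_bp * clock$generations_per_year
}

#' @rdname years_to_generations
#' @export
generations_to_years <- function(generations_bp, clock) {
  generations_bp / clock$generations_per_year
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> scenario '", x$name, "': ",
      nrow(x$demes), " demes, ", sum(x$demes$n_samples), " samples, ",
      length(x$bottlenecks), " bottleneck(s)\n", sep = "")
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> scenario '", x$model, "'\n", sep = "")
  if (nrow(x$bottlenecks)) print(x$bottlenecks) else
    cat("  no bottleneck parameters (implied severity 1.0)\n")
  invisible(x)
}
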