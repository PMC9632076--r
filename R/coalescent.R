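#' Simulate a dated genealogy under a structured serial coalescent
#'
#' Exact continuous-time simulation of the haploid (mitochondrial)
#' coalescent with heterochronous sampling, population joins and bottleneck
#' epochs. Backward in time:
#' \itemize{
#'   \item lineages activate at their samples' ages (converted to
#'     generations BP via the clock);
#'   \item within a deme currently holding `k` lineages and `N` females,
#'     pairs coalesce at rate `k (k - 1) / 2 * 1 / N` per generation;
#'   \item at a join event all lineages of the source deme move into the
#'     destination deme;
#'   \item during a bottleneck epoch `[onset, onset + duration]` the deme
#'     sizes are multiplied by the drawn severity `b`.
#' }
#' Waiting times are exponential with piecewise-constant rates; an event
#' queue over sampling ages, join times and bottleneck boundaries keeps the
#' simulation exact. Times are stored in generations BP.
#'
#' @param model A validated `demographic_model`.
#' @param params A `model_params` draw, by default a fresh [draw_params()].
#' @return Object of class `genealogy`: list with
#'   \describe{
#'     \item{nodes}{tibble `id`, `time` (generations BP), `parent`
#'       (`NA` for the root), `deme_id`, `is_leaf`; leaves are ids
#'       `1..n`, coalescent nodes `n+1..2n-1`.}
#'     \item{samples}{tibble `node_id`, `sample_id`, `deme_id`,
#'       `age_years_bp`, `time_generations`.}
#'     \item{clock}{the model's clock.}
#'   }
#' @examples
#' m <- build_model("constant")
#' set.seed(42)
#' g <- simulate_genealogy(m)
#' tmrca(g)
#' @seealso [drop_mutations()], [tmrca()], [as.phylo.genealogy()]
#' @export
simulate_genealogy <- function(model, params = draw_params(model)) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(params, "model_params"))
  clock <- model$clock
  g <- clock$generations_per_year
  demes <- model$demes
  nd <- nrow(demes)
  deme_ids <- demes$deme_id
  sizes <- unname(params$sizes[deme_ids])
  if (any(!is.finite(sizes) | sizes <= 0))
    stop("params must resolve a positive size for every deme", call. = FALSE)

  n_per <- demes$n_samples
  n <- sum(n_per)
  leaf_deme <- rep.int(seq_len(nd), n_per)
  leaf_time <- rep.int(demes$age_years_bp * g, n_per)
  sample_id <- paste0(rep.int(deme_ids, n_per), "_s", sequence(n_per))

  # ---- event queue (times in generations BP) ---------------------------
  events <- list()
  for (ut in sort(unique(leaf_time))) {
    events[[length(events) + 1]] <-
      list(time = ut, type = "sample", leaves = which(leaf_time == ut))
  }
  if (nrow(model$joins)) {
    for (i in seq_len(nrow(model$joins))) {
      events[[length(events) + 1]] <- list(
        time   = model$joins$time_years_bp[i] * g,
        type   = "join",
        source = match(model$joins$source[i], deme_ids),
        dest   = match(model$joins$dest[i], deme_ids))
    }
  }
  bn <- params$bottlenecks
  if (nrow(bn)) {
    for (i in seq_len(nrow(bn))) {
      events[[length(events) + 1]] <- list(
        time = bn$time_years_bp[i] * g, type = "bn_on", sev = bn$severity[i])
      events[[length(events) + 1]] <- list(
        time = (bn$time_years_bp[i] + bn$duration_years[i]) * g,
        type = "bn_off", sev = bn$severity[i])
    }
  }
  type_rank <- c(sample = 1, bn_off = 2, bn_on = 3, join = 4)
  ord <- order(vapply(events, `[[`, numeric(1), "time"),
               type_rank[vapply(events, `[[`, "", "type")])
  events <- events[ord]
  n_ev <- length(events)

  root_deme <- if (nrow(model$joins)) {
    match(setdiff(deme_ids, model$joins$source), deme_ids)
  } else 1L

  # ---- node storage ----------------------------------------------------
  n_nodes <- 2L * n - 1L
  time_v <- c(leaf_time, numeric(max(n - 1L, 0L)))
  deme_v <- c(leaf_deme, integer(max(n - 1L, 0L)))
  parent_v <- rep(NA_integer_, n_nodes)

  active <- integer(0)       # node ids of active lineages
  act_deme <- integer(0)     # deme index per active lineage
  bn_factor <- 1             # product of severities of open bottlenecks
  next_node <- n + 1L
  t <- 0
  ei <- 1L

  repeat {
    t_next <- if (ei <= n_ev) events[[ei]]$time else Inf
    k <- tabulate(act_deme, nd)
    n_eff <- if (model$options$bottleneck_scope == "ancestral") {
      s <- sizes; s[root_deme] <- s[root_deme] * bn_factor; s
    } else {
      sizes * bn_factor
    }
    rate_d <- k * (k - 1) / 2 / n_eff
    lambda <- sum(rate_d)
    if (length(active) <= 1L && ei > n_ev) break
    dt <- if (lambda > 0) stats::rexp(1, lambda) else Inf
    if (t + dt < t_next) {
      t <- t + dt
      dm <- sample.int(nd, 1L, prob = rate_d)
      in_dm <- which(act_deme == dm)
      pair <- in_dm[sample.int(length(in_dm), 2L)]
      id <- next_node
      next_node <- next_node + 1L
      time_v[id] <- t
      deme_v[id] <- dm
      parent_v[active[pair]] <- id
      active <- c(active[-pair], id)
      act_deme <- c(act_deme[-pair], dm)
    } else {
      if (ei > n_ev)
        stop("non-coalescing configuration: lineages remain in disconnected ",
             "demes", call. = FALSE)  # unreachable for validated models
      ev <- events[[ei]]
      t <- ev$time
      ei <- ei + 1L
      if (ev$type == "sample") {
        active <- c(active, ev$leaves)
        act_deme <- c(act_deme, leaf_deme[ev$leaves])
      } else if (ev$type == "join") {
        act_deme[act_deme == ev$source] <- ev$dest
      } else if (ev$type == "bn_on") {
        bn_factor <- bn_factor * ev$sev
      } else {
        bn_factor <- bn_factor / ev$sev
      }
    }
  }

  nodes <- tibble::tibble(
    id      = seq_len(n_nodes),
    time    = time_v,
    parent  = parent_v,
    deme_id = deme_ids[deme_v],
    is_leaf = seq_len(n_nodes) <= n)
  samples <- tibble::tibble(
    node_id          = seq_len(n),
    sample_id        = sample_id,
    deme_id          = deme_ids[leaf_deme],
    age_years_bp     = leaf_time / g,
    time_generations = leaf_time)
  structure(list(nodes = nodes, samples = samples, clock = clock),
            class = "genealogy")
}

#' Time to the most recent common ancestor
#'
#' @param genealogy A `genealogy`.
#' @return Root time in generations BP (for a single-leaf genealogy, the
#'   leaf's own age).
#' @export
tmrca <- function(genealogy) {
  stopifnot(inherits(genealogy, "genealogy"))
  max(genealogy$nodes$time)
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Each branch receives `Poisson(mu * L * length)` mutations; every mutation
#' occupies a distinct, uniformly drawn position in `1..L` (infinite-sites:
#' no recurrent or back mutation), and each leaf inherits all mutations on
#' its path to the root. Monomorphic positions are not stored; the alignment
#' records the segregating positions, the derived/ancestral state of every
#' sample at each of them, and the total sequence length `L`.
#'
#' @param genealogy A fully coalesced `genealogy`.
#' @param clock Clock list; defaults to the genealogy's own.
#' @return A [haplotype_alignment()] with 0/1 genotypes (0 ancestral,
#'   1 derived).
#' @examples
#' set.seed(7)
#' g <- simulate_genealogy(build_model("constant"))
#' aln <- drop_mutations(g)
#' dim(aln$genotypes)
#' @export
drop_mutations <- function(genealogy, clock = genealogy$clock) {
  stopifnot(inherits(genealogy, "genealogy"))
  mu <- clock$mu_per_site_per_gen
  L <- clock$seq_length
  stopifnot(mu >= 0, L >= 1)
  nodes <- genealogy$nodes
  n <- sum(nodes$is_leaf)
  nonroot <- which(!is.na(nodes$parent))
  blen <- nodes$time[nodes$parent[nonroot]] - nodes$time[nonroot]
  m <- stats::rpois(length(nonroot), mu * L * blen)
  s_tot <- sum(m)
  if (s_tot > L)
    stop("requested ", s_tot, " segregating positions but sequence length is ",
         L, "; infinite-sites placement impossible", call. = FALSE)
  pos <- sample.int(L, s_tot)

  geno <- matrix(0L, nrow = n, ncol = s_tot,
                 dimnames = list(genealogy$samples$sample_id, NULL))
  if (s_tot > 0) {
    desc <- descendant_leaves(nodes)
    mutated <- nonroot[m > 0]
    counts <- m[m > 0]
    col0 <- c(0L, cumsum(counts))
    for (i in seq_along(mutated)) {
      cols <- (col0[i] + 1L):col0[i + 1L]
      geno[desc[[mutated[i]]], cols] <- 1L
    }
  }
  haplotype_alignment(geno,
                      deme = genealogy$samples$deme_id,
                      seq_length = L,
                      positions = pos,
                      sample_ids = genealogy$samples$sample_id)
}

# list of leaf-index vectors below each node (children before parents)
descendant_leaves <- function(nodes) {
  n_nodes <- nrow(nodes)
  n <- sum(nodes$is_leaf)
  desc <- vector("list", n_nodes)
  for (i in seq_len(n)) desc[[i]] <- i
  internal <- which(!nodes$is_leaf)
  internal <- internal[order(nodes$time[internal])]
  kids <- split(which(!is.na(nodes$parent)),
                nodes$parent[!is.na(nodes$parent)])
  for (i in internal) {
    ch <- kids[[as.character(i)]]
    desc[[i]] <- unlist(desc[ch], use.names = FALSE)
  }
  desc
}

#' Convert a genealogy to an ape phylo object
#'
#' Branch lengths are in generations; tip labels are sample ids. Write to
#' Newick with [ape::write.tree()].
#'
#' @param x A `genealogy` with at least two leaves.
#' @param ... Unused.
#' @return An [ape::phylo] object.
#' @exportS3Method ape::as.phylo
as.phylo.genealogy <- function(x, ...) {
  nodes <- x$nodes
  n <- sum(nodes$is_leaf)
  if (n < 2) stop("need at least two leaves to build a phylo", call. = FALSE)
  internal <- which(!nodes$is_leaf)
  # root (deepest) first: ape expects the root at n + 1
  internal <- internal[order(-nodes$time[internal])]
  new_id <- integer(nrow(nodes))
  new_id[seq_len(n)] <- seq_len(n)
  new_id[internal] <- n + seq_along(internal)
  child <- which(!is.na(nodes$parent))
  edge <- cbind(new_id[nodes$parent[child]], new_id[child])
  edge_length <- nodes$time[nodes$parent[child]] - nodes$time[child]
  phy <- list(edge = edge, edge.length = edge_length,
              tip.label = x$samples$sample_id, Nnode = n - 1L)
  class(phy) <- "phylo"
  stats::reorder(phy, "cladewise")
}

#' Export a genealogy as a Newick string
#'
#' @param genealogy A `genealogy`.
#' @param file Optional path; when given the tree is written there.
#' @return The Newick string (invisibly when `file` is given).
#' @export
as_newick <- function(genealogy, file = NULL) {
  phy <- ape::as.phylo(genealogy)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}

#' @export
print.genealogy <- function(x, ...) {
  n <- sum(x$nodes$is_leaf)
  cat("<genealogy> ", n, " leaves over ",
      length(unique(x$samples$deme_id)), " demes; TMRCA = ",
      format(tmrca(x), digits = 6), " generations BP\n", sep = "")
  invisible(x)
}
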