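test_that("a single sample yields a leaf-only genealogy with TMRCA at its age", {
  cfg <- single_deme_config(n_samples = 1, size = 1000, age = 5000)
  m <- build_model("constant", cfg)
  set.seed(1)
  g <- simulate_genealogy(m)
  expect_identical(nrow(g$nodes), 1L)
  expect_equal(tmrca(g), 5000)
})

test_that("genealogies satisfy the structural invariants", {
  m <- build_model("lgm_eemian")
  n <- sum(m$demes$n_samples)
  set.seed(99)
  for (i in 1:25) {
    g <- simulate_genealogy(m)
    nodes <- g$nodes
    expect_identical(sum(!nodes$is_leaf), n - 1L)
    child <- which(!is.na(nodes$parent))
    expect_true(all(nodes$time[child] < nodes$time[nodes$parent[child]]))
    expect_gte(tmrca(g), max(nodes$time[nodes$is_leaf]))
    expect_equal(nodes$time[nodes$is_leaf],
                 g$samples$age_years_bp * m$clock$generations_per_year)
  }
})

test_that("isochronous pair coalesces at mean time N", {
  cfg <- single_deme_config(n_samples = 2, size = 1000)
  m <- build_model("constant", cfg)
  set.seed(7)
  t2 <- replicate(4000, tmrca(simulate_genealogy(m)))
  se <- stats::sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 1000), 3 * se)
})

test_that("mutation counts on a fixed tree are Poisson with mean mu*L*length", {
  # hand-built two-leaf genealogy: root at 50, total branch length 100
  g <- structure(list(
    nodes = tibble::tibble(id = 1:3, time = c(0, 0, 50),
                           parent = c(3L, 3L, NA),
                           deme_id = "d1", is_leaf = c(TRUE, TRUE, FALSE)),
    samples = tibble::tibble(node_id = 1:2, sample_id = c("s1", "s2"),
                             deme_id = "d1", age_years_bp = c(0, 0),
                             time_generations = c(0, 0)),
    clock = list(generations_per_year = 1, mu_per_site_per_gen = 1e-4,
                 seq_length = 1000)), class = "genealogy")
  # mu * L = 0.1 per generation -> expected 10 mutations on 100 generations
  set.seed(21)
  s <- replicate(10000, ncol(drop_mutations(g)$genotypes))
  expect_lt(abs(mean(s) - 10), 3 * sqrt(10 / length(s)))
  expect_lt(abs(stats::var(s) - 10), 4 * 10 * sqrt(2 / length(s)))
})

test_that("mu = 0 yields an alignment with zero segregating positions", {
  m <- build_model("constant", single_deme_config(n_samples = 5, size = 100))
  set.seed(2)
  aln <- drop_mutations(simulate_genealogy(m))
  expect_identical(ncol(aln$genotypes), 0L)
  expect_identical(segregating_sites(aln), 0L)
})

test_that("every infinite-sites mutation is polymorphic in the full sample", {
  cfg <- single_deme_config(n_samples = 8, size = 500, mu = 1e-4, L = 2000)
  m <- build_model("constant", cfg)
  set.seed(31)
  for (i in 1:20) {
    aln <- drop_mutations(simulate_genealogy(m))
    if (ncol(aln$genotypes) == 0) next
    carriers <- colSums(aln$genotypes)
    expect_true(all(carriers >= 1 & carriers <= nrow(aln$genotypes) - 1))
    expect_false(anyDuplicated(aln$positions) > 0)
  }
})

test_that("mean TMRCA shrinks as bottlenecks strengthen", {
  mk <- function(b) {
    bn <- list(lgm = list(label = "LGM",
                          timing_prior = prior_fixed(500),
                          severity_prior = prior_fixed(b),
                          duration_years = 1500))
    build_model("lgm", single_deme_config(n_samples = 6, size = 1000,
                                          bottlenecks = bn))
  }
  means <- vapply(c(0.2, 0.4, 0.6, 1.0), function(b) {
    m <- mk(b)
    set.seed(400)  # common random numbers across arms
    mean(replicate(1500, tmrca(simulate_genealogy(m))))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("reference tables have the promised shape and are reproducible", {
  cfg <- default_model_config()
  models <- lapply(c("constant", "lgm", "eemian", "lgm_eemian"),
                   build_model, config = cfg)
  ref1 <- build_reference_table(models, n_sims = 10, master_seed = 42)
  ref2 <- build_reference_table(models, n_sims = 10, master_seed = 42)
  expect_identical(nrow(ref1), 40L)
  expect_identical(ref1, ref2)
  stat_cols <- attr(ref1, "stat_cols")
  expect_identical(stat_cols, summary_vector_names(cfg$demes$deme_id))
  expect_false(anyNA(ref1[, stat_cols]))
  # parameter flattening: constant rows carry NA draws, lgm rows only LGM
  expect_true(all(is.na(ref1$lgm_severity[ref1$model == "constant"])))
  expect_true(all(!is.na(ref1$lgm_severity[ref1$model == "lgm"])))
  expect_true(all(is.na(ref1$eemian_severity[ref1$model == "lgm"])))
  expect_error(build_reference_table(models, n_sims = 2),
               "master_seed")
})

test_that("bottlenecks reduce mean total segregating sites at matched size", {
  bn <- list(lgm = list(label = "LGM", timing_prior = prior_fixed(200),
                        severity_prior = prior_fixed(0.2),
                        duration_years = 2000),
             eemian = list(label = "Eemian", timing_prior = prior_fixed(3000),
                           severity_prior = prior_fixed(0.2),
                           duration_years = 2000))
  cfg <- multi_deme_config(sizes = c(1000, 1000), n_samples = c(8, 8),
                           ages = c(0, 0), join_times = 1500,
                           mu = 1e-5, L = 5000)
  cfg$bottlenecks <- bn
  models <- lapply(c("constant", "lgm_eemian"), build_model, config = cfg)
  ref <- build_reference_table(models, n_sims = 300, master_seed = 77)
  s_const <- mean(ref$S_total[ref$model == "constant"])
  s_bn <- mean(ref$S_total[ref$model == "lgm_eemian"])
  expect_lt(s_bn, s_const)
})

test_that("genealogies export to valid Newick via ape", {
  m <- build_model("constant",
                   single_deme_config(n_samples = 6, size = 300))
  set.seed(12)
  g <- simulate_genealogy(m)
  nwk <- as_newick(g)
  phy <- ape::read.tree(text = nwk)
  expect_identical(ape::Ntip(phy), 6L)
  expect_identical(sort(phy$tip.label), sort(g$samples$sample_id))
  # root-to-tip depths reconstruct each node's time below the root
  depth <- ape::node.depth.edgelength(phy)[seq_len(6)]
  expect_equal(sort(tmrca(g) - depth),
               sort(g$nodes$time[g$nodes$is_leaf]), tolerance = 1e-6)
})
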