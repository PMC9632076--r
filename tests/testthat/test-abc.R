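make_toy_table <- function(stats, model) {
  out <- tibble::as_tibble(as.data.frame(stats))
  out <- dplyr::bind_cols(tibble::tibble(model = model), out)
  class(out) <- c("reference_table", class(out))
  attr(out, "stat_cols") <- colnames(stats)
  attr(out, "param_cols") <- character(0)
  out
}

test_that("standardization centers, scales, drops and reports", {
  set.seed(2)
  stats <- cbind(a = rnorm(50, 5, 2), b = runif(50), const = rep(3, 50))
  tbl <- make_toy_table(stats, rep(c("m1", "m2"), 25))
  obs <- c(a = 5, b = 0.5, const = 3)
  std <- abc_standardize(tbl, obs)
  expect_identical(std$scaling$stat[!std$scaling$used], "const")
  expect_false("const" %in% colnames(std$table_scaled))
  expect_equal(unname(colMeans(std$table_scaled)), c(0, 0),
               tolerance = 1e-12)
  expect_equal(unname(apply(std$table_scaled, 2, stats::sd)), c(1, 1),
               tolerance = 1e-12)
  # round trip
  back <- abc_unstandardize(std$observed_scaled, std$scaling)
  expect_equal(unname(back), unname(obs[c("a", "b")]), tolerance = 1e-12)
  # all-constant table is an error
  tbl0 <- make_toy_table(cbind(a = rep(1, 10)), rep("m1", 10))
  expect_error(abc_standardize(tbl0, c(a = 1)), "zero scale")
})

test_that("rejection matches a brute-force enumeration on a 10-row table", {
  set.seed(33)
  stats <- cbind(s1 = rnorm(10), s2 = rnorm(10), s3 = rnorm(10))
  model <- rep(c("m1", "m2"), each = 5)
  tbl <- make_toy_table(stats, model)
  obs <- c(s1 = 0.2, s2 = -0.1, s3 = 0.4)
  oracle <- bf_reject(stats, model, obs, tolerance = 0.3)

  fit <- abc_reject(tbl, obs, tolerance = 0.3)
  expect_identical(fit$n_accepted, 3L)
  expect_identical(sort(fit$accepted$row), oracle$accepted)
  expect_equal(fit$posterior$posterior, oracle$posterior)
  expect_equal(fit$accepted$distance,
               sort(oracle$distance)[1:3], tolerance = 1e-12)
})

test_that("rejection contract: tolerance 1, zero distance, exact counts", {
  set.seed(14)
  stats <- cbind(x = rnorm(40), y = rnorm(40))
  model <- sample(rep(c("m1", "m2", "m3", "m4"), 10))
  tbl <- make_toy_table(stats, model)

  fit_all <- abc_reject(tbl, c(x = 0, y = 0), tolerance = 1)
  expect_identical(fit_all$n_accepted, 40L)
  expect_equal(fit_all$posterior$posterior,
               as.numeric(table(factor(model, unique(model)))) / 40)

  # observed identical to a simulated row: that row is nearest at distance 0
  obs <- c(x = unname(stats[17, "x"]), y = unname(stats[17, "y"]))
  fit <- abc_reject(tbl, obs, tolerance = 0.05)
  expect_identical(fit$accepted$row[1], 17L)
  expect_equal(fit$accepted$distance[1], 0)

  expect_identical(abc_reject(tbl, obs, tolerance = 0.13)$n_accepted,
                   as.integer(ceiling(0.13 * 40)))
  expect_true(all(diff(fit$accepted$distance) >= 0))
  expect_equal(sum(fit$posterior$posterior), 1, tolerance = 1e-12)
  expect_error(abc_reject(tbl, obs, tolerance = 0), "tolerance")
  expect_error(abc_reject(tbl[0, ], obs, tolerance = 0.1), "empty")
})

test_that("rejection is invariant under row shuffling (distinct distances)", {
  set.seed(55)
  stats <- cbind(x = rnorm(30), y = rnorm(30))
  model <- rep(c("m1", "m2", "m3"), 10)
  tbl <- make_toy_table(stats, model)
  obs <- c(x = 0.3, y = -0.2)
  fit <- abc_reject(tbl, obs, tolerance = 0.2)
  perm <- sample(30)
  tbl_p <- make_toy_table(stats[perm, ], model[perm])
  fit_p <- abc_reject(tbl_p, obs, tolerance = 0.2)
  expect_equal(sort(fit$accepted$distance), sort(fit_p$accepted$distance))
  post <- fit$posterior[order(fit$posterior$model), ]
  post_p <- fit_p$posterior[order(fit_p$posterior$model), ]
  expect_equal(post$posterior, post_p$posterior)
})

test_that("cross-validation separates disjoint models and conserves counts", {
  set.seed(71)
  # four models with well-separated statistic distributions
  centers <- c(m1 = 0, m2 = 10, m3 = 20, m4 = 30)
  stats <- do.call(rbind, lapply(centers, function(cc)
    cbind(x = rnorm(40, cc, 0.5), y = rnorm(40, cc, 0.5))))
  tbl <- make_toy_table(stats, rep(names(centers), each = 40))
  cv <- abc_cross_validate(tbl, n_pseudo = 10, tolerance = 0.1, seed = 5)
  td <- tidy(cv)
  expect_true(all(td$n[td$true_model == td$assigned_model] == 10))
  sums <- tapply(td$n, td$true_model, sum)
  expect_true(all(sums == 10))
  expect_equal(glance(cv)$accuracy, 1)
})

test_that("cross-validation on exchangeable models is near-uniform", {
  set.seed(81)
  stats <- cbind(x = rnorm(320), y = rnorm(320))
  tbl <- make_toy_table(stats, rep(c("m1", "m2", "m3", "m4"), each = 80))
  cv <- abc_cross_validate(tbl, n_pseudo = 40, tolerance = 0.2, seed = 9)
  td <- tidy(cv)
  # all rows are draws from one distribution, so classification cannot beat
  # chance: accuracy sits near 1/4 (cells are correlated through the shared
  # table, so only the aggregate is constrained)
  expect_gt(glance(cv)$accuracy, 0.10)
  expect_lt(glance(cv)$accuracy, 0.45)
  expect_true(all(tapply(td$n, td$true_model, sum) == 40))
  expect_error(abc_cross_validate(tbl, n_pseudo = 81, tolerance = 0.1),
               "n_pseudo")
})

test_that("tidiers and plots expose the fit", {
  set.seed(3)
  stats <- cbind(x = rnorm(20), y = rnorm(20))
  tbl <- make_toy_table(stats, rep(c("m1", "m2"), 10))
  fit <- abc_reject(tbl, c(x = 0, y = 0), tolerance = 0.25)
  td <- tidy(fit)
  expect_identical(names(td), c("model", "n_accepted", "posterior"))
  gl <- glance(fit)
  expect_identical(gl$best_model, abc_best_model(fit))
  expect_s3_class(autoplot(fit), "ggplot")
  report <- write_abc_report(fit)
  expect_equal(sum(unlist(report$posterior)), 1, tolerance = 1e-12)
})
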