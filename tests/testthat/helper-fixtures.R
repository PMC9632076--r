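# Shared fixtures and independent brute-force oracles. The oracles use
# explicit pairwise loops and are deliberately kept independent of the
# package's vectorized implementations.

# the four-sequence toy alignment: two demes of two haplotypes each
toy_alignment <- function() {
  geno <- rbind(a1 = c("A", "A", "A"),
                a2 = c("A", "A", "T"),
                b1 = c("T", "T", "A"),
                b2 = c("T", "T", "T"))
  haplotype_alignment(geno, deme = c("pop1", "pop1", "pop2", "pop2"),
                      seq_length = 3)
}

# minimal single-deme configuration; times in generations (g = 1)
single_deme_config <- function(n_samples, size, age = 0, L = 1000,
                               mu = 0, bottlenecks = list()) {
  model_config(
    demes = tibble::tibble(deme_id = "d1", clade = "1", age_years_bp = age,
                           n_samples = n_samples, size_females = size),
    joins = tibble::tibble(time_years_bp = numeric(), source = character(),
                           dest = character()),
    bottlenecks = bottlenecks,
    clock = list(generations_per_year = 1, mu_per_site_per_gen = mu,
                 seq_length = L))
}

# demes joined into deme 1 at the given times; times in generations
multi_deme_config <- function(sizes, n_samples, ages, join_times,
                              L = 1000, mu = 0) {
  d <- length(sizes)
  ids <- paste0("d", seq_len(d))
  model_config(
    demes = tibble::tibble(deme_id = ids, clade = as.character(seq_len(d)),
                           age_years_bp = ages, n_samples = n_samples,
                           size_females = sizes),
    joins = tibble::tibble(time_years_bp = join_times,
                           source = ids[-1], dest = ids[1]),
    clock = list(generations_per_year = 1, mu_per_site_per_gen = mu,
                 seq_length = L))
}

# ---- brute-force summary-statistic oracles (explicit loops) -------------

bf_segregating_sites <- function(m) {
  if (nrow(m) < 2 || ncol(m) == 0) return(0L)
  s <- 0L
  for (j in seq_len(ncol(m)))
    if (length(unique(m[, j])) > 1) s <- s + 1L
  s
}

bf_pi <- function(m, L) {
  n <- nrow(m)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2) / L
}

bf_fst <- function(ma, mb, L) {
  hw <- (bf_pi(ma, L) + bf_pi(mb, L)) / 2
  tot <- 0
  for (i in seq_len(nrow(ma)))
    for (j in seq_len(nrow(mb)))
      tot <- tot + sum(ma[i, ] != mb[j, ])
  hb <- tot / (nrow(ma) * nrow(mb)) / L
  if (hb == 0) 0 else 1 - hw / hb
}

# random small alignment over a given alphabet
random_alignment <- function(n, s, demes, states = c("0", "1"), L = s + 2) {
  geno <- matrix(sample(states, n * s, replace = TRUE), nrow = n)
  rownames(geno) <- paste0("s", seq_len(n))
  haplotype_alignment(geno, deme = demes, seq_length = L)
}

# ---- brute-force rejection-ABC oracle -----------------------------------

bf_reject <- function(stats_mat, model, obs, tolerance) {
  mu <- numeric(ncol(stats_mat)); sdv <- numeric(ncol(stats_mat))
  for (j in seq_len(ncol(stats_mat))) {
    mu[j] <- mean(stats_mat[, j]); sdv[j] <- stats::sd(stats_mat[, j])
  }
  keep <- which(sdv > 0)
  d <- numeric(nrow(stats_mat))
  for (i in seq_len(nrow(stats_mat))) {
    acc <- 0
    for (j in keep)
      acc <- acc + ((stats_mat[i, j] - mu[j]) / sdv[j] -
                      (obs[j] - mu[j]) / sdv[j])^2
    d[i] <- sqrt(acc)
  }
  k <- ceiling(tolerance * nrow(stats_mat))
  accepted <- order(d)[seq_len(k)]
  post <- table(factor(model[accepted], levels = unique(model))) / k
  list(accepted = sort(accepted), distance = d,
       posterior = as.numeric(post))
}
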