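test_that("hand-enumerated toy alignment statistics are exact", {
  aln <- toy_alignment()
  expect_identical(segregating_sites(aln), 3L)
  expect_identical(segregating_sites(aln, "pop1"), 1L)
  expect_identical(segregating_sites(aln, "pop2"), 1L)
  expect_equal(nucleotide_diversity(aln, "pop1"), 1 / 3)
  expect_equal(nucleotide_diversity(aln, "pop2"), 1 / 3)
  # Hw = 1/3, Hb = 2.5/3 (between-pairs 2, 3, 3, 2), Fst = 1 - 0.4 = 0.6
  expect_equal(pairwise_fst(aln, "pop1", "pop2"), 0.6)

  sv <- summarize_alignment(aln, deme_order = c("pop1", "pop2"))
  expect_identical(ncol(sv), 2L * 2L + 5L + 1L)
  expect_equal(as.numeric(sv),
               c(1, 1, 1, 0, 3, 1 / 3, 1 / 3, 1 / 3, 0, 0.6))
  expect_identical(names(sv), summary_vector_names(c("pop1", "pop2")))
})

test_that("degenerate alignments are handled by convention", {
  mono <- haplotype_alignment(matrix("A", 4, 3),
                              deme = c("p1", "p1", "p2", "p2"),
                              seq_length = 3)
  expect_identical(segregating_sites(mono), 0L)
  expect_equal(nucleotide_diversity(mono, "p1"), 0)
  expect_equal(pairwise_fst(mono, "p1", "p2"), 0)  # Hb = 0 convention

  # single-sample deme: pi and S fixed at 0, flagged in the summary
  aln1 <- haplotype_alignment(rbind(x = c("A", "T"), y = c("T", "A"),
                                    z = c("T", "T")),
                              deme = c("p1", "p2", "p2"), seq_length = 2)
  expect_equal(nucleotide_diversity(aln1, "p1"), 0)
  expect_identical(segregating_sites(aln1, "p1"), 0L)
  sv <- summarize_alignment(aln1, deme_order = c("p1", "p2"))
  expect_identical(attr(sv, "single_sample_demes"), "p1")
  expect_equal(sv$pi_p1, 0)
})

test_that("statistics are invariant to sample order within demes", {
  set.seed(8)
  aln <- random_alignment(10, 25, demes = rep(c("p1", "p2"), each = 5))
  sv <- summarize_alignment(aln, deme_order = c("p1", "p2"))
  perm <- sample(10)
  aln_p <- haplotype_alignment(aln$genotypes[perm, ],
                               deme = aln$samples$deme_id[perm],
                               seq_length = aln$seq_length)
  sv_p <- summarize_alignment(aln_p, deme_order = c("p1", "p2"))
  expect_equal(as.numeric(sv), as.numeric(sv_p))
  expect_equal(nucleotide_diversity(aln, "p1"),
               nucleotide_diversity(aln_p, "p1"))
})

test_that("vectorized statistics agree exactly with brute-force loops", {
  set.seed(19)
  for (rep in 1:100) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1); n3 <- sample(1:4, 1)
    demes <- rep(c("p1", "p2", "p3"), times = c(n1, n2, n3))
    states <- if (rep %% 2) c("0", "1") else c("A", "C", "G", "T")
    aln <- random_alignment(n1 + n2 + n3, sample(1:12, 1), demes, states)
    m <- aln$genotypes
    L <- aln$seq_length
    sv <- summarize_alignment(aln, deme_order = c("p1", "p2", "p3"))

    expect_identical(segregating_sites(aln), bf_segregating_sites(m))
    expect_identical(sv$S_total, as.double(bf_segregating_sites(m)))
    for (d in c("p1", "p2", "p3")) {
      rows <- aln$samples$deme_id == d
      expect_equal(sv[[paste0("pi_", d)]],
                   if (sum(rows) > 1) bf_pi(m[rows, , drop = FALSE], L)
                   else 0)
      expect_identical(sv[[paste0("S_", d)]],
                       as.double(bf_segregating_sites(
                         m[rows, , drop = FALSE])))
    }
    for (pr in list(c("p1", "p2"), c("p1", "p3"), c("p2", "p3"))) {
      ra <- aln$samples$deme_id == pr[1]
      rb <- aln$samples$deme_id == pr[2]
      expect_equal(sv[[paste0("fst_", pr[1], "_", pr[2])]],
                   bf_fst(m[ra, , drop = FALSE], m[rb, , drop = FALSE], L))
    }
  }
})

test_that("summary vectors respect their bounds and composition", {
  set.seed(23)
  for (rep in 1:25) {
    aln <- random_alignment(12, 30, demes = rep(c("p1", "p2", "p3"),
                                                each = 4))
    sv <- summarize_alignment(aln, deme_order = c("p1", "p2", "p3"))
    expect_identical(ncol(sv), 2L * 3L + 5L + 3L)
    pis <- as.numeric(sv[paste0("pi_", c("p1", "p2", "p3"))])
    expect_true(all(pis >= 0 & pis <= 1))
    expect_gte(sv$S_total,
               max(as.numeric(sv[paste0("S_", c("p1", "p2", "p3"))])))
    fsts <- as.numeric(sv[grep("^fst_", names(sv))])
    expect_true(all(fsts <= 1))
    expect_gte(sv$S_sd, 0)
    expect_gte(sv$pi_sd, 0)
  }
  # canonical composition for the default 13-deme layout: 109 entries
  expect_length(summary_vector_names(default_model_config()$demes$deme_id),
                109L)
})

test_that("two demes drawn from one panmictic population show no structure", {
  cfg <- single_deme_config(n_samples = 12, size = 800, mu = 5e-5, L = 4000)
  m <- build_model("constant", cfg)
  set.seed(40)
  fst <- replicate(300, {
    aln <- drop_mutations(simulate_genealogy(m))
    relab <- haplotype_alignment(aln$genotypes,
                                 deme = rep(c("gA", "gB"), each = 6),
                                 seq_length = aln$seq_length)
    pairwise_fst(relab, "gA", "gB")
  })
  # mean Fst ~ 0 under the no-structure null (single-replicate estimates
  # are noisy and may be negative; only the mean is constrained)
  expect_lt(abs(mean(fst)), 0.02)
})

test_that("unassigned samples and empty layout demes are rejected", {
  aln <- toy_alignment()
  expect_error(summarize_alignment(aln, deme_order = c("pop1", "popX")),
               "pop2")
  expect_error(summarize_alignment(aln,
                                   deme_order = c("pop1", "pop2", "pop9")),
               "pop9")
})
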