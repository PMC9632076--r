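# coalabc

Serial coalescent simulation and rejection ABC for mitogenome demography.

`coalabc` is for population geneticists analysing temporally sampled
(ancient + modern) mitochondrial genome alignments who want to ask: did
this population pass through a bottleneck during the Last Glacial Maximum
(LGM), during the Eemian interglacial, during both, or neither? The
likelihood of a structured, heterochronously sampled alignment is
intractable, so the package answers by simulation: it simulates dated
genealogies under the four competing demographic scenarios, summarises
simulated and observed data with the same statistic vector, and chooses
among the scenarios with rejection-based approximate Bayesian computation
(ABC).

## The model in brief

Mitogenomes are maternally inherited and non-recombining, so the sample's
ancestry is a single genealogy governed by the haploid coalescent on the
female effective population size `N_ef`. Backward in time, with `k` active
lineages in a deme of `N` females, pairs coalesce at rate

```
k (k − 1) / 2 · 1 / N   per generation,
```

lineages enter the process at their (radiocarbon) sampling ages, whole
demes merge at join events (temporal population structure), and during a
bottleneck epoch every deme size is multiplied by a severity `b ∈ (0, 1]`.
Bottleneck timings carry log-uniform priors (LGM: 20–30 ka BP; Eemian:
115–130 ka BP), severities a uniform prior on 0.2–0.6 (fixed at 1.0 for
the constant scenario). Mutations are infinite-sites with
`Poisson(μ·L·branch length)` counts. The summary vector holds segregating
sites per deme (with mean, SD, total), per-deme nucleotide diversity π
(with mean, SD) and Hudson's `Fst = 1 − Hw/Hb` for every deme pair — 109
entries for the default 13-deme layout. Rejection ABC standardizes each
statistic, accepts the `ceiling(ε·n)` nearest simulated rows (ε = 0.05 by
default) and reads model posterior probabilities off the acceptance
frequencies.

See `vignette("bottleneck-abc")` for the full account of the model,
priors, conventions and design choices.

## Worked example

Generate a synthetic observed dataset under the dual-bottleneck scenario,
run the full pipeline at desk scale, and inspect the model choice:

```r
library(coalabc)

ds <- generate_observed("lgm_eemian", dir = "example_data", seed = 500)
report <- run_full(run_config(
  alignment = ds$paths[["fasta"]],
  metadata  = ds$paths[["metadata"]],
  out_dir   = "example_run",
  n_sims    = 500,        # per model; desk scale
  tolerance = 0.05,
  seed      = 2024))
report$posterior
```

```
# A tibble: 4 × 3
  model      n_accepted posterior
  <chr>           <int>     <dbl>
1 constant           17      0.17
2 lgm                26      0.26
3 eemian             16      0.16
4 lgm_eemian         41      0.41
```

Of the 100 accepted rows (5% of 2,000), the generating dual-bottleneck
scenario contributes the most and attains the highest posterior
probability (0.41). `example_run/` now holds `reference_table.csv`,
`observed_summary.csv`, `abc_report.json` (posteriors plus accepted
parameter quantiles), `accepted_rows.csv` and `run.log`; rerunning with
the same seed reproduces every file byte-for-byte.

Each building block is also usable on its own — e.g.

```r
m   <- build_model("lgm")          # scenario with priors
set.seed(1)
g   <- simulate_genealogy(m)       # dated genealogy, times in generations BP
aln <- drop_mutations(g)           # infinite-sites haplotypes
summarize_alignment(aln)           # 109-entry statistic vector (13 demes)
```

and `tidy()`, `glance()` and `autoplot()` work on fitted `abc_result` /
`abc_cv` objects. A thin command-line wrapper with subcommands
(`full-run`, `simulate-reference`, `abc-fit`, `cross-validate`,
`models print-defaults`, `summarize-observed`) lives at
`inst/cli/coalabc.R`.

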