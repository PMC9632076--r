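"""Independent coalescent oracle: TMRCA samples from msprime.

Simulates the fixed three-deme join scenario used by the package's
oracle-equivalence test and prints one TMRCA (generations BP) per line.

Scenario (haploid, times in generations):
  demes A (N = 1000), B (N = 800), C (N = 1200), two samples each at time 0;
  all B lineages join A at 1500; all C lineages join A at 4000.

Usage: python msprime_tmrca.py SEED N_REPS
"""
import sys

import msprime


def build_demography():
    dem = msprime.Demography()
    dem.add_population(name="A", initial_size=1000, initially_active=True)
    dem.add_population(name="B", initial_size=800)
    dem.add_population(name="C", initial_size=1200)
    dem.add_population_split(time=1500, derived=["B"], ancestral="A")
    dem.add_population_split(time=4000, derived=["C"], ancestral="A")
    return dem


def main():
    seed = int(sys.argv[1])
    n_reps = int(sys.argv[2])
    dem = build_demography()
    out = []
    for ts in msprime.sim_ancestry(
        samples={"A": 2, "B": 2, "C": 2},
        demography=dem,
        ploidy=1,
        num_replicates=n_reps,
        random_seed=seed,
    ):
        out.append(ts.max_root_time)
    sys.stdout.write("\n".join(f"{t:.10g}" for t in out) + "\n")


if __name__ == "__main__":
    main()
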