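"""Independent coalescent oracle used by the test suite.

Reads a JSON model description on stdin, simulates with msprime, and
prints per-population means (and standard errors) of mean pairwise
differences and segregating sites over the requested replicates.

Input schema:
  {"ne": {"pop": size, ...},                  # haploid sizes
   "samples": [["pop", time_gen, n], ...],    # serial sampling events
   "events": [[time_gen, "pulse", sink, source, p],
              [time_gen, "merge", child, parent]],
   "mu_site_gen": rate per site per generation,
   "L": sites, "nrep": replicates, "seed": int}
"""
import json
import sys

import msprime
import numpy as np


def run(cfg):
    demo = msprime.Demography()
    pops = list(cfg["ne"].keys())
    for p in pops:
        demo.add_population(name=p, initial_size=cfg["ne"][p])
    # events sorted by time; at equal times pulses must precede merges
    order = {"pulse": 0, "merge": 1}
    for ev in sorted(cfg["events"], key=lambda e: (e[0], order[e[1]])):
        if ev[1] == "pulse":
            demo.add_mass_migration(time=ev[0], source=ev[2], dest=ev[3],
                                    proportion=ev[4])
        else:
            demo.add_mass_migration(time=ev[0], source=ev[2], dest=ev[3],
                                    proportion=1.0)
    demo.sort_events()
    # deme-remap rule: a sample whose deme has already merged (looking
    # backward) by its sampling time enters the deme's current ancestor
    merges = sorted([e for e in cfg["events"] if e[1] == "merge"],
                    key=lambda e: e[0])
    def resolve(pop, t):
        cur = pop
        changed = True
        while changed:
            changed = False
            for tm, _, child, parent in merges:
                if tm <= t and child == cur:
                    cur = parent
                    changed = True
        return cur
    samples = [msprime.SampleSet(int(n), population=resolve(p, t), time=t,
                                 ploidy=1)
               for p, t, n in cfg["samples"]]
    rng = np.random.default_rng(cfg["seed"])
    pi = {p: [] for p, _, _ in cfg["samples"]}
    S = {p: [] for p, _, _ in cfg["samples"]}
    for _ in range(cfg["nrep"]):
        ts = msprime.sim_ancestry(
            samples=samples, demography=demo, ploidy=1,
            sequence_length=cfg["L"],
            random_seed=int(rng.integers(1, 2**31 - 1)))
        ts = msprime.sim_mutations(
            ts, rate=cfg["mu_site_gen"],
            model=msprime.BinaryMutationModel(),
            random_seed=int(rng.integers(1, 2**31 - 1)))
        G = ts.genotype_matrix()  # sites x samples (registration order)
        offsets = np.cumsum([0] + [int(n) for _, _, n in cfg["samples"]])
        for k, (p, _, _) in enumerate(cfg["samples"]):
            H = G[:, offsets[k]:offsets[k + 1]]
            n = H.shape[1]
            if H.size == 0 or n < 2:
                pi[p].append(0.0)
                S[p].append(0.0)
                continue
            seg = np.any(H != H[:, [0]], axis=1)
            S[p].append(float(seg.sum()))
            # mean pairwise differences
            tot = 0.0
            for i in range(n):
                tot += np.sum(H[:, i + 1:] != H[:, [i]])
            pi[p].append(tot / (n * (n - 1) / 2))
    out = {"pi": {}, "S": {}}
    for p in pi:
        a = np.asarray(pi[p])
        b = np.asarray(S[p])
        out["pi"][p] = [float(a.mean()), float(a.std(ddof=1) / len(a) ** .5)]
        out["S"][p] = [float(b.mean()), float(b.std(ddof=1) / len(b) ** .5)]
    return out


if __name__ == "__main__":
    cfg = json.load(sys.stdin)
    json.dump(run(cfg), sys.stdout)
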