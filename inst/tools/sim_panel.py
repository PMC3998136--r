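# Simulate a neutral coalescent haplotype panel over a 20 Mb region with
# scaled mutation and recombination rates of 0.001 per bp (Ne = 10,000,
# mu = r = 2.5e-8) and write it as site-major 0/1 text with positions.
# usage: python sim_panel.py <n_haplotypes> <seed> <out_path>
import sys

import msprime
import numpy as np

n_hap = int(sys.argv[1])
seed = int(sys.argv[2])
out = sys.argv[3]

ts = msprime.sim_ancestry(
    samples=n_hap // 2, ploidy=2, sequence_length=2e7,
    recombination_rate=2.5e-8, population_size=10000, random_seed=seed)
mts = msprime.sim_mutations(
    ts, rate=2.5e-8, random_seed=seed + 1,
    model=msprime.BinaryMutationModel())

with open(out, "wb") as f:
    for var in mts.variants():
        g = np.asarray(var.genotypes, dtype=np.uint8)
        np.minimum(g, 1, out=g)
        f.write(b"%d " % int(var.site.position))
        f.write((g + 48).tobytes())
        f.write(b"\n")
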