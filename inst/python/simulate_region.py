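"""Neutral coalescent region simulator (msprime backend).

Writes a single-replicate ms-format file: haplotypes of 2 * n_diploids
chromosomes over a region of given length, with uniform background
recombination and an optional hotspot. Positions are continuous
(infinite-sites style) and reported on the usual relative 0-1 scale.

Usage:
  python simulate_region.py OUT LENGTH_BP MU NE N_DIPLOIDS RECOMB_CM_MB \
      HOT_START HOT_LEN HOT_RATE SEED SITES_ONLY

Hotspot fields of 0 disable the hotspot. SITES_ONLY=1 prints the
segregating-site count instead of writing haplotypes.
"""
import sys

import msprime
import numpy as np


def main(argv):
    (out, length_bp, mu, ne, ndip, recomb, hot_start, hot_len, hot_rate,
     seed, sites_only) = argv
    L = float(length_bp)
    mu = float(mu)
    ne = float(ne)
    ndip = int(ndip)
    seed = int(seed)
    sites_only = int(sites_only) == 1
    r_bg = float(recomb) * 1e-8          # cM/Mb -> crossovers/bp/generation
    hs, hl, hr = float(hot_start), float(hot_len), float(hot_rate)

    if hl > 0:
        pos = [0.0, hs, hs + hl, L]
        rates = [r_bg, hr * 1e-8, r_bg]
        rec = msprime.RateMap(position=pos, rate=rates)
    else:
        rec = r_bg

    ts = msprime.sim_ancestry(
        samples=ndip, population_size=ne, sequence_length=L,
        recombination_rate=rec, discrete_genome=False, random_seed=seed)
    mts = msprime.sim_mutations(
        ts, rate=mu, discrete_genome=False, random_seed=seed + 1)

    if sites_only:
        sys.stdout.write("segsites %d\n" % mts.num_sites)
        return 0

    G = mts.genotype_matrix()            # sites x haplotypes, 0/1
    rel = np.array([s.position for s in mts.sites()]) / L
    H = G.T.astype(np.uint8) + 48        # ASCII '0'/'1'
    body = np.hstack(
        [H, np.full((H.shape[0], 1), 10, dtype=np.uint8)]).tobytes()

    with open(out, "wb") as f:
        f.write(b"ms %d 1\n%d\n\n//\nsegsites: %d\npositions: "
                % (H.shape[0], seed, G.shape[0]))
        f.write(" ".join("%.8f" % p for p in rel).encode())
        f.write(b"\n")
        f.write(body)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv[1:]))
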