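"""Convert a tskit tree sequence into the ibdbench text track format.

Usage: python trees_to_track.py <in.trees> <out.tsv>

For every unordered pair of sample nodes, emits run-length-encoded MRCA
node ids over the local trees (consecutive trees with an unchanged MRCA are
merged). Sample nodes 2k, 2k+1 are reported as individual ind<k+1>,
haplotypes 0/1, matching diploid sample layout.
"""
import sys

import tskit


def main(path_in, path_out):
    ts = tskit.load(path_in)
    samples = list(ts.samples())
    n = len(samples)
    ids = {s: ("ind%03d" % (k // 2 + 1), k % 2) for k, s in enumerate(samples)}
    pairs = [(samples[i], samples[j])
             for i in range(n) for j in range(i + 1, n)
             if ids[samples[i]][0] != ids[samples[j]][0]]
    cur = {}   # pair -> [start, mrca]
    rows = []
    L = ts.sequence_length
    for tree in ts.trees():
        left = tree.interval.left
        for p in pairs:
            m = tree.mrca(*p)
            if p not in cur:
                cur[p] = [left, m]
            elif cur[p][1] != m:
                rows.append((p, cur[p][0], left, cur[p][1]))
                cur[p] = [left, m]
    for p, (start, m) in cur.items():
        rows.append((p, start, L, m))
    with open(path_out, "w") as fh:
        chrom = "1"
        fh.write("#chrom=%s region_bp=%d\n" % (chrom, int(L)))
        fh.write("sample1\thap1\tsample2\thap2\tstart_bp\tend_bp\tlabel\n")
        for (a, b), start, end, m in rows:
            sa, ha = ids[a]
            sb, hb = ids[b]
            fh.write("%s\t%d\t%s\t%d\t%d\t%d\t%d\n"
                     % (sa, ha, sb, hb, int(start), int(end), int(m)))


if __name__ == "__main__":
    if len(sys.argv) != 3:
        sys.exit(__doc__)
    main(sys.argv[1], sys.argv[2])
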