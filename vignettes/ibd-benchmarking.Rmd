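---
title: "Benchmarking IBD segment detection with ibdbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking IBD segment detection with ibdbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdbench)
```

## The problem

Identity-by-descent (IBD) segments are chromosomal stretches two haplotypes
co-inherited from a common ancestor without intervening recombination.
Detectors that scan phased haplotype panels for such segments (hap-IBD,
RaPID, iLash, TPBWT, FastSMC and relatives) disagree substantially, and their
output quality depends on marker density, genotyping error and segment
length. `ibdbench` provides the scaffolding needed to measure that quality:
it extracts *ground-truth* IBD segments from coalescent local-tree tracks,
prepares test panels with controlled marker density and error rates, and
scores any detector's reported segments against the truth with six
length-stratified metrics, plus coverage profiles and relatedness-degree
tables for two common downstream applications.

The detectors themselves are never run by this package; their outputs are
consumed as tab-separated call files.

## Ground truth from local trees

At every genomic position, a pair of haplotypes has a most recent common
ancestor (MRCA) in the local genealogical tree; a true IBD segment is a
maximal run of positions over which that MRCA does not change. A
`local_tree_track` stores, per unordered haplotype pair, a run-length
encoding of opaque MRCA labels over half-open bp intervals partitioning the
region. `extract_truth_ibd()` reads the label at sampled positions
`0, s, 2s, ...` (default step `s` = 5,000 bp), turns maximal runs of one
label into segments, and drops segments whose genetic length on the supplied
map is below 1 cM (both defaults are tunable via `TruthConfig`-style
arguments).

Three boundary conventions matter and are fixed as follows:

* a segment starts at the first sampled position of its run and ends at the
  first sampled position *after* the run, so boundaries sit on the sampling
  grid (an `exact_breakpoints = TRUE` mode uses the tree breakpoints
  instead);
* the terminal run closes at the region end `L`, not at the last sampled
  position, which would otherwise truncate every final segment by up to one
  step;
* MRCA identity is label equality within one track; no attempt is made to
  merge runs whose distinct MRCA nodes have equal ages.

Adjacent runs carry different labels, so consecutive truth segments of one
pair may share a boundary point; segments never overlap. Pairs formed by one
individual's own two haplotypes are excluded by default (they reflect
inbreeding loops rather than the detector use case) and can be included via
`include_within`.

Binary `.trees` tree sequences are imported with `read_tree_sequence()`,
which delegates the pairwise-MRCA sweep to a bundled tskit helper script;
running the coalescent simulation itself (demography, mutation rate) is out
of scope and left to msprime/stdpopsim.

## Panels: filtering, array density, genotyping error

`filter_sites()` removes sites with more than two observed allele values and
sites whose minor allele count is 0 or 1 — multiallelic sites confuse
biallelic detectors, and singletons carry no pairwise sharing signal.

`downsample_to_array()` emulates genotyping-array marker selection. The
mapped genetic length is divided by the target marker count (the default
17,197 mirrors a dense-chip chromosome-20 design) to give an ideal
inter-marker interval *I* in cM; intervals are grouped into windows of
*w* = 5 intervals. Pass 1 takes the highest-MAF site in each interval; pass
2 fills each still-empty interval from the highest-MAF unused site in its
window. MAF ties break toward the lower bp position, making selection
deterministic. Windows are laid left to right from the first mapped cM, and
a final partial window is processed with whatever intervals it has.

`inject_genotyping_errors()` flips individual alleles 0↔1 uniformly at
random at a target per-allele rate (study rates 0.1–0.4%, with
0.0125–0.05% for error-sensitive sequencing runs). "Per genotype" is
interpreted as an independent per-haplotype-allele flip, since errors are
implanted into the phased panels the detectors actually read; users who
prefer a per-diploid-genotype reading can halve or double the rate. Error
sets layer incrementally: given the error set of a lower rate `r1`, only
additional cells are flipped with probability `(r2 - r1)/(1 - r1)`, so the
marginal rate is exactly `r2` and the `r1` set is a subset of the `r2` set —
a higher-error panel is the lower-error panel plus new errors, never a
re-roll. `merge_haplotypes_to_genotypes()` collapses haplotype pairs into
unphased genotypes for workflows that need genotype matrices.

## The six metrics

All comparisons use genetic coordinates (cM) under one map; physical or
variant-site comparison modes are deliberately not offered. Segments are
comparable only within the same unordered haplotype pair
(`pair_mode = "haplotype"`); `pair_mode = "individual"` pools the four
haplotype combinations of a sample pair for detectors that do not report
haplotype indices.

Reported-side, against the full truth set (`evaluate_reported()`):

* **accuracy** — fraction of reported segments whose best-matching truth
  segment (longest overlap) covers ≥ 50% of the reported length; `1 −
  accuracy` is the false-positive fraction;
* **length accuracy** — mean covered fraction of each reported segment by
  its best match, averaged over *all* reported segments (unmatched
  contribute 0; a matched-only average is available as an option);
* **length discrepancy** — RMS of |reported length − best-match truth
  length| over matched reported segments, in cM. Unmatched segments are
  excluded because no best match exists; an option penalizes them with
  their full length instead.

Truth-side, against the full reported set (`evaluate_truth()`):

* **recall** — fraction of truth segments covered ≥ 50% by one best
  reported segment;
* **power** — mean covered fraction of truth by the single best reported
  segment;
* **accumulative power** — as power, crediting the merged union of all
  overlapping reported segments (overlaps are merged first so shared
  coverage is not double-counted); accumulative power ≥ power always.

Coverage uses a *single* best segment, never a union, for accuracy and
recall; 50% is the `coverage_threshold` default and the boundary is
inclusive. Best-match ties on overlap break toward the candidate with the
smaller absolute length difference, then the earlier start; ties can affect
length discrepancy only.

### Length-stratified reporting

`evaluate_binned()` stratifies both sets into bins [2,3), [3,4), [4,5),
[5,6), [6,7), [7,∞) cM and scores every bin against the FULL other set.
The full-set reference prevents a boundary artifact: a 2.9 cM call nested
inside a 3.0 cM truth segment falls into [2,3) while its truth falls into
[3,4); under a per-bin reference this nearly perfect call would count as a
false positive. The rejected per-bin scheme remains available
(`reference = "bin"`) for demonstrating exactly this effect. The bin list
treats the gap between 6 and 7 cM as a typographical omission in the
protocol it mirrors and includes [6,7) by default; any bin set, including
non-contiguous ones, can be supplied via `metric_config(bins = ...)`.

## Coverage profiles and relatedness

`coverage_profile()` counts, at each panel marker, the number of segments of
length ≥ 2 cM (configurable) covering it — comparing a detector's profile to
the truth profile localizes over- and under-calling along the chromosome.
Profiles are computed at marker positions, not on a uniform grid, matching
how such plots are read against marker indexes.

`total_ibd_per_pair()` sums segment lengths over all haplotype combinations
of each individual pair, and `assign_degree()` converts the total to an
estimated kinship coefficient `phi = total_cm / (4 * genome_length_cm)`,
classified into relatedness degrees 1–4 by the standard dyadic ranges
`phi in (2^-(d+3/2), 2^-(d+1/2)]` (degree 1: (0.177, 0.354]). The interval
is upper-inclusive; kinship above the degree-1 upper bound (duplicate
samples, grossly inflated calls) clamps to degree 1, and anything at or
below the degree-4 lower bound is "unrelated". The reference protocol cites
but does not print its thresholds, so these defaults are the field-standard
ranges and are fully overridable; no adjustment is made for detector power
loss, mirroring the protocol.

## Synthetic data and the independent oracle

The generators exist so every stage is testable without external
simulations:

* `gen_track()` lays down per-pair MRCA breakpoints as a Poisson process
  with a configurable mean segment length and gives every run a fresh
  label — the piecewise structure of a tree sequence without its
  correlations;
* `gen_panel()` draws site MAFs from a configurable distribution and
  alleles as independent Bernoulli draws — no linkage disequilibrium;
* `gen_scenario()` plants truth segments (lengths
  `min + Exp(mean - min)`, defaults 2 and 5 cM, chosen to populate every
  length bin while keeping most mass at the short, hard end) and derives
  reported calls with a pseudo-caller that reproduces the failure modes
  observed in real detectors: missed segments, jittered boundaries,
  fragmentation into pieces with a gap, and off-truth false positives.

`gen_scenario()` stamps each scenario with its expected metric report
computed by `oracle_metric_report()`, a naive quadratic loop over all
segment pairs that shares no code with the indexed engine. This
anti-circularity rule is what makes engine-vs-oracle equivalence tests
meaningful. The same pattern covers truth extraction
(`extract_truth_ibd_oracle()`, a literal per-position scan).

What passing these tests does *not* show: the generators have no
demography, no linkage, and no realistic IBD length spectrum, so agreement
on synthetic data validates the *metric arithmetic and bookkeeping*, not
any claim about how detectors perform on real cohorts. Sequencing-error
realism (false non-variant calls, nucleotide- and region-specific profiles)
and phasing-error simulation are likewise out of scope; pre-perturbed
panels are consumed as inputs.

## Numerical choices

* Physical intervals are half-open `[start_bp, end_bp)`, 0-based
  internally; detector files are assumed 1-based inclusive and converted on
  read (overridable per dialect). Genetic length is `cm(end) − cm(start)`.
* Genetic maps interpolate piecewise-linearly and clamp outside the mapped
  range rather than extrapolate, so sparse maps cannot produce negative or
  inflated lengths.
* When a call file carries its own cM lengths *and* a map is supplied, the
  map wins (all tools must be scored in one coordinate system); rows
  deviating by more than 0.01 cM are counted and reported. Without a map
  the file's lengths are preserved exactly.
* The pseudo-caller works in cM space and rounds back to integer bp;
  rounding (not floor/ceiling) keeps map round trips exact, and a 0.05 cM
  floor prevents boundary jitter from inverting an interval.
* Unordered pairs are canonicalized lexicographically on
  (sample id, haplotype index); all containers store the canonical order.
* Degenerate inputs: empty reported sets yield NA (not 0) for
  reported-side metrics, empty truth sets NA for truth-side metrics, and
  empty bins NA rows with zero counts — absence of evidence is not a score.

## Problem sizes in the shipped tests

The test suite validates the engine against the oracle on 1,000 random
scenarios of up to 50 truth and 50 reported segments, truth extraction on
50 random tracks of up to 12 haplotypes, downsampling on 10,000-site panels
with a 1,000-marker target over 20 seeds, error injection on a
10⁶-allele panel over 100 seeds, and one end-to-end pipeline run on 200
haplotypes over 10 Mb — sizes chosen so the full suite exercises every code
path at meaningful scale on a single CPU.

## Limitations

* Only genetic-coordinate scoring is implemented; variant-site overlap
  (preferable for IBD mapping applications) is not.
* Metrics are point values; no uncertainty quantification is attached.
* The `.trees` importer computes pairwise MRCAs tree by tree and is
  quadratic in sample count; it is meant for moderate panels, not biobanks.
* The error model is a uniform allele-flip; it does not model
  false-positive variant sites (the singleton filter is assumed to remove
  most of them) nor error rates that differ by allele frequency class.
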