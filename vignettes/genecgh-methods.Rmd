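---
title: "Methods: gene-centric CNV calling from two-channel aCGH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-centric CNV calling from two-channel aCGH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Segmentation-based CNV callers walk along a chromosome looking for
breakpoints in probe log ratios. That requires a contiguous reference
genome; large conifer genomes (and many other non-model genomes) only
have fragmented assemblies of the gene space. `genecgh` therefore treats
the *gene* as the unit of inference. Each gene carries its own tile of
oligonucleotide probes (at least 6, on average ~12.6, up to 114 in the
design this package models), and the copy-number decision for a gene on
one hybridization is a vote over its probes.

The measurement model for one probe on one array is

    M = log2(I1 / I2),  A = log2(sqrt(I1 * I2)),

with `I1`, `I2` the background-subtracted intensities of the test and
reference channels. If the test genome has `c_t` copies of the gene and
the reference genome `c_r`, probe M values scatter around
`log2(c_t / c_r)` — 0.585 for 3:2, -1 for 1:2 — plus systematic terms
(dye bias, GC waves, probe composition) that the normalization removes,
plus approximately Gaussian noise.

A probe is *significant* when `|M| > tau` strictly, with
`tau = |log2(4/3)| ~ 0.41504` by default: the smallest ratio shift of
biological interest (a 3-versus-4 copy difference). A gene is called a
CNV when at least `ceiling(frac * n)` of its `n` probes are significant
*with a consistent sign* (`frac = 0.83`), the call direction being the
majority sign. Genes with fewer than 6 measured probes are untested, not
negative. Called genes whose absolute median M exceeds 3 are flagged as
presence/absence variants (PAV): at such ratios the dye intensity range
of the array no longer distinguishes "very few copies" from "none".

In a pedigree design, each offspring (test) is compared against one
parent (reference). Inherited CNVs recur across sibs, which is the main
internal replication of the design; self-self hybridizations — one DNA
in both channels — provide the null.

## FDR calibration from self-self arrays

Every gene called on a self-self array is a false positive, so the
empirical FDR of a parameter pair `(tau, frac)` is the fraction of
tested genes called, averaged across the self-self arrays.
`grid_search()` evaluates a grid (defaults: `tau` in `|log2(k/4)|` for
k = 3, 2, 1; `frac` in 0.75–1.0) and selects, among cells with pooled
FDR at or below 1%, the smallest `tau` and then the smallest `frac` —
i.e. the most sensitive admissible operating point. The selection rule
is this package's choice; the source design only reports that its
chosen pair achieved FDR << 1%. The FDR denominator is genes tested per
array, pooled by averaging across arrays, since the null design reports
an FDR per comparison.

The published description of this design gives the gene criterion as
83% in one place and 0.85 in another. The package defaults to 0.83 —
consistent with 5-of-6 probes on the smallest callable genes — and both
values sit in the default calibration grid, so the choice is visible in
every grid report rather than silently resolved.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tau` | `abs(log2(4/3))` ~ 0.41504 | log2 ratio | 3:4 copy ratio; printed as 0.42 in the literature. The exact value is the default; 0.42 is available via config. |
| `frac` | 0.83 | fraction | 5/6 on minimum genes; see discrepancy note above. |
| `pav_tau` | 3.0 | log2 ratio | beyond ~8-fold the array saturates; calls are PAV. Strict inequality. |
| `min_probes` | 6 | count | design floor; fewer probes = untested. |
| LOESS `span` | 0.3 | fraction of probes | standard MA-plot smoothing window; the source names the method, not its parameters. |
| `robust_iters` | 3 | iterations | robustifying reweighting of the smoother. |
| GC `level` | probe | — | `gene` reproduces contig-level correction by averaging probe GC within a gene. |
| `fdr_ceiling` | 0.01 | fraction | admissibility bound ("FDR << 1%"). |
| `cluster_window` | 1.0 | cM | chained-gap rule for map clusters. |

## The synthetic world

The simulator states one explicit world and the tests interrogate it:

* **Panel** — `n_genes` genes; probe count `6 + Poisson(6.6)` capped at
  114 (mean 12.6, minimum 6, maximum as in the modeled design); gene
  length gamma-distributed above 600 bp with mean 2869 bp; probes of
  60 bp placed evenly along the gene; GC per probe from a unimodal Beta
  rescaled to (0.2, 0.8), with independent C/G and A/T splits so the
  composition covariates are not collinear.
* **Pedigree** — with probability `p_cnv = 0.05` a gene segregates a
  CNV genotype (heterozygous deletion or duplication by default;
  homozygous states 0 and 4 optional). With probability `p_both = 0.2`
  both parents carry it — necessary for an offspring to reach zero
  copies, since a PAV offspring must receive a deletion allele from
  *each* parent. Otherwise the carrier parent is chosen at random; the
  reference genome is always parent 1. Offspring inherit one allele per
  parent uniformly (Mendelian transmission); 19 offspring per family by
  default.
* **Intensities** — per probe, `A ~ Normal(10, 1)`;
  `M = log2(c_t/c_r) + dye_intercept + dye_slope*(A - 10) +
  gc_amplitude*2*(gc - 0.5) + Normal(0, sigma)` with defaults 0.2,
  0.15, 0.3 and `sigma = 0.15`; channel intensities
  `I1 = 2^(A + M/2)`, `I2 = 2^(A - M/2)` so that A is independent of
  copy state; small positive backgrounds are added to the raws, so
  background subtraction recovers the generated signal exactly. A
  zero-copy test genome is represented by a floor `pav_floor = -4`
  rather than -Inf, mirroring the saturation of real arrays. No noise
  magnitudes are published for the real hybridizations; `sigma` is a
  free parameter of the stated world, not an estimate.

What the simulator deliberately omits: spatial (print-tip) artifacts,
saturation nonlinearity, cross-hybridization between paralogs, and
sequence divergence between test and probe design. A green test
establishes that the algorithms do what their closed forms say on data
obeying this generative model — not that the model captures every
failure mode of physical arrays.

## Numerical choices and degenerate inputs

* **Background subtraction** is `raw - background`; probes non-positive
  in either channel are dropped (counted, never imputed) because M is
  undefined for them. The source design does not state its rule.
* **Quorum arithmetic**: `ceiling(frac * n)` with a `1e-9` guard so
  that `0.83 * 100` does not ceil to 84 through floating point. Ceiling
  (not floor) implements the "minimum of 83%" reading.
* **Strictness**: probe significance, the 500-bp covered-length rule
  and the PAV threshold are all strict inequalities ("superior to").
  The 2x-background quality rule is inclusive; the source is ambiguous.
* **Sign consistency**: only majority-sign significant probes count
  toward the quorum. A gene split 6 gains / 6 losses is an artifact,
  not a CNV. Published criteria do not address mixed signs.
* **Gene summary** is the median probe M (robust); the gene-level "log
  ratio" is otherwise undefined in the source.
* **Smoothers**: the dye and GC corrections use `stats::lowess`
  (robust locally weighted regression; `iter` robustifying passes),
  interpolated back to the observed covariates. The test suite checks
  the dye correction against `limma::loessFit` as an independent
  oracle. Constant GC skips the correction with a warning; collinear
  composition covariates are dropped with a warning.
* **Stage enforcement**: tables carry a `stage` attribute and the order
  raw -> loess -> gc -> composition is mandatory, so a half-normalized
  table cannot silently enter the caller.
* **Probe selection**: the orientation tie-break keeps the sense probe
  (deterministic, arbitrary); spacing thinning is greedy from the
  leftmost probe and decides its spacing (200 vs 100 bp at the 16-probe
  switch) from the count *before* thinning; the filter order is quality
  -> dedup -> eligibility -> spacing. None of these details are stated
  in the source; all are idempotent by construction. Design-time probe
  validation against a genome (single hit, mismatch limits) needs an
  external aligner and is out of scope; `select_probes()` is the hook
  point where such a filter would slot in.
* **Zero-variance ANOVA**: two identical constant groups give the
  textbook 0/0; `compare_family_counts()` reports F = 0, p = 1.
* **Genetic map**: mean adjacent distances pool consecutive gaps across
  linkage groups without spanning them; a cluster is a maximal run of
  mapped CNV genes with chained gaps <= 1 cM; the Kolmogorov–Smirnov
  comparison min-max scales positions within each linkage group to
  [0, 1] before pooling (the source does not state its handling of
  multiple groups). Outlier individuals are flagged beyond the family
  mean + 2 SD, a definition the source describes but never fixes.
* **Config files** are flat `key = value` (the scalar subset of flat
  TOML), since no TOML parser is available in the dependency set.
  Vendor scanner exports are not parsed; converting a generic two-color
  export to the intensity TSV is a five-column rename, documented in
  `read_arrays()`.

## Known limitations

* Calls are relative to the reference genome: a gene duplicated in the
  reference parent shows offspring "losses" at ratio 2:3. Truth tables
  in the simulator make this explicit (`cn_ref` can be 0–4).
* The binomial sensitivity analysis assumes independent probe noise;
  correlated probe effects (shared sequence context) would widen the
  gene-level error beyond the closed form.
* FDR calibration bounds false positives under the null only; it says
  nothing about sensitivity, which is why the test suite carries a
  separate binomial-oracle sensitivity check.
* The integer copy number is never estimated — only direction and
  magnitude classes (CNV / PAV) — and no segmentation across genes is
  attempted, by design.
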