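---
title: "Temporal codon usage in viral genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal codon usage in viral genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codontempo)
```

# The question

Lytic viruses express their genes in temporal waves: *early* genes
(replication, host takeover) are transcribed before the onset of the
late program, *late* genes (structural proteins, assembly, lysis) after
it. Because the intracellular environment — tRNA pools, energy budget,
translation load — differs between these phases, selection can in
principle favor different *synonymous* codon choices in early versus
late genes even when the encoded proteins are unconstrained.
`codontempo` quantifies and tests that signal for any virus with a
literature-derived early/late gene classification, and computes the
companion genomic features commonly examined alongside it.

# Representation: RSCF vectors

Each coding sequence is represented by its relative synonymous codon
frequencies (RSCF): a 61-dimensional vector in which a sense codon's
entry is its count divided by the total count of its synonymous family
in that gene. Stop codons are excluded throughout, as is the terminal
stop of every CDS and any in-frame triplet containing a non-ACGT
symbol. Within every amino-acid family present in a gene, the entries
sum to 1.

Two genes with similar synonymous preferences are then close in
Euclidean distance regardless of their amino-acid composition. RSCF is
preferred here over the classical RSCU because it reads directly as a
frequency; RSCU (`rscu()`) is provided as an alternative and differs
only by a per-family scale factor, so conclusions are insensitive to
the choice.

**Fill policy.** A family absent from a gene has no defined frequency.
The default fills its entries with 0, keeping the vector a pure
frequency readout — in the Euclidean geometry absent families then sit
uninformatively near the origin. The alternative (`fill = "uniform"`,
1/degeneracy) is available; the policy is a single argument so an
analysis is always internally consistent.

# The separation statistic and its null

Separation of the two temporal groups in RSCF (or amino-acid frequency)
space is measured by the two-cluster Davies–Bouldin score

$$\mathrm{DBS} = \frac{S_\mathrm{early} + S_\mathrm{late}}{M},$$

where $S_g$ is the mean Euclidean distance of group $g$'s points to
their centroid and $M$ the distance between the centroids. Lower is
better separated; coincident centroids give an infinite (non-separable)
score.

Significance comes from a label-permutation null: group labels are
reshuffled uniformly at random (group sizes preserved) `n_perm` times
(default 1000), and the one-sided empirical p-value in the
smaller-is-better direction uses the add-one correction
$p = (1 + \#\{\mathrm{DBS}_\pi \le \mathrm{DBS}_\mathrm{obs}\})/(1 + n_\mathrm{perm})$,
so $p$ is never exactly zero and is exactly uniform on its support
under exchangeability. Significance is called at $\alpha = 0.05$.
Per-virus p-values are reported raw, matching the analysis style this
implements; Benjamini–Hochberg adjusted values across viruses are
emitted alongside (`p_adjusted_bh`) as a clearly labeled extension.

For display, `autoplot()` projects the vectors onto their first two
principal components (mean-centered only — RSCF entries share a scale,
so unit-variance scaling would inflate rare families) and overlays the
maximum-margin separating line, computed as a linear hard-margin SVM
(soft margin at penalty $10^6$ when the groups overlap, flagged
non-separable). PCA is per virus, so explained-variance percentages are
per panel.

# Companion genomic features

All features use natural logarithms wherever a base is unstated, and
the same ambiguity/stop exclusions as the codon counts.

* **ENC** (effective number of codons, 20 = maximally biased, 61 =
  uniform synonymous usage): $\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar
  F_3 + 5/\bar F_4 + 3/\bar F_6$, where $\bar F_k$ averages $F = (n\sum
  p_i^2 - 1)/(n-1)$ over $k$-fold families with $n \ge 2$ observed
  codons ($F = 0$ families excluded). A missing 3-fold class is
  estimated as the mean of the 2- and 4-fold classes (the published
  substitution); if any *other* degeneracy class is entirely
  unobserved — which essentially only happens in degenerate toy
  inputs — its term is dropped and the result rescaled by the fraction
  of codons covered, an extension of ours, and capped at 61. Genes
  under 100 codons are flagged as short.
* **GC content**: G+C over unambiguous bases.
* **CPB** (codon-pair bias): each adjacent in-frame codon pair $(A,B)$
  encoding amino acids $(X,Y)$ gets the score
  $\mathrm{CPS}(AB) = \ln\frac{N(AB)\,N(X)\,N(Y)}{N(A)\,N(B)\,N(XY)}$
  with counts pooled over all genes of the virus; CPB is the mean CPS
  over all pair *occurrences* (each occurrence counts once; a
  per-distinct-pair mean is available). Pairs spanning a dropped codon
  are excluded, as are pairs across gene boundaries; start codons are
  not treated specially.
* **DNTB** (dinucleotide bias): the observed/expected ratio
  $f(xy)/(f(x)f(y))$ per dinucleotide, counted overlapping within genes
  on the coding strand without distinguishing frame positions, averaged
  over occurrences.
* **NTB / AAB**: normalized Shannon entropies $-\sum p_i \ln p_i / \ln
  N$ of the nucleotide ($N=4$) and amino-acid ($N=20$) frequencies;
  1 means uniform.

Per-feature early/late differences are tested with the two-sided
Wilcoxon rank-sum test, reported with a direction sign (+1 when the
early-gene mean is higher).

# Host-adjusted tAI

The tRNA adaptation index scores a gene by the geometric mean of
per-codon relative adaptiveness weights $w$. Absolute weights accumulate
$W(\mathrm{codon}) = \sum (1 - s_\mathrm{class})\cdot
\mathrm{copies}(\mathrm{anticodon})$ over cognate anticodons;
$w = W/\max W$, with zero-weight codons imputed by the geometric mean of
the nonzero $w$. The pairing table is generated from a single rule — a
wobble anticodon is admissible only when its Watson–Crick codon encodes
the same amino acid — which reproduces the standard table (G:U, I:C,
I:A, U:G classes) and automatically excludes the Met/Trp cross-readings;
bacteria additionally gain the lysidine pairing (modified C34 reading
the AUA isoleucine codon). Default penalties are the published
prokaryotic values (G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68, L:A 0.89).

Because expression data for penalty calibration are unavailable for most
hosts, `optimize_penalties()` adjusts the free s-values by maximizing
the Spearman correlation between per-gene tAI and a per-gene
codon-usage-bias objective over a host gene collection (coordinate
ascent on a 0.05 grid, 10 seeded random restarts). **The default
objective is a stand-in**: the mean, over a gene's codons, of the ratio
of the codon's frequency to the product of its positional nucleotide
frequencies; negated ENC and an RSCU-based score are selectable.

**Known limitation.** The correlation surface over s is shallow:
simulations in which codon usage is driven by planted weights show the
achieved correlation barely distinguishes neighbouring s values, so the
*calibrated penalties themselves are weakly identified* even when the
achieved correlation is high (> 0.8). Downstream tAI values are stable
because they depend on s only through the weights of wobble-read
codons; but the recovered s should not be interpreted as estimates of
physical coupling efficiencies.

# Decoding rates from ribosome profiling

Per-gene footprint-count profiles (one count per codon position) are
normalized to NFC — count over the gene's mean count across included
positions — so a value of 2 means the ribosome dwells twice as long as
this gene's average codon. Defaults, each an explicit argument: the
first and last 5 codons are excluded (ramp and boundary artifacts);
zero-count positions are treated as missing coverage, not zero dwell
(`include_zeros = TRUE` inverts this, and both modes are tested); genes
with mean raw count below 1 footprint/codon are dropped.

Pooled per codon type across genes, the NFC distribution is skewed and
is modeled as an exponentially modified Gaussian — the sum of a Gaussian
$(\mu, \sigma)$ "typical dwell" component and an exponential
$(\lambda)$ tail of pausing events. Parameters are fitted by maximum
likelihood: the density is evaluated in log scale through
`pnorm(log.p = TRUE)` so extreme tails cannot overflow; optimization is
Nelder–Mead from a method-of-moments start (skewness-based) with three
seeded jittered restarts, and the fit never reports a likelihood below
its initializer. Codons need at least 200 pooled observations. The
typical decoding rate is $\mathrm{TDR} = 1/\mu$, and a gene's MTDR is
the geometric mean of its codons' TDRs (codons lacking a TDR are
skipped with a warning, or the gene can be skipped). Since ribo-seq is
typically available for the host rather than for each phage, a TDR
table fitted on host genes may be applied to the phage's genes; that
cross-application is an explicit, flagged mode, not a default.

# Alignment-free proteome phylogeny

The similarity of two proteomes is the average common-substring length:
for every residue position of proteome A, the length of the longest
substring starting there that occurs anywhere in B, averaged over all
positions of A. Matches never cross protein boundaries (proteins are
concatenated with side-specific sentinels), ambiguous residues never
match, and positions with no match contribute 0 (they can instead be
excluded with a flag). The corrected, symmetrized distance is

$$d(A,B) = \tfrac12\left[\frac{\ln|B|}{L(A,B)} - \frac{\ln|A|}{L(A,A)}
 + \frac{\ln|A|}{L(B,A)} - \frac{\ln|B|}{L(B,B)}\right],$$

which is zero on identical proteomes; the self term is computed by the
same operator rather than assumed from the single-sequence closed form
$(|A|+1)/2$. Small negative off-diagonal values from the correction are
clipped to 0 with a message. Trees are built by canonical Saitou–Nei
neighbor joining (negative branch lengths clipped to 0, deficit
logged).

The association between the tree and the per-virus significance flags
is tested with a statistic of our choosing (the upstream analysis's
exact statistic is not restated in its methods): the mean patristic
distance within the flagged group against a null of flags shuffled over
leaves, 1000 permutations.

# The synthetic generators

Every input the pipeline consumes can be generated with planted ground
truth, so all stages are testable without downloads.

* `synth_virus()` draws amino-acid sequences from a fixed typical
  globular-protein composition and codons per family from
  $P_\mathrm{early}$ (a seeded Dirichlet(1) draw per family) for early
  genes and $P_\mathrm{late} = (1-\delta) P_\mathrm{early} + \delta Q$
  for late genes, with $Q$ a sparse Dirichlet(0.5) perturbation — so
  $\delta$ monotonically controls RSCF divergence and $\delta = 0$
  means a shared distribution. Defaults: phage-scale 25 early/40 late
  genes (a human-virus preset uses 8/14, the group sizes typical of
  human viruses), gene lengths uniform on 100–400 codons. An optional
  GC target exponentially tilts every family distribution (infeasible
  targets error).
* `synth_ribo_profiles()` draws one dwell per codon position from that
  codon's planted EMG and converts to counts by depth-scaling and
  rounding.
* `synth_proteome_family()` evolves a root proteome of random segments
  down a given tree, replacing each segment with fresh sequence with
  probability proportional to branch length. Recovery simulations use
  6-taxon random trees with branch lengths uniform on [0.2, 1], shuffle
  rate 0.3, and 60 segments of 30 residues.

What the generators deliberately do *not* emulate: real codon tables of
particular viruses, gene overlap and operon structure, positional codon
effects, amino-acid covariation, sequencing noise models beyond
rounding. Passing tests therefore demonstrate the statistical machinery
is correct and calibrated, not that any particular real virus shows the
signal.

# Determinism and problem sizes

Every stochastic step takes an explicit integer seed; a study seed
deterministically derives per-virus, per-analysis sub-seeds
(`seed * 1009 + virus_index * 131 + analysis_index`, reduced modulo a
32-bit prime), so adding a virus to a study does not change the others'
results. Simulation-based checks in the test suite use: 500 null
replicates (50+50 genes, 200 permutations) for calibration; 100
replicates per divergence level for power; 50 planted phylogenies for
topology recovery; 100 subsampling rounds at 8 early/14 late. These
sizes put Monte-Carlo error comfortably inside the asserted bands while
keeping the default suite quick.

# Worked example

```{r example, eval = FALSE}
v <- synth_virus(synth_config(n_early = 10, n_late = 14,
                              divergence = 0.6, seed = 101))
st <- separation_test(v$genes, n_perm = 1000, seed = 1)
st
glance(st)
autoplot(st)

report <- run_study(v$genes, n_perm = 1000, seed = 1)
glance(report)
group_feature_comparison(report)
```

# Limitations

* The early/late dichotomy is an input; viruses with "middle" classes
  must be re-mapped by the user before analysis.
* ENC for genes missing whole degeneracy classes uses our documented
  rescaling extension; interpret such values qualitatively.
* Calibrated wobble penalties are weakly identified (see above).
* The phylogeny association statistic is this package's stand-in for
  an analysis whose exact form its source does not restate.
* The NFC normalization knobs (edge trimming, zero handling, coverage)
  mirror common practice but are not a reconstruction of any single
  published pipeline; all are explicit arguments.
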