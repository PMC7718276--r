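---
title: "Methods: master-regulator inference and companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: master-regulator inference and companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mraxis)
```

# Scope

`mraxis` implements the computational core of a master-regulator analysis
for oncohistone-driven transcriptome remodelling: signed gene significance
scores from differential-expression tables, a distance- and
out-degree-weighted TF network score with aggregate ranking, pre-ranked and
single-sample GSEA, hypergeometric overlap, somatic-variant consensus
filtering for matched and unmatched tumour designs, pathway mutant
classification, and strand-oriented TSS metagene profiles. This vignette
records the model, the parameters that matter, and the design decisions
taken where the procedure was genuinely open.

# Gene scoring

A differential-expression table (one row per gene: log2 fold-change, p,
BH-adjusted p) is consumed, never fitted — count modelling and dispersion
estimation are out of scope. The per-gene score is

$$S_r = \operatorname{sign}(\log_2 FC_r)\,\bigl(-\log_{10} q_r\bigr),$$

with $q_r$ the Benjamini–Hochberg adjusted p-value. Two conventions need
fixing:

- **"Fold-change > 1" is read on the log2 scale.** A threshold of 1 on the
  *linear* scale would call every upregulated gene; |log2FC| > 1 (2-fold)
  with q < 0.05 is the standard edgeR-style call, and both inequalities are
  strict as printed.
- **q = 0 is capped** at the smallest positive double before the log, so
  scores stay finite (cap ≈ 308). A zero fold-change scores exactly 0
  regardless of q.

The step-up BH procedure is implemented in the package (sorted p-values
multiplied by m/i, running minimum from the largest rank, capped at 1); the
test suite checks it against `stats::p.adjust` on random vectors, keeping
implementation and oracle distinct. Ranking for pre-ranked GSEA sorts by
score descending with lexicographic gene-id tie-breaks, so a ranking is a
pure function of the table. One-to-many homolog mappings emit every target
(flagged); many-to-one collisions keep the entry with the largest |score|,
which preserves the strongest signal a human gene can inherit from its
mouse homologues.

# The network score and regulator ranking

Edges are directed `source → target` with kind `tf_dna` (TF–DNA regulatory
edge, MARA-style) or `ppi` (protein–protein interaction, String-style,
stored as two directed edges), each with a confidence $S_n \in (0,1]$. For
a root TF $t$, a subnetwork is grown breadth-first to depth 3 and scored

$$N_t = \sum_{r \in V_t} \frac{S_r \, S_n}{D_r \, L_r},$$

where $D_r$ is the BFS distance of gene $r$ from $t$ and $L_r$ the
out-degree of its parent. Decisions the formula leaves open:

- **Multi-parent genes** are recorded once, at their minimum distance;
  among equal-distance parents the highest-confidence edge wins, then the
  lexicographically smallest parent. Any fixed rule works; this one makes
  the traversal deterministic and testable against an independent
  path-enumeration oracle (agreement to 1e-12 on random graphs is part of
  the test suite).
- **Out-degree** is counted over the edge kinds active in the traversal, on
  the full network — a hub parent dilutes the evidence each child carries
  regardless of how much of the hub's fan-out landed inside this
  subnetwork.
- **Signed scores enter the sum as-is** (down-regulated genes subtract), so
  $N_t$ is linear in the gene scores and a TF of incoherent targets scores
  near zero; `use_abs = TRUE` is available for an activity-magnitude
  reading but is off by default.
- **Genes missing from the DE table contribute 0** rather than erroring:
  interaction databases always contain genes outside any one experiment.

Each TF receives three sub-scores: (m1) $N_t$ over the TF–DNA-only
subnetwork, (m2) $N_t$ over the combined TF–DNA + PPI subnetwork, and (m3)
the −log10 upper-tail hypergeometric enrichment of its depth-1 TF–DNA
targets among DE-called genes. Only the network-score formula is uniquely
determined by the method description; the trio was chosen so that the
metrics probe direct regulation, network context, and plain overlap — three
readings of "influence among differentially expressed genes" that fail in
different ways. Each metric is ranked descending (rank 1 = largest, ties
averaged) and the aggregate rank is the sum of the three; the smallest
aggregate is the strongest candidate, with identifier tie-breaks.

# Enrichment statistics

**Pre-ranked GSEA** uses the classic weighted Kolmogorov–Smirnov running
sum: hits increment by $|S_r|^{w}$ normalised by the in-set total (weight
$w = 1$ by default; $w = 0$ gives the rank-only statistic), misses
decrement by $1/(N - N_h)$, and the ES is the signed maximum deviation. The
null permutes gene labels — the ranked lists here come from full-cohort
statistics, so phenotype permutation is not applicable. NES divides the ES
by the mean |null ES| of matching sign; the empirical p-value is computed
over same-sign null scores with the +1 small-sample correction. If no
same-sign null score exists at low permutation counts, NES is reported
missing with a warning rather than infinite. Across a collection, FDR uses
the standard NES-based pooled-null procedure, with Benjamini–Hochberg
available as a flag. 1000 permutations is the default; permutation streams
are seeded per set so adding a set never perturbs another's null.

**ssGSEA** ranks genes within each sample (ties broken by gene id), weights
the in-set empirical CDF by rank$^{\alpha}$ with $\alpha = 0.25$, and
integrates the difference against the unweighted out-set ECDF. Raw scores
are min–max normalised over the whole sample × set score matrix, which
preserves all within-matrix comparisons while fixing the scale; the exact
normalisation used by any given toolchain varies, so `normalize = "none"`
exposes the raw integral. Expression matrices are first filtered: genes
with mean FPKM < 1 dropped, duplicate gene names resolved to the
highest-total row.

**Hypergeometric overlap** is the upper tail $P(X \ge k)$ with the stated
universe, and is validated against full combinatorial enumeration for every
configuration with universe ≤ 12. The universe is always an explicit
argument — in practice the set of genes expressed/testable in the
experiment — because the p-value is meaningless without it.

# Variant consensus and pathway classification

Variant keys are (chrom, pos, ref, alt) after normalisation: shared allele
suffix trimmed first, then shared prefix with the position advanced, each
keeping at least one base. This makes two callers' indel representations
comparable without a reference genome; full-allele matching (not
position-only) is used throughout. The two-caller consensus keeps keys
present in both call sets; the unmatched-tumour rule keeps keys present in
*every* caller × normal call set and absent from a strain-polymorphism
blacklist (a tumour without its own matched normal cannot exclude
strain-private germline variants any other way). The somatic filter applies
depth > 10 in both tumour and normal (strict, as printed), tumour VAF ≥
0.05 and normal VAF ≤ 0.01.

Pathway classification is three-state. *Mutant*: any pathway gene with a
damaging SNV/indel (missense, frameshift, nonsense, splice-site) at VAF >
0.2 and depth > 20 (both strict), or overlapping a copy-number segment with
≥ 5 copies or a homozygous deletion. *Wild-type*: every pathway gene free
of SNV/indels of any effect and copy-neutral (CN = 2 assumed for "no
change" on autosomes). Everything else — synonymous-only hits,
sub-threshold damaging variants, non-extreme CN changes — is
*indeterminate*, because the mutant and wild-type definitions are not
exhaustive and silently binning borderline samples would bias downstream
group comparisons. Classification is monotone: adding qualifying evidence
can never move a sample away from mutant.

# TSS profiles

All genomic inputs are 0-based half-open (BED/bedGraph). The TSS is the
annotation start for + genes and the end for − genes; windows span
[TSS − 15 kb, TSS + 15 kb) by default, binned at 300 bp (100 bins).
Binning is exact per-base averaging of the bedGraph step function
(interval-overlap weighting), verified against a brute-force per-base
oracle. Gaps in the track count as coverage 0, per bedGraph convention.
Minus-strand windows are reversed before aggregation so every profile
reads 5′→3′ of the gene; the per-gene bin vector of a strand-flipped gene
is exactly the reverse of the original. Windows overhanging position 0 are
clipped and the missing positions masked (excluded from bin means) rather
than dropping the gene, which would bias profiles of promoter-proximal
gene sets. Profiles are raw mean coverage; no RPKM or input normalisation
is applied (tracks should be depth-normalised upstream if cross-sample
comparison is intended), and bin size is configurable since no single
value is canonical.

# Synthetic data: what it does and does not emulate

The generators define the package's standard validation conditions; they
are stand-ins with documented structure, not models of any real dataset.

- **Network**: TF–DNA out-degrees are Poisson with mean 20 per TF, targets
  uniform over all other nodes (so TFs regulate TFs and the TF–DNA graph
  has depth beyond 1); PPI edges are uniform random pairs at mean degree 4;
  confidences uniform on (0.5, 1]. Defaults of 50 TFs and 1000 target
  genes give subnetworks that overlap substantially — the regime in which
  distance and out-degree weighting actually matter.
- **Planted signal**: genes in the planted TF's depth-≤3 subnetwork draw
  $z \sim N(\mu_D, \sigma)$ with $\mu_D = \text{effect} \cdot
  \text{decay}^{D-1}$ (defaults: effect 2, decay 0.5, $\sigma = 1$), all
  other genes $N(0, \sigma)$; p-values are exact two-sided normal tails of
  $z/\sigma$, so they are uniform under the null by construction. The
  geometric decay is a modelling choice — nothing in the method prescribes
  how real regulatory influence attenuates — included precisely so the
  score's distance weighting is testable.
- **Expression matrices**: per-gene log-normal baselines (meanlog 1,
  sdlog 1 — arbitrary but documented and configurable), multiplicative
  log-normal sample noise, and a $2^{\text{shift}}$ multiplier on the
  planted set in group 2.
- **Variant calls**: true somatics (tumour VAF binomial around 0.4,
  Poisson(60) depths, normal VAF 0) appear in both callers against every
  normal; caller-private false positives in exactly one caller; strain
  polymorphisms in both callers but on the blacklist. By construction the
  truth set is contained in the all-set intersection minus the blacklist.
- **Coverage tracks**: constant baseline (10×) in 200 bp segments with
  mild log-normal noise (sdlog 0.1), promoter windows (TSS ± 2 kb) of the
  depleted set multiplied by the depletion factor.

All generators are pure functions of (config, seed); one master seed is
expanded into per-component substreams by a counter-based hash of the
component name, so adding a generator never perturbs the draws of existing
ones. What passing tests on these data do *not* show: robustness to
correlated gene noise, scale-free network topology, realistic mutational
signatures or VAF distributions, fragment-level ChIP noise, or
batch/library-size effects. Real-data behaviour inherits only the
correctness of the algorithms, not these distributional idealisations.

# Validation sizes and numerical choices

The shipped test and acceptance runs use: 200 random graphs of ≤ 20 nodes
for oracle equivalence (tolerance 1e-12, pure floating-point error); 100
simulated cohorts at the default conditions (50 TFs, 1000 genes, effect 2,
noise 1, decay 0.5) for planted-regulator recovery; 1000 null rankings of
100 genes with 200 permutations each for GSEA type-I control; exhaustive
enumeration to universe 12 for the overlap test; 100 simulated call sets
for filter-chain recall/precision; and per-base oracles on ≤ 2 kb windows
for profiling. These sizes make the whole suite run in a few minutes while
keeping every Monte-Carlo check comfortably powered. Degenerate inputs are
defined rather than left to chance: empty subnetworks score 0, a gene set
covering the whole ranked list is an error (its ES is undefined), an
all-zero in-set weight vector falls back to unweighted hit increments, and
zero-variance vectors are a correlation error.

# Limitations

- The three regulator sub-scores are this package's concrete reading of a
  loosely specified trio; rankings under other third metrics may differ.
- Gene-label permutation is the only GSEA null offered; no
  phenotype-permutation mode.
- The variant machinery consumes caller output; it performs no calling,
  realignment or clonal deconvolution, and effect annotations are taken
  from the input, not re-derived from sequence.
- ssGSEA normalisation conventions differ between toolchains; compare
  scores only within one normalisation mode.
- TSS profiles assume single-TSS gene models (the annotation interval's
  ends); alternative promoters are not handled.
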