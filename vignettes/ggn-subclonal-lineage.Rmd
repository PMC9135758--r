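---
title: "Joint CNV/LOH subclonal inference and lineage classification for paired lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint CNV/LOH subclonal inference and lineage classification for paired lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggnclone)
```

# The question and the data

Synchronous paired lesions — for instance multiple lung ground-glass
nodules resected from one patient — either descend from a single founding
clone (*parallel* lineage) or arise independently (*independent* lineage).
Somatic copy-number aberrations (CNV) and loss of heterozygosity (LOH) are
well suited to making that call from whole-genome sequencing because they
are abundant even in early lesions, and their genomic footprints are
specific enough that sharing the *same* aberration type at the *same* loci
across two lesions is unlikely by chance.

`ggnclone` consumes two summary tracks per lesion — binned tumor/normal
depth log ratios and reference/alternate allele counts at germline
heterozygous SNPs — and produces (i) per-lesion typed segments with
subclone assignments and cellular prevalences, and (ii) a cross-lesion
parallel-vs-independent call with its evidence.

# The joint CNV/LOH model

## State space

A locus's hidden state pairs an allele-specific genotype with a subclone
cluster. Genotypes are all $(c, a)$ with total copies $1 \le c \le 4$ and
reference-allele copies $0 \le a \le c$ — 14 states, each carrying one LOH
label (DLOH, HET, NLOH, GAIN, ALOH, BCNA, UBCNA) and one CNV label
(HEMD/NEUT/AMP); `enumerate_states()` prints the full catalog. Two choices
deserve comment:

* The label map must be a total function (every $(c,a)$ gets exactly one
  LOH label), so the allele-specific amplification label ASCNA is exposed
  as a *track alias* for the unbalanced amplified states
  $(3,1),(3,2),(4,1),(4,3)$ rather than a primary label; display tracks
  that collapse amplification subtypes can use the `amp_track` column.
* Homozygous deletions ($c = 0$) are excluded: at realistic contamination
  they are nearly indistinguishable from hemizygous loss in these data, and
  a zero-copy state has no defined allelic ratio.

## Emissions

Let $n$ be the normal-cell fraction of the sample and $s_z \in (0,1]$ the
cellular prevalence (fraction of **tumor** cells) of cluster $z$. Because
prevalence is defined on tumor cells, $n$ and $s_z$ compose
multiplicatively and a nested minor subclone may coexist with a clonal
cluster ($s = 1$) without any sum constraint. A locus in genotype $(c,a)$
carried by cluster $z$ has expected total copy number

$$\bar c = 2n + (1-n)\,\big(s_z c + (1-s_z)\,2\big),$$

an expected depth log ratio $\log_2(\bar c / 2)$ (Gaussian emission, shared
SD $\sigma$), and an expected reference-read fraction

$$p = \frac{n + (1-n)\,(s_z a + 1 - s_z)}{\bar c}$$

(binomial emission on the observed site depth). The binomial is exact for
the generator below; real sequencing shows mild overdispersion, and the
emission function is the single place a beta-binomial would slot in.

## Chain, E-step, M-step

Depth and allelic tracks are fused on one locus grid: each het site is a
locus carrying both emissions (its bin's log ratio is looked up by
position); each bin without a het site is a depth-only locus. The chain
over loci uses a sticky, exchangeable transition kernel — self-transition
$\rho = 0.999$ by default, remaining mass uniform — restarting at
chromosome boundaries. The kernel's rank-1 structure makes each
forward–backward step $O(K)$ in the number of joint states; the recursions
are implemented in C++ with per-step rescaling so no emission underflows.
$\rho$ is the one knob trading segmentation smoothness against sensitivity
to short events; it folds the segment-length prior into a single constant
rather than modelling genomic distance explicitly.

The M-step uses per-state sufficient statistics, making its cost
independent of the locus count: $n$ and each $s_z$ are updated by bounded
1-D maximization of the expected complete-data log-likelihood on
$[0.01, 0.99]$ (coordinate ascent; a candidate is accepted only if it does
not decrease the objective, so the EM likelihood trace is non-decreasing —
a property the test suite asserts on every seeded dataset), and $\sigma$ in
closed form. Consequences of the bounds: a truly clonal cluster
($s = 1$) is estimated at $\le 0.99$, and a cluster driven to the lower
bound has collapsed onto the diploid background. Degenerate cases are
handled explicitly: all-diploid data leaves $n$ unidentifiable (left at its
current value, with a warning), and a cluster with responsibility below
$10^{-6}$ over informative states is dropped with a warning.

EM is multimodal, so the default initialization is a multi-start over
$n_0 \in \{0.1, 0.3, 0.5\}$ with prevalences equally spaced in $(0,1]$;
each start is burned in for 8 iterations and the best continued to
convergence ($|\Delta \log L| < 0.01$ by default). Convergence is assessed
on the absolute likelihood change; at the reference problem size
(~11,000 loci) this tolerance is far below one locus's worth of likelihood.

## Choosing the number of subclones

`select_n_clusters()` fits $Z = 1..z_{\max}$ and minimizes
$\mathrm{BIC} = -2\log L + (Z+2)\ln N$, ties to the smaller $Z$. One
pitfall required an explicit rule: a fit whose smallest prevalence sits at
the lower bound has collapsed a cluster onto diploid, duplicating states
that soak up noise and inflate the likelihood without describing any new
clonal structure. Such fits are excluded from the BIC comparison (the
corresponding smaller-$Z$ model is always a candidate). A cluster-validity
index would be an alternative selection criterion; BIC was chosen for
determinism and simplicity. The default $z_{\max} = 5$ mirrors the 2–5
subclones typically reported for early lesions; pipeline runs on data known
to contain at most two subclones use $z_{\max} = 2$.

# The lineage call

Two statistics are computed on the shared bin grid:

* **Genome-wide correlation** `cnv_correlation()`: Pearson correlation of
  the two lesions' per-bin MAP total copy numbers (raw log ratios serve as
  fallback when no clonal fit is available). A constant profile makes the
  correlation undefined and raises an error rather than silently returning
  0. Note copy-neutral LOH is invisible to this statistic.
* **Feature sharing** `shared_feature_analysis()`: for every cluster pair,
  the number of bins where both lesions carry the same non-HET LOH label at
  the same locus, versus bins altered in only one lesion. Diploid HET bins
  are excluded — diploid agreement says nothing about ancestry.

`call_lineage()` declares *parallel* when $r > 0.8$ **or** the best cluster
pair's shared fraction reaches 0.5. The disjunction is the load-bearing
design decision: a pair can lack global CNV similarity while a minor
subclone in each lesion carries identical typed aberrations, which is
strong founder evidence; a conjunctive rule would misclassify exactly the
interesting cases. The 0.8 correlation threshold matches the level at
which clearly parallel pairs separate from independent ones; the sharing
threshold of 0.5 ("more shared than private") is a package default exposed
as configuration and echoed in every run log, since no canonical value
exists for it.

# The synthetic-data generator

`simulate_ggn_pair()` generates the study conditions the inference is
validated under. Defaults: 2 chromosomes × 50 Mb in 10 kb bins
(10,000 bins), 5,000 het sites at mean Poisson depth 30, depth noise
$\sigma = 0.15$ (typical bin scatter for low-depth WGS), normal
contamination 0.30 (the level reported for resected early lesions of this
kind), events of 50 bins placed uniformly with rejection of overlaps.
Under the *parallel* scenario a founder event set is drawn once and planted
in both lesions — carried by each lesion's lowest-prevalence subclone,
mirroring founder aberrations that persist in a minor descendant subclone,
which is the configuration that makes feature sharing (not global
correlation) the decisive evidence. Under the *independent* scenario the
two lesions' events are drawn with disjoint genomic footprints. Prevalence
lists are validated as siblings (sum $\le 1$) or, when non-increasing, as a
nested chain (no sum bound), so clonal-plus-minor configurations like
$(1.0, 0.28)$ are expressible.

What the generator does **not** emulate: GC and mappability bias,
replication timing, read-level artifacts, beta-binomial overdispersion of
allele counts, subclone-overlapping events, and whole-genome doubling.
Passing the recovery tests therefore demonstrates correctness of the
inference machinery under its own emission assumptions — not robustness to
real-data artifacts, which require the usual depth-correction
preprocessing upstream.

# The low-depth segmenter

`fit_depth_hmm()` is a deliberately small 3-state (DEL/NEUT/AMP) HMM for
shallow-coverage samples where allele counts are too noisy to type LOH.
Default state means $(-0.5, 0, +0.35)$ in log2 units bracket one-copy loss
and gain at moderate purity; the shared emission SD is estimated by one
pass of method-of-moments on the central 50% of bins, which the neutral
background dominates. Viterbi ties break toward NEUT (conservative
calling), and a stay-vs-switch tie stays (fewest segments). No
GC/mappability correction stage is built in; a pass-through hook
(`normalize_depth()`) marks where one would go for real data.

# Numerical and testing notes

* Forward–backward and Viterbi are validated against brute-force
  enumeration of all state paths: 3-state chains at 8 loci (6,561 paths),
  the 10-state joint space (genotypes to $c_{\max}=2$, 2 clusters) at
  6 loci, and the full 28-state joint space at 4 loci (614k paths) —
  enumeration at $28^8$ paths is not computable, and short chains already
  exercise every recursion branch.
* Recovery checks run at the reference scale over 10 seeds each: mean
  recovered contamination within ±0.05 of 0.30, and mean recovered
  minor-subclone prevalence within ±0.05 at simulated 0.28 and 0.26 (the
  minor cluster is supported by ~1,200 event bins, well above the ~200
  loci below which prevalence recovery degrades).
* End-to-end classification is checked over 20 seeded pairs (10 parallel
  with the founder carried at prevalence 0.5, 10 independent), requiring
  ≥ 90% verdict accuracy with $z_{\max} = 2$.
* All writers emit deterministic text (fixed-precision numeric formats), so
  fixtures are byte-identical across runs with the same seed, and
  read-then-rewrite is byte-identical too.

# Limitations

* Copy numbers above 4 and whole-genome doubling are out of scope; a
  tetraploid baseline would be misread as widespread amplification.
* SNV-based phylogeny is not attempted; the lineage call rests on CNV/LOH
  only, and no permutation significance is attached to the shared-feature
  fraction (a natural extension).
* The correlation arm of the lineage rule is blind to copy-neutral LOH;
  recurrently shared aberration types (amplification LOH in particular) are
  not down-weighted in the sharing arm.
* Cluster prevalences at the optimization bounds (0.01, 0.99) flag
  degenerate or clonal clusters rather than being exact estimates.
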