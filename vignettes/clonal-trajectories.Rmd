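---
title: "Reconstructing clonal trajectories across tumor lesions"
author: "clonetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing clonal trajectories across tumor lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

## The problem

When a colorectal cancer is resected together with one or more of its
metastases, the somatic mutations called in each lesion carry more
information than their mere presence or absence: the *allele frequency* of
each mutation reflects the fraction of tumor cells carrying it, and the way
those fractions shift between lesions reveals which subclones seeded the
metastasis, which were left behind, and which arose afterwards — possibly
under the selective pressure of interval chemotherapy.

Raw variant allele frequencies (VAFs) are not directly comparable across
lesions, for two reasons:

1. **Copy-number context.** A duplication of the mutated chromosome, a
   deletion of the wild-type chromosome, or a copy-neutral loss of
   heterozygosity (LOH) all distort the read-count ratio away from the
   half-per-cell expectation of a heterozygous point mutation.
2. **Tumor purity.** A specimen that is only 50% tumor cells halves every
   somatic VAF.

`clonetrace` corrects both, clusters the corrected frequencies of two
lesions jointly with an expectation–maximization (EM) Gaussian mixture, and
classifies each mixture component — a putative subclone — as **maintained**,
**lost** or **emergent** between the lesions.

## The correction model

For a variant with `Ref` reference reads and `Alt` alternate reads the
package applies closed-form count adjustments, under the deliberately
conservative ("largest-extent") assumption that the copy-number aberration
always affects the mutated allele as much as possible: a duplication is
assumed to have duplicated the mutated chromosome, a deletion to have
removed the reference chromosome, and a copy-neutral LOH to have replaced
the reference homolog with a second mutated copy.

| context | Ref′ | Alt′ |
|---|---|---|
| duplication (AMP) | Ref | Alt / 2 |
| deletion (DEL) | Ref + Alt | Alt |
| copy-neutral LOH | Ref + Alt / 2 | Alt / 2 |
| chromosome X, male | Ref × 2 + Alt | Alt |
| neutral | Ref | Alt |

Fractional adjusted counts (Alt/2 on odd counts) are kept as-is; halves are
dyadic rationals, exactly representable in floating point, so no rounding
error is introduced. The adjusted frequency is then divided by the
histology-estimated tumor content and capped at 1 (capped variants carry a
`CAPPED` flag). The hemizygous male-X rule *replaces* any copy-number rule
on X rather than composing with it — a composed formula would have to be
invented, and such variants are flagged `AMBIGUOUS` instead so a reviewer
can inspect them. X variants of patients with unknown sex, and variants on
Y or MT, are excluded with a reason rather than corrected wrongly.

On this corrected scale a heterozygous single-copy mutation present in a
fraction φ of tumor cells has expected corrected VAF φ/2; the package
reports both `corrected_vaf` and `cellular_proportion = min(2 ·
corrected_vaf, 1)`, clusters on the former and reports clone dynamics on
the latter. Whether the upstream study scaled by 1/purity or used a fuller
cellular-prevalence transform is not recoverable from its description;
the simple scale correction used here is stated in every output header via
the two reported columns.

## The generative model (and why it is exactly invertible)

The bundled simulator draws, for each mutation of clone *c* in lesion *l*
with purity *p* and clone proportion φ, reads at a Poisson depth and
alternate reads binomially with expected VAF

$$ v = \frac{p\,\varphi\,m}{2 + p\,\varphi\,(C-2)} $$

where the local copy state contributes multiplicity *m* and total tumor
copy number *C*: (1, 2) neutral, (2, 3) duplication, (1, 1) deletion,
(2, 2) copy-neutral LOH. This places the copy-number event *in the
mutation's carrier cells* — the generative counterpart of the
largest-extent correction assumption. With that coupling the four count
rules above invert the generator *algebraically*: on noiseless counts the
corrected VAF equals φ/2 exactly, for every purity, proportion and state
(the test suite asserts this to 1e-12, and the scale-invariance of the
correction makes the identity independent of depth). Treating the CNA as
clonal in all tumor cells instead (denominator *pC* + 2(1 − *p*)) breaks
exactness for subclonal mutations, which is why the carrier-coupled form
is the default; both coincide for clonal mutations, the common case for
arm-level events.

Germline heterozygous SNPs, in contrast, exist in every cell, so for the
CNA-caller inputs the simulator uses the clonal form: a het SNP in a
region of state (*b* major-allele copies, *C* total) has expected B-allele
frequency (p·b + (1 − p)) / (p·C + 2(1 − p)) with the major allele
assigned to ref or alt at random, and bin coverage scaled by
(p·C + 2(1 − p))/2.

What the simulator does **not** model: sequencing error (alternate reads
arise only from true mutations), mapping artifacts, overdispersion beyond
Poisson depth (FFPE noise is typically overdispersed), subclonal
copy-number events, and multi-region heterogeneity within one lesion.
Passing recovery tests on these data therefore demonstrates correctness of
the estimators under the stated model, not robustness to every artifact of
real FFPE exomes.

## CNA calling

Arm-level events are called from two observables per segment or arm: the
mean folded B-allele-frequency deviation |BAF − 0.5| over het SNPs, and
mean coverage normalized to the genome-wide baseline. The decision rule is
deterministic and total: BAF deviation ≥ 0.10 with a coverage ratio
≥ 1.15 is an amplification, with a ratio ≤ 0.85 a deletion, and in
between a copy-neutral LOH; smaller BAF deviation is neutral. The 0.10 /
1.15 / 0.85 cutoffs operationalize an upstream description that never
quantified "significant" coverage change; they are exposed in
`default_thresholds()` and were chosen so that arm-scale events at purity
≥ 0.5 sit comfortably on the correct side (at purity 0.7 an amplified arm
has expected BAF deviation ≈ 0.13 and ratio ≈ 1.35). Segments with fewer
than 10 informative SNPs are `UNCALLABLE`, never silently neutral. An arm
takes a non-neutral state when ≥ 80% of its callable length agrees.
Breakpoint discovery is out of scope: segments come from input or from the
packaged GRCh37 arm table (whole-Mb boundaries — arm-level resolution is
all the aggregation needs).

## Clustering and model selection

Corrected VAFs of a lesion pair are joined on variant identity; a variant
absent from one lesion contributes coordinate 0 there (absence is the
signal for lost/emergent clones), unless the site is known to be
uncovered (< 10 reads), in which case it is dropped and reported. The EM
mixture uses diagonal-covariance Gaussians: private-mutation clusters have
near-zero variance on one axis and binomial-scale variance on the other,
which a spherical model would distort. Numerical choices worth knowing:

* **Initialization** is k-means++ from an explicit seed; `select_k`
  fits 5 restarts per candidate k (default 1–6) and keeps the best
  likelihood.
* **Model selection** is BIC with *p* = k(2d + 1) − 1 free parameters.
  Components closer than the binomial noise floor (≈ 0.005 at typical
  depth) are not resolvable and collapse to one — by design, not failure.
* **Variance floor** 1e-5: point masses at exactly 0 (private mutations)
  would otherwise drive the likelihood to infinity.
* **Degenerate input** (all points identical) returns a single flagged
  component regardless of the requested k.
* **Ties** in posterior responsibility go to the lower cluster id after
  components are sorted lexicographically by center, making hard
  assignments reproducible.

The log-likelihood trace is recorded on every fit and asserted
non-decreasing (the EM guarantee) across random fixtures in the tests.

A cluster is *present* in a lesion when its center coordinate reaches
`presence_min` = 0.05 on the corrected-VAF scale — i.e. the subclone
comprises at least ~10% of tumor cells. The upstream work never states a
floor (its calls were expert-curated figures); 0.05 sits above the noise
of a 100× exome while catching the minor clones those figures show. Fates
follow from presence: both lesions → `MAINTAINED`, first only → `LOST`,
second only → `EMERGENT`.

## Signatures

Each lesion's substitutions are folded to the pyrimidine strand and binned
into the conventional 96 trinucleotide contexts. Exposures to a reference
signature matrix are refit by nonnegative least squares, iteratively
discarding signatures whose weight falls below 6% and refitting until
stable — the discard threshold mirrors common refitting practice and is
config-exposed. Reference matrices are user input (tests use packaged
*synthetic* signatures with disjoint support, labelled as such); profiles
under 20 mutations are flagged `LOW_COUNT`.

## Problem sizes and defaults

The simulator defaults mirror the study conditions: whole-exome depth
~95–100×, ultra-deep targeted depth 25 000×, purity 0.3–0.8
(histology-estimated), hypermutation flagged at ≥ 1000 exonic mutations,
and the six-gene driver panel (APC, TP53, KRAS, NRAS, PIK3CA, BRAF) with a
presence floor of ≥ 3 alternate reads and VAF ≥ 0.02 chosen for
ultra-deep sensitivity. The canonical test scenario (`fig2_config()`) is a
primary–metastasis pair with purities 0.6/0.55 and three 100-mutation
clones at proportions 0.8/0.8, 0.5/0 and 0/0.4, i.e. corrected-scale
centers (0.4, 0.4), (0.25, 0) and (0, 0.2). Recovery checks use 10 seeds
for clustering and 20 for CNA calling with 200 het SNPs per arm at 60× —
sizes at which the suite runs in about a minute while the Monte-Carlo
margins stay far from the pass thresholds.

```{r example}
res <- simulate_and_run(fig2_config(seed = 1), seed = 1)
res$metrics$k_selected
round(res$run$pairs[[1]]$clusters[, c("center_a", "center_b", "weight")], 3)
res$run$pairs[[1]]$fates$fate
```

## Known limitations

* Purity is an input, never estimated; a wrong histology estimate shifts
  every corrected VAF proportionally (the `CAPPED` flag is the symptom).
* No mutation-multiplicity estimation: a clonal mutation duplicated
  *after* occurring violates the largest-extent assumption and will be
  over-corrected.
* Clustering is pairwise 2-D; patients with many lesions are analysed as
  primary-vs-each plus consecutive metastasis pairs, not jointly.
* No phylogeny: fates are per-pair statements, and therapy or dormancy
  interpretations remain expert narrative on top of the reported evidence
  tables.
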