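---
title: "Methods: establishing biallelic tumour-suppressor inactivation at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: establishing biallelic tumour-suppressor inactivation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitrio)
```

`epitrio` implements the three lines of computational evidence by which a
"two-hit" inactivation of a tumour suppressor can be established from
paired tumour/normal sequencing: loss of the second allele through
(copy-neutral) LOH, silencing of the second allele through promoter
CpG-island hypermethylation, and a distinctive expression subtype downstream
of the inactivation. The motivating setting is Wilms tumour with TRIM28
inactivation, where a frameshift on one allele is completed by 19q cn-LOH in
one tumour and by allele-specific exon 1 methylation in another, and where
affected tumours match the early-onset, monomorphic-epithelial "S1"
expression subgroup. The package works at desk scale: every stage runs on a
laptop against small variant tables, amplicon read sets and expression
matrices, with a synthetic-data module supplying truth-known inputs.

This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic studies do and do
not demonstrate.

## Strand 1: B-allele fractions, LOH segmentation, and the aberration score

### Model

At a biallelic site heterozygous in the normal, the tumour B-allele
fraction is `alt / (ref + alt)`. The *mirrored* BAF, `max(baf, 1 - baf)`,
folds out the arbitrary labelling of alleles: heterozygous-balanced sites
sit at 0.5 and any allelic imbalance pushes the value toward 1. The second
coordinate is the log2 tumour/normal depth ratio, library-size-normalised
and median-centred so the dominant (neutral) state sits at 0.

Under a single-copy-change model at tumour purity $p$, the expected alt
fraction of the affected allele is:

| state   | tumour copies | alt fraction (affected allele) | mirrored BAF | log ratio |
|---------|---------------|-------------------------------|--------------|-----------|
| neutral | 2             | $1/2$                         | 0.5          | 0         |
| cn-LOH  | 2             | $(1+p)/2$                     | $(1+p)/2$    | 0         |
| loss    | $2-p$         | $1/(2-p)$                     | $1/(2-p)$    | $\log_2\frac{2-p}{2}$ |
| gain    | $2+p$         | $(1+p)/(2+p)$                 | $(1+p)/(2+p)$| $\log_2\frac{2+p}{2}$ |

Copy-neutral LOH and single-copy loss both raise the mirrored BAF; only the
log ratio separates them. That separation is the reason the state space of
the segmentation is two-dimensional.

### Segmentation

Site filtering keeps heterozygous-in-normal sites with genotype quality
$\ge 14$ and read depth within $[11, 1001]$ in *both* samples. The depth
bounds are treated as inclusive; the boundary reading is a documented
choice (the interval endpoints are conventional hard cut-offs against
artefactual pile-ups and under-covered sites).

Per chromosome, the hidden state sequence over {neutral, cn-LOH, loss,
gain} is decoded by a 4-state HMM with independent Gaussian emissions on
(mirrored BAF, log ratio) and Viterbi decoding. This is a deliberately
simple, documented segmentation engine standing where a dedicated
tumour-exome caller would sit in a full-scale pipeline; its internals are
this package's own. Choices:

* **Emission means** (`hmm_emission_model()`): neutral (0.52, 0), cn-LOH
  (0.87, 0), loss (0.83, -0.6), gain (0.64, 0.45). These are purity-free
  reference points bracketing the exact dosage-model centres over the
  purity range 0.7–1.0; the neutral BAF mean sits slightly above 0.5
  because mirroring a binomial proportion at depth ~100 biases its mean
  upward by a few hundredths. All means and the two shared standard
  deviations (0.07 BAF, 0.3 log ratio) are user-configurable for other
  depths and purities.
* **Transition stickiness**: self-transition 0.999, the remaining mass
  split evenly. At typical exome site spacing this encodes an expectation
  of megabase-scale events and suppresses single-site state flips.
* **Degenerate inputs**: a chromosome with fewer than 5 sites carries too
  little information for decoding and is emitted as a single neutral
  segment with a warning. Sites with zero tumour depth are dropped (with a
  warning) before the track is built.

Adjacent same-state sites merge into segments spanning first to last
supporting site (1-based, closed; BED export converts to 0-based half-open
in exactly one function, `to_bed()`).

### Fractional copy-number aberration score

The score is the summed length of loss/gain segments divided by the summed
length of all reported segments. Copy-neutral LOH counts in the denominator
only: it changes zygosity, not copy number, so a genome whose only somatic
event is a cn-LOH tract scores 0 — the configuration that makes a
"genomically quiet" tumour quantitatively visible next to tumours with
widespread copy-number change. Segment length is `end - start + 1` over the
supporting-site span; chromosome ends are not extrapolated. Because the
score is a ratio, any consistent length convention gives the same
asymptotics; the supporting-site span is the least presumptive.

LOH *runs* — maximal stretches of consecutive filtered sites in cn-LOH or
loss states — are reported with their site counts and the positions of the
nearest flanking heterozygous (neutral-state) sites, i.e. the most distal
retained heterozygosity on each side; a run reaching the covered end of a
chromosome (telomeric LOH) has a missing flank on that side.

### What the synthetic study shows

The generator implants segments with known states at a given purity and
draws normal allele depths as Binomial(depth, 0.5) and tumour depths from
the dosage table above, with Poisson coverage scaled by the purity-diluted
copy number. The package's recovery study (three 100 Mb chromosomes, one
20 Mb event of each kind, ~2000 sites, depth 100, purity 0.8) achieves
per-site state accuracy above 0.9 and a score within 0.02 of the implanted
40/300 truth. This demonstrates correctness of the decoding and the score
under the generator's assumptions — clonal events, single-copy changes, no
subclonality, no GC or mappability structure in coverage. It does not
demonstrate robustness to the waviness, segmentation-scale artefacts and
reference biases of real exome depth tracks.

## Strand 2: bisulfite amplicon epialleles and mosaicism

### Conversion model and calling

Bisulfite treatment converts unmethylated cytosine to uracil (read T);
methylated CpG cytosines survive. For an amplicon sequenced from both
treated strands, reads in reference orientation follow one of four
templates: top/bottom strand × methylated/unmethylated CpGs
(`convert_reference()`). On the top strand the informative base at a CpG is
the C itself (C = methylated, T = unmethylated); on the bottom strand it is
the following G (G = methylated, A = unmethylated).

Reads are position-fixed amplicon products, so calling uses ungapped,
anchored comparison rather than alignment: each read is assigned to the
strand whose converted template matches best over CpG-independent
positions, discarded as off-target when best identity falls below a floor
(default 0.8) or when it covers less than half the amplicon. Indel-carrying
reads fall below the identity floor and are discarded rather than
misinterpreted — acceptable for targeted amplicons, wrong for anything
shotgun. Per-read bisulfite conversion failure is measured as the fraction
of covered non-CpG cytosine positions still unconverted; a filter on it is
available but off by default.

### Epiallele classification

A read with at least `min_called = 5` non-missing CpG calls is *densely
methylated* when its methylated fraction is $\ge$ `dense_min = 0.9`,
*unmethylated* when $\le$ `unmeth_max = 0.1`, *intermediate* otherwise.
The dense class operationalises "methylated at essentially every CpG":
a literal all-CpGs rule breaks on a single miscalled or missing site, so
the 0.9 default tolerates roughly one discordant call in a 23-CpG amplicon
while remaining far above any plausible intermediate pattern. The dense
fraction among classified reads carries a Wilson 95% score interval
(`prop.test(correct = FALSE)`).

Allele-specific promoter methylation shows up as a two-mode pattern: a
dense mode near 100% per-CpG methylation and an unmethylated mode near 0,
with the dense fraction near the fraction of affected alleles. Mosaicism in
a normal tissue appears as a small dense fraction; under the model that
each affected cell carries exactly one methylated allele among two, the
affected *cell* fraction is exactly twice the allele fraction
(`estimate_cell_fraction()`, rejecting inputs above 0.5 which would
contradict the heterozygous-event assumption). The worked example in the
analysis scripts doubles a 1.2% dense-read fraction (8 of 661) to ~2.4% of
cells.

The mutation counterpart (`mutation_allele_fraction()`) counts reads by
exact local-context match around the variant (reference vs mutant context),
excluding ambiguous reads, and refuses to report when fewer than half the
reads contain either context (wrong amplicon). Reported precision follows
the field's convention: methylation percentages to one decimal, mutation
fractions to two.

### Generator and its limits

`gen_bisulfite_reads()` draws each read from the dense epiallele with
probability `dense_fraction`, on a random strand. The dense epiallele is
methylated at every CpG by default (`p_meth_dense = 1`) — the emulated
pattern is dense methylation of *all* CpGs, and apparent deviations in real
reads belong to the error processes, which the generator models separately:
incomplete conversion (`conversion_rate = 0.995` applied to every
unmethylated cytosine) and uniform substitution error
(`seq_error = 0.001` per base). The background epiallele has sporadic
methylation at `p_meth_background = 0.02`. Reads are full amplicon length
(targeted MiSeq design), so the generator does not emulate fragmentation,
quality decay along the read, PCR duplicates or chimeras.

On the interval check used in the recovery study, one numerical fact is
worth recording: the Wilson interval's exact coverage oscillates with $(n,
p)$ through binomial discreteness. By direct enumeration it is 94.7% at
$n = 1043, p = 0.395$ and 95.5% at $n = 661, p = 0.012$ — so
coverage-counting experiments at these sizes sit within a point or two of
nominal even for an estimator that recovers the realized dense-read count
exactly, as this caller does in the package's own simulations.

```{r wilson, eval = FALSE}
# exact Wilson coverage by enumeration at the study sizes
cover <- function(n, p) {
  inside <- vapply(0:n, function(k) {
    ci <- suppressWarnings(prop.test(k, n, correct = FALSE))$conf.int
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  sum(dbinom(0:n, n, p) * inside)
}
cover(1043, 0.395)   # 0.9467
cover(661, 0.012)    # 0.9546
```

## Strand 3: expression subtypes

### Filtering and clustering

Probes are ranked by inter-sample variance and the top half retained by
default (`variance_filter()`, ties broken by original probe order — a
documented deterministic rule); known cross-hybridising probes can be
excluded by blacklist. Samples are clustered on Euclidean distance with
average (UPGMA) linkage, and the dendrogram serialises to Newick via `ape`.

### Moderated differential expression

The two-group moderated t is implemented in the package rather than taken
from a library, since this test is part of the analysis contract. For probe
$g$ with pooled variance $s_g^2$ on $d$ residual df, an inverse-chi-square
prior $s_0^2$ on $d_0$ df is fitted by marginal moment matching on
$\log s_g^2$: with $e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$, solving
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d/2)$ for $d_0$ (Newton on the
inverse trigamma) and $s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$.
The posterior variance $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$
yields a t statistic on $d_0 + d$ df. When the spread of $\log s_g^2$ is no
larger than expected by chance ($\mathrm{var}(e) \le \psi'(d/2)$) the prior
df are infinite and all probes share $s_0^2$. As $d_0 \to 0$ the statistic
reduces to the ordinary equal-variance t, a limit the test suite checks
numerically, and the whole construction is cross-checked against the
reference empirical-Bayes implementation in the suite. Designs with fewer
than two samples in either group are refused — there are no residual df to
moderate. BH adjustment uses the stock step-up (`p.adjust`).

Selection at "two-fold and adjusted p < 0.01" is interpreted on the log2
scale as $|\log_2 FC| \ge 1$ (expression matrices are assumed log2, as RMA
output is). Cross-cohort signature overlap reports, per direction, the
count and the integer-rounded percentage of query probes present in the
reference signature; the id universes must be intersected upstream, which
is exposed as an explicit step rather than hidden inside the comparison.

### Metagene scoring

For a developmental-stage marker set, each gene's row is z-scaled across
samples, zero-variance genes are dropped with a warning (at least two must
survive), and the per-sample metagene score is the first right singular
vector of the scaled submatrix, scaled by the first singular value (the
unscaled variant is exposed as an option; the scaled one is the default
because it keeps scores comparable across stages with different coherence).
The SVD's sign is arbitrary, so it is anchored by requiring positive
correlation with the mean marker z-score — higher score always means
coherently higher marker expression. The anchor resolves only the SVD
ambiguity: negating the data negates the scores, as it should. Z-scaling
makes the score invariant to per-gene affine rescaling (positive scale) of
the input, to numerical tolerance.

Group comparison of metagene scores uses a two-sided Welch test and
reports the raw p value, explicitly labelled uncorrected; correcting
across stages is the caller's decision. The degenerate all-tied case
(both groups constant and equal) is defined as p = 1.

## Synthetic-data module: what the defaults are

The generator defaults are the study conditions, fixed once:

* CNV strand: purity 0.8, mean depth 100, ~6.7 sites/Mb over three 100 Mb
  chromosomes with one 20 Mb cn-LOH, loss and gain event each (~2000
  sites); GQ drawn from 50–99 so the filter boundary logic is exercised by
  unit tests rather than by the simulation.
* Bisulfite strand: 253 bp amplicon with 23 CpGs; 1043 reads; dense
  fraction 0.395; conversion 0.995; substitution error 0.001.
* Expression strand: 1000 probes, 8 vs 8 samples, residual sd 1 (log2
  scale), one 20-gene stage marker set shifted +3 sd in the focal
  subgroup, one unshifted 20-gene set as a negative control.

These sizes keep every study inside a couple of minutes on one CPU; they
are also the sizes at which the test suite runs its property studies
(per-site recovery across purities 1.0 and 0.8; Wilson-coverage counting
over 100 seeded replicates per condition; 200-replicate null calibration of
the moderated test; 100-seed metagene power).

All generators are bit-reproducible given a seed, and the end-to-end
pipeline (`run_pipeline()`) writes byte-identical summaries for identical
configurations.

## Interface shape

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers (simulate → segment →
methylation → expression) that read and write files under `results/`,
while every computation lives in exported package functions so the test
suite and the acceptance script exercise the same code paths. No shell
wrapper beyond `Rscript` is provided; the functions, the scripts and this
vignette are the interface.

## Known limitations

* The segmentation engine assumes clonal, single-copy events and
  well-behaved coverage; it does not fit integer allele-specific copy
  numbers, subclonal fractions, or purity (purity enters only through the
  synthetic truth and the emission defaults).
* The aberration score depends on the reported-segment universe; on real
  capture data, unsegmented gaps (off-target deserts) are simply absent
  from the denominator.
* The bisulfite caller is ungapped: reads with indels are discarded, and
  methylation is not phased to the mutation beyond context counting.
* The moderated test covers the two-group design only — no covariates,
  no trends in the prior, no robust down-weighting.
* Marker-set metagenes assume the set's genes move coherently; an
  anti-correlated subset would split the first singular component and
  lower the variance explained, which is reported for exactly that reason.
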