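---
title: "The varcall model: Bayesian genotypes, confidence scores, indel consensus and somatic typing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The varcall model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcall)
```

varcall calls germline and somatic single-nucleotide variants and short
indels from per-site pileup columns — the textual summaries of aligned
read bases and qualities that `samtools mpileup` produces. This vignette
is the package's own account of the statistical model, the tunable
parameters, the numerical choices, and what the bundled simulator does and
does not emulate.

## The germline genotype model

At a genomic site with reference base $\gamma$, a diploid individual
carries one of $K = 10$ unordered genotypes $G_k = G_k^1 G_k^2$ over
$\Sigma = \{A, C, G, T\}$. The retained read bases $X_{i,1}, \dots,
X_{i,N}$ at site $i$ are modeled as a multinomial sample conditioned on
the genotype:

$$P(X_i \mid G_k) \propto \prod_{j=1}^{N} P(X_{i,j} \mid G_k), \qquad
  P(X_{i,j} \mid G_k) = \alpha\, P(X_{i,j} \mid G_k^1) +
  (1-\alpha)\, P(X_{i,j} \mid G_k^2),$$

where $\alpha$ is the probability that a read was sequenced from the
first haploid chromosome (default 0.5: impartial sequencing of both
haplotypes). Each haploid term is

$$P(X_{i,j} \mid g) = \begin{cases}
  \omega_{i,j} & X_{i,j} = g \\
  (1 - \omega_{i,j})\,\Phi(X_{i,j}, g) & \text{otherwise,}
\end{cases}$$

with the observation weight $\omega_{i,j}$ combining the Phred base
quality $B_q$ and mapping quality $M_q$ as one minus the harmonic mean of
the two error probabilities,

$$\omega_{i,j} = 1 - \frac{2 \cdot 10^{-0.1 (B_q + M_q)}}
  {10^{-0.1 B_q} + 10^{-0.1 M_q}},$$

so a read is only as trustworthy as the worse of its base call and its
alignment. $\Phi$ is a $4\times4$ substitution table giving the
probability of each true base given a miscalled observed base. The
default is non-informative ($1/3$ off the diagonal,
`flat_substitution_table()`); a platform-specific error profile can be
supplied through any `phi_table` argument. We deliberately ship no
hard-coded instrument profile: published Illumina tables are tied to
specific chemistry generations, and a wrong informative prior is worse
than a flat one.

The posterior $P(G_k \mid X_i) \propto P(X_i \mid G_k)\,P(G_k)$ is
normalized over the 10 genotypes and the maximum a posteriori genotype is
reported. Three prior families are available (`prior_mode`):

* **theta** (default) — heterozygous-reference genotypes get the
  heterozygous mutation rate $\theta$ (default $10^{-3}$, the human
  between-haplotype rate), homozygous variants $\theta/2$, heterozygous
  variants $\theta^2$, and the homozygous reference the remainder. The
  $\theta^2$ mass for heterozygous variants is taken literally from the
  prior's definition, with no ploidy multiplicity correction.
* **flat** — $1/10$ each; useful for oracle tests and as a neutral
  baseline.
* **titv** — the theta priors reweighted per genotype by the product over
  its non-reference alleles of $\delta/(1+\delta)$ for transitions of
  $\gamma$ and $0.5/(1+\delta)$ for transversions ($\delta$ the Ti/Tv
  ratio, default 2.0 for human whole-genome data), rescaled so the total
  non-reference mass equals the theta mode's. The reweighting is one
  consistent reading of "similarly defined" Ti/Tv-aware priors; the
  renormalization keeps the two modes comparable site by site.

All likelihood arithmetic is in natural-log space: the linear-space
product underflows around depth 300, well inside the range of real
exome data. Exact posterior ties break deterministically by the canonical
genotype order `AA, CC, GG, TT, AC, AG, AT, CG, CT, GT`, so results are
platform-independent. A sliding-window strand mode
(`use_window_alpha = TRUE`, window default 1000 sites) replaces the fixed
$\alpha$ with the local forward-strand fraction and uses the max-form
likelihood that is symmetric in the haplotype-to-strand assignment; it is
off by default because a constant $\alpha = 0.5$ performed equivalently
in the source work's evaluations.

## The variant confidence score

Calls that are not homozygous reference are graded by the variant
confidence score: the mean, over reads whose base belongs to the called
genotype, of the surprisal $-\log P(X_{i,j} \mid \gamma)$ of the implied
reference substitution, where transitions cost
$S_{ti} = \delta\theta/(1+\delta)$, transversions
$S_{tv} = 0.5\,\theta/(1+\delta)$ and reference matches $1-\theta$.
Intuitively: a variant supported by many non-reference reads accumulates
high mean surprisal; reference reads matching a heterozygous call dilute
it only mildly.

The analytic thresholds mirror the score a *clean* variant column would
achieve. For a heterozygous-reference genotype (Case 1),
$HC = -\tfrac12\log\big((1-\theta)S_{ti}\big)$ — exactly the score of a
perfectly balanced reference/transition column — and for genotypes
without the reference allele (Case 2), $HC = -\log S_{ti}$, the score of
a pure transition column. The low-confidence thresholds interpolate
between the reference surprisal and the mean variant surprisal with
weights $\phi$ (Case 1) and $\psi$ (Case 2). Not every weight keeps
$HC \ge LC$: at the defaults $\theta = 10^{-3}, \delta = 2$ the Case-1
constraint requires $\phi \gtrsim 0.543$. `var_params()` therefore
computes the admissible interval per $(\theta, \delta)$
(`admissible_conf_weights()`), defaults each weight to the midpoint of
its admissible interval, and rejects explicit values that violate the
constraint — the constraint is part of the model, not a soft suggestion.

Natural logarithms are used throughout; since score and thresholds
rescale together under any change of base, the classification is
base-invariant (asserted by test). Boundary scores grade upward
(score $= HC$ is "high"), with a $10^{-9}$ comparison tolerance so a
score assembled as a mean of exactly the threshold's terms cannot fall a
floating-point ulp short.

## Indel candidates and the ungapped consensus

A site with at least one inserted/deleted sequence in its column is
screened by two one-sided Fisher's exact tests, each comparing observed
counts with the counts expected under a background rate on the same
total: first substitutions versus reference reads under the
point-mutation rate `mu` (a significant substitution excess, $p < a_1$,
disqualifies the site — the signal is a substitution variant or alignment
noise), then indel events versus reference reads under the indel rate
`mu_indel` (significance, $p < a_2$, qualifies it). The contingency
construction (observed row vs. expected-under-rate row) and the defaults
`mu = mu_indel = 1e-3`, `a1 = a2 = 0.01` are package choices — the source
model names the tests but not the tables or cutoffs. The tests run
through `stats::fisher.test`; the suite checks them against an
independent exact hypergeometric computation.

The reads' indel sequences at a candidate site usually disagree (sequencing
error, alignment jitter), so the reported allele is a consensus from a
multiple ungapped alignment, in the spirit of the starting-point search
of motif discovery: for every window length $l$ between the shortest and
longest sequence, every $l$-mer in the set seeds a gapless overlay
(score +1/−1 per position, seed fully inside each sequence, leftmost
best match per sequence, sequences shorter than $l$ contributing
nothing). Each overlay yields a position-specific weight matrix
$W_{i,j} = \log_2(p_{i,j}/q_i)$ over raw column frequencies $p$ and a
uniform background $q = 1/4$; the consensus is the columnwise argmax,
ties broken by alphabet order. Zero frequencies are floored at
$\varepsilon = 1/(2|S|)$ *inside the log only*, so $W$ stays finite while
unanimous columns keep exactly $W = \log_2 4 = 2$ and the frequency
columns still sum to one.

The overlays are ranked by the likelihood
$L = \tfrac{1}{l}\log_2 \sum_j W_{S'[j], j}$. Taken literally this is
the log of a sum of log-odds, which can be non-positive; such overlays are
assigned $-\infty$ and rank last. An alternative mean-log-odds mode
($L = \tfrac{1}{l}\sum_j W_{S'[j],j}$, `mua_mode = "mean"`) avoids the
guard entirely; the literal form is the default. Ties on $L$ go to the
larger $l$ (more aligned columns carry more evidence), then to the
earlier seed — a fully deterministic cascade.

Zygosity of an indel call is heterozygous unless the supporting-read
fraction reaches `hom_frac` (default 0.75). At a mixed site insertions
and deletions are pooled separately and the kind with more events wins,
ties toward insertion.

## Somatic calling from matched pairs

The somatic caller is a hybrid. The **subtraction analysis** genotypes
both samples independently; where the normal is homozygous reference and
the tumor carries a high-confidence variant, a Somatic record is emitted
immediately. Every other site proceeds to the **joint analysis**: the
posterior over the 100 genotype pairs

$$P(G^N_k, G^T_t \mid X_i, Y_i) \propto
  P(X_i \mid G^N_k)\, P(Y_i \mid G^T_t)\, P(G^T_t \mid G^N_k)\, P(G^N_k)$$

couples the samples through a dependency prior, reflecting that both
genomes come from one individual and share germline polymorphism. The
dependency matrix is parametrized by the somatic rate $s$ (default
$10^{-4}$): staying equal costs $1-s$, changing one allele $s$ times its
Ti/Tv weight, changing both $s^2$ times the product of weights (the
allele pairing with the larger weight is used), rows normalized. As
$s \to 0$ it collapses to the identity. The normal likelihood is assumed
free of tumor reads, and the tumor likelihood is conditioned on the
tumor genotype alone — tumor purity does not enter the likelihood, only
the post-processing threshold below.

Post-processing of a joint call runs in four steps: (i) a joint genotype
contradicting the subtraction call survives only with a high-confidence
score, otherwise it is demoted to homozygous reference; (ii) a joint
genotype confirming the subtraction call passes under a relaxed
read-count constraint — variant-supporting reads at or above
$\max(\texttt{min\_var\_reads},\ \lceil f \cdot \text{depth} \rceil)$
with $f = 0.25 \cdot \text{purity} \cdot \texttt{relax\_factor}$, i.e.
half the expected heterozygous variant-allele fraction scaled by purity —
or is marked a false positive; (iii) a site where both genotypes end up
false positives is discarded; (iv) the surviving pair is typed by the
symbolic reference/variant table (Somatic, LOH, Germline, Unknown, Wild)
and written to VCF. Heterozygous-variant genotypes map through the
homozygous-variant column; a heterozygous-variant normal maps through
the heterozygous row when it shares an allele with the tumor genotype.
Subtraction-stage Somatic calls re-enter only at step (iv): they already
passed a stricter confidence bar than the relaxed constraint would
impose.

Somatic indels follow an exclusivity rule: a site that passes the indel
candidate screen in exactly one sample is reported — Somatic with the
tumor's consensus when tumor-only, and LOH-typed when normal-only
(mirroring the SNV table's reading of a variant the tumor lost). Sites
that are candidates in both samples are germline indels, not somatic
events.

Purity is a user parameter. When it is not supplied, a fallback
estimator takes the median of twice the tumor variant-allele fraction
over confident subtraction-Somatic sites, clamped to $(0, 1]$ —
"confident" meaning at least low-confidence, because restricting to
high-confidence variants selects fractions above one half and biases the
estimate toward 1. With no somatic site at all, purity defaults to 1
with a warning. This estimator is a simple stand-in for a dedicated
estimation procedure and is labelled as such in its documentation.

## The simulator: what it emulates, what it does not

`simulate_germline()` and `simulate_tumor_normal()` generate columns
with exactly the structure the models assume: genotypes from the theta
priors, Poisson depth, haplotype sampling at $\alpha$, uniform base
error, constant qualities ($B_q$ the Phred encoding of the error rate,
$M_q = 60$). The tumor design matches the study conditions the package
documents: somatic mutations at 1% of sites, restricted to sites with a
homozygous-reference normal genotype, heterozygous for a novel allele;
purity 0.9 mixing tumor- and normal-genotype reads; 15% of mutations as
indels with length $1 + \mathrm{Geometric}(1 - 0.3)$ (extension
probability 0.3) and per-base noise applied to the event sequences;
uniform base error 1%, coverage 30.

The simulation operates at pileup level. It does **not** emulate read
sequences, alignment, soft clipping, indel realignment artifacts,
duplicate reads, GC or strand bias, overlapping mates, or contamination
of the normal. Passing tests on this simulator therefore demonstrate the
*statistical engine* under its own model assumptions, with alignment
noise absent; published read-level figures act as conservative lower
bounds for the recall/precision floors the acceptance suite asserts, and
results on real alignments will be worse in ways the simulator cannot
show. Deletion placeholders downstream of a deletion event are likewise
not simulated (each column is independent).

## Numerical and policy choices

* Quality floors default to $B_q \ge 13$, $M_q \ge 0$
  (mpileup-compatible); filtered reads still count toward raw depth.
  When input lacks mapping qualities, a configurable constant (default
  60) keeps the observation weight defined.
* Coordinates are 1-based inclusive throughout; VCF indel records anchor
  on the site's reference base (REF includes deleted bases, ALT includes
  inserted ones).
* `*` deletion placeholders and reference skips contribute to raw depth
  but never to allele counts — the multinomial is over $\Sigma$ only.
* The BAM input path shells out to `samtools mpileup -s` and inherits
  samtools' duplicate and overlapping-mate policies (overlap-corrected
  counting); the text path is the reference implementation.
* Minimum depth to call is 1 retained read, exposed as `min_depth`.
* Empty columns yield no-call (`NA` genotype); a paired site covered in
  only one sample falls back to the covered sample's germline call,
  typed Unknown.

## Problem sizes

The test suite exercises the engines at the scale a desk run affords:
oracle equivalence over the full enumeration of columns with up to six
reads (qualities 10/20/30, all four reference bases, 18,563 columns per
reference), 10,000-site germline recovery, two 200,000-site
tumor-normal runs at coverage 30 for the somatic floors, and 200 noisy
consensus-recovery trials. `scripts/acceptance.R` re-runs the two
200,000-site experiments from scratch through the file-level interface.

## Known limitations

Copy-number variation, subclonal populations and contaminated normals
are outside the model; the somatic rate matrix is a parametrized stand-in
for an empirically fitted tumor-given-normal prior; the purity estimator
is a fallback, not a replacement for a dedicated procedure; and indel
confidence is reported through the candidate-screen p-values and
consensus likelihood rather than the SNV confidence score, whose
reference-substitution form does not transfer to indel alleles.
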