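# varcall

Integrated Bayesian calling of germline and somatic SNVs and short
indels from pileup columns, for anyone who has `samtools mpileup` output
(or a matched tumor–normal pair of them) and wants genotypes, graded
variant calls and somatic mutation types in VCF without running a
multi-tool pipeline.

## The model in brief

At a site with reference base γ, allele counts are multinomial given the
diploid genotype *G<sub>k</sub>* (10 genotypes over {A,C,G,T}):

    P(X_i | G_k) ∝ ∏_j [ α P(X_ij | G_k¹) + (1−α) P(X_ij | G_k²) ]

with per-read haploid probabilities ω (match) or (1−ω)·Φ(x, g)
(mismatch), where ω = 1 − harmonic mean of the base- and mapping-quality
error probabilities. Posteriors combine mutation-rate genotype priors
(θ = 10⁻³; optional flat and Ti/Tv-weighted modes) and the maximum a
posteriori genotype is reported. Non-reference calls are graded
high/low/false-positive by the variant confidence score — the mean
reference-substitution surprisal of genotype-supporting reads — against
analytic thresholds built from θ and the Ti/Tv ratio δ.

Indels are screened by two one-sided Fisher's exact tests (substitution
excess disqualifies, indel excess qualifies) and their allele is the
consensus of a multiple ungapped alignment: every substring of the
observed indel sequences seeds a gapless overlay, scored by a
position-specific weight matrix of log₂ frequency/background odds.

Somatic calls from matched pairs combine a subtraction analysis (normal
homozygous reference + high-confidence tumor variant ⇒ Somatic) with a
joint posterior over the 100 genotype pairs, coupled by a
tumor-given-normal dependency prior, followed by confidence-based
post-processing and classification into Somatic / LOH / Germline /
Unknown. A pileup-level simulator with ground truth makes the whole
engine testable without external data.

## Worked example

Simulate a 300-site tumor–normal pair and call somatic variants, either
from R:

```r
library(varcall)
sim <- simulate_tumor_normal(300, coverage = 30, error_rate = 0.01,
                             purity = 0.9, somatic_fraction = 0.01,
                             indel_fraction = 0.15, seed = 7)
calls <- call_somatic(sim$normal, sim$tumor, var_params(purity = 0.9))
glance(calls)
```

or from the shell with the bundled front end:

```sh
exec/varcall simulate --sites 300 --seed 7 -o demo
exec/varcall somatic -n demo_normal.mpileup -t demo_tumor.mpileup \
                     -o demo.vcf --purity 0.9
```

which prints

```
simulate: 300 sites, 30x, error 0.01, purity 0.90, somatic 0.01, indel 0.15 (ext 0.30), seed 7
somatic: 5 records (Somatic 2 SNV + 1 indel, LOH 0, Germline 2, Unknown 0); purity 0.900
```

and writes a two-sample VCF whose body begins

```
sim1  22   .  T  G   .  PASS  SS=Somatic   GT:DP:VCOS  0/0:26:0.0010  0/1:28:3.4183
sim1  28   .  T  G   .  PASS  SS=Germline  GT:DP:VCOS  0/1:34:4.8619  0/1:23:6.0521
sim1  137  .  T  TA  .  PASS  SS=Somatic   GT:DP:VCOS  0/0:27:.       0/1:33:.
```

Row one is a somatic SNV: the normal genotyped homozygous reference
(GT 0/0), the tumor heterozygous T→G with confidence score 3.42 and 28
retained reads. Row two is a shared germline heterozygote (SS=Germline).
Row three is a somatic single-base insertion (REF T, ALT TA) whose
allele is the ungapped-alignment consensus of the tumor's inserted
sequences. Three implanted mutations, two reported — the third site drew
too few mutant reads at this depth to clear the read-count constraint,
which is the sensitivity/specificity trade the confidence machinery is
making explicit.

Germline-only calling works the same way on a single sample
(`call_germline()` / `exec/varcall germline`), and `autoplot()` on
either result type shows the confidence-score distribution against its
thresholds.

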