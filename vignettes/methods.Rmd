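---
title: "Distinguishing low-level mutations from sequencing error: models and design"
author: "minorcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing low-level mutations from sequencing error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minorcall)
```

## The problem

Deep resequencing of a small shared target — a mitochondrial genome, an
amplicon panel, a pooled sample — routinely reaches coverages of hundreds to
thousands of reads per position. At that depth, variants present in only a
few percent of the template molecules (heteroplasmies, somatic mutations,
minor components of pools; here called low-level mutations, LLMs) become
statistically visible, but so does the sequencing error floor: an instrument
error rate of about 1% produces several spurious minor-allele reads at
essentially every position. Worse, errors are not uniform. They are
strand-specific, they depend on the position within the read, and the same
error-prone sites recur across individuals sequenced on the same platform,
so a global error rate badly miscalibrates exactly the sites that matter.

`minorcall` addresses this with three ideas used together:

1. **Population-derived error profiles.** For a target position in a query
   sample, every other sample whose consensus nucleotide matches the query's
   consensus is a reference individual. Their minor-allele counts estimate
   the local, fully context-aware error rate — including mapping artefacts,
   since references ran through the same pipeline.
2. **Read bins.** Quality-passing bases are stratified by strand and by
   10-bp segment of the read in sequencing order (16 bins for 76-bp reads;
   read positions 2–11, 12–21, ..., 72–76, with the noisy first cycle
   excluded). Error rates are estimated and tested per bin, so reads in
   error-prone bins carry less weight.
3. **Per-strand Phred-like scores.** Per-bin deviation P-values are combined
   into a per-strand bias statistic and reported as a Phred-like quality,
   leaving the sensitivity/specificity trade-off to the investigator instead
   of hard-coding thresholds.

## Quality control

Reads are dropped when they carry more than 5 bases (2 for 36-bp reads) at
Phred quality 15 or below, map with quality below 20, or mismatch the
reference more than twice; of the surviving reads only bases with quality 20
or more are counted. These are the defaults of `filter_config()`; all are
configurable. Indels are ignored throughout — the package calls single-base
substitutions only — and soft-clipped bases are excluded (they do not align
to the reference). Duplicate reads are deliberately **not** removed:
collapsing by start coordinate discards most of a deep single-end library,
and the score combination bounds what any one bin (the signature of a
duplicate stack) can contribute.

## The error model

For query sample $q$ at position $p$, let $k_b$ and $n_b$ be the minor-allele
count and depth in bin $b$, and let $E_b$ and $N_b$ be the pooled count of
that allele and pooled depth over the $R$ reference individuals. The pooled
error rate is pseudocounted,

$$\lambda_b = \frac{E_b + \tfrac12}{N_b},$$

so downstream tail probabilities are defined even when the panel shows zero
errors. When $R \le 50$ the profile is *degraded*: position-specific
estimation is abandoned in favour of a fixed fallback rate (default 0.01,
the platform average), and the empirical method — which needs the per-sample
frequency list — refuses to run. When the panel itself segregates for a
variant, the pooled "error" rate is inflated; where a one-sided binomial
test finds it significantly above 0.01, the rate is capped at 0.01
(`cap_common_variant()`), which keeps genuinely common variants callable.

Three deviation P-values are computed per covered bin:

* **Poisson**: $P_b = \Pr(X \ge k_b)$ with $X \sim
  \text{Poisson}(n_b \lambda_b)$ — assumes errors arrive at a well-defined
  rate;
* **Fisher exact**: the one-sided hypergeometric tail of the table
  $[k_b, n_b - k_b;\ E_b, N_b - E_b]$ — no rate assumption, raw counts;
* **Empirical rank**: $P_b = (1 + \#\{r : e_{rb}/n_{rb} \ge k_b/n_b\}) /
  (R_b + 1)$ — the rank of the observed frequency among the reference
  individuals' own frequencies, distribution-free and sensitive when the
  absolute excess is small.

## The bias statistic and quality score

Each covered bin ($n_b > 0$) contributes a Phred term
$\min(-10\log_{10}\max(P_b, 10^{-6}),\ \text{per-bin cap})$; the per-strand
bias statistic is the **mean of these terms over the covered bins**, and the
quality score is that mean capped at 60. For the empirical method the floor
$1/(R_b+1)$ is intrinsic, which makes its maximum $-10\log_{10}(1/(R+1))$ —
about 18 with 63 references — grow with the panel rather than being fixed.

This combination has the properties the method needs. The maximum per-strand
score is exactly 60 for Poisson/Fisher. A strand whose minor allele deviates
in only one of $m$ covered bins can reach at most $60/m$ — e.g. 10 when six
bins have reads — so concentrated evidence (the signature of duplicate reads
or a position-specific artefact) is strongly discounted, while an allele
supported across all bins of both strands scores highly. A single sequencing
error read contributes on the order of $10/8 \approx 1.3$, so error-only
positions score near zero. Summation with a per-bin cap is available
(`caller_config(combine = "sum")`) for users who prefer additive evidence.

A position is called when each strand reaches the minimum quality (default
10; `strand_rule` offers `min_strand` and `sum` variants because a
single-strand threshold is also defensible) and the minor-allele frequency
reaches `min_minor_freq`. The package default for the frequency floor is 0;
the mtDNA study's reporting configuration — used by the validation code here
— adds `min_minor_freq = 0.05` to guard against low-level
cross-contamination masquerading as heteroplasmy.

## The simulator

`simulate_panel()` emulates the validation design: a 16,569-bp target
(mitochondrial-genome-sized), 76-bp single-end reads with uniform random
starts and strands, a uniform 1% per-base error rate (erroneous base uniform
over the three alternatives), read counts of 40k/100k/200k/400k for the
nominal 200–2,000x tiers, and one planted mutation per test sample at a
uniformly random position, modelled as a second haplotype sampled per read —
the mixture semantics of heteroplasmy — at frequencies 2–10% and 20%.
Reference samples are error-only. Optional features: strand-specific error
hot-spot maps shared by all samples (hot spots recur across individuals),
two-haplotype mixtures at arbitrary ratios, and chimeric-read injection that
re-templates a fraction of reads evenly from the other samples of a library.

Two deliberate design choices:

* **The target is circular by default.** Both study genomes (human mtDNA,
  PhiX174) are circular. On a linear target the outermost read-length of
  positions is covered by a single shallow bin per strand, and any scorer
  that averages over covered bins will occasionally promote two or three
  chance errors there to a confident call; this is a simulation artefact,
  not a property of the method, and wrapping reads around the origin removes
  it. `sim_config(circular = FALSE)` restores linear behaviour (required
  when emitting plain SAM records, which cannot wrap).
* **Panels are simulated at pileup level.** Because bin slot sets are
  disjoint and per-base errors independent, per-bin depths and error counts
  can be drawn directly (binomial totals allocated uniformly over base
  slots) with exactly the same joint distribution as per-read simulation;
  the test suite verifies the read-level path against its own SAM
  serialisation and against the fast path. Mixtures and chimeras, which
  need within-read haplotype correlation, always use the read-level path.

What the simulator does **not** emulate: quality-score decay along the read
(qualities are constant Q40), indel errors, GC and amplification bias,
paired-end structure, and real error hot-spot structure unless injected.
Passing the simulation study therefore demonstrates calibration of the
statistics under the stated error model, not performance on any particular
instrument's artefacts — on real data the reference panel is what absorbs
those.

## Validation design and problem sizes

`simulation_study()` reruns the grid: 4 depth tiers x 10 planted frequencies
x 20 replicates. Replicates are independent test samples; per depth they
are grouped into panels that share 51 fresh error-only references (the
reference gate requires more than 50) — 10 replicates per panel at the
shallow tiers, 5 at the 1,000x and 2,000x tiers, where the denser error
tables make smaller panels the better memory trade — and every query is
scored against the error-only reference samples, so the effective reference
pool is the configured 51 regardless of the grouping. (On real panels the
package's default reference rule is all other samples sharing the
consensus, as in `call_panel()`.) The false discovery rate is
the fraction of called (sample, position) pairs whose position/allele was
not planted, pooled over the grid; with the study configuration (quality 10
on both strands, frequency at least 5%) it is 0 in a typical run, against a
target of below 1%. Detection of 5% mutations at the 500x tier is close to
one half (long-run estimate about 0.57 by the Poisson and Fisher methods,
0.46 empirical). `null_study()` runs a 60-sample error-only panel at 500x:
the median per-strand Poisson/Fisher quality lands at about 1.3 — zero up to
the granularity of a single error read, whose contribution is $10.3/8$ —
and empirical scores concentrate between 0 and about 5. These sizes keep
the whole validation run within minutes on one CPU while preserving the
stated replicate counts.

## Numerical and degenerate-case choices

* Consensus and minor alleles break ties lexicographically (A < C < G < T),
  and consensus ties are flagged; no randomness anywhere in the caller.
* P-values are floored (1e-6 for Poisson/Fisher; $1/(R_b+1)$ empirical)
  before the Phred transform, which fixes the caps.
* A strand with no covered bin has no quality (`NA`) and fails the strand
  rule; bins with $k_b = 0$ contribute 0 ($P_b = 1$).
* Empirical rank comparisons are exact on the frequency ratios (equal
  rationals yield identical doubles), not tolerance-based.
* Mismatch counts come from the NM tag when present, otherwise are
  recomputed against the reference; reads without either raise an error
  naming the read.
* Text-pileup input has no read-position information: bases collapse into a
  single segment per strand with a warning, and indel/`*`/`<`/`>` symbols
  are consumed without being counted.

## Contamination and chimera forensics

A contaminating sample leaves minor alleles identical to its consensus.
`screen_contamination()` examines every sample with more than five verified
minor alleles against every other sample: a candidate that explains all of
them, covering more than 60% of the pairwise consensus differences, is a
*strong* mixture signal; at least three explained gives *partial* (flagged
for exclusion rather than auto-excluded — mixtures of several samples and
true LLMs are indistinguishable at this level). The mixture proportion is
the mean frequency of the contaminant allele over all differing positions,
counting misses as zero. `assess_chimera()` asks whether a minor allele is
consistent with a fraction $f$ (default 0.15) of reads deriving evenly from
the other samples in the library: the expected chimeric frequency is $f$
times the share of library mates whose consensus carries the allele, and a
call is *explainable* when a one-sided exact binomial test fails to place
the observed count above that expectation at $\alpha = 10^{-7}$. The
direction of this test is a design choice (the screen asks "could chimeras
alone account for this?"), and the test is per position.

## Error hot and cold spots

`scan_panel()` pools non-consensus counts per position and strand over the
panel. A strand is a **hot spot** when its depth is at least 10,000x, the
upper Poisson tail of its error count under the panel-average rate falls
below $1/(L \times 10^6)$ — a familywise-safe threshold, under which the
expected number of false hot calls on uniform data is far below one — and
its rate is at least ten-fold the other strand's (strand-specificity
separates error artefacts from genuine variants, which load both strands).
**Cold spots** mirror this with the lower tail and a half-rate gate. The
panel mean rate is pooled over strands and positions; a strand-specific mean
is a one-line change but was not adopted, as the definition targets outliers
orders of magnitude beyond either mean.

## Known limitations

* The score-combination rule is a reconstruction pinned to the published
  behaviour of the method (caps, single-bin strand scores, null behaviour);
  it is not a claim about any other implementation's internals. All
  constants are exposed in `caller_config()`.
* Only the second-most-frequent allele is tested; tri-allelic positions are
  not decomposed.
* Substitutions only; indel LLMs are out of scope.
* Diploid genotyping (error models for heterozygotes, low-coverage binning)
  is future work.
* The empirical method inherits between-run rate differences: when
  reference and query samples come from different lanes or runs, rank
  P-values can capture run effects as signal. Pool references from the same
  run where possible.
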