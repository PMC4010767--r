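---
title: "Multi-evidence fine-mapping of a dominant coat phenotype"
author: "slickmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-evidence fine-mapping of a dominant coat phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slickmap)
```

# The problem

A dominantly inherited coat phenotype — the motivating case is the short,
sleek "slick" coat of tropically adapted Criollo-derived cattle — segregates
in a handful of composite breeds and their crossbred lineages. Because the
carrier breeds are young, closed, and strongly selected, the causal allele
sits on a long shared founder haplotype, so no single statistic localizes it
well: association signals spread over megabases of linkage disequilibrium,
and haplotype-based statistics are confounded by breed structure. `slickmap`
implements the complementary evidence tracks such a study combines and
intersects them into a consensus locus:

1. **Mixed-model case/control association** with a kinship random effect
   and adaptive label permutation;
2. **Haplotype-block pattern association** (EM-based LD, Gabriel-rule
   blocks, per-pattern chi-square with a sample-level permutation null);
3. **Runs of homozygosity (ROH)** frequency scanning among affected
   individuals at several run-length thresholds;
4. **Standardized |iHS|** selection scans with windowed averaging;
5. **Identity-by-state (IBS)** sliding-window consensus haplotype mapping.

Tracks 1 and 3 are *span* evidence (their intersection defines the
consensus interval); tracks 4 and 5 are *support* evidence (checked for
overlap, reported as corroborating or failing). This two-tier rule reflects
how such evidence intervals combine in practice: for the bundled
worked-example tracks, the association span intersected with the ROH peak
already yields the 0.8 Mb consensus, while the selection-scan peak (a
point) and the IBS sub-regions confirm it without constraining it. A strict all-intersection mode is available via
`integrateConsensus(..., all_intersect = TRUE)`.

# Models and statistics

## Mixed-model association

The null model is $y = \mu + g + e$ with $g \sim N(0, \sigma_g^2 K)$ and
$e \sim N(0, \sigma_e^2 I)$, where $K$ is a genomic relationship matrix
(`kinshipMatrix(gm, "grm")`, VanRaden centering and scaling; an IBS
allele-sharing mode is used for relatedness-based sample pruning). The
variance ratio $\delta = \sigma_e^2/\sigma_g^2$ is estimated once by REML:
after rotating by the eigenvectors of $K$ the likelihood is a
one-dimensional function of $\delta$, profiled on a log grid and refined
with Brent optimization. Each SNP is then tested by generalized least
squares with the variance *structure* fixed at the null estimate — the
EMMAX approximation — while the residual scale is re-estimated per SNP so
that with $K = I$ the test reduces exactly to the ordinary regression
t-test (df $n-2$), a property the test suite asserts to $10^{-6}$.
Case/control status is coded 0/1 and analysed as quantitative; missing
genotypes are mean-imputed per SNP; constant SNPs report `NA`.

Permutation p-values use sample-level label permutation with add-one
smoothing, $p = (1 + \#\{|t^*| \ge |t|\})/(1 + n)$, so $p \ge 1/(n+1)$
always. The adaptive rule drops a SNP from the active set once its
exceedance count reaches `drop_count` (default 10): its p-value is then
already resolved as non-significant to the precision that matters.

## LD, blocks, and pattern association

`ldR2EM()` computes maximum-likelihood two-locus haplotype frequencies from
unphased genotypes; only the double heterozygote is phase-ambiguous and is
split between cis/trans in the E step (convergence at $10^{-8}$, cap 1000
iterations). $r^2 = D^2/(p_A p_a p_B p_b)$ and signed $D'$ are derived from
the fitted frequencies. Blocks follow the Gabriel confidence-interval rule
with Haploview's constants: the 90% CI of $|D'|$ is profiled on a 101-point
grid with allele frequencies fixed at their MLEs; a pair is "strong LD"
when CI lower $\ge 0.70$ and upper $\ge 0.98$, informative-recombinant when
upper $< 0.90$; a contiguous candidate is a block when $\ge 95\%$ of its
informative pairs are strong, accepted greedily largest-first without
overlap, ignoring pairs further apart than 1000 kb.

Within a block, chromosomes are grouped by exact allele string and each
pattern is tested pattern-vs-rest on case/control chromosome counts with a
1-df chi-square. The permutation null permutes sample labels with both
chromosomes of a sample moving together, preserving within-individual
phase correlation; each pattern's corrected p counts its own permuted
chi-squares (add-one). The output mirrors the familiar published table
schema (block id, bounds, block distance = end − start, allele string,
group frequencies, p-values), and `patternTableStats()` recomputes the
headline arithmetic of any such table (longest/shortest block,
distinct-block and zero-control-pattern counts, largest case-control
frequency increase) after validating the distance invariant row by row.

## Runs of homozygosity

`detectROH()` finds maximal runs of consecutive homozygous calls per
sample; run length is counted in SNPs (thresholds 100/200/300/500 by
default) and bp extent is reported but never used for calling. Defaults
are strict — one heterozygous or missing call breaks a run — with
`het_tolerance`/`missing_tolerance` available because PLINK-style callers
allow slippage. `rohFrequency()` divides each locus's covering-sample
count by the subset size (typically all affected individuals), and
`peakInterval()` extracts the smallest interval holding every locus at or
above a fraction of the track maximum.

## Selection scan

EHH at extension $x$ is the probability that two random chromosomes
carrying the core allele are identical over core..$x$,
$\sum_h \binom{n_h}{2}/\binom{n}{2}$. iHH integrates EHH over physical bp
(trapezoid) in both directions, truncating at the first of: EHH below 0.05,
5 Mb from the core, or the chromosome end (the trapezoid ending at the
first below-cutoff SNP is included; the truncation reason is recorded).
Unstandardized iHS is $\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$; scores are
standardized to zero mean and unit variance within 20 equal-width
derived-allele-frequency bins (bins under 5 scores merge into a
neighbour), and a centered 30-SNP moving average reduces background noise.
Integration is in bp because no genetic map is assumed; chromosomes with a
missing call are excluded from extensions spanning it (exclusion is
cumulative along a walk). EHH monotonicity holds exactly only without such
exclusions, which is when the suite asserts it.

The ancestral allele is assigned by the group-frequency rule: at each
variant, the allele at higher frequency among the affected group's
chromosomes is labelled ancestral, with exact ties broken toward the
panel-wide major allele. This deliberately inverts the usual outgroup
convention — under strong recent selection the swept allele behaves like
the "old", long-haplotype allele — and standard outgroup-based assignment
can be supplied instead by passing any 0/1 vector to `ihsScan()`. The scan
panel in `runPipeline()` is the affected (consanguine) chromosomes, where
the sweep contrast lives; scanning the full mixed-breed panel buries it
under between-breed haplotype sharing. A compiled scan (`engine = "cpp"`)
and a plain-R reference (`engine = "r"`) produce identical numbers; the
suite checks them against each other and against hand-computed trapezoids.

## IBS consensus mapping

Windows of $w$ consecutive SNPs (default stride 1, $w$ from 1 to 50) group
chromosomes by exact allele string; pattern ids for all window positions
are computed by binary lifting (ids of length-$2k$ windows combine two
length-$k$ ids; a general $w$ combines its largest power-of-two prefix
with an overlapping suffix), so a full scan is $O(nm\log w)$. A window
supports a phenotype-bound consensus when some pattern reaches in-group
frequency $\ge 0.4$ — the frequency expected for a dominant allele carried
on one shared founder haplotype in a mostly affected breed — with
out-group frequency $\le 0$ by default ("zero frequency in unaffected").
Passing windows over all $w$ merge into maximal regions annotated with
their best supporting window size. `sharedBetweenGroups()` applies the
same machinery across two groups, and `homozygoteConsensus()` verifies a
set of individuals homozygous over a hint region and extends their shared
homozygous haplotype outward, splitting at internal conflicts (the longer
side is returned and every clean piece reported). Missing calls exclude a
chromosome from a window rather than wildcard-matching, which avoids
false sharing at the cost of slightly conservative frequencies.

# The synthetic cohort generator

Genotype panels for this kind of study are rarely public, so every stage
is exercised on seeded forward simulations (`simulateCohort()`):

* **Breed divergence.** Ancestral allele frequencies are
  Uniform(0.05, 0.95); each breed draws Balding–Nichols frequencies
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with $F = 0.15$ by default
  (pairwise Hudson $F_{ST}$ between two such breeds equals $F$, which the
  suite checks at $F = 0.2$).
* **LD.** Founder haplotypes are mosaics copied from a small per-breed
  template pool (default 8 templates, per-SNP switch rate 0.02), giving
  blocky background LD without a coalescent.
* **The causal haplotype.** One founder haplotype receives the derived
  allele and is planted at low frequency (5%) in every carrier breed
  (single shared origin by default; an independent-origins mode mimics
  the two-mutation scenario). Forward breeding (Haldane meioses: Poisson
  crossovers at 1 cM/Mb, uniform breakpoints, no interference) then
  sweeps it up a linear selection ramp to a final frequency of 0.55,
  so only the hitch-hiking region around the locus rises — planting at
  the final frequency outright would put the whole founder chromosome at
  high frequency everywhere and erase the local ROH/IBS contrast.
  At 0.55, the expected fraction of heterozygotes among affected
  individuals, $2q(1-q)/(1-(1-q)^2) \approx 0.62$, sits in the 0.6–0.7
  range reported for such breeds (note the printed "heterozygosity" of
  0.6–0.7 can only be a carrier-heterozygote fraction; $2pq$ cannot
  exceed 0.5).
* **Design.** Defaults emulate the study layout: three carrier breeds
  (30/15/10 samples), four non-carrier ancestral breeds (12 each), and a
  four-generation backcross lineage (12 samples) selected for carrier
  status, whose expected donor-genome fraction is $2^{-g}$ (6.25% at
  $g = 4$, i.e. ~94% recipient ancestry — within the 40–97% recipient
  range such lineages report). On a single selected chromosome the
  realized donor fraction exceeds the pedigree expectation near the
  causal locus because the retained allele drags flanking donor material;
  `makeCross(..., select_carrier = FALSE)` recovers the unconditional
  $2^{-g}$, which the suite verifies by Monte Carlo.
* **Scale.** 4,000 SNPs uniformly spaced on one 40 Mb chromosome,
  ~115 samples, 8 generations, full penetrance, no missingness — sizes
  chosen so twenty independent cohorts run through the entire pipeline
  comfortably on a single CPU while leaving the evidence tracks their
  characteristic shapes (association peaks, a ~0.3–0.4 ROH plateau among
  affected samples, megabase-scale haplotype sharing).

What the generator does *not* emulate: realistic demography (bottleneck
ages, effective sizes), array ascertainment bias, genotyping error, sex
chromosomes, or interference in recombination. Passing tests therefore
show the statistics behave correctly under a controlled truth, not that
the pipeline is robust to every artefact of real array data.

# Numerical choices and degenerate inputs

* QC order: samples by call rate first (strictly greater than 0.95), then
  variants by call rate (> 0.90), then MAF recomputed and filtered
  (> 0.05, strict per the usual "greater than" phrasing); removing
  everything is an explicit error. MAF uses non-missing calls only;
  missing is a sentinel, never conflated with 0.
* Intervals are 1-based inclusive; the span convention is end − start
  (matching printed "block distance" columns), not the inclusive width;
  BED export converts explicitly.
* Kinship pruning (`selectLeastRelated`) is greedy — drop the sample in
  most violating pairs, ties by mean kinship then lexicographic id —
  because no published algorithm is specified for this step; on 15-sample
  instances it matches the exhaustive optimum within one sample.
* PCA uses EIGENSTRAT scaling (center $2\hat p$, scale
  $\sqrt{\hat p(1-\hat p)}$, mean-impute missing) and returns orthonormal
  sample eigenvectors.
* The ROH span evidence in `runPipeline()` is the plateau of the
  30-SNP-smoothed frequency track at $\ge 0.8$ of its maximum: the
  elevated-autozygosity region, like a published "peak between X and Y
  Mb", is broad, and the raw argmax wanders within it seed to seed.
* Permutation counting always uses $\ge$ with add-one smoothing, so
  reported p-values are valid (never zero).
* `peakInterval` on an all-zero track, EM on a monomorphic locus, EHH
  with fewer than two carrier chromosomes, and kinship for a pair with no
  overlapping calls are all explicit errors naming the offending input.

# Limitations

* Statistical phasing is out of scope: the simulator emits true phase,
  and real unphased data must be phased externally before the
  haplotype-based stages.
* The mixed model is linear on a 0/1 trait (as EMMAX-style tools do);
  logistic mixed models are not provided.
* Block detection cost grows with the block-size cap
  (`max_block_snps`); `runPipeline()` restricts it to the neighbourhood
  of the association signal.
* The 0.4 IBS frequency rule is a threshold motivated by dominant
  inheritance in a mostly affected breed, not a fitted quantity; it is a
  parameter, and its derivation for other designs is the user's
  responsibility.

# A worked run

```{r pipeline, eval = FALSE}
co <- simulateCohort(cohortConfig(seed = 42))
res <- runPipeline(co, out_dir = "slickmap-out")
res$consensus
res$top_snp
```

The consensus object prints its interval, the span tracks that defined it
and the support tracks that corroborate it; `slickmap-out/` holds the
per-track TSV/BED files and a JSON run manifest.
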