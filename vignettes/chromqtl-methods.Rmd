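---
title: "chromQTL: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromQTL: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

chromQTL maps histone quantitative trait loci (hQTLs) — variants whose two
alleles carry systematically different amounts of a histone modification's
ChIP-seq signal — and follows them downstream into gene expression through
chromatin topology. This vignette is the package's own account of the
statistics it implements: the models, their assumptions, the parameters
that matter, and the choices made where the design was genuinely open.
Everything quantitative shown here is computed by the package's tests or
by `scripts/acceptance.R`; the vignette states no empirical result of its
own.

## 1. Consensus enhancer peaks

Per-individual reproducible peak calls (one BED file per individual, the
output of an upstream peak caller plus reproducibility filtering) are
combined by a per-base-pair majority rule: a base belongs to a candidate
consensus region when at least `min_support` individuals (default 13, a
majority of a 25-individual panel) have a peak covering it. Disjoint
candidate regions separated by *fewer than* `merge_gap` bp (default 147,
one nucleosome footprint) are then merged; the inequality is strict, so a
gap of exactly 147 bp survives. Merging is applied after support
thresholding; the alternative order is not meaningfully different on real
peak geometries but the choice is fixed and tested at the 146/147 bp
boundary.

Support for a merged interval is reported as the number of individuals
whose peak set overlaps it. After merging, a per-base support count is no
longer well defined for the whole interval; the overlap count is the
conservative summary. The per-base rule itself (which bases survive) is
unaffected.

Candidate variants for allelic-imbalance testing are the heterozygous
autosomal variants inside any consensus interval (`variants_in_peaks`);
intervals are half-open, so a variant at an interval's end coordinate is
outside.

## 2. The combined haplotype test (CHT)

For one SNP, the data are per-sample counts in the surrounding region:
reference and alternate allele-specific (AS) reads at heterozygotes, and
the total region read count for every sample. The joint likelihood has a
beta-binomial component for allelic imbalance and a negative-binomial
component for genotype-dependent depth:

$$
L(\alpha,\beta,m)=\sum_{j\,\in\,\text{hets}}
\log \mathrm{BetaBin}\!\left(r_j \mid n_j,\ \pi=\tfrac{\alpha}{\alpha+\beta},\ \rho\right)
+\sum_{j}\log \mathrm{NB}\!\left(t_j \mid \mu_j,\ \phi\right),
\qquad
\mu_j = s_j\, m\, \frac{g_{\mathrm{ref},j}\,\alpha + g_{\mathrm{alt},j}\,\beta}{2},
$$

with the normalisation $\alpha+\beta=2$, so that the allele ratio
$\alpha/\beta$ is the single effect parameter and $m$ the genotype-neutral
mean depth ($s_j$ are size factors; $g_{\mathrm{ref}}+g_{\mathrm{alt}}=2$
are allele counts). The null fixes $\alpha=\beta=1$; the likelihood-ratio
statistic is referred to a 1-df chi-square. The reported effect size is
$\hat\alpha/\hat\beta$, log2 of which measures imbalance strength — a
value of 1 means twice as many reads from the reference as from the
alternate haplotype.

Assumptions worth keeping in mind: genotypes are treated as known (no
haplotype-probability calibration); the depth component is negative
binomial; AS depth $n_j$ is conditioned on, not modelled. A GC-bias
adjustment enters only as an optional user-supplied size-factor column —
the package performs no GC estimation, and the synthetic data carry no GC
structure.

**Testability.** A SNP is tested only if its region holds at least
`min_as_reads` AS reads summed over samples (15 by default; 10 is the
conventional replication-cohort setting) and at least one heterozygote.

**Dispersions.** $\rho$ (beta-binomial overdispersion, in $[0,1)$) and
$\phi$ (NB size; larger is closer to Poisson) are learned once across all
testable regions and held fixed per-SNP. Each region contributes with its
own free nuisance parameter (allele fraction, mean depth) profiled out.
Plain profile likelihood noticeably underestimates $\rho$ at 25 samples
and a dozen heterozygotes per region, which inflates the test; the
estimator therefore maximises the Cox–Reid adjusted profile likelihood
(the $-\tfrac12\log$ observed-information correction familiar from NB
dispersion estimation in count-model packages), which removes the bias in
simulation.

**Multiple testing.** Holm's step-down FWER correction across all tested
SNPs, with two tiers: significant at FWER $\le 0.1$, suggestive at FWER
$\le 0.2$. Holm rather than BH because FWER control behaves better under
the strong local dependence of LD. Nominal tier thresholds are whatever
Holm implies for the actually-tested SNP count; no fixed nominal cutoff is
assumed.

**Calibration.** `cht_calibrate` re-runs the test after destroying the
genotype–count association: each sample's (ref, alt, total) count triple
is shuffled across samples relative to the genotype labels, and the
ref/alt assignment at heterozygote labels is flipped with probability 1/2
(a phase randomisation). Moving the triple as a unit keeps totals
exchangeable and the count invariants intact; the flip removes directional
imbalance. Under a correct model the permuted p-values are uniform; the
observed-vs-permuted quantile table is the QQ diagnostic.

**Numerics.** The alternative is maximised by L-BFGS-B over
$(\log_2(\alpha/\beta), \log m)$ with the effect box-constrained to
$[1/64, 64]$ (hitting the bound is flagged `at_bound`); if the line search
aborts — it occasionally does on very flat likelihoods — a derivative-free
nested golden-section profile takes over. The LRT is clamped at zero
against rounding.

## 3. Risk-haplotype enrichment by matched permutation

Whether hQTLs are over-represented on risk haplotypes cannot be judged
against a naive background: hQTLs live inside enhancer peaks and have
ascertainment-biased allele frequencies. The matched-permutation design
controls both. Pool variants (everything inside any consensus peak) are
binned into deciles of minor allele frequency crossed with deciles of
absolute distance to the nearest 5′ TSS — up to 100 categories (decile
edges are right-closed; duplicate edge values collapse bins). Each of
`n_perm` repetitions (default 1000) draws, per category, exactly as many
non-query pool variants as the query holds there, so every matched set
reproduces the query's category histogram exactly — this is asserted, not
hoped for.

Risk haplotypes are the LD blocks (PLINK-style `.blocks.det` input; blocks
are consumed, never inferred) containing each catalog index SNP, with
membership by variant-id set. Enrichment of a set is the one-sided
Fisher's exact test of the 2×2 overlap table, and the permutation p-value
is the add-one estimator $(1+\#\{\text{null}\ge\text{obs}\})/(1+n_{perm})$
— never zero by construction. The expected-by-chance count is reported as
the null mean. An optional exclusion interval drops variants (e.g. the
HLA region) from both query and pool before binning, for
sensitivity analyses. hQTLs themselves are excluded from the matchable
pool by default (`exclude_query`).

One property of the add-one estimator deserves a note: on a discrete
overlap count, ties between null and observed counts are counted against
the query, so the estimator is mildly conservative and its null
distribution is a lattice, not exactly uniform. With a dense catalog the
effect is negligible; with a very sparse catalog (a handful of expected
overlaps) it is visible in uniformity diagnostics. This is a property of
the estimator, not an error, and the package keeps the standard form.

## 4. Cis-eQTL scan

Expression (gene-level CPM) is filtered for coefficient of variation
$\ge$ `cv_min` (0.15) *on the raw CPM scale* — after a rank transform the
CV is meaningless — then transformed per gene by the rank-based
inverse-normal map with the Blom offset, $\Phi^{-1}((r - 3/8)/(n + 1/4))$,
to suit the linear model. Every variant with MAF $\ge$ `maf_min` (0.05)
within `window` (1 Mb, strict inequality) of the transcript is tested by
OLS of transformed expression on dosage; distance is measured to the
nearest transcript edge (TSS/TES interval), not the TSS alone — the
boundary convention is flagged because conventions differ between tools.
BH FDR is applied across all tested pairs (significant at $q \le 0.05$),
and per gene the significant SNPs are greedily pruned in ascending p-value
order, retaining a SNP only when $r^2 < 0.8$ against every retained one.
Exclusions (window, MAF, CV) are recorded with reasons, never silently
dropped.

No latent-factor correction is implemented; the synthetic generator can
add sample-level log-normal noise, which the inverse-normal transform
partially absorbs, but structured confounding as in real cohort data is
out of scope and the package does not claim robustness to it.

## 5. LD statistics

$D$, $D'$ and $r^2$ are always computed from phased haplotype tallies
($D = p_{AB} - p_A p_B$; $D' = |D|/D_{max}$; $r^2 = D^2/(p_A p_a p_B
p_b)$). Unphased records are rejected rather than resolved by EM — the
supported data are phased by construction, and an EM fallback would be
untested surface. Monomorphic variants raise an error: their LD is
undefined.

## 6. Local joint models and D²

For haplotype blocks of at least six variants containing an eQTL and an
hQTL in strong but incomplete LD ($D' \ge 0.8$, $r^2 < 0.6$), the package
asks whether the hQTL genotype explains expression variance beyond the
eQTL. The workhorse is the NB GLM with log link (via `MASS::glm.nb`,
profile-ML dispersion), and the summary is the deviance explained

$$D^2 = \frac{\text{null deviance} - \text{residual deviance}}
{\text{null deviance}},$$

with the null deviance from the intercept-only model and dosage coded
0/1/2. When a block holds several candidates, the lead eQTL is the variant
with maximum single-variant $D^2$ for the target gene and the lead hQTL
the one with the most significant CHT p-value (reading "maximum nominal
p-value" in its context of lead selection as maximum significance).

The observed statistic is the $D^2$ of the full joint model — eQTL and
hQTL main effects plus their product; the same interaction form is used
for the local and the distal analysis, resolving an ambiguity in favour of
one model family. The null distribution substitutes each non-QTL variant
of the block for the hQTL; if there are fewer distinct substitutions than
`n_perm` (10,000 by default), they are exhausted once and resampled with
replacement. The permutation p-value uses the add-one estimator with a
Clopper–Pearson 95% CI. Two numerical notes: $D^2$ is clamped to $[0,1]$
(profile-dispersion refits can produce trivially negative differences),
and a fit on a degenerate substitution (e.g. a dosage column collinear
with the eQTL) is dropped from the null rather than aborting the scan.
When `glm.nb`'s dispersion iteration diverges because residual variation
is at or below the Poisson limit, the dispersion is pinned at a large
fixed value and the fit retained.

## 7. Distal eQTL × hQTL interactions in loop networks

HiChIP loops (BEDPE, intrachromosomal, anchors ordered) are filtered to
PET support $\ge 4$ and anchor-midpoint span in [5 kb, 2 Mb] — the
quality conventions of loop-calling pipelines, applied here as
consumed-data filters. A chromatin network is a connected component of the
loop graph in which overlapping anchors collapse into one node.

Eligible pairs must be LD-independent ($r^2 < 0.6$ *and* $D' < 0.6$), on
separate haplotype blocks, with the hQTL inside an H3K27ac anchor whose
network reaches the target gene's transcript range (10 kb upstream of the
TSS through the TES, strand-aware), and with all nine dosage combinations
observed — an empty cell would leave the interaction coefficient
unidentifiable in practice. Each eligible pair is fit with the NB GLM
design $[1, d_e, d_h, d_e d_h]$ on de-normalised counts (CPM times stored
library size over $10^6$, rounded — the count model needs counts, and the
discretisation is documented rather than hidden). Significance of the
interaction coefficient $\gamma$ is the two-tailed z-test
$\gamma/\mathrm{se}$, BH-controlled across pairs.

**Topology labels.** The six labels in common use are not a well-defined
partition if read in isolation (a literal "hQTL in a loop anchor without
the eQTL" would make "Off-target" unreachable), so the classifier is an
explicit first-match cascade with a fixed evaluation order:

1. **Anchored** — some single anchor contains both SNPs;
2. **Unanchored** — the hQTL lies in no anchor;
3. **Looped** — the eQTL lies in some (other) anchor;
4. **Off-target** — no loop containing the hQTL reaches the target range;
5. **Joint** — a loop connects an anchor overlapping the hQTL's haplotype
   block to one overlapping the eQTL's block;
6. **Disjoint** — otherwise.

All six labels are reachable, the function is total, and it is tested
against an independently coded truth table on 1000 random configurations.
Note the eligibility filter already demands an anchored, network-connected
hQTL, so scans restricted to eligible pairs can only ever produce
"Anchored"/"Looped"; the classifier supports the full label set so it can
be applied to broader candidate sets.

**Quadrants.** Converged fits are classified by
$\mathrm{sign}(\beta_e) \times \mathrm{sign}(\gamma)$: enhancing-opposed
$(+,-)$, repressive-opposed $(-,+)$, enhancing-concordant $(+,+)$,
repressive-concordant $(-,-)$; an exactly zero coefficient yields the
tie-label "boundary" and is excluded from quadrant counts.

## 8. What the synthetic data do and do not emulate

The generators exist so every stage is testable without any external
download, and their defaults are the study conditions the pipeline
targets: 25 diploid samples at hQTL scale and 358 at eQTL scale; AS depths
of 30 (discovery-like) to 50; beta-binomial overdispersion 0.05 and NB
size 10 for ChIP counts; NB size 20 and baseline mean 500 for expression;
log-normal library sizes around 30 million reads; TSS distances
exponential with mean 50 kb.

* **Genotypes** are drawn per block from a finite haplotype pool, two
  haplotypes per sample independently, so D′/r² are exact functions of
  pool composition — no recombination or coalescent machinery. The
  `"independent"` block type (i.i.d. alleles) is the zero-LD limit, used
  where exchangeable variants are needed.
* **AS counts** follow the CHT generative model itself: zero-truncated
  Poisson AS depth (depth is a nuisance; the test conditions on it),
  beta-binomial reference reads at heterozygotes, NB totals with
  genotype-scaled mean, floored at the AS count so the count invariant
  holds by construction.
* **Expression** is NB with log-linear dosage effects and a multiplicative
  interaction — exactly the model the joint analyses fit.
* **Loops** are placed deterministically between hQTL positions and
  promoters; **catalogs** select hQTL-bearing blocks at `fold` times the
  background probability.

Because generator and model agree, passing calibration tests demonstrates
the inference machinery is correct — it does not demonstrate robustness to
real-data pathologies: reference-alignment bias in AS reads, GC and
copy-number structure in ChIP depth, PEER-style latent expression factors,
genotyping and phasing error, or realistic recombination-driven LD decay.
Those require real data and are deliberately out of scope.

`simulate_study()` writes a complete fixture directory (VCF, per-individual
BEDs, counts and expression TSVs, BEDPE loops, catalog, blocks, YAML
config, JSON manifest) exercised by the bundled CLI
(`inst/scripts/chromqtl-cli.R`), one subcommand per stage. Its demo block
places the designated hQTL and eQTL at D′ = 1, r² ≈ 0.43 — inside the
local-analysis eligibility window — and its matching bins are coarsened to
3×3 in the emitted config because a fixture-sized pool cannot support
10×10 matching.

## 9. Problem sizes used by the checks

The test suite and `scripts/acceptance.R` size their simulations as
follows (chosen as the smallest designs whose Monte-Carlo error is
comfortably below the property margins being asserted): CHT calibration on
2000 null regions of 25 samples; effect recovery on 200 replicates per
grid point over $\log_2 ES \in \{0, 0.5, 1, 2\}$; enrichment uniformity
over 200 catalog realisations at 200 matchings each, with the uniformity
fixture using a dense catalog (pool 3000, 300 queries, background 0.3) so
the overlap statistic has enough distinct values for a KS diagnostic, and
the power fixture using 500 queries at background 0.05; D² null uniformity
on 200 blocks of 20 exchangeable variants at n = 358 (18 distinct
substitutions keep the permutation-p lattice fine); interaction type-I on
1000 pairs and CI coverage on 200 replicates at n = 358.

## 10. Known limitations

* The CHT depth component is NB; a beta-NB variant (heavier-tailed) is not
  offered.
* Haplotype blocks are consumed, not estimated; results inherit whatever
  block definition the user supplies.
* The enrichment permutation p is conservative on very sparse catalogs
  (Section 3).
* Expression confounder correction is limited to what the inverse-normal
  transform absorbs.
* `eligible_pairs` evaluates LD per pair with no indexing; it is meant for
  candidate sets of lead QTLs (hundreds by thousands), not genome-wide
  crosses.
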