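---
title: "Methods: population-genomic analysis of a diploid SNP panel"
author: "duripop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic analysis of a diploid SNP panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

duripop implements the post-variant-calling half of a resequencing
population-genomics study: it starts from a filtered multi-sample SNP
VCF (plus gene models, a reference sequence and sample metadata) and
carries the analysis through diversity, differentiation, linkage
disequilibrium, population structure, phylogeny, selective-sweep
scanning, variant effect classification and core-collection design. The
motivating design is a durian (*Durio zibethinus*) germplasm panel of
114 accessions that partitions into three populations (POP1/POP2/POP3,
sizes 52/40/22), with pairwise differentiation in the moderate range
(Fst 0.12-0.20), per-population nucleotide diversity near
0.0019/0.0016/0.0012 per bp, and a handful of admixed individuals.
Everything upstream of the VCF (read QC, alignment, genotype calling)
is out of scope.

The package is a library: its interface is the exported R functions and
the `runPipeline()` orchestrator, not a shell executable. All
randomness flows from one master seed through `deriveSeed(seed,
stream)`, a documented splitting scheme, so every stage is reproducible
in isolation.

# The genotype panel and its filters

`GenotypePanel` holds a variants x samples matrix of alternate-allele
dosages (0/1/2, `NA` for missing calls) over biallelic SNPs with sorted
unique coordinates. VCF and GFF3 coordinates are 1-based inclusive;
window arithmetic is 0-based half-open, and the conversion lives in one
internal function so off-by-one drift cannot creep in per call site.

`filterVariants()` applies the two standard panel filters with strict
inequalities: a site is removed when its missing fraction exceeds 0.20
or its minor allele frequency falls below 0.01. MAF uses the
non-missing allele count as denominator — the behaviour of the usual
VCF toolkits — rather than 2N. Multi-allelic records are dropped at
read time, not split: the analysis treats SNPs as biallelic markers
throughout. Filtering is idempotent and the retained sites are
re-verified by brute-force recount in the test suite.

# Diversity and differentiation statistics

Per-site nucleotide diversity is the unbiased mean pairwise difference
`pi = n_ref * n_alt / choose(n, 2)` over the non-missing alleles at the
site. Windowed pi divides the per-window sum by the *window length in
bp*, treating sites absent from the panel as monomorphic; this matches
the ~1e-3 per-bp magnitudes a resequencing panel reports. A window with
no SNPs is 0 (with `n_snps` recording the lack of evidence), not `NaN`
— the monomorphic interpretation, which also makes total diversity
exactly invariant to the tiling window size.

Windows default to 100-kb non-overlapping — the convention behind the
headline scans — with any sliding scheme available through
`windowSpec(size, step)`; a 50-kb sliding alternative is one argument
away. `minSnps` (default 5) gates only the statistics whose variance
explodes in near-empty windows (Tajima's D, Fst).

Tajima's D uses the standard constants (a1, a2, b1, b2, c1, c2, e1,
e2). With missing data the allele count n varies site to site inside a
window; the constants are evaluated at the window's modal non-missing
allele count. An exact missingness-aware variance is not established
practice, and the modal-n approximation is what the field's tools do.
Neutral-coalescent calibration in the test suite checks the mean of D
across 500 neutral replicates; D is not exactly mean-zero under
neutrality at finite sample size (its normalization makes the mean
slightly negative), so the suite asserts |mean| < 0.2 on a statistic
whose neutral standard deviation is close to 1, rather than zero.

Weir-Cockerham Fst is computed from the per-site variance components a
(among populations), b (among individuals) and c (within individuals)
for two populations with per-site sample sizes, using the observed
heterozygote fractions. Window and genome-wide values are the weighted
"ratio of sums" `sum(a) / sum(a + b + c)`; per-site components may be
negative and are deliberately not truncated before summation — that is
what keeps the ratio-of-sums estimator consistent.

The pi-ratio track reports `pi_A / pi_B` per window with the
genome-wide median attached; the ROD track is `1 - pi_B / pi_A`, so
large values mean diversity lost in B relative to A. The source study
never prints the ROD formula, so the orientation is a package decision:
the swept candidate population is placed as B, and `mirror = TRUE`
computes the opposite orientation for transparency.

# Linkage disequilibrium

r² is the squared Pearson correlation of dosage vectors over samples
non-missing at both sites — the composite (Rogers-Huff) estimate, which
needs no phasing assumption and is standard for unphased diploid
panels; EM haplotype-frequency r² is out of scope. Pairs are
same-chromosome within `maxDistance`, subsampled uniformly per distance
stratum under a fixed seed when a cap is set. Decay summaries (the
half-maximum point, with the maximum defined as the first defined bin's
mean, and absolute-threshold crossings) interpolate linearly between
bin midpoints, which stabilizes "about X kb" summaries against bin
quantization; a curve that never crosses returns `Inf`.

# Population structure

PCA standardizes dosages by `sqrt(p(1-p))` after mean-imputing missing
calls and dropping monomorphic sites, then eigendecomposes the sample
covariance.

The admixture model maximizes the binomial likelihood `sum g log p +
(2-g) log(1-p)`, `p_il = sum_k q_ik f_kl`, by FRAPPE-style EM updates —
simpler than block-relaxation quasi-Newton and adequate at this scale,
with seeded Dirichlet(1) initializations and multiple restarts against
local optima. F is clamped to `[1e-6, 1-1e-6]` to keep the likelihood
finite; Q rows are renormalized each step to guard floating-point drift
off the simplex. The log-likelihood trace is recorded every iteration
and is non-decreasing (asserted in the tests). The update loop is
compiled code (RcppArmadillo) because cross-validation fits the model
hundreds of times.

The number of clusters K is chosen by masking cross-validation over a
configured range (default 2-5): 10% of the observed genotype entries
are masked per fold (5 folds), the model is fitted on the rest, and
masked entries are scored by squared error against `2 p_il`; the
chosen K minimizes mean CV error with ties going to the smaller K. The
source study reports an optimal K without naming its criterion; masking
CV is the established stand-in. CV fits use a loose EM stopping rule
(gain < 5 log-likelihood units or 100 iterations): held-out error
stabilizes long before the terminal likelihood crawl, and the loose
rule keeps the 2-5 x 5-fold sweep affordable. `assignPopulations()`
labels each sample by argmax ancestry and flags samples whose maximum
ancestry is below 0.8 as admixed — the threshold is a package decision,
the study prints none.

# Phylogeny

The tree module uses allele-sharing distances `d_ij = mean |g_i - g_j|
/ 2` over shared non-missing sites rather than converting SNPs to
pseudo-sequences for a nucleotide-model distance: concatenated SNP
columns violate the assumptions of F84-style distances anyway, so the
package makes the simplification explicit instead of imitating it.
Neighbor joining follows Saitou-Nei with the Studier-Keppler Q
criterion; ties are broken deterministically by the smallest pair of
current cluster indices, negative branch lengths are clamped to zero
with the deficit moved to the sibling edge, and additive matrices are
recovered exactly (tested against an independent NJ implementation).
Bootstrap support resamples variants with replacement, rebuilds the
tree, and maps bipartition frequencies onto the full-data tree as
internal node labels — support-mapping replaces majority-rule
consensus, conveying the same per-edge support. Newick round-trips
preserve topology, lengths (1e-9) and supports.

# Variant effects

`annotateEffects()` classifies each SNP against the gene models:
coding changes are evaluated by strand-aware codon translation under
the standard code, and consequences map to impact classes —
stop_gained/stop_lost/start_lost HIGH, missense MODERATE,
synonymous/stop_retained LOW, and all non-coding contexts (UTRs,
introns, 5-kb flanks, intergenic) MODIFIER. The 5-kb flank mirrors
common annotator defaults. The worst impact across transcripts is
reported. Frameshift consequences are unreachable in a SNP-only panel
and are deliberately absent. A transcript whose CDS is not a valid ORF
is skipped with a warning; a REF allele that contradicts the reference
sequence is a hard error, because it almost always indicates a
coordinate bug. Every coding call is cross-checked in the tests by
re-translating the whole CDS with and without the alternate allele.

# Sweep scanning

Candidate sweep windows are the joint upper tail of Fst and ROD: the
95th percentile of each track over its defined windows, with candidates
required to meet both cutoffs simultaneously (`>=`, so degenerate
distributions behave predictably). NaN windows are excluded from the
quantiles. Under independent null tracks the expected candidate
fraction is 0.25%, which the property suite verifies. Adjacent
candidate windows are also reported merged (bookended union) because
genes, not windows, are the unit of interpretation. Gene overlap is
>= 1 bp against half-open windows, and the three pairwise candidate
gene sets are partitioned into shared/unique regions exactly.

# Core collection

Allelic diversity of a subset is the fraction of SNP alleles retained:
the universe is both alleles at every polymorphic site of the full
panel, and an allele counts as retained when at least one non-missing
genotype in the subset carries it. The study's ">95% of allelic
diversity" does not define its metric, so this explicit, auditable one
is used, with an expected-heterozygosity retention companion metric
reported alongside. Selection is strict greedy (M-strategy-like):
repeatedly add the sample covering the most unretained alleles, ties
broken lexicographically — deterministic and testable, a documented
stand-in for the study's unspecified "diversity-maximization strategy".
Population quotas (e.g. 10/8/8) restrict each step to populations with
unmet quota; the default is unstratified.

# The synthetic panel generator

`simulatePanel()` generates the study conditions: 114 samples in
populations of 52/40/22 under the Balding-Nichols model — population
allele frequencies drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)` around a
uniform (0.05, 0.95) ancestral frequency. The POP2 size is the one the
study prints; the 52/22 split of the remainder is a calibrated choice
consistent with POP1 largest and POP3 smallest. Drift defaults
(0.07/0.17/0.23) come from solving `E[Fst_ij] ~ (F_i + F_j)/2` for the
printed pairwise targets; `calibrateDrift()` refines any target matrix
against pilot simulations. Six admixed individuals draw Dirichlet(1.5)
ancestry (reordered so the dominant component stays their source
population, keeping the 52/40/22 labels exact) and sample each allele
from the population indicated by a per-site ancestry draw.

SNP density (0.0056/bp) makes POP1's per-bp diversity land near 0.0019
with POP2 and POP3 ordered below it. Density and drift jointly cannot
reproduce all three printed diversities *and* all three printed Fst
values exactly — the Balding-Nichols model ties them together — so the
generator prioritizes the Fst targets and the diversity ordering.

LD is induced by a latent Gaussian process per haplotype: an AR(1)
chain with correlation `exp(-rho d)` plus an independent component, so
the between-site latent correlation is `nugget * exp(-rho d)` and
marginals stay exactly Bernoulli(p). Two deliberate departures from
the real system's scales: (1) the nugget (0.75) caps short-range LD
because real panels plateau well below r² = 1 at short distances, and
duplicated SNP columns are not a feature worth emulating; (2) the decay
rates are scaled to the miniature 6-Mb genome (half-decay roughly
2.5/7/15 kb for POP1/POP2/POP3) rather than the tens-to-hundreds of kb
of a full-size genome — a 6-Mb toy genome cannot hold thousands of
weakly linked SNPs if LD extends hundreds of kb, and the analyses that
matter (structure inference on a thinned panel, decay-curve ordering
across populations) depend on the linked/unlinked contrast, not on the
absolute bp scale. The ordering — fastest decay in the most diverse
POP1 — is preserved.

Planted sweeps push the target population's allele frequencies toward
the nearer boundary so within-interval expected heterozygosity is
multiplied by the requested factor; the default panel carries one sweep
in POP3 (chr01:900,001-1,100,000, reduction to 0.2x). Random gene
models (120 genes, 1-3 exons, valid ATG...stop ORFs, UTRs and introns)
are embedded in the generated reference on both strands, so effect
annotation can be verified against ground truth.

What the generator does not emulate: genotype-calling error and
depth-dependent missingness (missingness is uniform at 2%), ancestry
LD in admixed individuals (their ancestry switches site to site),
recombination-explicit haplotype genealogy, allele-frequency spectra
shaped by demography (the Beta model is not a coalescent; the separate
`simulateCoalescentLocus()` Hudson simulator exists precisely for
SFS-sensitive statistics), and any phenotype. Passing tests therefore
demonstrate estimator correctness and pipeline behaviour under the
stated model, not robustness to the artefacts of real calling
pipelines.

`simulateCoalescentLocus()` is a standard Hudson neutral coalescent
without recombination — exponential coalescence times at rate
`choose(k, 2)`, Poisson mutations at `theta * L / 2` per unit branch
length, infinite-sites placement on an integer grid — used to calibrate
pi and Tajima's D against their neutral expectations.

# Problem sizes and numerical choices

The calibration protocol uses 200 independent 10-kb loci of 50
haplotypes for diversity recovery (Monte-Carlo standard error about
3.5% of the target, comfortably inside the 10% band), 50,000 unlinked
SNPs for 50 + 50 diploids for Fst recovery (within 0.02), ten seeds of
the default 114-sample panel thinned to 5,000 SNPs for the K = 3
cross-validation check, and the default filtered panel for the
26-accession core (>= 95% allele retention). These sizes are the
package's calibration choices, stated here so the acceptance script
and the test suite mean the same thing by each number.

Numerical details worth knowing: empirical quantiles use R's default
type-7 definition; windows with fewer than `minSnps` SNPs are NaN and
excluded from quantiles and medians; `site_pi` needs two non-missing
alleles; Fst sites need at least one genotyped diploid per population
and three overall; EM convergence is an absolute log-likelihood gain
threshold; NJ ties and greedy-core ties are broken by fixed index or
lexicographic rules so every result is reproducible bit for bit under
a fixed seed.

# Known limitations

Only two-population Fst per call (the three pairwise comparisons are
three calls); no haplotype-based sweep statistics (iHS, XP-EHH); no
indel or splice-site consequences; no phasing; LD summaries are means,
not significance tests; the admixture model is the standard
unsupervised one, with no spatial or graph extensions. The real
study's headline dataset-scale numbers (tens of millions of SNPs, the
specific shared-gene count, the named 26 accessions) depend on the
deposited resequencing data and are outside what a synthetic desk-scale
panel can or should reproduce.
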