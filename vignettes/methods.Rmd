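---
title: "Methods: sweep scanning, CNE discovery and substitution scanning in domestiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep scanning, CNE discovery and substitution scanning in domestiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the rules and thresholds,
and the design decisions behind `domestiscan`. It is the reference for what
each stage assumes and why its defaults are what they are.

# Windowed population-genetic statistics

## Nucleotide diversity

Per site, with $j$ alternate alleles among $n$ non-missing alleles,
$\pi = 2j(n-j)/(n(n-1))$ — the unbiased mean number of pairwise differences
per site. Window $\pi$ sums site values and divides by the *window length in
base pairs*: positions without a variant record are treated as invariant.
This is the convention of windowed-diversity tools operating on SNP-only
VCFs; it assumes the VCF's invariant positions were callable, and window
$\pi$ is therefore an underestimate wherever callability is poor. Windows
are tiled from each scaffold origin (default 50 kb size, 10 kb step,
0-based half-open); terminal short windows are kept and normalised by their
actual span.

## Weir–Cockerham F~ST~

`windowed_wc_fst()` computes the 1984 variance components per site for two
populations — $a$ (among populations), $b$ (among individuals within
populations), $c$ (within individuals) — from sample sizes, allele
frequencies and observed heterozygote frequencies, and windows them as the
ratio of sums $\sum a / \sum(a+b+c)$. Missing genotypes are excluded per
site; sites with fewer than two genotyped individuals in either population
are skipped. Estimates are stored *unclamped*: negative window values are
legitimate draws from the estimator's null distribution, and clamping them
at zero would distort the empirical Z thresholds computed downstream. A
window whose component sum is zero (e.g. all sites monomorphic) is `NaN`.

## Per-sample statistics

Heterozygosity is the fraction of a sample's non-missing genotypes that are
heterozygous. The inbreeding coefficient is the method-of-moments
$F = (O_{hom} - E_{hom})/(M - E_{hom})$, with
$E_{hom} = \sum_s [1 - 2 p_s q_s n_s/(n_s-1)]$ over the sites genotyped in
the sample and cohort frequencies $p_s$ taken over *all* samples; it is
`NaN` when every usable site is fixed. Runs of homozygosity use the
PLINK-style scan: 50-SNP windows passing with at most 1 heterozygote and 5
missing calls, a site eligible when at least 5% of its covering windows
pass, and runs reported at ≥ 100 SNPs, ≥ 1,000 kb span, ≥ 1 SNP per 50 kb,
and no internal gap above 1,000 kb. These run-level defaults are the
documented defaults of the standard tool; none are stated by any single
analysis convention, so all are exposed as arguments. LD decay uses the
squared Pearson correlation of dosage vectors (composite LD — phase is not
required), binned by distance up to 501 kb; the half-decay distance is the
midpoint of the first bin at or below half the maximum bin mean.

## Variant filtering and unit conversion

`filter_variants()` applies the GATK-style hard filters
(QD < 2.0, FS > 60.0, MQ < 40.0, MQRankSum < −12.5,
ReadPosRankSum < −8.0; a missing INFO key passes) and removes sites
genotyped in fewer than 90% of samples. `convert_mutation_rate()` divides a
per-generation rate by the generation time in years — the conversion needed
to put coalescent-scaled inferences on a calendar axis (e.g.
$8.42\times10^{-9}$ per generation over 4-year generations is
$2.105\times10^{-9}$ per site per year).

# Sweep-region calling

The sweep statistic pair is the windowed F~ST~ and the log diversity ratio.
`ln_diversity_ratio()` defaults to $\ln(\pi_{ref}/\pi_{target})$, i.e.
*positive when the putatively selected (target/domestic) population has
lost diversity*, so that positive thresholds select sweep candidates.
Published notation for this ratio is inconsistent — the same analyses are
described both as domestic/wild and with positive cutoffs selecting
diversity loss in the domestic group, which cannot both hold — so the
orientation is an explicit flag (`orientation = "target_over_ref"` flips
the sign) rather than a silent assumption. Windows where either $\pi$ falls
below `min_pi` or either population has fewer than 3 variant sites are
dropped and recorded in a `dropped` attribute, since a log ratio of two
near-zero estimates is noise.

Thresholds are empirical one-tailed Z cuts, mean $+ z_{1-\alpha}\,$sd of the
comparison's own window distribution ($z_{0.95} = 1.6449$); they can also be
supplied directly (e.g. values carried over from a prior study). The cut is
exact only if the window distribution is normal; on realistic (skewed)
F~ST~ distributions the marginal tail can exceed $\alpha$ slightly, while
the *joint* rule — both statistics above threshold — stays below $\alpha$
because the two statistics are imperfectly correlated. The acceptance tests
assert exactly that: marginals near $\alpha$ within binomial noise, joint
at or below $\alpha$.

Selected windows merge into maximal regions (overlapping or book-ended;
`max_gap` widens this). Region sets from several comparisons intersect to
maximal intervals covered by at least one region of *every* set. The
significance of the shared overlap is a Monte Carlo null: each iteration
independently re-places every region of every set, choosing a scaffold with
probability proportional to its number of valid start positions and the
start uniformly; lengths and counts are preserved, inter-region spacing is
not, and within-set overlap after placement is allowed — the simple,
standard null. The p-value is the add-one estimator
$p = (1 + \#\{T_{null} \ge T_{obs}\})/(1 + N)$, never zero. On the analytic
toy (three length-1 regions on a length-10 scaffold, observed triple
overlap 1) the null probability is $10 \cdot (1/10)^3 = 0.01$, which the
test requires within three Monte Carlo standard errors at $N = 10{,}000$.

# Conserved noncoding elements

"Conservation" is operationalised as *column-majority agreement*: per
column, the fraction of the chosen species whose residue equals the most
frequent non-gap residue of that column (lexicographic tie-break for
determinism); gaps and species absent from the block count as mismatches;
the element score is the mean over columns. The source analyses never
define their similarity measure (pairwise identity and consensus agreement
are both plausible readings); majority agreement was chosen because it is
symmetric in species, insensitive to a single outlier row, and cheap to
audit column by column. It is exposed in the configuration.

The pipeline is: excise alignment columns whose focal coordinate lies in an
annotated exon and split segments at the excisions (segments shorter than
`min_len = 50` columns are discarded — no published minimum exists; the
motivating example element is ~140 bp, and 50 bp is the shortest element
for which an 80% score is meaningfully different from noise); candidate
CNEs are segments with non-focal conservation strictly above 0.8; then:

- **lost**: the focal row is absent from every covering block *or* gap in
  more than 80% of columns. "Lost" alone does not decide partially aligned
  edge cases, so absence and heavy gapping are both accepted and the
  gap-fraction cutoff is configurable.
- **divergent**: a run of at least 10 *contiguous* focal-variant columns —
  a column where at least 80% of the non-focal species share a majority
  residue and the focal residue is present but differs — inside an element
  whose conservation over *all* species (focal row included) still exceeds
  0.8. The all-species reading of the 80% rule is the literal one; since
  the divergent focal row itself drags this score down, it is the more
  conservative choice, and the 15-way alternative is available by passing
  the non-focal subset to `conservation_score()`.

Nearest-gene assignment minimises the distance from the element midpoint to
the gene span (0 inside the span), signed relative to the annotated strand
(negative = upstream of the gene start); equidistant genes are all
reported. Enrichment is an upper-tail hypergeometric test per annotation
term with Benjamini–Hochberg adjustment across terms — annotation-agnostic:
the gene-to-term map is the caller's, and no ontology structure is
propagated.

# Ortholog substitution scan

One-to-one orthologs are reciprocal best hits under Smith–Waterman local
alignment with BLOSUM62, gap open 11 / extend 1 (the classical protein
search parameterisation); score ties in either direction drop the pair, so
paralogous ambiguity never silently resolves. Groups form when a focal gene
has partners in at least `min_species` non-focal proteomes. Instead of a
full progressive MSA, each partner is globally aligned to the focal protein
and projected onto focal columns (partner insertions are discarded): the
stacked alignment is deterministic, linear in partners, and exactly
sufficient for per-column identity tests — residues aligned to the same
focal position are compared, nothing else.

A column is called a focal-specific substitution iff (i) every non-focal
row carries one identical residue — a gap or a single dissenting species
disqualifies (strict reading; a tolerance knob exists but defaults to
strict), (ii) the focal residue differs, and (iii) flank similarity over
the 10 columns on each side exceeds 0.6. Flank similarity is the mean
column-majority agreement over all rows; it is computed as one joint
20-column window (`flank_mode = "split"` requires each side separately —
the published wording supports either reading, and joint is the weaker,
hence default, interpretation). Columns within 10 residues of a protein
terminus are never called: their flank is undefined rather than truncated.

# Synthetic data: what it emulates and what it does not

The generators produce the study conditions every test runs under.

**Genotypes** follow the Balding–Nichols model: ancestral frequency
$p \sim U(0.05, 0.95)$ per SNP, population frequencies
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with $F$ the target F~ST~
(variance $F\,p(1-p)$, matching the Weir–Cockerham expectation; $F = 0$
short-circuits to identical frequencies), genotypes binomial. Defaults —
two populations of 20 diploids, 20,000 SNPs over four 5-Mb scaffolds,
target F~ST~ 0.10 — mirror a two-population resequencing panel at the
published wild/domestic differentiation scale (0.06–0.15). Sweep planting
moves the target population's frequency toward the nearest boundary by
solving $2p'(1-p') = c \cdot 2p(1-p)$ in closed form, so expected window
heterozygosity is multiplied *exactly* by the configured
`diversity_reduction`; a rejection-sampling scheme conditioning Beta draws
toward the boundary would only approximate the same target, so the closed
form was preferred as deterministic and auditable. Pushing frequencies
toward fixation also elevates differentiation in the window, as a real
sweep does. Not emulated: linkage (sites are independent, so LD decay on
simulated data is flat), recombination maps, demography, genotyping error.
Passing tests therefore show estimator correctness and calibration under
the model, not robustness to demographic confounding.

**Alignments** evolve site-independently down a balanced 16-taxon tree
(abstract labels `sp01..sp16`, focal `sp01`, equal branch lengths 0.08)
under a uniform-exchange single-substitution process — adequate because
every downstream rule uses identity only. Site evolution is implemented
directly (a per-site Jukes–Cantor-style sampler over the `ape` tree)
because elements need per-column rate classes and planted focal-branch
events inside single blocks. CNEs evolve at `conserved_rate_scale`
(default 0.02; 0 gives the noiseless limit used for exact-recovery tests),
background loci at rate 1. Losses delete the focal row over a whole
element; the emitted MAF keeps a focal anchor line of size 0 at the
deletion point so lost elements retain focal coordinates for nearest-gene
assignment (this package's own MAF reader and writer are the producer and
consumer of that convention). Divergences substitute `burst_length ≥ 10`
contiguous focal sites. Indels other than whole-element loss, rearrangement
and alignment error are not emulated.

**Proteomes** are random amino-acid sequences (120–240 residues) copied
across species with per-site substitution probability
`background_divergence` (default 0); planted sites put one residue in all
15 non-focal species and a different one in the focal species, at least 11
residues from each terminus. The simulator guarantees the planted column
stays clean under background divergence; flanks keep background
conservation.

# Numerical choices and degenerate inputs

- All coordinates are 0-based half-open internally; VCF/GFF 1-based
  conventions are converted at the boundary; BED output is native.
- Interval merge/intersection and the Monte Carlo loop use a dedicated
  base-R two-pointer sweep: the null test re-intersects three region sets
  10,000 times, and per-iteration container construction dominates runtime
  in any heavier representation.
- Oracle-equivalence tests hold to 1e-12 (brute-force enumeration of
  pairwise differences and scalar variance components on ≤ 50-site
  instances); stochastic recovery tests use fixed seeds with tolerances
  stated per test (e.g. mean windowed F~ST~ within ±0.02 of target over
  five seeds).
- Degenerate cases are explicit: zero-variance inputs to the Z threshold
  and empty backgrounds error; FST with an empty denominator, inbreeding F
  with $M = E_{hom}$, and monomorphic LD pairs are `NaN`/`NA`, never
  silently zero.
- All simulators and the Monte Carlo test save and restore the global RNG
  state, so a fixed seed gives byte-identical outputs regardless of
  surrounding code.

# Problem sizes

Test and acceptance runs use desk-scale sizes chosen to make every
stochastic assertion stable: genotype simulations of 20+20 samples and
20,000 SNPs (five seeds for recovery), alignments of 30 CNEs with 5 planted
losses and 5 divergences, proteomes of 8–16 genes across 16 species, and
10,000 Monte Carlo iterations for the overlap toy. The full synthetic
pipeline fixture (10+10 samples, 4,000 SNPs, 20 CNEs, 12 genes) runs in
well under a minute per invocation.

# Limitations

- The sweep caller is threshold-based; composite-likelihood sweep
  detection and haplotype statistics are out of scope.
- The stacked ortholog alignment cannot represent residues absent from the
  focal protein; substitutions in partner-specific insertions are invisible
  by construction.
- Enrichment treats terms independently (no ontology DAG propagation).
- Simulated data validate correctness and calibration, not robustness to
  demographic structure, alignment error or annotation noise.
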