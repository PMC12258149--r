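---
title: "Models and methods behind zwscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zwscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`zwscan` analyzes young female-heterogametic (ZW) sex-chromosome systems:
females carry one Z and one W, males two Z copies, and the W-linked region
stopped recombining so recently that most genes still have a W copy. This
vignette explains the models each stage assumes, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## 1. Sex-linked variant ascertainment

At a fully sex-linked site, every female is Z/W heterozygous and every male
Z/Z homozygous. The scan (`find_sex_linked_variants`) therefore calls a
variant ZW-like when at least `min_het` females are heterozygous and males
are homozygous, and XY-like under the mirrored criterion. Two homozygosity
policies are exposed because both arise in practice: `"all"` demands that
every individual of the homozygous sex be *observed* homozygous (a missing
genotype disqualifies the site — the strict reading we adopt for
degeneration-grade ascertainment), while `"min_count"` demands at least
`min_het` observed homozygotes and no observed heterozygote, tolerating
missingness during discovery. With 24 individuals per sex a threshold of 18
allows for genotyping dropout; with 12 per sex, 9. The heterogamety call is
the majority class when it reaches 80% of qualifying variants — systems are
called from overwhelming majorities, not narrow ones.

Under random sex labels the qualifying probability per truly sex-linked site
is about `1/choose(n, n/2)`, so a label permutation collapses the signal to
(essentially) zero calls; this is tested as a property.

## 2. Windowed differentiation and dose

Between-sex F<sub>ST</sub> uses the Weir–Cockerham (1984) variance
components for two populations, computed per variant without sample-size
pruning, and combined per window as the weighted ratio Σa/Σ(a+b+c). Windows
tile each chromosome as half-open `[start, start + window)` intervals
(default 50 kb; coordinates are otherwise 1-based inclusive throughout, the
VCF/GFF convention). Windows without variants are reported missing rather
than zero. A fixed difference between the sexes gives an estimate of 1; at a
W-specific site with all females heterozygous the estimate is 0.5, which is
why sex-linked regions show a high but not saturated F<sub>ST</sub> plateau.

Female:male contrasts (`fm_log2_windows`) are `log2(mean_F) − log2(mean_M)`
of any per-sample window quantity. Windows where either sex has mean zero
are reported missing, never ±∞. Halved female coverage over a W deletion
reads as −1 within Poisson counting error; elevated female SNP density over
the sex-linked region reads as a positive shift.

Linkage disequilibrium (`ld_profile`) follows the usual population-genomic
recipe: a minor-allele-frequency filter (default 0.15), complete cases only
by default, thinning to one variant per 10 kb (first by position), squared
Pearson correlation of diploid dosages, and — because a single outlier pair
is uninformative — the *second-largest* r² per 100-kb window pair.
Monomorphic vectors after filtering make a pair undefined and it is skipped.
For n unrelated diploid samples the null expectation of r² is ≈ 1/n, which
the tests verify.

## 3. k-mer sex markers

The k-mer scan is reference-free: k-mers (default k = 31, odd so that no
k-mer equals its own reverse complement) are canonicalized as the
lexicographic minimum of the k-mer and its reverse complement, presence
means at least one occurrence in an individual's reads, and markers must be
present in at least `min_target_presence` individuals of the target sex
(default 11 of 12, tolerating one dropout) and at most `max_other_presence`
(default 0) of the other. The store is an exact hash set — at desk scale
there is no need for approximate counting structures. The output is
invariant to read order and to reverse-complementing any read, and marker
k-mers fall only within the sex-specific insertion (plus a k−1 junction
flank) in the planted-truth validation.

## 4. Evolutionary strata

### Changepoint boundary

Stratum boundaries are detected on female SNP density per 50-kb window with
a single changepoint under a Gaussian cost in which both mean and variance
may shift: `C(seg) = n·log(σ̂²_MLE)`. `force_one` mode returns the
exhaustive argmin over split points (ties broken toward the smaller
position, with at least two windows per segment so the variance is defined);
`penalized` mode accepts the split only when the cost improvement exceeds a
penalty, default `3·log(n)` for the three extra parameters. The exhaustive
scan doubles as its own oracle; the tests reimplement it independently and
check equality on series up to 200 windows, plus localization within ±2
windows on noisy planted steps.

### Gametolog divergence

Ka/Ks uses Nei–Gojobori (1986) counting: fractional synonymous sites per
codon (changes to stop codons count as nonsynonymous), averaged over the two
sequences; codons differing at several positions are averaged over all
shortest substitution pathways with equal weights, skipping pathways through
stop codons. Proportions are corrected for multiple hits with Jukes–Cantor,
`d = −(3/4)·ln(1 − 4p/3)`; `p ≥ 3/4` is flagged saturated. Jukes–Cantor is
the classical companion of NG86 and matches the generator's uniform
substitution model, making the estimator/generator pair internally
consistent (the estimator recovers generator settings across
dS ∈ {0.01, 0.035, 0.08} within 5% relative bias plus Monte-Carlo error).
Pairs whose Z and W sequences differ in length (deletions, frameshifts)
would need a frameshift-aware aligner to codon-compare; they are flagged
`defective`, excluded from Ks averaging by default, and handled by the
degeneration module instead.

Ortholog pairing between the Z and W protein sets uses reciprocal best hits
under exact global alignment (BLOSUM62, affine gaps): each must be the
other's *unique* best hit (a score tie is ambiguous and drops the pair),
with query coverage ≥ 0.6 both ways and many-to-one relationships removed.
Desk-scale sets make exact alignment feasible and deterministic, so no
seeded heuristic search is needed.

Strata are compared by two-sided Mann–Whitney U tests with midrank ties
(exact p for small untied samples, tie-corrected normal approximation
otherwise, via `stats::wilcox.test`). The PAR mean Ks is reported but
labeled diversity-dominated: where recombination persists, a single
haplotype comparison measures the population's nucleotide diversity, not
divergence.

### Dating and degeneration rates

With the assumption that Z and W diverge at the same rate as the two
species, `rate = Ks_interspecies / t_split` (the pairwise-divergence-
per-year convention, no factor of two) and `age = Ks_stratum / rate`.
Degeneration rates follow as `%LoF / age_My` and, multiplied by the
generation time in years, percent per million generations. The arithmetic
is scale-invariant: doubling all Ks values leaves age ratios unchanged.

## 5. W-allele degeneration

Each Z coding sequence is aligned to its W gene region exon by exon with a
semi-global alignment (exon global, region local). Scoring is match +2,
mismatch −3, gap open 10, gap extension 0.2. These values were chosen so
that absent sequence cannot masquerade as present: with cheap gap *opens*
the aligner cherry-picks scattered matches out of unrelated sequence (80%
"identity" on pure noise), while with expensive gaps it threads mismatches;
expensive opens with near-free extensions make genuine deletions collapse
into single long gaps and leave spurious alignments short and low-identity.
An exon counts as lost when under 20% of it aligns, the aligned part falls
below 60% identity, or fewer than half of its bases match (the last gate
protects short exons from chance alignments).

Classification is mutually exclusive with the precedence: (1)
`sequence_loss` when overall query coverage < 0.5 or identity < 0.6; (2)
`exon_loss` when at least `min_lost_exons` (default 1 — "more than one exon"
is ambiguous in common usage, and one complete lost exon already destroys
the product) complete exons are lost; (3) `orf_disrupt` on a lost start
codon, an in-frame premature stop at least one codon before the annotated
stop, or a net indel not divisible by 3; (4) `splice_disrupt` when any
checkable intron terminus deviates from GT…AG (non-canonical input introns
are flagged, not classified); else `intact`. On error-free synthetic data
the classifier recovers planted classes with a clean diagonal and never
calls an intact gene nonfunctional.

## 6. Dosage compensation

TPM is `count/length_kb`, rescaled so each sample sums to 10⁶. Ratios are
built per sex-linked gene: `wz_female` is the mean over female samples of
W/Z counts (samples with zero Z counts for a gene are excluded from that
gene's mean), and `zf_zzm` is mean female Z-allele TPM (allele fraction ×
gene TPM) over mean male total TPM. Genes with mean male TPM below 1 are
excluded — an expression floor the source analyses leave implicit. The W:Z
categories are [0], (0, 0.256), [0.256, 0.667), [0.667, ∞); the 0.256
boundary is treated as a fixed configuration default. Without dosage
compensation `zf_zzm` concentrates near 0.5; female-specific upregulation
moves genes toward 1.

Crucially, TPM is computed over *all* quantified genes: if only sex-linked
genes entered the table, within-sample renormalization would cancel the
global halving of female sex-linked output and every ratio would collapse
to 1. The generator therefore emits autosomal reference genes
(`n_ref = 2000` by default) that anchor the library the way the rest of the
transcriptome does in real data, and `build_ratios` reports ratios only for
the sex-linked set.

Unimodality of `zf_zzm` per category is tested with Hartigan's dip — the
sup-distance between the ECDF and the closest unimodal distribution,
computed by the iterative greatest-convex-minorant / least-concave-majorant
modal-interval algorithm. The implementation reproduces the exact known
values (0.25 for an equal two-point mass, the minimum 1/(2n) on a uniform
grid) and is affine-invariant. The p-value is Monte-Carlo: the fraction of
uniform(0,1) samples of the same size with a dip at least as large (the
classical, slightly conservative calibration null). Mixture structure in
the low-W categories is decomposed with a univariate Gaussian mixture fit
by EM (convergence |Δ logL| < 10⁻⁸, at most 500 iterations, variance floor
10⁻⁶, best of 10 random starts) with k ∈ {1, 2} chosen by
BIC = −2 logL + (3k−1) log n.

A calibration caveat worth stating plainly: with the generator's default
expression noise (negative binomial, dispersion `size = 10`, two replicates
per sex) the per-gene ratio standard deviation is ≈ 0.3, and *no*
unimodality test can separate components at 0.5 and 1.0 under that noise at
a few hundred genes — we measured essentially zero dip power even at eight
replicates. Published ratio distributions that visibly resolve a second
peak near 1 imply per-gene measurement noise of roughly 0.1 or better. The
dip-power and mixture-recovery validations therefore operate on planted
ratio-level mixtures (components 0.5 and 1.0 with sd 0.08–0.1), which is
the regime the method is meant for; detecting compensation from the
desk-scale generator's raw two-replicate output is not attainable and
passing tests should not be read as claiming otherwise.

## 7. Gene-tree topologies

Rooted on the designated outgroup and pruned to the four decisive taxa (Z,
W, the sister species, the outgroup — extra outgroup taxa are pruned first
since the decision depends only on these), a tree is `ZW_sister` when the
smallest clade containing Z and W excludes the sister species, `W_loss`
when the sister species forms a clade with Z alone, `Z_loss` with W alone,
and `unclassifiable` for polytomies that break the rule (never resolved
arbitrarily). All fifteen rooted four-taxon topologies are checked against
an independent four-point-condition oracle. No branch-support filter is
applied by default; `min_support` is available. Percentages are reported
rounded to the nearest integer, matching how such splits are conventionally
quoted.

## 8. The synthetic generator

`simulate_dataset` draws everything from one global RNG seeded by
`SimConfig$seed`, in a fixed documented order (genome, gene placement, W
evolution, loss-of-function planting, cohort genotypes, coverage, reads,
expression, gene trees), so identical seed and configuration give
byte-identical outputs.

Defaults define the study conditions at desk scale: a 2-Mb chromosome with
PAR up to 0.6 Mb, Stratum 2 to 1.4 Mb and Stratum 1 beyond; per-region
synonymous divergence 0.016 / 0.020 / 0.035 with Ka/Ks 0.31 / 0.45 / 0.51
(the ratios implied by the per-region Ka and Ks means); 20 genes per region
of 900–1800 bp CDS in 2–6 exons; loss-of-function probabilities 0 / 0.271 /
0.544 with class weights 0.241 / 0.090 / 0.455 / 0.214 (sequence loss, exon
loss, ORF disruption, splice — the observed evidence mix); 12 females and
12 males at ~10× depth with 2% missingness and 0.2% genotype error; PAR
heterozygosity 0.005; 150-bp reads; expression baseline 100 with negative-
binomial dispersion 10 and two replicates per sex; 10% of silenced genes
compensated; and planted gene-tree counts (164, 20, 6). A 1-Mb autosome
serves as the null control.

Sequence evolution is Jukes–Cantor-like: substitution events are placed
uniformly over single-nucleotide changes of the requested (synonymous or
nonsynonymous) type, with counts drawn Poisson at `dS·S` and `ω·dS·N` on the
ancestor's NG86 site counts, avoiding premature stops; multiple hits can
occur and are what the downstream correction accounts for. Several
exclusions keep planted truth unambiguous: the start codon and terminal
stop never mutate, splice dinucleotides are excluded from neutral
intergenic divergence, exon-loss events remove an exon covering at most
half the CDS (a larger loss *is* sequence loss under the classification's
own precedence), and frameshift indels stay 5 bp clear of exon junctions.
In the genotype matrix, W-specific sites are restricted to the
non-recombining region — PAR gametolog differences reflect diversity, so
PAR variation is emitted as Hardy–Weinberg polymorphism instead — and
Z-linked SLR polymorphism is added at a quarter of the PAR diversity with
alternate-allele frequencies capped at 0.5, because a Z allele near
fixation over a reference-state W is statistically indistinguishable from a
W-specific site.

What the generator does **not** emulate: read-level sequencing errors and
quality strings, recombination within the PAR, demography and linkage
structure beyond complete sex linkage, inversion breakpoints at nucleotide
resolution, tissue effects in expression, and mapping artifacts. Passing
tests on this generator demonstrate that the estimators recover planted
truth under their own model assumptions — not that those assumptions hold
in any particular real dataset.

## 9. Problem sizes and reproducibility

The test suite and the acceptance script run at deliberately modest sizes:
simulated chromosomes of 0.15–2 Mb, 6–60 genes, 300 gametolog pairs of
1,500 bp for estimator recovery, 200 replicates for changepoint
localization, 1,500-sample Monte-Carlo null tables for the dip, and
hundreds (not thousands) of mixture replicates — sizes chosen so a complete
validation runs on a single CPU in minutes while keeping Monte-Carlo error
comfortably inside every asserted tolerance. All randomness flows from
explicit seeds; `scripts/acceptance.R --seed N` reproduces its JSON output
exactly for a given seed.

## 10. Known limitations

- The degeneration aligner assumes the W gene region is given (from truth
  spans or user intervals); it does not search a whole W assembly for
  translocated copies.
- NG86+JC saturates near p = 3/4 and the JC model ignores
  transition/transversion bias; both are acceptable at the few-percent
  divergences this package targets but not for deep comparisons.
- The dip test's uniform null is conservative; its Monte-Carlo p-values
  inherit resolution 1/(n_boot + 1).
- Variant-effect annotation is reduced to the planted-class rule set;
  there is no full transcript-effect ontology.
- The CLI is a thin convenience layer; programmatic use of the exported
  functions is the primary interface.
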