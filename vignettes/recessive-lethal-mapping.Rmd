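---
title: "Mapping recessive lethal haplotypes from routine herd data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive lethal haplotypes from routine herd data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethalscan)
library(dplyr)
```

## The problem

Intensively bred livestock populations carry recessive defects that are
almost invisible in routine records. A fully penetrant recessive lethal that
kills homozygotes around birth leaves three correlated traces in the data a
breeding company already collects:

1. **A deficit of homozygotes.** Homozygous animals never reach genotyping
   age, so among tens of thousands of SNP-array genotypes *no* animal is
   homozygous for the haplotype carrying the defect, although
   Hardy-Weinberg predicts dozens.
2. **Depressed litter survival in carrier-by-carrier matings.** When both
   parents carry one copy, a quarter of the offspring is homozygous; litter
   size at birth looks normal but pre-weaning (lactation) survival drops by
   roughly a quarter.
3. **A causal variant riding on the haplotype.** Among whole-genome
   sequenced animals, the causal variant is in complete linkage
   disequilibrium with the flagged haplotype.

`lethalscan` implements this chain of evidence end to end — scan, litter
contrast, variant prioritization, frameshift consequence prediction,
Mendelian validation, and a carrier association model — plus a gene-drop
simulator so every stage can be exercised and tested with no external data.

## The deficit-of-homozygotes scan

For a haplotype with frequency $f$ among $2N$ phased chromosomes, random
mating predicts $N f^2$ homozygous animals. The scan slides windows of
`window_markers` consecutive markers (default 20, configurable; the
defect-bearing region in the motivating data spanned 19 markers) along each
chromosome, counts every window haplotype, and for each haplotype with
expected homozygote count of at least `min_expected_hom` computes the
lower-tail exact binomial probability

$$P(X \le x_\mathrm{obs}), \qquad X \sim \mathrm{Binomial}(N, f^2),$$

accumulated in log space so that probabilities of order $10^{-30}$ — the
regime a true lethal inhabits at $N \approx 30{,}000$ — remain accurate.
A haplotype is flagged at $P < 5\times10^{-3}$; overlapping significant
windows whose haplotypes agree on shared markers are merged into regions.

Numerical and design choices:

* `min_expected_hom = 10` by default: testing haplotypes with fewer
  expected homozygotes has essentially no power and inflates the test
  count. The small simulated panels in the examples lower it explicitly.
* No multiple-testing correction enters the significance call (the method
  uses a fixed threshold); a Bonferroni-adjusted column is reported
  alongside for transparency.
* $N$ is the number of animals with both window haplotypes scored, which
  equals the panel size for post-imputation input.
* Ties in region merging: windows merge only when they overlap by at least
  one marker *and* their focal haplotypes are identical on the shared
  markers.

**Known limitation — family structure.** The binomial null assumes
independent diplotypes. In a pedigreed population littermates share
parental haplotypes, which inflates the variance of homozygote counts and
makes the test mildly anticonservative: in a two-generation null
simulation we observed slightly more sub-threshold haplotypes than the
nominal rate. The property-style null test in the suite therefore draws
independent Hardy-Weinberg diplotypes (a founders-only panel), and the
fixed $5\times10^{-3}$ threshold should be read as a pragmatic screen, not
a calibrated error rate.

## Genotype quality control

`apply_qc()` applies the conventional pre-scan filters in a fixed order so
its report is deterministic: animals with more than 15% missing genotypes;
then markers with unknown map position, call rate below 0.85, minor allele
frequency not above 0.01 (a MAF of exactly 0.01 is removed), and a
Hardy-Weinberg exact-test p-value below $10^{-12}$. The HWE test is the
two-sided conditional exact test with probability-mass ordering, the
definition standard genotype-QC tools use; mid-p is not applied. Each
marker is tallied once, in the first filter that removes it.

## Litter contrasts

Litters are classified by parental carrier status with the sire's letter
first (`CxN` = carrier sire, non-carrier dam); the motivating analysis
never states its convention, so ours is documented here and a
`pool_reciprocal` flag pools `CxN` with `NxC` when the distinction is not
wanted. Aggregate survival percentages are pooled ratios of sums (total
weaned over total live born), which is robust to litter-size variation;
the Welch unequal-variance t-test, by contrast, operates on per-litter
values because it needs replicates. The default contrast is `CxC` against
`CxN` only, the literal reading of the source analysis.

With full penetrance and all homozygote deaths falling after birth, the
expected CxC lactation survival is

$$\frac{0.75\, s_F\, s_L}{0.75\, s_F + 0.25}$$

with baseline farrowing survival $s_F = 0.914$ and lactation survival
$s_L = 0.900$: about 65.9%, a relative drop of ~27% against the ~24%
observed in the motivating data — a quarter of live-born piglets plus the
usual baseline losses.

## Variant prioritization and frameshift consequences

`haplotype_ld()` computes $r^2$ as the squared Pearson correlation between
variant genotype dosage and haplotype dosage over the sequenced animals —
the pseudo-marker construction used with standard LD tools, well defined
for unphased sequence genotypes. Zero-variance dosages yield `NA`
(undefined, not zero). `prioritize_variants()` keeps variants with
$r^2 > 0.8$ and ranks high-impact consequences (frameshift, stop gained,
splice acceptor/donor) above missense predicted deleterious, above
missense predicted tolerated, above everything else; the tolerated cutoff
defaults to the conventional 0.05 of the usual deleteriousness predictor
(the motivating analysis reports observed scores but not its cutoff).
Variants at $r^2 = 1$ within $10^{-9}$ are flagged as perfect LD.

`apply_deletion_and_translate()` maps a genomic deletion into CDS
coordinates (strand-aware, via the exon model), rejects deletions spanning
splice sites (the motivating deletion is intra-exonic; multi-exon
deletions are out of scope), and translates the shifted frame through the
trailing transcript sequence until the first stop codon, reporting the
retained wild-type prefix, the novel residues, and the lost wild-type
tail. HGVS-style `del` identifiers are parsed and the deleted bases
validated against the CDS. The suite exercises this on compact synthetic
transcripts; the full-length transcript of the motivating gene is not
bundled, so the worked checks are desk-scale by design.

## Segregation and penetrance validation

Fully genotyped carrier-by-carrier litters are tested against 1:2:1 at
birth, or 1:2 (wild type : carrier) among survivors when homozygotes die
before genotyping — complete pre-genotyping lethality is assumed for the
survivor expectation, matching the finding the pipeline is built around;
partial-lethality expectations are deliberately not implemented. Genotype
counts are sufficient, so pooling litters and summing counts give the same
test. Alongside the chi-squared statistic an exact multinomial p-value
(probability-mass ordering, the same convention as the HWE test) is
enumerated for totals up to 100. Penetrance is the fraction of homozygotes
dying within a 48-hour window, with the matching background rate among
non-homozygous littermates.

## The carrier association model

For each trait, deregressed breeding values (DEBVs) are regressed on
carrier dosage under the weighted animal model

$$y_j = \mu + \beta\, d_j + a_j + e_j, \qquad
  a \sim N(0, A\sigma^2_a), \qquad e_j \sim N(0, \sigma^2_e / w_j),$$

where $d_j$ counts copies of the detrimental allele, $A$ is the pedigree
numerator relationship matrix and $w_j$ the deregression weight. Records
are filtered to weight $> 0$ and DEBV reliability $> 0.20$ on load.
Choices:

* The variance ratio $\sigma^2_a/\sigma^2_e$ is supplied per trait from
  heritability ($h^2/(1-h^2)$), mirroring evaluations that take variance
  components from the routine genetic evaluation; REML estimation is out
  of scope.
* The mixed-model equations are solved sparsely with $A^{-1}$ built
  directly by Henderson's rules, with inbreeding handled through
  Mendelian-sampling variances $d_i = 0.5 - 0.25(F_s + F_d)$; inbreeding
  coefficients come from a tabular relationship matrix restricted to the
  ancestor subset, keeping memory linear in the number of parents.
* Only the variance *ratio* is assumed known; the residual scale is
  estimated from the generalized residual sum of squares
  $(\hat e' W \hat e + \hat a' A^{-1} \hat a / \lambda^{-1}) / (n - p)$,
  and the carrier effect is tested with a Wald z-test against a standard
  normal — the conventional large-sample choice at $n \approx 15{,}000$.
  Significance is declared at $-\log_{10}(p) > 5$.
* The solution is identical to generalized least squares with direct
  inversion of the full covariance; the suite verifies this to $10^{-8}$
  on 200-animal instances, including the standard errors.

## The gene-drop simulator

`simulate_population()` emulates the statistical structure every
downstream stage assumes: a pedigreed boar-line-like population with one
recessive lethal on a tagged marker haplotype.

* **Founders** (default 1,000, half each sex) draw marker alleles with
  frequencies uniform on (0.05, 0.95). Lethal copies are assigned to
  founder haplotypes at frequency 0.045; founders are live breeding
  animals, so no founder is homozygous (surplus copies move to non-carrier
  animals, preserving the allele count). Carrier haplotypes share one
  marker haplotype over 19 markers centred on the (hidden) lethal locus,
  so the lethal starts in complete LD with a taggable window.
* **Transmission** follows Haldane recombination: Poisson crossover count
  at `chromosome_length_cM`/100 expected crossovers, uniform positions;
  1 cM corresponds to 1 Mb. The lethal locus recombines as a pseudo-marker
  and is removed from the exported panel.
* **Demography**: discrete generations, random mating with one sire per
  ten dams, litter sizes Poisson around 10.08, at most 850 litters per
  generation (keeping the population near-stationary). Four generations
  yield roughly 25,000 genotyped animals — the scale of the motivating
  dataset and the size used by the heavy acceptance checks and the
  acceptance script; unit tests use far smaller configurations of the same
  generator.
* **Fates**: lethal homozygotes are stillborn with probability 1/3,
  otherwise die within 48 h (mostly inside 24 h); the two probabilities
  sum to one under full penetrance. All other piglets are stillborn at
  1 − 0.9137 and die pre-weaning at 1 − 0.8997 — the baseline rates of the
  non-carrier mating class in the motivating litter table. Only weaned
  animals (and founders) enter the genotyped panel. The recorded litter
  table in that source shows *no* farrowing-survival depression in CxC
  litters, i.e. homozygote deaths effectively all land in the lactation
  window; analyses that emulate that table (the litter-contrast acceptance
  checks and the acceptance script) therefore set
  `p_stillborn_given_homozygote = 0`, while the config default keeps the
  1/3 observed in the single directly monitored litter. The choice only
  shuffles homozygote deaths between the farrowing and lactation columns.
* **Sequenced subset**: 71 animals including 5 carriers; around the lethal
  locus a 16-bp-deletion-like causal variant sits at $r^2 = 1$ (its
  identifier round-trips through the HGVS `del` parser) with flanking
  variants whose extra non-carrier copies grow with distance, giving a
  graded LD decay; a handful carries missense/splice annotations with
  tolerated-range scores, mimicking an annotation sidecar.
* **Trait records**: DEBV-like response = carrier effect (−0.39 per copy)
  × dosage + pedigree-correlated polygenic value (heritability 0.2 on a
  unit-variance scale) + residual with variance $\sigma^2_e / w$ for a
  drawn weight $w \in (0.5, 2.5)$ and reliability $\in (0.25, 0.95)$ —
  weights and reliabilities are generated directly; deregression itself is
  an input contract, not re-implemented.

The same seed reproduces the dataset bit for bit.

**What the simulator does and does not show.** Passing tests demonstrate
the pipeline recovers a planted lethal under Mendelian transmission,
Haldane recombination, and clean genotypes. Real data add genotyping
error, imperfect phasing, selection on breeding values, assortative
mating, and historical frequency fluctuations, none of which are
simulated. Two systematic effects *are* visible in the simulation and
worth understanding: selection removes two lethal copies with every dead
homozygote, so the allele frequency declines (~0.045 → ~0.037 over four
generations) and the observed carrier fraction sits below the founder
expectation; and recombination steadily erodes the tag haplotype, so the
scan's frequency estimate of the exact 19-marker haplotype undershoots
the allele frequency in older, sparser maps. The frequency-recovery
property is therefore checked on a founders-only panel, where the
binomial sampling model holds exactly.

## Reproducibility

`run_pipeline()` executes qc → scan → carriers → litters → prioritize →
segregate → assoc from one validated config, writes deterministic,
sorted TSV/BED outputs, and records a manifest (package version,
parameters, seed, input checksums) sufficient to re-execute the run.
Identical configs produce byte-identical outputs. A thin command-line
wrapper (`inst/scripts/lethalscan.R`) exposes `simulate` and `run` for
shell use; the R functions above are the primary interface.

`scripts/acceptance.R` recomputes the headline numbers from scratch — the
published-table arithmetic from its printed counts and the full synthetic
rediscovery at study scale — and writes them as JSON; see the README.
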