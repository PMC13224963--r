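---
title: "Strain deconvolution with straindecon: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain deconvolution with straindecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A metagenomic sample of a bacterial species usually contains several
strains of that species at unequal abundances. Short-read assemblies
collapse them into a consensus, yet the phenotypically decisive
variation — antibiotic resistance, metabolic capability, virulence — is
often strain-level. `straindecon` reconstructs up to three strain
genotypes, and their relative frequencies, from one paired-end sample
mapped against a single annotated reference genome.

# The model

## From reads to allele pairs

The reference genome (GenBank flat file) is decomposed into a database
of individual genes, each extended by one read length of flanking
sequence on both sides (less at contig ends). Mapping against genes
rather than the whole genome tolerates strain-level differences in gene
content; the flanks stop coverage from tapering at gene boundaries, and
variant calling later ignores flank positions entirely. When less than
60% of the core gene positions receive any coverage, processing stops:
the reference is too distant (likely a different species) to yield
trustworthy genotypes.

Variants are called from a base-quality filtered pileup (phred >= 30).
A column must lie inside a depth band of 1.5 standard deviations around
the genome-wide mean depth — columns outside it are the footprint of
gene duplications, deletions, and cross-mapping from relatives — and an
allele needs at least 20 supporting reads and a frequency in [1%, 99%].
A column whose minor bases all fail these filters is not a variant site:
isolated sequencing errors at 0.1% per base would otherwise create
thousands of spurious one-read alleles. Non-reference alleles *above*
the band (> 99%) are tracked separately as *fixed differences*: alleles
private to the mapping reference, which every reconstructed strain must
carry. Fixed differences are scanned on the unfiltered pileup because
they are output, not model input, and the depth band exists only to
protect the frequency model.

Every fragment (a read or its mate pair) that covers two variant sites
links them: for each pair of called alleles, `co_count` counts the
fragments carrying both and `span_count` the fragments covering both
sites with any base. Their ratio estimates the joint frequency of the
strains carrying both alleles — the quantity the peak model needs.
Pairs require `co_count >= 3` (isolated chimeric observations) and
`span_count >= 20`: a frequency estimated from fewer than 20 fragments
is too noisy to assign to a peak, and combined with the `co_count`
floor it would otherwise be biased upward into a spurious
high-frequency cluster. Pairs merge transitively into linkage groups —
connected components of the allele graph — which can span genes,
because mate pairs bridge neighbouring genes.

## The hexamodal peak model and its score

Three strains at frequencies $(f_1, f_2, f_3)$ on the simplex imply six
expected allele-frequency modes: $f_1, f_2, f_3$ for strain-private
alleles and $f_1{+}f_2, f_1{+}f_3, f_2{+}f_3$ for alleles shared by two
strains. Each observed pair frequency $x_k$ is assigned to its nearest
peak and its complement $1-x_k$ to the nearest peak as well; a
configuration is *compatible* when the two peaks correspond to
complementary strain subsets. The score is

$$ S = \sum_k d_k, \qquad
   d_k = \begin{cases}
     |x_k - p_{a(k)}| + |(1-x_k) - p_{c(k)}| & \text{compatible} \\
     1 & \text{otherwise,}
   \end{cases} $$

minimized over the simplex. Two numerical details matter:

* **Ties are resolved in favour of compatibility.** At degenerate
  distributions peaks coincide (at $(0.8, 0.2, 0)$, peak $\{1\}$ and
  peak $\{1,3\}$ both sit at 0.8). Breaking ties one-sidedly would
  penalize such configurations with spurious "incompatible" unit
  contributions and wall off exactly the two-strain solutions the
  search must be able to reach.
* With compatibility-aware ties, the peak symmetry
  $p_k + p_{\mathrm{comp}(k)} = 1$ makes the unit penalty provably
  unreachable for any simplex distribution: the complement frequency is
  always exactly as close to the complementary peak as the pair is to
  its own. The penalty branch remains implemented and is exercised in
  the unit tests through the scoring kernel.

## The stochastic search

500 walkers run greedy accept-if-better chains. The first walker starts
exactly at the equal-frequency assumption $(1/3, 1/3, 1/3)$ — which
also guarantees the final score never exceeds the equal-frequency
score — and the rest at Gaussian perturbations of it (SD 0.1, projected
back to the simplex). A proposal shifts two randomly chosen frequencies
by signed draws from Normal(0.002, 0.002) and sets the third to the
complement. Every 10th iteration, and whenever 20 consecutive
iterations fail to improve, a *big jump* is attempted: with equal
probability the step scale is inflated 5-, 10- or 100-fold, or a fresh
distribution is drawn uniformly from the simplex. A walker stops after
100 consecutive non-improving iterations; the best walker wins. All
randomness flows from R's RNG, so a single seed makes the whole
pipeline bit-reproducible. For large samples, pair frequencies are
aggregated into 0.001 bins before scoring (only when more than 2000
distinct values are present); the reported score is always recomputed
exactly.

Two choices deserve explanation because the description of the search
leaves them open. The shift distribution Normal(0.002, 0.002) is
almost surely positive; an optimizer needs to move both ways, so each
draw carries a random sign. And the auxiliary ensemble from which
"movements are drawn" is under-determined; we implement the movement
distribution directly rather than a second sampler ensemble.

## Degenerate-solution selection

A pure nearest-peak distance score has a known pathology: a single
noisy frequency cluster can always be fitted slightly better by *two*
nearby peaks straddling it than by one peak at its center. For a
two-strain sample this manifests as a phantom third strain at a few
percent frequency — stable enough to survive the 1% minimum-frequency
filter, and incoherent enough to corrupt phasing. The remedy is model
selection against a *model-independent noise floor*: under a correct
model each pair's expected contribution is
$2\sqrt{2/\pi}\,\sqrt{x(1-x)/\mathrm{span}}$ (twice the mean absolute
deviation of a binomial proportion). After the search, the simplest
configuration whose score is within 1.5x this floor is reported
instead of the three-strain optimum: first a single strain, then the
equal-frequency assumption (kept when it matches the best two-strain
refit to within the proposal resolution of 0.002 per pair — the two
are spectrally identical exactly when the data look equal-frequency),
then the best two-strain fit $(a, 1-a, 0)$ found by grid refinement.
Measured on simulated samples, true simpler structure sits at 1.0–1.2x
the floor while genuine three- and four-strain structure sits at 2x and
above, so the 1.5x threshold separates the regimes with a wide margin.

## Phasing, masking, merging

Each allele pair votes for the strain subset of its nearest peak,
weighted by its read support. An allele's subset is the plurality vote
and its confidence the plurality share; an allele assigned to a
different peak more than half of the time (confidence <= 0.5) is
ambiguous and masked as "N". Voting over pairs pools linkage evidence
across the allele's whole neighbourhood, which is far more robust than
the allele's own site frequency (whose binomial noise misassigns
several percent of alleles at moderate coverage). Votes tied across
peaks of *identical* frequency are kept when the tied peaks agree about
every live strain (peaks $\{1\}$ and $\{1,3\}$ once strain 3 is fitted
at zero) and discarded as uninformative otherwise — at an exactly
equal-frequency fit every vote is uninformative, every allele is
masked, and the sample is honestly reported as unphaseable rather than
arbitrarily phased.

A pair's peak reflects the *intersection* of its two alleles' strain
sets, so plurality votes systematically under-set reference alleles at
biallelic sites. Genotype construction is therefore driven by
non-reference alleles: an unmasked alternative allele is written into
the strains of its subset; a position becomes "N" for a strain only
when the evidence is ambiguous (conflicting claims, or a masked
alternative allele plausibly belonging to it); every other position
carries the mapping-reference base — the same convention standard
evaluations apply to unpredicted positions. Fixed differences are
written into every strain.

Strains fitted below 1% frequency are dropped, and genotypes at or
above 99.5% genome-wide nucleotide identity — the conventional strain
delineation threshold — are collapsed transitively onto the most
abundant member (frequency ties onto the member with fewest masked
positions), frequencies renormalized. Identity is computed over
positions where neither genotype carries "N", so denominators differ
per pair.

# The simulator

`simulate_sample()` generates the desk-scale experiments the package is
validated on: a random uniform-composition reference of `n_genes` genes
(default 50 x 900 bp) separated by 200 bp spacers — short enough that
flank-extended gene regions overlap and mate pairs can bridge genes,
long enough that read placement stays unambiguous; strain genomes
derived by independent random substitutions at rate `1 - identity`
(pairwise strain ANI is therefore about `2*identity - 1`); and paired
150 bp reads from fragments of Normal(300, 30) length, drawn from
strains at the design frequencies, with uniform substitution errors
(default 0.1%, phred strings encoding that rate). Because strains
differ from the reference only by substitutions, every read's true
placement is known and a "perfect" SAM is emitted alongside the FASTQ —
the default test path needs no external mapper; `bowtie2` integration
is a thin optional wrapper.

What the simulator does *not* emulate matters for interpreting results:
real strains share phylogenetic structure, so real samples contain
shared (two-strain) alleles, which are rare under independent
substitutions; coverage is uniform rather than GC- or position-biased;
errors are uniform substitutions rather than an empirical Illumina
profile; and there are no indels, so reference coordinates are exact
and no realignment is needed. Passing the battery therefore
demonstrates correct inference under clean, identifiable conditions,
not robustness to every artifact of real sequencing.

# Evaluation metrics

Genotype accuracy is the fraction of genome-wide variant positions
(sites where any truth strain differs from the mapping reference) at
which a reconstructed strain carries the truth strain's allele; "N"
positions are excluded from numerator and denominator, and unpredicted
positions count as the mapping-reference base. Reconstructed strains
are matched to truth strains by exhaustive injective assignment
maximizing total accuracy (ties broken by closest frequencies); when
more strains were simulated than the model can represent, each reported
strain is matched to its best truth strain instead. Frequency accuracy
is `1 - |f_est - f_true|` averaged over matched strains — the natural
reading, adopted as a documented stand-in since no exact formula for
this figure is conventional. Reconstructions from this pipeline are
already in reference coordinates; an externally produced genotype whose
gene lengths differ is first projected onto the truth strain by global
alignment, with gap positions excluded like "N".

# The standard battery and the problem sizes used

`battery_designs()` fixes twenty samples: four single-strain, eight
two-strain (80/20 to 65/35, including 90/10) and eight three-strain
(70/20/10 style) designs, identities 0.98–0.99, coverages 30–250x
chosen so every strain is covered at least ~25x and clears the 20-read
support filter. Frequency vectors are identifiable by construction:
when one strain's frequency equals the sum of the other two (50/30/20),
two hexamodal peaks coincide and pairs at that frequency are
unassignable — a limitation of the model itself, not of the
implementation. `equal_freq_designs()` (five samples at 1/3 each) and
`four_strain_designs()` (five samples at 40/30/20/10 style) probe the
two regimes the model is expected to degrade in. These sizes keep the
full battery within minutes on one CPU while leaving hundreds of
variant sites per sample.

# Known limitations

* At most three strains are modeled; additional strains are absorbed
  into chimeric or merged genotypes. With independently derived
  simulated strains the reported genotypes of a four-strain sample mix
  two truth strains and their accuracy drops accordingly; with real,
  phylogenetically structured strains the merged pair tends to be the
  most similar pair, which is more forgiving.
* Strains at (near-)equal frequencies are spectrally indistinguishable;
  the pipeline masks rather than guesses, reporting the reference-plus-
  fixed-differences consensus.
* Frequency configurations with $f_i = f_j + f_k$ leave one peak pair
  coincident and the corresponding alleles unassignable.
* Genes absent from the mapping reference cannot be reconstructed, and
  close relatives in the sample can cross-map; running once per related
  reference genome is the recommended practice.

# A worked example

```{r, eval = FALSE}
library(straindecon)

design <- sim_design(n_strains = 2, frequencies = c(0.7, 0.3),
                     coverage = 100)
sim <- simulate_sample(design, seed = 1, dir = "example_sim")
result <- run_pipeline(sim$files$genbank, sam = sim$files$sam,
                       config = run_config(seed = 1),
                       out_dir = "example_out")
result
evaluate_sample(result, sim)
```
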