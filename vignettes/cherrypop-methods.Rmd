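---
title: "Methods: haplotype-based phylogeography and demographic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-based phylogeography and demographic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fruiting cherries (*Prunus*, subgenera *Cerasus* and *Microcerasus*) were
domesticated at least twice — sweet and sour cherries in Europe, Chinese
cherry (*P. pseudocerasus*) in China — and wild relatives across the
Himalaya–Hengduan region harbour most of the genus's diversity. Panels of
hundreds of accessions genotyped at one nuclear ribosomal locus (ITS) and a
few concatenated chloroplast fragments are the workhorse data for asking
where a crop was domesticated, when its wild progenitors diverged, and which
populations acted as refugia. `cherrypop` implements the full analysis chain
for such panels: alignment ingestion and indel recoding, haplotype
collapsing, diversity and neutrality statistics, mismatch-distribution
expansion tests, hierarchical AMOVA and pairwise Φ~ST~, median-joining
haplotype networks, a structured-coalescent scenario simulator, and
approximate Bayesian computation (ABC) over competing demographic scenarios.

The package is organised as an analysis compendium: the computation lives in
the package functions (`R/`), the numbered scripts under `analysis/` narrate
one complete study-shaped analysis over a synthetic panel, and
`scripts/acceptance.R` recomputes the headline quantities from scratch.

## Data model and ingestion

An `aligned_dataset` couples an equal-length character matrix over
`{A,C,G,T,-,N}` with a metadata table assigning every sample to a population
(deme), a geographic subgroup, and a group (the five panel groups are
conventionally CC, WC, RC, EC, MC: cultivated/wild Chinese cherry, wild
relatives, European cherries, *Microcerasus*). Every deme must map to
exactly one subgroup and group; violations are ingestion errors, as are
ragged alignments and samples missing from the metadata.

**Indel recoding.** Gaps carry signal but break nucleotide substitution
models. `recode_indels()` offers two treatments: *simple indel coding*
(each distinct maximal shared gap run becomes one appended binary
character — state 1 for rows carrying exactly that run, inapplicable for
rows whose gap strictly contains it — and all gap-bearing columns leave the
base matrix) and *drop gapped columns* (the treatment usually applied to
concatenated chloroplast matrices). Simple indel coding is our reading of
"indels treated as substitutions": the cited gap-coding programs implement
exactly this family of rules. Polymorphic-site counts include the indel
characters by default (`include_indels = TRUE`), with a flag to exclude
them, because published site counts for such data are usually quoted with
indels counted.

**Haplotypes.** Distinct character rows are enumerated in first-seen order;
`relabel = "by_frequency"` renumbers them so H1 is the most frequent, the
convention of published haplotype tables. The default missing-data policy
is *strict* (every distinct string is its own haplotype), matching directly
sequenced panels from which ambiguous individuals were already removed;
`match_ignoring_N` merges a row containing N into an existing fully
resolved haplotype only when exactly one is compatible. Coordinates are
0-based half-open internally and 1-based in reports.

## Distances

`pairwise_differences()` counts sites at which both rows carry resolved,
differing states; indel characters count (consistent with
treating indels as substitutions). `tn93()` implements the Tamura–Nei
(1993) correction, which separates the two transition classes (A↔G, C↔T)
from transversions and allows unequal base frequencies — the distance
conventionally fed to AMOVA and Φ~ST~ for organellar and ribosomal data.
Base frequencies are pooled over the whole haplotype set by default (stable
on short fragments; a per-pair option exists), indel characters are
excluded (the model is defined on nucleotides), saturated pairs (a
logarithm argument ≤ 0) are flagged and assigned the largest finite
distance in the matrix, and an alignment with an empty base class falls
back to p-distance with a warning. In the equal-frequency, equal-rate limit
the formula collapses to Jukes–Cantor, which the tests exploit as a
closed-form check alongside an independent implementation.

## Diversity and neutrality

Gene diversity uses Nei's corrected estimator
$h = \frac{n}{n-1}(1 - \sum_i p_i^2)$ with his sampling variance;
nucleotide diversity is the mean pairwise difference per site with the
standard total variance. Tajima's D follows the textbook constants;
Fu's *F*~s~ evaluates $S' = \Pr(K \ge k_{obs} \mid \theta = \hat{k})$ under
the Ewens sampling distribution, with unsigned Stirling numbers of the
first kind computed by their recurrence in log space (samples of several
hundred sequences pose no overflow problem), and
$F_s = \ln(S'/(1-S'))$.

**Simulated p-values.** Significance comes from constant-size neutral
coalescent simulation *conditioned on the observed number of segregating
sites*: exactly S mutations are placed on each simulated genealogy with
probability proportional to branch length. Conditioning on S rather than on
an estimated θ is the default behaviour of the standard software for these
tables, and it makes the null self-contained. The default tail is one-sided
lower — the expansion signal of interest is "significantly negative" — with
a two-sided option. All Monte-Carlo routines take explicit seeds and are
byte-reproducible.

## Mismatch distributions

The observed distribution of pairwise differences is fitted to the sudden
demographic expansion model: a population of mutation-scaled size θ₀ grows
instantaneously to θ₁ at τ mutational time units before present. We
evaluate the expected class probabilities exactly, by integrating the
two-epoch pairwise coalescent density against the Poisson mutation kernel
(regularized incomplete gamma functions; the ancient-epoch term is
evaluated in log space because its exponential prefactor and gamma tail
can separately overflow). The fit minimises the sum of squared deviations
(SSD) from five deterministic starts under box constraints (θ₁ ≤ 9999, the
conventional "effectively infinite" value; difference classes truncated at
the observed maximum plus five empty classes). Harpending's raggedness
index is computed over the observed class frequencies with one trailing
empty class appended; the observed class-0 frequency enters the first
squared difference, the field-standard form of the index.

Significance of SSD and raggedness uses a parametric bootstrap: samples of
the same size are simulated under the fitted model by a two-epoch
coalescent in mutational units, each replicate is refitted, and the
p-value is the fraction of replicates at or above the observed statistic.
We read the customary "5000 permutations" of such analyses as 5000
parametric-bootstrap replicates, since no other resampling scheme is
defined for this test; the replicate count is a parameter (`n_boot`,
default 5000). The calibration study in the test-suite uses 99 bootstrap
replicates per dataset, which is enough to check the uniformity of
*P*~SSD~ under the correctly specified model.

## AMOVA and Φ-statistics

The three-level AMOVA (among groups / among populations within groups /
within populations) follows the squared-distance framework with
unequal-sample-size coefficients; haplotype-level distances are expanded by
their counts, and squared internally. We use Φ-statistics (distance-based)
rather than allele-frequency F-statistics because the same Tamura–Nei
distances drive both AMOVA and the pairwise matrices. Negative variance
components are reported as computed (truncation is an option; percentages
always use untruncated components). Permutation schemes are the standard
three: individuals among populations across the system (Φ~ST~),
individuals among populations within groups (Φ~SC~), and whole populations
among groups (Φ~CT~); p-values use (b+1)/(n+1) with the default 1000
permutations. Pairwise Φ~ST~ is the two-level special case with
permutation of individuals between the pair; units with fewer than two
samples are excluded with a warning. On a dataset whose two demes have
identical composition the estimator is deterministically negative
(−1/(n_d−1)); this is a property of the estimator, not a defect, and the
permutation test correctly reports no differentiation.

## Median-joining networks

`median_joining()` implements the Bandelt–Forster–Röhl algorithm on
unordered multistate characters: iteratively build the ε-relaxed
minimum-spanning network (all links of a weight class joining components
not connected at a smaller class; ε = 0 by default, the usual software
default), add quasi-medians (per-position majority of linked triplets;
positions where all three states differ spawn every resolution, capped at
64 per triplet in lexicographic order) whenever they shorten the triplet's
connection, and prune obsolete median vectors. Pruning removes any median
whose removal does not lengthen the network's spanning connection — this
subsumes the degree-≤-2 rule (such a median sits on a geodesic and
shortens nothing) and guarantees that the network's connection length
never exceeds the minimum-spanning-tree length over the observed
haplotypes. All tie-breaking is lexicographic on state strings, so the
construction is deterministic and seedless.

`network_summaries()` reports degree, betweenness and per-group composition
percentages (the quantities used to describe central and
subgroup-dominated haplotypes); `cut_sublineages()` returns connected
components after cutting links above a weight threshold — a purely
topological convenience, deliberately *not* a replacement for model-based
population structure assignment (e.g. BAPS), which is out of scope and
whose lineage boundaries no network-intrinsic rule reproduces.

On deeply divergent panels (saturated distances) the network is dense and
construction takes minutes rather than seconds; the analysis scripts build
the network over the Chinese groups, where the published network figures
live, and the deep inter-group divergences are read from the trees and
AMOVA instead.

## The coalescent scenario simulator

Scenarios are demes with current effective sizes, time-ordered events
(splits viewed backwards as merges, admixture pulses, size changes) with
times in years converted through a generation time (default 4 years, the
conservative field estimate for cherries), optional continuous backward
migration, and uniform priors over sizes, times, fractions and the
mutation rate. Within a deme, k lineages coalesce at rate k(k−1)/2 · 1/(2N)
per generation; the simulation is exact (event-driven, no time
discretisation). Mutation models: infinite sites (each mutation a fresh
column; refuses datasets whose expected mutation count exceeds the locus
length) and finite-sites Jukes–Cantor (uniform target sites, current base
replaced by one of the other three; recurrent and back mutations arise
naturally). The stated uniform mutation-rate prior, 10⁻⁴–10⁻³ per locus
per generation, is the one customary for such perennial-tree panels.

A note on mutation models: the generalized stepwise model sometimes quoted
for such analyses is a microsatellite model and cannot apply to sequence
data as written; we implement infinite sites (default for shallow
histories) and Jukes–Cantor (default for ABC and deep histories, where
prior draws can imply many substitutions).

**Gene flow.** Post-divergence gene flow between wild relatives and wild
Chinese cherry is modelled as a single admixture pulse (event-based
scenario description, as in standard ABC software), with continuous
migration available as an option; the island-model calibration in the test
suite uses the continuous form.

## The synthetic panel

`make_fixture("five_group")` generates the study-shaped dataset: groups
CC/WC/RC/EC/MC with sample sizes 331/204/174/120/79 (the published group
sizes) over 12 populations in four geographic regions, a 710-bp ITS-sized
locus, and the history: MC diverges 3.52 Ma, EC 1.76 Ma, WC from RC 34,200
years ago, CC domesticated 2,660 years ago, with current effective sizes
1530 (CC), 5890 (WC), 37,500 (RC), 1610 (EC), 37,300 (MC) and an ancestral
Chinese pool of 43,900. Where a published point estimate exists it is used
directly; two choices are the package's own: the EC divergence is set to
half the MC divergence because the source quotes the same 3.52 Ma for both
events while requiring strict time ordering, and the within-group
population splits (centuries to a few thousand generations) are chosen to
produce the low-to-moderate subgroup differentiation such panels show. The
default mutation rate, 2×10⁻⁴ per locus per generation, sits inside the
customary prior and reproduces nucleotide diversities of the observed
magnitude (π ≈ 0.01 in CC, ≈ 0.04 in RC). The deep inter-group divergences
make recurrent substitution likely, so the five-group preset uses the
Jukes–Cantor model; the three-group (Chinese-only) preset is shallow and
uses infinite sites.

One emergent property is worth stating plainly: under these point
estimates the cultivated group's bottleneck (N ≈ 1530 over ~665
generations) lets several deep wild lineages survive into the cultivated
gene pool, so the synthetic CC group carries intermediate-frequency
variants and shows *positive* Tajima's D rather than the negative,
star-like signature a single-founder domestication leaves. The generator
is kept faithful to the published parameter values rather than tuned to
reproduce any table's statistic; the tests that check the direction of
neutrality statistics do so on histories constructed for that purpose
(pure sudden expansions), not on this panel.

What the generator does *not* emulate: intra-individual ITS polymorphism,
sequencing error, recombination, selection, geographic substructure within
populations, and the multi-locus linkage structure of a real
chloroplast + nuclear design (a single locus is simulated; a linked
organellar locus at halved effective size is a straightforward extension).
Passing tests therefore demonstrate the correctness and calibration of the
statistical machinery under the stated model, not the biological fidelity
of any particular parameter value.

## ABC scenario choice

`demographic_scenarios("three_group")` defines the three domestication
hypotheses for Chinese cherry: stepwise splits (RC → WC → CC), independent
splits of CC and WC from RC, and stepwise splits with a post-divergence
RC→WC admixture pulse. Priors are uniform, with size and time priors set
to the credible ranges panels of this design support (CC 500–6000,
WC 1000–10⁴, RC 5000–8.3×10⁴; domestication split 1000–6000 years, wild
divergence 1.2×10⁴–10⁵ years; admixture fraction 0.05–0.5; rate
10⁻⁴–10⁻³ per locus per generation).

The reference table simulates a fixed number of datasets per scenario from
the priors, summarises each with a fixed-layout vector (per deme: number
of haplotypes, gene diversity, nucleotide diversity, segregating sites,
mean pairwise differences; per deme pair: Φ~ST~ and mean between-deme
differences — the summary set is a package choice, as the exact list used
by the original ABC runs is unstated), and z-normalises the statistics by
the table's mean and standard deviation. Model choice retains the closest
1% of rows by Euclidean distance (the customary retained fraction) and
fits a multinomial logistic regression of the scenario indicator on the
statistics centered at the observed point; posteriors are the fitted
probabilities there, with 95% intervals from the regression's asymptotic
covariance by the delta method (whether published intervals are asymptotic
or bootstrap is ambiguous; we implement asymptotic and note it). Singular
or failed regressions fall back to rejection proportions, flagged.
Parameter estimation restricts to one scenario and applies the standard
local-linear regression adjustment to the retained draws (skipped and
flagged below 50 rows). Confusion errors classify pseudo-observed datasets
simulated from each scenario's own prior: type I is the fraction of a
scenario's pods not assigned to it, type II the mean fraction of other
scenarios' pods assigned to it.

Problem sizes: the acceptance study uses 10,000 reference rows per
scenario and 60 pseudo-observed datasets with 10 samples per deme — a
documented scaled-down design standing in for reference tables of a
million rows per scenario; the analysis script defaults to 5000 rows and
is adjustable through an environment variable.

## Numerical choices and degenerate inputs

* Monomorphic samples: h = π = 0; Tajima's D and Fu's *F*~s~ are reported
  undefined with a reason (no segregating sites / single haplotype), not
  as numbers; a monomorphic pair of demes has Φ~ST~ = 0.
* Mismatch fitting: five deterministic starts; non-convergence from all
  starts is an error; θ₀ ≤ θ₁ enforced by ordering.
* TN93 saturation: flagged pairs take the maximum finite distance rather
  than infinity, keeping AMOVA inputs finite.
* Permutation p-values never return 0: (b+1)/(n+1).
* The pipeline fans one master seed into fixed per-stage offsets, so any
  stage can be rerun in isolation and a rerun of the whole pipeline is
  byte-identical.

## Known limitations

* Φ~ST~ on very small demes is biased negative (see above); report sizes
  alongside estimates.
* The median-joining implementation targets panels of up to a few hundred
  haplotypes; saturated, homoplasy-rich inputs produce dense networks and
  long runtimes, as the algorithm itself does.
* The ABC layer assumes all candidate scenarios share one deme design and
  sampling scheme.
* Divergence-time posteriors from a single locus are wide; the published
  confidence ranges for such estimates span nearly an order of magnitude,
  and the package's coverage study makes the same point.
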