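---
title: "Models and methods: simulating and analysing a pseudo-bipolar mating system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analysing a pseudo-bipolar mating system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudobipolar)
```

# The biological setting

Basidiomycete sexual compatibility is decided at two molecular checkpoints:
pheromone/receptor recognition between cells (the PR region, *STE3*
alleles), and heterodimerization of homeodomain transcription factors
encoded by the divergently transcribed *HD1/HD2* pair, which only pair
across allele classes. In bipolar species the two regions are fully linked
(one *MAT* locus, two mating types); in tetrapolar species they are
unlinked and multiallelic (up to four mating types per meiosis). The
pseudo-bipolar configuration modelled here has both regions on one
chromosome with recombination between them infrequent but not suppressed:
mating tests look bipolar, but the HD region accumulates many alleles, each
associated with a single receptor, and rare meiotic products carry new
receptor–HD combinations.

This vignette documents the models, the tunable parameters, the synthetic
data generator, and the numerical and design choices, in the order a reader
is likely to question them.

# The compatibility model and sib-mating odds

`cross_outcome()` is deliberately categorical. Receptor alleles equal →
`NONE` (no switch to filamentous growth); receptor alleles different but HD
alleles equal → `PHEROMONE_ONLY` (pseudohyphal growth from pheromone
signalling, no clamps, no teliospores); different at both → `COMPLETE`.
Signalling intensity, allele-specific affinities and dosage are not
modelled.

For sib-mating odds the unit is one meiosis of a cross heterozygous at both
regions. With recombination fraction $r$ between the regions, the four
product genotypes occur at frequencies $(1-r)/2$ (two parental) and $r/2$
(two recombinant). Two spores are drawn **independently with replacement**
from this distribution, and are compatible iff they differ at both regions:

$$P(\text{compatible}) = \frac{(1-r)^2 + r^2}{2}$$

which is $1/2$ at $r=0$ (bipolar), $1/4$ at $r=1/2$ (tetrapolar) and
strictly in between otherwise; it is continuous, strictly decreasing on
$[0, \tfrac12]$ with range exactly $[\tfrac14, \tfrac12]$. The
with-replacement convention is what reproduces the classical 25% tetrapolar
figure; sampling two *distinct* tetrad members without replacement would
give 1/3 and is not used. Multi-allelic populations do not change the
per-meiosis calculation, because one meiosis segregates at most two alleles
per region. `simulate_sib_matings()` is a Monte-Carlo check of the same
quantity through the `cross_outcome()` path; at $10^5$ pairs its standard
error is about 0.0016, and tests require agreement within four standard
errors.

# The meiosis simulator

## Crossovers

Crossovers are placed along each scaffold (chromosome) as a Poisson process
on the physical axis, with piecewise-constant genetic rate: expected
crossovers per kb **at the four-chromatid bundle level** equal
$2/(100 \cdot \text{kb/cM}_{\text{local}})$. The factor 2 encodes the
standard convention that map distance in Morgans is half the expected
number of bundle crossovers, because each crossover involves only two of
the four chromatids. There is no chiasma interference.

Products are built by the strand-walk construction: all crossovers form on
the aligned bundle of original strands (two sisters per homolog); each
crossover joins one randomly chosen strand of each homolog, and a product
follows its strand from the left, jumping to the partner at every crossover
that involves it. Under this construction every crossover flips a given
product's parental origin with probability $\tfrac12$, independently, so
the recombination fraction across an interval of $m$ Morgans is Haldane's
$RF = (1-e^{-2m})/2$ exactly and disjoint intervals are independent. (An
earlier sequential tail-swap implementation violated this — a later
exchange could move already-recombined material and silently cancel — and
was replaced; the test suite pins the Haldane expectation.) Scaffolds
assort independently, so "pure parental products" is a per-chromosome
statement on multi-scaffold maps.

## Gene conversion

Conversion tracts initiate at each marker of each product with probability
`conversion_rate_per_marker`, extend an exponential length (mean
`conversion_tract_mean_kb`) downstream, and overwrite covered markers with
the homologous parent's allele. This breaks the 2:2 segregation at covered
markers only (3:1, the genetic definition of gene conversion). Segregation
data of the kind analysed here record conversions only as isolated marker
patterns, so any tract model reproducing single-marker switches would do;
the exponential/anchored choice is the simplest with a length scale.

## Teliospore packaging and recovery

With probability `p_diploid` a teliospore bypasses meiosis and yields one
diploid product (heterozygous everywhere, self-fertile in the study). The
default 1/8 matches one diploid among the eight teliospores examined.
Otherwise the four nuclei are partitioned at random into two binucleate
basidiospores; asynchronous germination is collapsed into a single
probability `p_recover_both_spores` (default 1/8, matching the one
teliospore of eight from which both parental mating types were recovered)
that a product of the later spore is recovered besides the one clonal
product of the first. Germination kinetics are not modelled. Colonies are
mitotic clones of the recovered product(s); the analysis side collapses
identical within-teliospore genotypes back to products.

## The emulated cross

`mat_cross_map()` lays both MAT regions on one chromosome: the HD scaffold
(MIP … HSP70, HD, IsocL) joined at the IsocL–PAN6 junction to the receptor
scaffold (PAN6 … LSm7, STE3, RibL6 … GEFsec7), plus nine autosomal markers
on four scaffolds at 525–1870 kb spacings. `mat_cross_hotspots()` adds the
27-kb hotspot at 0.63 kb/cM on the **MIP side** of the HD pair — crossovers
there did not separate the receptor from the HD region in the study, so the
hotspot cannot lie between them — and a 10× suppressed interval between HD
and PAN6, where no crossovers were observed. Positions are plausible round
numbers; the real coordinates are not published, so the map is a labelled
synthetic stand-in, not a reconstruction. The baseline 32 kb/cM is the
study's autosomal average. The split-scaffold `example_marker_map()` is the
same marker panel as the assembly presents it, used for orientation
inference and per-scaffold tests.

# Segregation analysis

`assign_origin()` maps raw progeny alleles to `P1/P2/HET/NA` and drops
markers where the parents are identical (with a warning).
`detect_diploid()` flags a product heterozygous at at least a configurable
fraction (default: all) of its informative markers.

`call_events()` implements **exact minimal-event parsimony** per scaffold:
candidate conversions are internal runs of at most `max_conversion_markers`
markers (default 1) spanning at most `max_conversion_kb`; the labeling
minimizing conversions + crossovers is found by enumerating non-adjacent
candidate subsets (candidates must stay flanked by the opposite origin on
both sides). Ties prefer the conversion labeling, matching how isolated
internal switches are naturally read. Runs touching a scaffold end have one
flank unobserved and can never be called conversions; by default their
boundary switches are reported `AMBIGUOUS` (set
`terminal_ambiguous = FALSE` to call them crossovers). Missing markers are
skipped and widen the affected event's interval.

`recombination_fraction()` uses the small-sample convention
$\text{cM} = 100 \cdot RF$ with no mapping function — this is the
arithmetic under which 3 recombinants among 7 products across 27 kb give
exactly 0.63 kb/cM. It deliberately over-states map length for large RF;
the simulation-recovery tests therefore estimate densities from chains of
short intervals, where the Haldane distortion is below 1%. Linkage classes
come from an exact binomial test of $RF = \tfrac12$ (default
$\alpha = 0.05$); note that at $n = 7$ the test can never reject, which is
why the hotspot is an argument about map density, not significance. One
product per meiosis is counted (clones collapsed) unless both spores were
recovered with distinct genotypes.

`mat_cohesion_summary()` classifies each teliospore as DIPLOID,
RECOMBINANT (some haploid product with a non-parental receptor–HD
combination) or PARENTAL; parental teliospores yielding two distinct
receptor–HD classes are additionally counted `both_types_recovered`. The
three classes partition the teliospores; the both-types count annotates the
parental class, which is how a count of six-of-eight teliospores with
cohesion maintained can include the one teliospore that yielded both
parental mating types.

`infer_scaffold_orientation()` scores the four junction configurations
(which end of scaffold A meets which end of B) by total origin switches
over all haploid products and returns the minimal configuration(s), ties
unresolved. The analysis scripts include a small power study: with seven
products — the study's scale — the junction resolves reliably only when the
wrong configurations accumulate events quickly (recombination-rich flanks);
at uniform baseline rates seven products are usually insufficient.

## Validation against the truth log

Conversion-free simulations are compared **exactly** against the
simulator's truth log, reduced to what a marker-based caller can see: the
log records, per crossover, the two products whose origin flips, and the
observable truth for a product is the set of inter-marker intervals
containing an odd number of its crossovers (an even number cancels — the
same conversion-versus-double-crossover identifiability limit the study
notes for its own data). With conversions enabled at default rates, tests
require at least 90% of observable single-marker conversions (internal,
flanks intact) to be recovered as `CONVERSION` calls.

# Sequence evolution statistics

`ng86_pair()` is the Nei–Gojobori (1986) statistic: synonymous sites
counted fractionally per codon (stop-codon mutations counted as
nonsynonymous so that $N + S = 3L$), averaged over the two sequences;
differences at multi-substitution codons averaged over all orderings of
single-step pathways, excluding pathways through stop codons (with a
fall-back to all pathways if every one is blocked); proportions
Jukes–Cantor corrected, $d = -\tfrac34 \ln(1 - \tfrac43 p)$, undefined at
$p \ge \tfrac34$. Only the universal code is supported; codons containing
gaps or ambiguity characters are excluded pairwise. The test suite checks
the implementation against an independently written brute-force pathway
enumerator over all 61 × 61 sense-codon pairs.

`sliding_window_dnds()` uses 20-codon windows, step 1 (window units are
codons). The per-window ratio is **mean dN over mean dS** across all
unordered allele pairs — robust when individual pairs have $dS = 0$ —
with per-pair ratio averaging available behind a flag; a window with mean
$dS = 0$ reports a missing ratio. A full-length window reproduces the
global pairwise statistic exactly. `domain_dnds()` applies the same
machinery to a user-supplied partition; the real domain boundaries are not
published, so domain analyses of real data need user coordinates.

The generator `synthesize_coding_alignment()` evolves alleles independently
from one stop-free ancestor, accepting proposed nonsynonymous changes with
probability $\min(1, \omega)$ and synonymous ones with $\min(1, 1/\omega)$,
so realized pairwise ratios approximate the per-domain targets. The default
three-domain gene (80/60/60 codons at $\omega$ = 1.5/0.1/0.3, 0.5 proposed
substitutions per codon per lineage) yields clearly separated domain
averages without saturating synonymous sites; tests require the domain
ordering and the confinement of windows above 1 to the high-$\omega$
domain in at least 9 of 10 seeds. Independent evolution from a star
ancestor ignores the real allele genealogy, recombination and codon-usage
bias, so passing tests demonstrate statistical machinery, not realism of
any particular gene family.

# Allele survey

`association_summary()` and `classify_system()` are pattern-based, not
statistical: BIPOLAR needs exactly two HD alleles, one per receptor;
TETRAPOLAR needs an HD allele observed with both receptors;
PSEUDO_BIPOLAR needs more than two HD alleles, each strictly associated
with one receptor. Below four haploid strains the classifier returns
UNDETERMINED rather than over-claim — the original inference rests on 36
strains. Self-fertile and two-receptor records are reported separately and
never counted as haploid evidence. Whether a one-to-many association
reflects rare recombination or population-genetic structure is an empirical
question the classifier does not attempt to answer.

# Problem sizes and determinism

All stochastic routines take explicit seeds and are exactly reproducible.
The test suite uses 2,500 meioses (10⁴ products) for recombination-fraction
recovery, 10³ meioses for hotspot density and tetrapolar mating-type
counts, 10⁵ spore pairs for the Monte-Carlo odds, 100–300 meioses for
truth-log equivalence and conversion recovery, and 10 seeds for the
dN/dS parameter-recovery study; these sizes keep every Monte-Carlo check
at least four standard errors wide of its expectation. The analysis
scripts use 400 teliospores for the mapping tables and 100 replicates for
the orientation power study.

# Known limitations

* No chiasma interference, no mapping-function correction (by design, to
  match the small-sample arithmetic), no multi-point map ordering.
* Conversion tracts extend downstream from their anchor only; tract
  initiation is marker-anchored rather than uniform in space.
* The compatibility model is categorical; pheromone signalling strength and
  HD heterodimer affinities are out of scope.
* The survey classifier is a pattern test; it does not model sampling
  error in allele discovery.
* Synthetic alignments have no indels, no genealogy and no rate variation
  beyond the domain partition.
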