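---
title: "Founder-variant analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder-variant analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderage)
library(dplyr)
```

founderage implements the computational chain behind a founder-variant
population study: genotyping a cohort by restriction-fragment patterns,
estimating the carrier-allele frequency with exact binomial confidence
intervals and projecting recessive disease incidence under Hardy-Weinberg,
detecting runs of homozygosity (ROH) around the variant, converting their
physical bounds to sex-averaged Kosambi centimorgans on a genetic map, and
dating the founder event from the genetic lengths of the shared autozygous
segments. This vignette explains each model, its assumptions and tunable
parameters, the numerical choices, and what the bundled forward simulator
does and does not emulate.

## Carrier frequency and incidence

A population screen of `n` individuals for an autosomal variant is a
binomial observation on `2n` alleles. `allele_frequency()` reports
`q = x / 2n` and attaches the exact Clopper-Pearson interval, computed in
beta-quantile form (`qbeta(alpha/2, x, n - x + 1)` and
`qbeta(1 - alpha/2, x + 1, n - x)`), with the conventional hard boundaries
`lower = 0` at `x = 0` and `upper = 1` at `x = n`. The exact interval
inverts the binomial tail sums, so its coverage is at least nominal for
every true `q` — conservative, which is the behaviour wanted when a single
carrier drives the estimate. The test suite keeps an independent bisection
of the tail sums as an oracle for the beta-quantile form.

`hwe_incidence()` squares the *unrounded* point estimate and both unrounded
bounds and rescales to cases per 100,000 (configurable). Squaring is
monotone on [0, 1], so the transformed bounds remain an equal-tailed
interval at the same level. Rounding happens only at display: six decimals
for frequencies, five for per-100,000 incidences. No inbreeding-coefficient
or mutation-selection adjustment is applied; the projection is pure
Hardy-Weinberg `q^2`.

```{r freq}
cohort_counts(c("Bashkir", "Tatar", "Mari"), c(284, 87, 132), c(0, 0, 1)) |>
  allele_frequency() |>
  hwe_incidence() |>
  select(population, q_hat, ci_lower, ci_upper, incidence)
```

## RFLP genotyping in silico

The RFLP module works at the fragment-arithmetic level. `simulate_pcr()`
binds primers by exact match only — assay design, not hybridisation
thermodynamics, is in scope — and distinguishes "no amplification" from
"non-specific amplification" (every forward/reverse pairing is enumerated
and more than one product is an error listing all product lengths).
`find_sites()` matches degenerate IUPAC recognition sites; at enzyme
construction the site is checked for self-complementarity (TCNNGA's reverse
complement is itself), in which case a single-strand scan suffices;
non-self-complementary sites are scanned on both strands with the cut
mirrored. Cut coordinates count bases left of the cut; digestion of a
linear molecule with `k` internal cuts yields `k + 1` fragments conserving
total length.

`genotype_from_fragments()` compares an observed size multiset against the
wild-type pattern, the mutant pattern, and their union with shared sizes
collapsed — on a gel, a fragment present in both alleles is one band.
`tolerance_bp` (default 0, exact in-silico sizes) merges co-migrating
bands when calling parsed gel sizes. A pattern matching none or several
references is `"uncalled"`, a value rather than an error, since uncalled
lanes are routine assay output.

The fixture built by `make_rflp_fixture()` encodes the assay's printed
arithmetic: a 357-bp amplicon between the published primers, one
constitutive Hpy188III site cutting 189 bp in (wild type: 189 + 168), and
a two-base substitution creating exactly one extra site that splits the
189-bp fragment into 122 + 67. Filler bases contain no T, so no spurious
TCNNGA site can arise anywhere, and the constructor digests its own output
before returning. The fixture is synthetic: it reproduces fragment sizes,
not the genomic sequence, whose exact position within the amplicon is not
derivable from published sizes alone.

## Genetic maps and the Kosambi scale

`genetic_map()` stores per-chromosome knots of (bp, cumulative
sex-averaged cM), requiring strictly increasing bp and non-decreasing cM
(ties are recombination deserts). `interpolate_cm()` is piecewise linear
and exact at knots. Outside knot support the genetic position is held
constant at the terminal value, with a warning: linear extrapolation would
fabricate recombination where the map has no information, and ROH ends
beyond map coverage are exactly where that would do damage. Coordinates
are 1-based inclusive throughout; BED export converts to 0-based half-open
at the I/O boundary only. The genome build is the caller's responsibility
— the map records a declared build string but verifies nothing.

`kosambi_rf()`/`kosambi_d()` implement `r = tanh(2d)/2` and its inverse.
Map distances in cM are already additive, so the map function is only
needed where recombination fractions are (e.g. cross-checking the
simulator); cM convert to Morgans by a fixed factor of 100.

## ROH detection

`detect_roh()` is a parameterised sliding-window caller in the style of
window-based autozygosity mappers. Windows are counted in markers, not bp,
which keeps behaviour stable under uneven exome marker density. A window
passes if it contains at most `max_het_per_window` heterozygous and
`max_missing_per_window` missing calls; markers covered by any passing
window merge into maximal runs; each run is trimmed so both terminal
markers are homozygous and non-missing; runs below `min_length_bp` or
`min_markers` are dropped. Missing calls never terminate a run by
themselves — only heterozygote excess does, because missingness in exome
data is platform noise, not evidence of heterozygosity. Defaults
(25-marker windows, 1 heterozygote, 2 missing, 1 Mb, 50 markers) are
exome-scale choices; no canonical values exist, so all are exposed.
Because flanking markers can be homozygous by chance, called boundaries
can overshoot the true autozygous segment by up to about one window span;
the tests assert exactly this bound, and equality with an exhaustive
loop-based oracle on randomized tracks. Published ROH calls typically add
manual inspection of borders, which no parameter setting reproduces.

`intersect_segments()` takes one segment per patient, verifies each
contains the anchor locus (error naming the offending sample otherwise),
and returns `[max(starts), min(ends)]` — the core autozygous in all
patients. `segment_length_mb()` reports `(end - start + 1)/1e6`, with
display rounding half-up to one decimal, the convention used in print.

## Dating the founder event

For an autozygous patient whose two haplotypes each trace `g` meioses to
the founder, each flank of the shared segment survives recombination with
exponentially distributed genetic length, rate `2g` per Morgan (the
minimum of two independent rate-`g` erosions). A patient's segment length
is the sum of two flanks, `Gamma(2, rate 2g)`; pooling `n` patients, the
total `S` in Morgans is `Gamma(2n, 2g)`. The package uses the pooled
maximum-likelihood estimator

$$\hat g = n / S,$$

with an equal-tailed interval from the exact pivot
`2 g S ~ Gamma(2n, 1)`. Pooling was chosen over averaging per-patient
estimates because it is the MLE of the shared parameter and the pivot
gives an exact small-`n` interval; with four patients, asymptotic
intervals would be meaningless. Years follow by multiplying by the
generation interval, default 25 years, configurable.

Two deliberate simplifications, stated because they matter for
interpretation: segment lengths enter as genetic lengths of *called* ROH,
and calls are length-biased — segments below the caller's detection
threshold are invisible, which biases `g_hat` downward. The default path
applies no correction, matching common practice; an optional
threshold-conditioned likelihood (`min_length_cm`), a left-truncated
`Gamma(2, 2g)` fit with a profile likelihood-ratio interval, is provided
and demonstrably removes the bias in simulation. Second, all patients are
assumed to sit at equal lineage depth `g`; unequal depths would need
per-segment meiosis counts, which the tabular interface admits but no
published per-patient depth usually supports.

```{r dating}
segs <- tibble::tibble(
  sample_id = c("WES1", "WGS1"), chrom = "chr9",
  start_bp = c(35096634, 35805740), end_bp = c(38543655, 40610122)
)
core <- intersect_segments(segs, 36214441, 36279281)
core
segment_length_mb(core$start_bp, core$end_bp, display = TRUE)
```

Point estimates of this kind are not reproducible from published summary
numbers alone — they need the patients' genotypes and the exact reference
map — so the estimator is validated by parameter recovery instead: the
acceptance script simulates 500 cohorts of 50 patients at a true depth of
10 generations and checks that the mean estimate lands within 5% of truth
and the 95% interval covers it in 93–98% of replicates. (The estimator's
small-sample bias is `E[hat g] = g * 2n/(2n - 1)`, about +1% at `n = 50`,
well inside that band.)

## The forward simulator

`simulate_cohort()` generates every input the pipeline needs, seeded and
deterministic. Flank erosion is simulated directly in genetic distance —
each side of each haplotype draws its surviving founder flank — because
that is exactly the distributional assumption the estimator inverts,
making recovery tests a closed loop. To guard against that circularity, an
independent crossover-process path
(`simulate_roh_intervals_crossover()`: Poisson crossovers at rate `g` per
Morgan per lineage, segments intersected between haplotypes) is included
and cross-checked against the exponential path in the tests.

Genotypes: markers inside the autozygous segment are homozygous for a
founder haplotype drawn once per cohort (so overlapping segments are
allele-concordant across patients, sufficient for ROH-detection tests
without coalescent machinery); markers outside are Hardy-Weinberg draws
from per-marker population frequencies, by default `Uniform(0.1, 0.9)` —
a generic polymorphic panel, not a fitted frequency spectrum. Optional
`het_error_rate` flips homozygous calls inside the segment to
heterozygous, and `missing_rate` masks calls, to exercise the caller's
tolerances. Map fixtures draw per-interval recombination rates around
1 cM/Mb from a Gamma with shape 8 — locally varying but strictly
increasing, hence invertible for the Morgan-to-bp conversion;
`rate_shape = Inf` gives the exact identity-rate map used in tests.

What the simulator does *not* emulate: linkage disequilibrium and
realistic allele-frequency spectra outside the segment, marker-density
heterogeneity of real exome capture, mutation on markers, pedigree
structure beyond the shared founder, and sequencing-level artefacts. A
passing recovery test therefore shows the estimator inverts its own model
correctly at realistic sizes — not that real exomes satisfy that model.

## Problem sizes and numerical notes

Simulation-backed tests use cohorts of up to 3,000 markers, oracle
comparisons of 50–100 randomized instances of 600–700 markers or 1.5–2 kb
sequences, and 500 dating replicates of 50 patients on a 400-knot map —
sizes at which every distributional check has comfortable power while the
whole suite runs in well under a minute. Ties and degenerate inputs are
decided explicitly: duplicate map knots keep the first with a warning;
zero-trial cohorts, empty length sets, and non-positive generation
intervals are errors, not NaNs; an undigested sequence is one fragment;
an unmatched gel pattern is `"uncalled"`. The truncated-likelihood fit
maximises over a bracket spanning three orders of magnitude around the
naive estimate with `optimize()` at tolerance 1e-10 and brackets the
likelihood-ratio roots by doubling.
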