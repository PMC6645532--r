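---
title: "Combined-evidence diet inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined-evidence diet inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophmix)
```

`trophmix` infers the diet of a consumer that cannot be observed feeding
by combining two independent evidence streams: the prevalence of
chloroplast 16S reads in gut-content amplicon libraries, and a two-source
stable-isotope mixing model with trophic discrimination left free. This
vignette is the package's account of both methods, the synthetic data
they are tested on, and the design choices behind them.

## The chloroplast-prevalence stream

Universal bacterial 16S primers co-amplify plastid and mitochondrial 16S
because of their ancient homology with bacterial ribosomal genes. In gut
contents this is information, not contamination: the proportion of a
sample's reads assigned to chloroplast OTUs tracks how much plant
material the animal ingested. The stream needs three things, all in this
package: taxonomic predicates, a quality filter, and rank-based tests.

**Predicates.** A lineage is *chloroplast* when any rank token equals
"chloroplast" (case-insensitive), tolerating truncated lineages and the
unstable rank placement of organellar 16S in reference taxonomies. A
lineage is *bacterial* when its domain rank is "bacteria" — which keeps
chloroplast (and mitochondrial) OTUs through the non-bacterial filter,
deliberately: they are the signal. Mitochondrial OTUs are never counted
as chloroplast, and `filter_spec(drop_mitochondrial = TRUE)` removes
them entirely.

**Filtering.** `filter_feature_table()` applies five steps in a fixed
order: (1) drop non-bacterial OTUs; (2) drop OTUs with fewer than
`min_otu_total = 10` reads overall; (3) zero any per-sample count below
`min_sample_fraction = 0.01%` of that sample's library as it stands
after steps 1–2; (4) drop OTUs left all-zero; (5) drop samples left
under `min_library_size = 500` reads. The order itself is a design
choice — descriptions of such filters rarely pin it down — and two points
were genuinely open:

* *Scope of the 0.01% rule.* We read it per sample (a count is zeroed in
  the sample where it is negligible), matching common phyloseq-style
  practice and keeping the rule well-defined; the alternative global
  reading (drop the OTU everywhere if it clears the floor nowhere) is
  available as `fraction_rule = "global"`.
* *When proportions are computed.* After sample exclusion, so every
  reported proportion refers to a sample that survived quality control.

All thresholds use strict inequalities, mirroring the "fewer than / less
than" phrasing such rules are stated with. Filtering is idempotent and
monotone (stricter thresholds never retain more), and both properties are
tested on randomized tables.

**Tests.** Proportions are compared across diet classes with
`kruskal_wallis()` (midrank tie correction; ties are guaranteed because
carnivore samples sit at exactly 0) and `pairwise_ranksum()`. The
pairwise tests use the exact null distribution when both groups have at
most 8 observations and the pair is tie-free, and otherwise the normal
approximation with tie correction and no continuity correction. The
multiplicity correction is Holm by default: it controls the family-wise
error rate at the same level as Bonferroni while never being less
powerful. Summaries report type-7 (linear-interpolation) quartiles;
published IQRs are convention-dependent, so the convention is fixed and
stated.

## The isotope-mixing stream

With two candidate sources (host-plant leaves, fraction *p*; ant larvae,
fraction 1 − *p*) the consumer's expected ratio is

$$\delta^{15}N_{cons} = p\,\delta^{15}N_{leaves} +
  (1-p)\,\delta^{15}N_{larvae} + \Delta^{15}N,$$

with one discrimination parameter per element, assumed constant across
sources — a deliberate simplification: with group means for the three
roles the model would otherwise be unidentifiable. Discrimination is
genuinely unknown for most insects, so instead of fixing it we solve for
*p*:

$$p = \frac{\delta^{15}N_{cons} - \delta^{15}N_{larvae} -
  \Delta^{15}N}{\delta^{15}N_{leaves} - \delta^{15}N_{larvae}}
  = \text{intercept} + \text{slope}\cdot\Delta^{15}N.$$

`mixing_line()` carries this pair; `fraction_at()` and
`discrimination_at()` read it in both directions. Two policies matter:

* Fractions outside [0, 1] are returned **unclamped** with an
  `out_of_range` flag. The line is a diagnostic over a range of plausible
  discriminations; truncating it would hide exactly the implausibility it
  is meant to expose (e.g. a full-trophic-step Δ of 3.4‰ implying a leaf
  fraction near 1.9).
* Equal source means are an error (`degenerate mixing model`), not an
  NaN: the fraction is unidentifiable and silence would be worse.

`fit_mixing_line()` estimates the line from measured data via role means
and attaches delta-method standard errors: with
$I = (m_c - m_2)/(m_1 - m_2)$ and $S = -1/(m_1 - m_2)$, the partial
derivatives with respect to the three means propagate the means' standard
errors. Display convention: two decimals for line coefficients, one
decimal for implied discriminations; full precision is kept internally.

Group comparisons use the Welch unequal-variance t test by default —
fractional degrees of freedom are the giveaway that reported "Student"
tests on such data are in fact unequal-variance tests — with the pooled
test behind a flag, and a paired mode driven by explicit pairing ids
(consumer and source samples from the same tree), never inferred from
labels. `oneway_anova()` guards the zero-within-variance corner by
reporting a divergent F with p = 0 rather than failing.

`reference_group_means()` ships the published role means of the
motivating system (consumer 3.74/−25.5, leaves 2.13/−28.3, larvae
4.12/−26.5 ‰), from which the worked example reproduces the nitrogen
line 0.19 + 0.50·Δ and carbon line −0.55 + 0.55·Δ and the implied
discriminations 1.6‰ and 2.8‰ at *p* = *q* = 1.

```{r}
gm <- reference_group_means()
nline <- mixing_line(gm$d15N[1], gm$d15N[2], gm$d15N[3], "N",
                     source_labels = c("leaves", "larvae"))
c(intercept = nline$intercept, slope = nline$slope,
  implied = discrimination_at(nline, 1))
```

## What the synthetic data emulate — and what they do not

`generate_feature_table()` draws, per sample: a library size uniform on
15,000–47,000 reads (bracketing realistic MiSeq gut libraries); a true
chloroplast fraction from a per-class distribution — Beta(1.2, 0.9) for
phytophagous and unknown classes, giving the broad ~1–99% spread seen in
real plant-feeder libraries, and a point mass at 0 for aphytophagous
classes; a binomial split of reads between the chloroplast and bacterial
pools around that fraction; and multinomial reads over OTUs with
table-wide Dirichlet weights. A configurable slice of bacterial OTUs is
made rare (about 0.3 expected reads per sample, so their expected total
sits under the 10-read filter for tables up to a few dozen samples), and
a few Archaea/Unassigned OTUs exercise the domain filter. One global
seed governs everything, with per-sample substreams derived from
(seed, class index, sample index) so enlarging one class never reshuffles
existing samples.

The generator does **not** simulate sequencing error, chimeras, PCR bias,
phylogenetic structure among OTUs, or compositional correlation between
taxa. Passing tests therefore demonstrate that the statistics do what
they claim on data satisfying the model's assumptions — not that real
libraries satisfy them.

`generate_isotope_dataset()` is the mixing model run forwards plus
Gaussian noise (default 0.5‰, a typical between-sample spread for bulk
tissue), with per-role counts defaulting to the reference design
(17 consumers, 47 leaves, 20 larvae). With noise at zero the analytic
round trip — generate, fit, read the line at the true Δ — recovers the
true fraction to machine precision, and that is a test, not a remark.

## The combined evidence report

`run_pipeline()` chains simulate (optional) → filter → prevalence →
tests → mixing model → report, writing every intermediate table, a JSON
and Markdown report, and a run log (versions, seeds, thresholds). Every
number in the report is copied from the upstream result object; the
reporting layer computes nothing.

`classify_diet()` turns the two streams into a qualitative call. No
field standard exists for this synthesis, so the rule is an explicit
package convention with every threshold configurable and echoed in the
report: *herbivory-consistent* when the focal class is indistinguishable
from known herbivores (corrected p > α) while differing from known
carnivores (corrected p ≤ α) and any implied Δ¹⁵N at fraction 1 lies in a
plausible range (default 0–4‰, spanning published values from
low-fractionating caterpillars to a full trophic step);
*carnivory-consistent* for the mirrored prevalence pattern; *ambiguous*
otherwise — including whenever the implied discrimination is implausible,
which overrides prevalence in either direction, and whenever data are
insufficient. Default α is 0.05 on corrected p-values.

## Numerical choices and problem sizes

* Exact rank-sum enumeration is the test oracle up to group sizes with
  n₁ + n₂ ≤ 10 (252 labelings at worst); the implementation's exact path
  is capped at 8 per group by default, configurable.
* The null-calibration suite uses 2,000 replicates of three groups of 6
  from a single Beta(1.2, 0.9), checking rejection rates at α = 0.05
  against 99% binomial bounds; large-sample recovery checks use 10,000
  measurements per role. Property suites run on tables of 30 OTUs × 12
  samples across 100 seeds.
* Ties in both rank tests use midranks with the standard tie correction;
  an all-tied pair (two all-zero carnivore classes) short-circuits to
  p = 1 rather than a degenerate normal approximation.
* Seeds are plain integers; derived per-sample seeds stay below 2³¹.

## Known limitations

The two-source model cannot separate sources with similar isotopic
profiles (plant tissue vs. ant regurgitations of plant nectar), and read
proportions are semi-quantitative at best — copy number, digestion rates
and primer bias all distort them. The qualitative call is a reporting
convention, not an estimator with coverage guarantees. Real feature
tables violate the generator's independence assumptions in ways that can
only make the tests' behaviour better-calibrated here than in the field.
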