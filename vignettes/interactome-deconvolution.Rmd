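---
title: "Deconvolving multi-bait interactomes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving multi-bait interactomes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsdecon)
```

## The analytical problem

Affinity-purification mass spectrometry (AP-MS) recovers every protein that
co-purifies with a bait, and chromatin immunoprecipitation MS (ChIP-MS)
recovers every protein sitting on the chromatin fragments the bait occupies.
Neither, on its own, says *which assembly* a prey belongs to. For a hub
subunit shared by several complex variants — the motivating case is a
PCGF-family subunit such as BMI1, present in both canonical PRC1 (with
CBX/PHC subunits) and non-canonical PRC1 (with RYBP in their place, around
the same RING–PCGF core) — attribution requires comparing pull-downs:

* a second bait that defines one variant (RYBP for the non-canonical form),
* a catalytic product (the H2AK119ub histone mark) that proxies enzymatic
  engagement of the complex,
* perturbation of the hub's expression, because true stoichiometric partners
  should follow the hub's abundance,
* and replication across cell lines, so that line-specific passengers can be
  discarded.

`apmsdecon` implements that comparative logic as a pipeline of small,
separately testable operations, and ships a synthetic-data generator whose
ground truth lets every stage be scored.

## Filtering model

Filtering is deliberately presence/absence-based. MS2 spectral intensities
are kept for quantification, but inclusion in an interactor set depends only
on detection patterns:

1. **Detection rule.** A protein is detected in an experiment when it has a
   non-missing intensity in at least `min_runs` of the replicate runs. The
   default is 2 of the 4 runs of a 2-culture x 2-technical-replicate design:
   one run is too permissive for sporadic identifications, all four is
   fragile under dropout. The rule is exposed because reasonable analyses
   differ here.
2. **Mock subtraction.** Any protein detected in *any* no-antibody mock run
   of the matching cell line and condition is removed. Mocks capture
   bead-binding background, and bead binders can be abundant, so an
   intensity-ratio rule would let strong binders through; the strict binary
   rule is the conservative reading and an intensity-based alternative is
   deliberately not offered.
3. **Contaminant-repository filter.** Proteins whose detection frequency
   across negative-control AP-MS runs (a CRAPome-style frequency table)
   exceeds `max_freq` are removed; proteins absent from the table are kept.
   The default cutoff of 0.10 removes proteins seen in more than one in ten
   control runs — a common working threshold for such repositories — and is
   configurable.

Both filters are idempotent, subset-preserving and (for the frequency
filter) monotone in the threshold; the test suite asserts these properties
on a thousand random instances, and each `interactor_set` carries a
provenance record of what each filter removed.

## Modulation quantification

For the hub bait, the pipeline quantifies how each prey responds when hub
expression is increased in one line and decreased in the other:

* **Normalization** (`none`, `total`, `median`) rescales each sample so the
  chosen statistic of its detected intensities is equal across samples.
  The default is `none`: the generator produces samples on a common scale,
  and total-signal normalization is actively harmful when a large fraction
  of preys genuinely changes with the hub, as it absorbs the effect being
  measured. With real instrument drift, `total` or `median` should be used.
* **Replicate averaging** is the arithmetic mean over the runs of one
  (bait, line, condition) experiment. Missing values default to
  *impute-floor*: a missing run contributes the detection floor
  (`floor = 1` intensity unit), so a prey detected in half its runs is
  penalized rather than credited with its detected mean. `ignore-missing`
  is available for designs where dropout is uninformative.
* **Fold-change** is `log2((mean_mod + pseudo) / (mean_ctrl + pseudo))` with
  `pseudo = 1`. Intensities are of order 10^6, so the pseudocount's only
  role is keeping fully absent preys finite; its distortion is negligible.
* **Significance.** Per prey, a fixed-effects two-way ANOVA (cell line x
  genotype condition, with interaction) is fitted to the replicate-level
  log2 intensities, and the genotype main-effect p-value is reported.
  Log-transformation reflects the multiplicative noise model. When the
  residual variance is numerically zero the p-value is returned as a
  flagged `NA`, never silently 0 or 1. One caveat is intrinsic to the
  design: a perfectly *concordant* response (up in the overexpression line,
  down in the knockdown line) is antisymmetric across lines, so it loads on
  the line x genotype interaction rather than the genotype main effect.
  The main-effect p is therefore reported as supporting evidence and the
  default classification is sign-based (`alpha = NULL`); switching `alpha`
  on gates concordance calls conservatively.
* **Concordance classes.** With thresholds `fc_min` (default 0) and the
  optional `alpha`: *concordant* means `log2fc_up > fc_min` and
  `log2fc_down < -fc_min`; *discordant* means both fold-changes exceed
  `fc_min` in magnitude with the same sign; everything else — including
  ties at exactly `fc_min`, the opposite antisymmetric pattern, and preys
  with missing fold-changes — is *unchanged*. The tie-to-unchanged rule is
  the conservative choice: with `fc_min = 0` it means a prey whose means
  are exactly equal is never called modulated.

## Set deconvolution

All multi-list reasoning goes through one primitive, `venn_report()`, which
computes the full `2^k - 1` exclusive regions of k sets. Regions are
disjoint and cover the union, which the suite verifies against per-element
enumeration; because the regions are disjoint, membership categories map
one-to-one onto regions and no precedence rules are needed.

The canonical workflow is: per bait, intersect the two cell lines and keep
the shared proteins (`intersect_lines`) — cross-line sharing is required
before any bait comparison, since line-exclusive preys cannot be
distinguished from line idiosyncrasies; then compare the hub's shared
interactome with the discriminating bait's (`compare_baits`), giving
`canonical_only`, `shared_core` and `noncanonical_only`; in the chromatome
arm, partition hub / partner / catalytic-mark datasets
(`chromatome_partition`), where hub-and-mark co-occurrence defines
`chromatome_catalytic` and hub-exclusive occupancy defines
`chromatome_independent`. Proteins of the analysis universe (by default the
union of all post-filter sets) that fall in no category are labelled
`bait_independent_unassigned` rather than being silently dropped: mixed or
inconsistent evidence (e.g. a protein seen in one line's proteome and only
the other line's chromatome) deliberately lands in this bucket instead of a
complex category.

`recovery_metrics()` scores an assignment against simulated ground truth as
per-category precision and recall; an empty category yields a flagged `NA`
precision, not zero.

## Overlap statistics

Overlap of a query set with a reference list in a universe of size N is
tested with the upper-tail hypergeometric probability P(X >= k), including
the observed overlap — the standard over-representation convention, so
k = 0 always gives p = 1 and p is never 0. The two-sided Fisher test on a
2x2 table uses the minimum-likelihood rule (sum all tables with the same
margins whose point probability does not exceed the observed one). Both
reduce to `stats` distribution functions, which are computed in log space
and stable far beyond the set sizes seen here; the suite nevertheless
verifies them exhaustively against direct combinatorial enumeration (all
N <= 60 for the hypergeometric tail; all tables with total <= 40 for
Fisher). Benjamini–Hochberg adjustment is the usual step-up, checked
against a literal O(m^2) implementation of its definition.

For differential-exon-usage (DEU) tables, exon-level raw p-values are
BH-adjusted across all exons, a gene counts as a DEU gene when any of its
exons passes `alpha = 0.05` (each gene once), and the DEU gene set is
tested against each reference collection. The universe defaults to all
genes present in the DEU table — published overlap claims rarely state
their universe, and the p-value is meaningless without one, so the chosen
universe is always echoed in the output rather than guessed to match any
external figure.

## The synthetic generator

`simulate_interactome()` emulates the replicate design the analysis
assumes: 2 cell lines x {control, modulated} x a bait panel including a
mock x 2 independent cultures x 2 technical replicates, one sample column
per run. Its statistical structure:

* **Intensities** are log-normal around a per-protein baseline
  (`baseline_log_intensity_mean = 20` log2 units, i.e. ~10^6, with
  between-protein sd 1), with per-measurement log2 noise
  (`log_noise_sd = 0.5`). MS2 intensity distributions are right-skewed and
  strictly positive, and the analysis averages raw intensities, so the
  generator must produce positively skewed values.
* **Detection** is structural: complex members appear in the pull-downs of
  their detecting baits; contaminants appear in every run — mocks included —
  with probability 0.5 per run; unaffiliated background proteins appear
  sporadically (probability 0.05 per non-mock run) at low abundance.
  "Not detected" is an explicit missing value, never zero.
* **Dropout** removes measurements below `dropout_threshold = 1000`
  intensity units, mimicking the detection limit.
* **Modulation** multiplies hub-coupled members by 4 in the modulated
  overexpression line and by 0.25 in the modulated knockdown line. The
  magnitude of a stoichiometric partner's response is not something the
  motivating experiments pin down; 4-fold was chosen once as an effect
  comfortably detectable at 4 replicate runs with 0.5 log2-units of noise,
  and is a free parameter.
* **Determinism**: a single seed drives one generator pass in a fixed
  order, so a seed reproduces an experiment byte-for-byte, and seeds that
  share structure parameters share their ground truth exactly.

The default experiment (`default_simulation_config()`) plants 500 proteins:
a 105-member hub-exclusive canonical-complex module and a 30-member shared
core (both hub-coupled, the core also recovered by the partner bait and the
catalytic mark), an 80-member partner-exclusive non-canonical module
(uncoupled), 50 contaminants and 285 background proteins. The module sizes
mirror the scale of published PRC1-variant interactomes; the core is
hub-coupled because structural subunits of a complex are expected to follow
the hub's stoichiometry.

What the generator does **not** emulate: peptide-level identification and
inference, correlated (batch) noise between samples, intensity-dependent
dropout curves, ratio compression, misidentified proteins, or preys shared
between complexes. Passing recovery tests therefore demonstrate that the
pipeline's logic is correct under its own assumptions — clean design,
independent log-normal noise — not that real chromatome data will be
recovered at the same rates.

## Problem sizes and numerical choices in the test suite

The suite runs entirely from generated data: the exhaustive oracle sweeps
above; ANOVA type-I calibration from 5000 uncoupled preys in one simulated
null experiment (rejection at nominal alpha = 0.05 asserted within +/-
0.02); power from 1000 independent realizations of a 4-fold same-direction
genotype effect at 0.1 log2-noise; and end-to-end recovery on the default
500-protein experiment, where membership precision and recall for the
canonical and shared-core categories and the recall of planted coupled
preys as "concordant" must all clear 0.9/0.95. These sizes were chosen so
the full suite runs in about a minute and a half while keeping Monte-Carlo
error well inside the asserted bands.

## Known limitations

* Quantification is protein-level MS2 intensity only; no peptide models,
  no empirical-Bayes variance moderation, and no multiple-testing
  correction at the concordance stage (BH is available in the overlap
  module where families of tests arise).
* The genotype main-effect ANOVA is insensitive to perfectly antisymmetric
  concordant responses (see above); sign-based classification carries that
  information instead.
* Identifiers are opaque strings; no mapping between accession types is
  attempted.
* The contaminant filter reimplements repository frequency logic but does
  not query any live service.
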