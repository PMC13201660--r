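---
title: "Methods: quantifying pre-rRNA processing from single-reference long reads"
author: "riboslicer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying pre-rRNA processing from single-reference long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboslicer)
```

## The measurement model

All analyses in this package rest on one observation: when long reads are
aligned against a single rDNA transcription-unit reference (a 47S/45SN1-like
sequence), the aligned start and end of a read are direct estimates of the 5'
and 3' ends of the sequenced RNA molecule. Because pre-rRNA maturation
consists of cleavages at defined positions and processive exonucleolytic
trimming, the joint distribution of (start, end) pairs is highly structured:
abundant intermediates concentrate at their literature boundary pairs,
cleavage sites appear as marginal spikes of read starts or ends, and
one-nucleotide trimming produces lines of adjacent boundary pairs.

The package assumes alignment has already been done (e.g. minimap2 against
the single reference), that reads derive from the forward strand of the
transcription unit, and that the aligned span -- not soft-clipped bases --
represents the molecule. Reverse-strand and secondary/supplementary
alignments are excluded at ingestion and counted.

Coordinates are 1-based and inclusive throughout the user-visible surface,
the native convention of the IRanges/GenomicRanges containers the package is
built on; BED and bedGraph exports convert to 0-based half-open at the I/O
boundary, as those formats require.

## Supervised assignment: minimal reciprocal overlap

A read span $r$ and a template span $t$ with overlap $O$ score

$$\mathrm{MRO}(r, t) = \min\left(\frac{O}{|r|}, \frac{O}{|t|}\right),$$

which is 1 only when the intervals coincide and 0 when they are disjoint.
Taking the minimum of the two reciprocal fractions penalises both reads much
shorter than the template and reads extending far beyond it, so a truncated
28S fragment is not swallowed by 47S, and a 30S-sized read is not credited
to 18S. Each read is assigned wholly to the argmax template (no fractional
EM-style assignment): the quantities of interest are molecule counts, and
the boundary pairs of the catalogued species are distinct enough that the
argmax is nearly always unambiguous.

Two numerical choices make the assignment deterministic:

* **Ties** (identical MRO against several templates) go first to the
  template whose length is closest to the read's, then to the
  lexicographically smallest name. Ties occur for reads symmetric between
  two templates and for duplicated catalogue intervals; any fixed rule
  works, this one favours the template that explains the read's length.
* **Minimum score**: any MRO > 0 assigns by default (`minMro = 0`). There
  is no natural floor -- a heavily trimmed fragment legitimately scores low
  against its precursor -- but the parameter is exposed for stricter runs.

Abundances are reported as reads per million aligned reads, the denominator
including unassigned reads so that counts partition the total. For log10
heatmap values a pseudocount of 1 RPM is added, keeping species with zero
reads finite. Replicate summaries report log10 of the replicate-mean RPM by
default; the alternative (mean of per-replicate log10 values) is available
via `summariseAbundance(average = "mean_of_log10")` — with three replicates
and well-covered species the two differ negligibly, and the default keeps
the heatmap value interpretable as a transformed mean abundance. Condition
comparisons use a two-sided Welch t-test on replicate RPM values with
Benjamini-Hochberg adjustment: a plain, assumption-light test appropriate
for n = 3 replicate designs; count-model alternatives (negative binomial)
would need dispersion sharing across a 30-species catalogue and offer
little at these effect sizes.

## The template catalogue

`defaultTemplates()` ships the 45SN1 catalogue: precursors (47S, 45S, 30S,
26S, 21S, 21S-C, 18S-E, 32S, 12S, 7S, and the newly-described 47S-01 /
47S-02 species), mature rRNAs, spacer fragments, aberrant species (34S,
36S, 36S-C) and the 18S-E 3'-extension series. Processing-site coordinates
(`processingSites()`) follow the single-nucleotide refinements of the
thirteen known human sites (01, A0, 1, 3, E, C, 2, B1, 4', 4a, 4, 3', 02);
where a site has several reported endpoints the principal one is recorded.
Species whose exact ends are not published (spacer fragments, the aberrant
species, 32S/12S/7S interiors) carry coordinates derived once from the site
catalogue and standard processing topology; the 21S_S/21S_L isoform ends
are provisional placeholders at the two edges of the C-site region.

One coordinate choice deserves note. The 18S-E extension series (+10, +24,
+36, +40, +78) is validated to end exactly those offsets past the 18S-E
3' end, and reads ending k nt past the 18S 3' boundary must route to the
corresponding +k member. Both constraints hold simultaneously only if
18S-E's own 3' end essentially coincides with the 18S 3' end, so the
catalogue places 18S-E one nucleotide past 18S -- distinct intervals, and
the argmax assignment still lands reads ending at 18S+k on member +k (the
one-nucleotide offset costs < 0.1% of MRO, far less than the gap to the
neighbouring members at 10-14 nt spacing).

Hubs discovered by the unsupervised analysis can be promoted into the
catalogue with `extendWithHubs()`; automatic names are
`novel_<start>_<end>` (deterministic, coordinate-addressable), user labels
override them, and re-promoting an already-catalogued interval is a no-op
so the operation is idempotent.

## Unsupervised analysis: the intensity matrix

`buildMatrix()` increments one cell per read at its (start, end) pair. The
conceptual object is a reference-length-squared matrix (~1.8e8 cells for
13,351 nt); only occupied cells are stored -- a few hundred to a few
thousand in practice.

**Hubs.** Occupied cells within Chebyshev distance `mergeRadius` (default
3 nt) are single-linkage clustered; clusters totalling at least `minReads`
(default 10) reads become hubs. The 3-nt radius absorbs the boundary
wobble of minor species whose ends are estimates, while keeping the
18S-E extension ladder (10+ nt spacing) unmerged. The hub apex is the
modal cell, ties resolved to the smallest (start, end) pair. Each hub is
annotated with the nearest processing site on each axis *as a distance,
not a cutoff*: closeness to a known site is evidence, not a filter, so
novel species remain visible.

**Display normalisation.** Counts are min-max scaled, then contrast-
enhanced by clipping at the 2nd/98th percentiles of occupied-cell values
and rescaling (`contrastPct = 2`; 0 disables). Percentile clipping over
occupied cells only is the concrete reading of "2% contrast enhancement":
it saturates the handful of dominant hubs so trails and minor hubs become
visible. A constant matrix maps to zero (degenerate-range guard), and an
empty matrix renders with a warning.

**Trails and pauses.** `extractTrails()` reads out one row (fixed end,
5'->3' trimming) or column (fixed start, 3'->5') of the matrix and flags
pause positions: strict local maxima at least `prominence` (default 2)
times the larger immediate neighbour. On a decaying trail this fires only
where an exonuclease stalls; on noise-free geometric decay it never fires.

**Overlays.** Per-condition matrices are rendered independently, coloured,
and composited with screen blending, so single-condition regions keep the
pure condition colour and shared regions blend -- the nuclear/cytoplasmic
(or nucleolar/nucleoplasmic/cytoplasmic) contrast reads directly off the
image.

## Cleavage-site statistics

Start and end boundary counts are accumulated separately along the
reference (they are never pooled: a position can be an end-generating site
on one side of a cleavage and a start-generating site for the downstream
product). Within each template interval the mean and **sample** standard
deviation (n-1) of the counts form a threshold mean + k·SD (k = 2); a
position is called when its count reaches the threshold *and* the SD is
positive — the guard excludes degenerate uniform intervals where every
position would otherwise qualify. The interval-local baseline follows from
the rule being defined per intermediate; positions inside several
overlapping intervals use the mean of the covering templates' means and
the mean of their SDs, and positions outside every interval fall back to a
whole-reference baseline so the rule is total. Length-1 intervals are
skipped (SD undefined) with a warning. The threshold comparison is
inclusive (">= mean + 2SD"), matching the "at least two standard
deviations" phrasing.

Replicate consensus keeps a (position, kind) pair present in at least
`minReplicates` of the replicate call lists (default 2 of 3). Both rules
are monotone: raising k or the replicate requirement can only shrink the
call set, a property the test suite asserts.

## Modification stoichiometry

A base is called modified on a read when its MM/ML-decoded probability is
at least 0.95 (inclusive at the boundary, as at every threshold in the
package). Site stoichiometry is the modified fraction among covering reads
that carry a probability record -- reads without a record (e.g. the site
deleted in that read) do not dilute the ratio, and an empty denominator
yields NA, never 0.

The site-level filter removes sites whose ratio stays below 10% in *every*
condition; a site reaching 10% anywhere is retained. The alternative
reading (filter each condition independently) is available via
`filterSites(mode = "each")`; the retain-if-any default is the one under
which an unmodified IVT control contributes no sites of its own while true
sites hypomodified in one compartment survive.

The U-to-C mismatch ratio -- an orthogonal pseudouridine signature arising
from basecalling errors at isomerised uridines -- is computed at
reference-U positions as C calls over (coverage minus deletions): a
deleted base expresses no identity, so it is excluded from the
denominator.

Per-precursor stoichiometry recomputes the site ratios over each
template's assigned reads, giving the precursor-by-site matrices used for
modification heatmaps; sites outside a precursor's interval are NA for
that row, and the "all" row over every read equals the coverage-weighted
mean of the per-precursor rows.

Raw-signal evidence enters through a per-read table of z-normalised mean
current values at offsets -10..+10 around a locus (the output contract of
signal-space resquiggling); `signalWindowSummary()` reports, per offset,
the mean over reads and semi-standard deviations computed separately from
values below and above that mean -- an asymmetric error bar suited to the
skewed current shifts modifications cause. Resquiggling itself is out of
scope: the package consumes its tabular output, keeping the statistics
testable on synthetic signal.

Coverage: no minimum is inherent to the ratio, but sites with fewer than
`minCoverage` (default 30) covering reads are flagged low-coverage so
downstream heatmaps can grey them out.

## The synthetic-data generator

`simulateReads()` emulates exactly the structure the analyses exploit:
reads sample a template by proportion; both boundaries get rounded
Gaussian jitter (truncated to keep spans valid); a configurable fraction
of reads has one boundary retracted into the template by a geometric
number of nucleotides, reproducing one-nucleotide exonucleolytic trails
(3' retraction by default -- the exosome direction -- or 5', or a coin
flip); a background fraction is uniform random fragments; reads spanning a
planted deletion acquire it. `simulateModifications()` plants per-site
stoichiometries: covering reads are modified Bernoulli(stoichiometry),
with probabilities from clipped Normal(0.99, 0.02) (modified) or
Normal(0.02, 0.02) (unmodified) -- cleanly straddling the 0.95 threshold
the way a well-separated basecaller does -- and optionally a fraction of
modified reads basecalled C at U sites. `simulateKnockdown()` multiplies
control proportions by per-template fold changes, renormalises, and
derives per-replicate seeds from the master seed by a fixed integer mix,
so every replicate is individually reproducible and a fixed configuration
is byte-identical down to the SAM output.

What the generator does **not** emulate: sequencing errors beyond planted
mismatches and deletions, basecaller-specific probability distributions,
raw current, coverage bias along the molecule, or reverse-strand and
multi-reference artefacts. Passing tests therefore demonstrate that the
algorithms recover planted structure through the SAM/BAM interface at
realistic scales -- not that any particular basecaller meets the
Normal(0.99, 0.02) separation. One SAM-format consequence is documented in
`writeSam()`: MM-tag positions index occurrences of the canonical base in
the read sequence, so a read basecalled C at a modified U cannot carry its
probability record through SAM; the in-memory pipeline keeps both kinds of
evidence.

## Problem sizes and numerical conventions in the test suite

The suite exercises the pipeline at desk scale, chosen to make binomial
error bounds tight while keeping runs fast: proportion recovery at 10,000-
30,000 reads (3-SD binomial bounds), stoichiometry recovery at 500x
coverage across stoichiometries 0-1, hub recovery with 15 planted hubs at
jitter SD half the merge radius, the full 104-site pseudouridine catalogue
(42 in 18S, 60 in 28S, 2 in 5.8S) at 500x coverage against an IVT control,
and 13-site boundary-peak recovery at 60 reads per site over a 400-read
uniform background (>= 20-fold local enrichment) in three replicates.
Brute-force oracles (interval-membership coverage, per-read MRO argmax
scans, per-interval mean/SD scans, the Rsamtools pileup engine) provide
independent answers wherever the implementation takes a vectorised or
pooled shortcut. Seeds are fixed in tests; all randomness flows through
the configuration seed.

## Known limitations

* Single reference only: no multi-copy rDNA or genome-wide mode.
* Each read contributes wholly to one template; near-duplicate catalogue
  intervals (18S vs 18S-E, the 21S isoforms) therefore split reads by the
  tie-break rather than sharing them.
* Cleavage-site calling inherits the template catalogue: a site inside no
  interval is judged against the whole-reference baseline, which is
  conservative where coverage varies strongly.
* Modification analysis requires MM/ML tags or basecall mismatches;
  modifications invisible to both are out of reach.
* The hub-site annotation reports distances only; deciding whether a hub
  *is* a known site remains with the analyst.
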