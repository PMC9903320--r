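---
title: "Comparing tandem mass spectrometry datasets with ms2dist"
author: "ms2dist authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing tandem mass spectrometry datasets with ms2dist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms2dist)
```

`ms2dist` computes a symmetric distance between sets of tandem mass
spectra (MS/MS), such as two LC-MS/MS runs, and builds phylogenetic trees
from many such distances. The premise is that proteome-wide MS/MS data
carry a strong species signal: conserved tryptic peptides fragment into
near-identical spectra across related species, so the fraction of spectra
a pair of datasets shares decreases with evolutionary divergence. Because
the comparison is spectrum-to-spectrum, no protein database, search
engine, or identification step is involved.

This vignette is the package's account of the model, its parameters, the
numerical choices made where the design was genuinely open, and what the
synthetic data used by the tests can and cannot show.

## The similarity model

### Pairs of spectra

Each spectrum is mapped to a sparse non-negative vector:

1. **Noise removal.** Peaks with intensity below the noise floor are
   dropped. The floor is absolute by default (10 intensity units, matching
   the tool's standard parameter set). If the absolute floor is unset
   (`noise_floor = NA`), a relative floor is applied instead: `noise ×
   10⁻³` of the base peak. A relative rule has to be defined somewhere for
   an "automatic" mode to be reproducible; this one is deliberately simple
   and documented so an independent implementation can mirror it.
2. **Scaling.** Surviving intensities are raised to `scaling_exponent`
   (default 0.5, i.e. square root; 1/3 gives cube root, 1 leaves raw
   intensities). Square-root scaling damps the dominance of a few intense
   fragment ions, a standard practice in spectral matching.
3. **Binning.** Each peak joins bin `floor(mz / bin_width)` and weights
   within a bin are summed. No peak is split across neighbouring bins; the
   rule is deterministic and cheap, and any boundary effect is far smaller
   than the bin width itself. The default width of 0.2 Th is compatible
   with ion-trap fragment mass accuracy; with high-resolution Orbitrap
   fragments a narrower bin is appropriate, which is why the width is an
   exposed parameter rather than a constant — it materially affects the
   score.
4. **Normalisation.** The vector is scaled to unit Euclidean length. A
   spectrum whose peaks all fall below the noise floor yields the zero
   vector, which scores 0 against everything; comparison stays total
   rather than erroring mid-run.

Two vectorised spectra are scored by the **cosine score** `s = â · b̂ ∈
[0, 1]` (the default) or the **spectral angle**, rescaled to the same
interval as `1 − 2·arccos(s)/π` so that identical spectra score 1 and
orthogonal spectra 0 under both measures, and one `s_min` threshold is
interpretable for either. The rescaling is a package choice; the angle is
a strictly monotone function of the cosine, so thresholding either
measure selects nested sets of pairs.

Noise removal happens before binning (removal after binning would let
many sub-threshold peaks accumulate into a spurious bin weight). Both
scores are symmetric, bounded in `[0, 1]`, and invariant to scaling all
intensities of either spectrum by any positive factor — co-directional
spectra are *identical* to this metric, by design: absolute MS/MS
intensities depend on when during the chromatographic peak the ion was
sampled, which is not reproducible.

```{r pair-scores}
a <- cbind(mz = c(100, 200), intensity = c(9, 16))
b <- cbind(mz = 100, intensity = 25)
p <- similarity_params(scaling_exponent = 1, noise_floor = 0)
spectrum_similarity(a, a, p)   # identical: 1
spectrum_similarity(a, b, p)   # shared 100-bin only
```

### Sets of spectra

For datasets 𝒜 and ℬ, spectrum `a ∈ 𝒜` is *matched* when some `b ∈ ℬ`
inside the comparison window satisfies `s(a, b) ≥ s_min` (threshold
inclusive; default 0.8). The global similarity averages the two matched
fractions,

$$S = \frac{1}{2}\left(\frac{|\mathcal{A}_\mathcal{B}|}{|\mathcal{A}|} +
\frac{|\mathcal{B}_\mathcal{A}|}{|\mathcal{B}|}\right),$$

which is symmetric in the inputs — the property that distinguishes this
metric from the earlier directional scan of one set against the other.
The distance is

$$D = \frac{1}{S} - 1 \quad (S > 0).$$

When no spectra match at all, `S = 0` and `1/S` diverges, so the
distance is kept finite through the smallest *positive* similarity the
two sets could have had — exactly one matched pair,
`S_minpos = (1/|𝒜| + 1/|ℬ|)/2` — halved:

$$D_{S=0} = \frac{1}{S_{\text{minpos}}/2} - 1,$$

i.e. the sets are treated as sharing a hypothetical half matching
spectrum, which is strictly worse than any real match. Two singleton
sets therefore sit at `D = 0` when similar and `D = 1` when not:

```{r floors}
global_distance(1)           # identical sets
global_distance(0, 1, 1)     # dissimilar singletons
global_distance(0, 10, 40)   # the finite floor grows with set size
```

**Undefined values.** The similarity of an empty set — an LC-MS/MS run
with no tandem spectra, which usually means the measurement failed — is
left undefined rather than imputed. `NA` propagates from `S` to `D` to
the distance matrix, is written to files as the literal `UNDEFINED` (or
the `?` missing symbol in MEGA output), and only the tree-building step
excludes the affected taxa, with a log entry. Imputation, if wanted, can
always happen downstream.

### Windowed candidate search

Scoring all `|𝒜|·|ℬ|` spectrum pairs is expensive for runs with tens of
thousands of spectra. Matching therefore only evaluates pairs inside a
**comparison window**: precursor m/z difference at most 2.05 Th (two
neutrons at charge 1, covering common isotope-selection errors), and
retention time difference at most 60 s when both spectra carry retention
times, otherwise scan-number difference at most 10000. When a spectrum
has neither coordinate the chromatographic constraint is waived — a file
converted without retention times should not silently match nothing. RT
takes precedence over scan number because it is comparable across
instruments; scan difference is the fallback.

The implementation sorts one dataset by precursor m/z and scans a
sliding interval, which provably evaluates exactly the window-passing
pairs: the result is identical to brute-force enumeration (the test
suite asserts this against an independent dense-algebra oracle on
hundreds of random pairs), only faster. Shrinking any window bound can
only remove candidate pairs, so matched counts are monotone in the
window — also asserted as a property.

### The diagnostic histogram

Every *evaluated* pair (i.e. every window-passing pair, matched or not)
contributes one count to a 2-D histogram of signed precursor m/z
difference (`mz(b) − mz(a)`) by similarity, with 0.01-wide bins on both
axes by default — fine enough to resolve the side bands at 1/2 and 1/3 Da
that isotope-selection errors produce at charge 2 and 3. The histogram
reveals charge states, isotope errors and mass precision *before* any
database search, and can guide the choice of m/z window and `s_min`.
Pairs rejected by the window never reach the histogram; including them
would swamp the structure near zero with the unconstrained bulk.

## From comparisons to trees

Sample-level distances are combined per species pair by the arithmetic
mean (an unweighted average over replicate run pairs; `min` is exposed
as an alternative for heterogeneous replicates). Intra-species distances
are computed and reported per pair but excluded from the species matrix,
whose diagonal is 0 by convention. Undefined sample pairs are dropped
from the mean with a log note; a species pair with *no* defined
comparison stays `UNDEFINED` with a warning.

The species matrix becomes a rooted tree by **UPGMA**: repeatedly merge
the closest pair of clusters, place the merged node at height `d/2`, and
set the merged cluster's distance to every other cluster to the
size-weighted average of its members' distances (true UPGMA, not WPGMA
— the unweighted variant is what the downstream phylogenetics tools
assume). Equal-distance ties are broken by the lexicographically
smallest pair of cluster representative labels, making the output
deterministic and testable; the tie-break only matters on exactly-equal
distances, which real data essentially never produce. Every output tree
is ultrametric — all root-to-leaf paths equal — which the suite asserts
to 10⁻⁹, and agreement with average-linkage `hclust` is asserted on
random matrices up to 8 taxa.

Leaves carry a QC value (default: spectrum count per species, summed
over member samples) plus its min–max position on a `[0, 1]` colour
scale; when all leaves tie, the position is 0.5 by convention (display
only, and it avoids 0/0). The annotation travels as bracketed Newick
comments plus a sidecar TSV, so tools that choke on comments can use the
plain tree.

## The pipeline

`compare_ms2()` reads a directory of MGF files (every file is parsed —
and thus format-checked — before the first comparison starts), applies
the filters, schedules `(N² − N)/2` unordered comparisons for the
symmetric metric (or `N² − N` directed ones for the directional mode),
and commits results row-major: all comparisons of dataset *i* against
datasets `1..i−1` form row *i*. After each completed row a checkpoint
matrix (and tree, once distances are defined) over the completed
datasets is written, so an interrupted run of hundreds of files still
leaves usable artifacts, and each checkpoint is a restriction of the
final matrix to the completed labels (asserted in the tests). The
default *smallest-largest-first* order sorts datasets by ascending
spectrum count, so the cheapest rows complete first and feedback arrives
early; the final matrix is identical under every order, which the suite
asserts for all three.

The directional mode scores each unordered pair once and derives both
directed matched fractions from the same evaluated pairs; the directed
distance applies the same `1/f − 1` transform (floor `2n − 1` at zero).
This is a documented matched-fraction variant, not a re-implementation
of the historical asymmetric formula, and both strictly triangular
matrices are emitted so they can be averaged downstream.

### MGF dialect and filters

The reader accepts `TITLE`, `PEPMASS` (first token = precursor m/z; an
optional second intensity token is ignored), `CHARGE` (`2+`, `+2`, `2`),
`RTINSECONDS` and `SCANS`, ignores unknown keys with a note, tolerates
Windows line endings, and fails with file and line number on structural
errors (unclosed block, non-numeric peak line). This matches what
msconvert and vendor exporters emit. All filter thresholds are inclusive
(`≥`, closed intervals) — "minimum base peak 10000" means 10000 passes —
and spectra lacking a retention time or scan number pass the
corresponding range filter rather than being silently discarded. The
top-N filter ranks by total ion current (the natural "most intense
spectrum" notion for whole-spectrum comparison; base peak would reward
single-spike spectra), breaks ties by file order, and returns survivors
in file order.

## The synthetic-data generator

Real cross-species runs contain 40000+ spectra each and live in public
repositories; the package's tests instead generate data. A synthetic
"peptidoform" is a random peak list template (60 peaks, log-normal
intensities, random precursor in 400–1400 Th, random retention time);
one acquisition of it adds small m/z jitter (σ 0.002 Th), multiplicative
intensity noise, precursor and RT jitter, and a handful of sub-noise
peaks. Jittered copies of one template score ≥ 0.95 by construction, so
they match at the default `s_min = 0.8`.

`make_dataset_pair()` plants a known shared fraction *f*: that fraction
of each dataset derives from common templates, the rest from
dataset-unique templates in disjoint precursor ranges that the 2.05 Th
window can never pair up. The expected similarity is then *f* itself and
the expected distance `1/f − 1`. `make_species_panel()` extends this to
a ladder (caterpillar) phylogeny via nested clade template pools: the
fraction of templates two species share is a decreasing function of the
depth of their most recent common ancestor (20% at the root to 80% for
the closest pair, interpolated linearly), so expected distances depend
only on that ancestor and UPGMA can recover the planted topology
exactly.

The generator reproduces the *statistics* the metric consumes — peak
multiplicity, intensity spread, precursor distribution, chromatographic
coordinates, controlled overlap. It does **not** simulate peptide
fragmentation chemistry, chimeric (cofragmented) spectra, charge-state
dependent fragment series, or systematic retention-time drift between
runs. Passing tests therefore demonstrate that the implementation
computes the defined metric correctly and recovers planted structure;
they do not demonstrate species resolution on real instruments — that
depends on data quality and parameter choices the histogram diagnostic
is meant to inform.

Test and example problem sizes are chosen to exercise the estimators at
meaningful scale while keeping the suite quick: the fraction-recovery
check uses 1000 spectra per dataset (recovering planted *f* within
±0.05), the topology check a 5-species × 2-replicate panel of
100-spectrum samples, and the brute-force equivalence check hundreds of
pairs of up to 50 spectra.

```{r recovery}
pair <- make_dataset_pair(n_spectra = 300, shared_fraction = 0.25,
                          seed = 42)
tidy(compare_datasets(pair$a, pair$b, histogram = FALSE))[, c("S", "D")]
```

## Numerical and degenerate-input choices

* Thresholds are inclusive everywhere (`s ≥ s_min`, closed filter
  intervals, `≤` window bounds).
* Binned vectors are normalised to unit length within 10⁻⁹; zero vectors
  are legal and score 0.
* Dot products are clamped to `[0, 1]` before `arccos` to absorb
  floating-point overshoot.
* Branch lengths and distances serialise with 15 significant digits
  (Newick) and 6 significant digits (MEGA, the format's customary
  precision; round-trip fidelity at that precision is asserted).
* Empty datasets, all-noise spectra, all-equal QC values, and all-equal
  distance matrices all take defined, documented paths rather than
  erroring: `UNDEFINED` sentinels, zero vectors, mid-scale positions,
  and lexicographic tie-breaks respectively.
* `upgma()` refuses matrices with `UNDEFINED` entries and says to
  exclude or impute first; `compare_ms2()` automates the exclusion by
  dropping the fewest species needed to clear them.

## Known limitations

* The metric is not a mathematical metric: co-directional spectra are
  indistinguishable after normalisation (by design), so `D = 0` does not
  imply identical input files.
* Distances from very small sets are coarse — with singletons, `D` can
  only be 0 or 1 — and the `S = 0` floor depends on set sizes, so
  filtering choices shift absolute distances (not orderings within a
  consistently-filtered study).
* One spectrum may match many, and matching is not transitive; matched
  *fractions* are robust to this, but the per-pair histogram will show
  chimera-driven off-diagonal similarity on real data.
* UPGMA assumes a constant divergence rate (ultrametricity); with
  strongly rate-varying proteome evolution the recovered topology can
  differ from the true species tree even when distances are computed
  perfectly.
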