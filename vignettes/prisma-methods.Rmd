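---
title: "Peptide-matrix interaction screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-matrix interaction screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prisma)
```

## The screening model

A protein interaction screen on a peptide matrix (PRISMA) deconstructs a
bait protein into short overlapping peptides, spot-synthesized on a solid
support. Here the default geometry is 14-residue peptides shifted by 4
residues, so consecutive spots share 10 residues; a C-anchored tail tile
guarantees that the last residues are covered. Because a short linear motif
(SLiM) recognized by an interactor is usually shorter than one tile, a
genuine binder produces signal on *several adjacent* tiles: maximal on the
spot presenting the optimal motif plus flanking context and attenuated on
neighbors where the motif is shifted or truncated. Spots carrying
post-translationally modified residues (phospho-S/T/Y, acetyl-K, methyl-K/R,
citrulline-R) probe modification-dependent binding; a modified spot has the
same coordinates as its unmodified parent spot.

After incubation with a nuclear extract, proteins on each excised spot are
quantified by mass spectrometry, giving a protein x spot intensity table
per replicate. Everything upstream of those tables (acquisition, spectral
search, protein inference) is out of scope here; the package starts from
the intensity tables.

## The filter chain

Four stages, in a fixed order, each idempotent on its own output:

1. **Integration.** Two replicates are merged per (protein, spot) as the
   mean of the *detected* (nonzero) values. Detection in both replicates
   is labelled `double` (high confidence), in one `single`, in neither
   `absent`. Averaging only the detected values preserves the intensity
   scale; reproducibility is rewarded through the confidence label rather
   than by halving singly-detected signals.
2. **Normalization.** Each protein's profile is divided by its maximum
   across all matrix spots, so profiles range over [0, 1] and every
   detected profile peaks at exactly 1. This removes abundance differences
   between proteins (which span several orders of magnitude in a nuclear
   extract) before profiles are compared or accumulated.
3. **Outlier filtering.** Many proteins additionally bind promiscuously at
   low level across the matrix. Per protein, the nearest-rank 90th
   percentile of its *detected* values defines a threshold; values below
   it are zeroed, values at or above it survive. Zeros are excluded from
   the percentile so that a sparse binder is not trivially self-thresholded
   by its own missing values; the quantile, the nearest-rank convention and
   the "keep at or above" rule are all recorded in the output provenance.
   Two boundary behaviors are deliberate: a constant profile survives
   entirely (every value equals the threshold), and re-filtering an
   already-filtered profile set is a no-op by construction -- the filter
   records its state, because recomputing the percentile on the survivors
   would silently double-filter.
4. **Consecutive-binding criterion.** Surviving spots are collapsed onto
   the unmodified tile order (a modified spot marks its parent tile, since
   both occupy the same coordinates). A protein passes when some run of at
   least `min_run = 2` adjacent tiles carries surviving signal. This
   exploits the tiling redundancy: motif-driven binding reaches across
   neighboring spots, while single-spot artifacts do not.

Replicate membership (SET1/SET2) is defined on raw detection before any
filtering, mirroring how replicate overlap is usually reported; the **core
set** is the subset of proteins detected in both replicates that pass the
consecutive criterion on the integrated, normalized, filtered profile.
Footprints map each surviving run back to residue coordinates, from the
first residue of the run's first tile to the last residue of its last tile.

## PTM-response classification

For each (protein, peptide group) the binding signal on every modified
variant is divided by the signal on the unmodified parent spot, using
integrated *raw* intensities -- per-protein 0-1 normalization would distort
within-group ratios. With fold threshold delta = 2 (configurable; the
four response categories are conceptually a gradient, so the cutoff is a
reporting choice, and it is echoed in every output):

- **repressed** -- all detected ratios at or below 1/delta;
- **enhanced** -- all at or above delta;
- **independent** -- all strictly inside (1/delta, delta);
- **regulated** (PTM-specific) -- everything else, i.e. at least one
  variant outside the band while the group as a whole is not.

A variant with signal over a silent parent would have an infinite ratio;
it instead receives a finite cap (64 by default) and a `capped` flag, which
keeps downstream clustering well-defined without pretending the ratio was
measured. The four categories partition every evaluable pair, and the rule
is scale-invariant.

## Validation statistics

**Overlap and FDR.** Screens are compared to reference interactomes by
exact set intersection with isoform-normalized UniProt identifiers. The
interaction false-discovery rate uses an intersection (capture-recapture)
argument under the assumption that false positives do not replicate: with
screens A and B and a high-precision reference R, the sensitivity of B is
estimated as |B∩R|/|R|, the true positives of A as |A∩B| divided by that
sensitivity, giving FDR(A) = 1 − |A∩B|·|R| / (|A|·|B∩R|), clipped to
[0, 1]. The estimator is undefined (reported as not evaluable, never as 0)
when the reference recaptures nothing. Its main bias is the small fraction
of false positives that do replicate by chance; in the shipped Monte-Carlo
benchmark (1,000 planted true interactors, sensitivity 0.8, 5,000-protein
false-positive pool, 200-member reference) this bias stays within a few
hundredths at planted FDRs up to 0.30.

**Enrichment.** Annotation terms are tested with the exact upper-tail
hypergeometric probability against a user-supplied background (no database
retrieval is performed), with Benjamini-Hochberg control at 0.01 by
default.

**Complex ranking.** Against a CORUM-style catalog, complexes sharing at
least one protein with the screen set and at least three with the union of
screen and IP sets are retained. The choice of *union* for the combined
overlap (rather than requiring three in each set) is deliberate: the two
datasets are complementary evidence, and an "each" mode is available. Two
criteria order the retained complexes: percent coverage by the screen set,
and deviation from randomness of the coverages (hypergeometric p-values for
the screen and IP overlaps, combined with Fisher's method into one key).
Absent a published formula for combining the two criteria, the final rank
is the mean of the two criterion ranks -- the simplest symmetric
combination -- with ties broken by complex size then identifier, so ranks
are always a full permutation. The upper quartile is ranks 1..floor(n/4).

## The synthetic screen

The generator plants the structures the filters are designed to separate,
at the scale of the default matrix (203 spots: 72 tiles + 131 single-PTM
variants over a synthetic 297-residue disordered-protein-like sequence):

- **True binders** (default 500): a plateau of peak intensity over 2-5
  adjacent tiles, flanks attenuated to 0.5x one tile out and 0.2x two
  tiles out, plus low-level promiscuous signal on 30 further spots
  (0.01-5% of peak). Peaks are log-normal (sdlog 2.3), spanning roughly
  six orders of magnitude across binders, as protein abundances in a
  nuclear extract do.
- **Background binders** (default 1500): one isolated spot each, at low
  log-normal intensity.
- **PTM effects**: planted per (binder, group) pair with multipliers 0.1
  (repressed), 1 (independent), 8 (enhanced), or one variant at 8 with the
  rest at 1 (regulated); one planted group per binder, and regulated
  requires at least two variants, otherwise it would be indistinguishable
  from enhanced.
- **Replicates**: truth times multiplicative log-normal noise (CV 0.3 by
  default) with 10% dropout per detected value.

In the noise-free limit the pipeline's core set provably equals the
planted true binders detected in both replicates, which the test suite
asserts exactly (precision = recall = 1 on 500 true / 1,500 background
binders). The flank attenuation interacts with the outlier filter by
design: the plateau ties at the per-protein threshold and survives, the
flanks and promiscuous spots fall below it.

What the generator does *not* emulate: correlated noise between
neighboring spots, composition-dependent synthesis efficiency, shared
peptides between proteins, or intensity-dependent dropout. Variant spots
of *unplanted* groups carry no signal, so those groups classify as
repressed (ratio 0); on real matrices most indifferent binders would bind
the modified peptide too and land in the independent class. Passing the
synthetic benchmarks therefore demonstrates the correctness of the
filtering logic, not the biological error rates of a real screen.

## Numerical and design choices

- Coordinates are 1-based inclusive everywhere; tile indices are 0-based.
- The tiling generator is only for de-novo designs; a design file with
  arbitrary per-spot starts can override it, since real matrix layouts
  deviate from a strict offset.
- Isoform identifiers are merged by per-spot **maximum** (not sum), so a
  peptide shared between isoform rows is never double-counted.
- Quantiles use the nearest-rank convention (`ceiling(q * k)`-th order
  statistic), which is exact, distribution-free and matches the brute
  order-statistic oracle in the tests.
- The isoelectric point solver bisects the composition-based
  Henderson-Hasselbalch net charge on pH [0, 14] to |charge| < 1e-6; the
  pKa set (EMBOSS by default, Lehninger available) is recorded in the
  result, since pI values are only comparable within one set. GRAVY uses
  the Kyte-Doolittle table. Both are composition-based and therefore
  permutation-invariant.
- Heatmap clustering defaults to average-linkage on Euclidean distances
  with rows pre-sorted by id, making leaf order deterministic and
  input-order-invariant; linkage and distance are configurable since no
  single convention is canonical.
- Accumulated per-spot intensities are emitted in both filtered and
  unfiltered form, labelled, because either can be the quantity of
  interest.

Problem sizes in the shipped tests and the acceptance script (2,000
simulated proteins over 203 spots, 20 FDR simulations per planted rate,
10 noisy PTM-recovery seeds) were chosen as the smallest sizes at which
the stochastic assertions are stable; all complete in well under a minute
each.

## Known limitations

- The consecutive-binding criterion assumes the design's tile indices are
  contiguous; gapped custom designs should renumber tiles accordingly.
- The intersection FDR estimator inherits the "false positives do not
  replicate" assumption; correlated contamination across replicates will
  bias it downward.
- Whether the outlier percentile should be taken over detected values only
  or over all spots is a genuine modeling choice; this package uses
  detected values (recorded in provenance), and profiles dominated by
  zeros will behave differently under the alternative.
- The four-category PTM classification is threshold-based; a
  clustering-based assignment can give different boundaries for ratios
  near the band edges, which is why the cluster order is emitted alongside
  the rule-based category.
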