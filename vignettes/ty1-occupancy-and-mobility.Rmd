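---
title: "Metaelement occupancy and retromobility statistics for the Ty1 family"
author: "TyProfiler authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaelement occupancy and retromobility statistics for the Ty1 family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TyProfiler)
```

# The problem

The budding-yeast genome carries 31 full-length copies of the Ty1 LTR
retrotransposon plus 266 solo-LTR ("delta") remnants, 263 of them shorter
than 350 bp. Every full copy is flanked by a ~334 bp long terminal repeat
(LTR); the Ty1 promoter and its transcription start site sit *inside* the
5' LTR, at +238 from the element start, while a second, internal promoter
(Ty1i, encoding the retromobility inhibitor p22-Gag) initiates at +1000.
Two consequences shape any sequencing-based analysis of this family:

1. **Reads are ambiguous.** A fragment wholly inside an LTR matches, base
   for base, the 5' LTR and 3' LTR of every full copy and every
   sufficiently long solo LTR; a fragment inside the element body matches
   every full copy. Only family-averaged ("metaelement") signal is
   interpretable — individual copies cannot be resolved.
2. **Promoter usage is a two-point contrast.** Regulatory shifts between
   the element promoter (+238) and the internal promoter (+1000) are the
   biological readout, so the occupancy profile must keep both positions
   addressable at base-pair resolution.

TyProfiler implements the full desk-scale computational chain: a synthetic
genome and ChIP simulator with *exact* multimapping ground truth, fragment
processing (duplicate removal, random multimapper assignment, pileup,
control normalization), the anchored metaelement profile and a
dual-promoter balance statistic, and the colony-count / RT-PCR arithmetic
used to quantify retromobility and expression.

# The synthetic study

## Genome construction

`buildToyGenome()` places `nFull` full-length copies (default 31, length
5918 bp, LTR 334 bp) and `nSolo` solo LTRs (default 266, lengths uniform
on [150, 334] bp, echoing that most delta elements are sub-LTR-length)
uniformly over template chromosomes, on random strands, with a minimum
inter-copy gap of one maximum fragment length (500 bp). All full copies
are sequence-identical (including their two LTRs, identical to each
other); solo copies are prefixes of the LTR. Background sequence is
i.i.d. random and rejected if it contains any exact element k-mer of the
minimum fragment length (200 bp, checked with a `PDict` scan).

One subtlety matters: because the LTR recurs at both ends of every full
copy, a window that crosses a copy boundary by `j` bp can still exactly
match an element k-mer when the first flanking background base happens to
equal the element's continuation in the *other* LTR context (probability
1/4 per boundary). The builder therefore forces each flanking base to
differ from every such continuation ("guard bases"). With that, mapping
ambiguity is a pure function of geometry, and `candidateLoci()` —
interval-arithmetic enumeration over the identity groups returned by
`identityGroups()` — is exact, replacing sequence search entirely. The
identity groups deliberately *nest* rather than partition: full copies are
identical end-to-end, so a fragment straddling the LTR/internal junction
is still shared among all full copies, while remaining unique with respect
to solos.

## Fragment model

`simulateFragments()` draws fragment centers from a mixture: uniform
background plus per-element enrichment components, each a symmetric
triangular window of halfwidth `spread` around an element-relative offset
(the component shape is a modelling choice; only the center and scale are
biologically constrained). Fragment lengths are uniform integers on
[200, 500] bp, the range of sonicated ChIP fragments. Fragments are
represented directly as aligned intervals plus candidate lists — no read
sequences, base-call errors, or aligner behaviour are simulated, and
copies never diverge (the idealization that makes the candidate lists
exact). What passing tests on these data show is therefore that the
*processing* chain is correct under known ground truth — not that a real
aligner's mismatch handling at slightly diverged copies is harmless.

## Mobility counts

`simulateMobilityCounts()` emulates the His+ frequency assay: per culture,
whole-culture CFU is Poisson around `cfuPerCulture` (default 2e8),
His+ cells are binomial with the strain's true frequency, and each plate
receives a binomial subsample with fraction
`volume / (dilution x culture volume)` — 1 uL of a 1:1000 dilution on the
permissive plate, the whole culture on the selective plate, three
biological replicates each diluted in quadruplicate.

# Fragment processing

* **Duplicate removal** keys on (length, candidate set), order-insensitive,
  keeping first occurrences. It runs *before* assignment: duplicates share
  identical mapping ambiguity, and deduplicating on a post-assignment
  locus would stochastically retain duplicates sent to different copies.
  (`dedupFragments(on = "assigned")` provides the other order for
  pre-assigned data.) Orientation is ignored: fragments are unstranded
  intervals.
* **Assignment** is uniform over candidates (they are equally good by
  construction), seeded, non-mutating.
* **Coverage** is fragment pileup: each fragment adds 1 to every bp of its
  interval, so a raw track sums to total assigned fragment length. Tracks
  are run-length encoded per chromosome.
* **Control normalization** scales both tracks to coverage per million
  fragments, then takes the per-bp ratio with an additive pseudocount
  (default 0.5 per-million units, well under 0.1% of typical control depth
  in the bundled study — negligible except where the control is empty). The flat
  ~1 baseline this produces outside elements is what makes enrichment
  directly readable; a subtraction mode is available
  (`mode = "subtract"`).

# The metaelement profile

`metaProfile()` averages per-copy profiles on a fixed layout anchored at
the TSS (+238 from element start) and TES (element end by default;
`tesOffset` is configurable since the TES position within the element is
not otherwise pinned down):

| segment | span | resolution |
|---|---|---|
| upstream flank | TSS-2000 .. TSS | per bp |
| TSS margin | TSS .. TSS+1000 | per bp |
| body | TSS+1000 .. TES-1000 | 100 bins |
| TES margin | TES-1000 .. TES | per bp |
| downstream flank | TES .. TES+2000 | per bp |

Design notes:

* "Flanking regions at base-pair resolution" is read as *everything
  outside the 100-bin body*, including the TSS..TSS+1kb and TES-1kb..TES
  strips — the only reading that keeps both the +238 and +1000 markers
  per-bp addressable.
* The window is anchored on the TSS per the layout above (so the element
  start sits at -238); `profileTable()` reports element coordinates, which
  is what all user-facing windows use.
* Body bins come from an even integer partition of the body span, with the
  remainder spread over the first bins: deterministic and
  order-independent. An element body shorter than the bin count is an
  error that suggests smaller margins or fewer bins.
* Minus-strand copies are reversed so profiles read 5'-to-3' of the
  element; positions beyond chromosome ends are masked (NA) and averaging
  is per-position over unmasked copies only. Copies are averaged with
  equal weight regardless of mappable length.

## Promoter balance and peak location

`promoterBalance()` reports mean occupancy in +/-100 bp windows around
+238 and +1000 and their ratio (Ty1i/Ty1); a zero denominator produces an
explicit undefined flag, never a silent NaN.

`profilePeaks()` estimates peak *positions*. On ratio tracks the per-bp
noise is correlated on the scale of a fragment length (~350 bp), so the
argmax of a smoothed profile wanders across the broad peak plateau. The
estimator therefore finds coarse local maxima (51-bp running mean, 300-bp
minimum separation) and refines each as the background-subtracted
intensity centroid of a +/-250 bp window, with background the median
smoothed value away from all peaks — the standard centroid localization
used for symmetric peaks. In repeated simulations of the bundled
two-promoter study this localizes both injected TSSs to within ~15 bp;
a plain argmax misses by 50+ bp on occasional seeds.

## The LTR mirroring artifact

Because LTR-resident fragments are assigned uniformly among all LTR
copies, enrichment that is physically confined to the 5' LTR necessarily
re-appears at the 3'-LTR segment of the averaged profile (and drains into
solo LTRs). This is a property of random multimapper assignment, not a
bug; the package's tests assert it quantitatively (3'-LTR window mean
above flank background under 5'-LTR-only enrichment).

# Assay arithmetic

* **Frequency**: per culture, His+ CFU over total CFU, each
  back-calculated as `colonies x dilution x (culture volume / plated
  volume)`. Technical cultures are averaged within a biological replicate
  before the cross-replicate mean and s.d. (`pooling = "culture"` pools
  all 12 cultures instead); with exactly two biological replicates the
  range is reported instead of an s.d.
* **Censoring**: a strain with zero selective colonies everywhere is
  reported as an upper limit, `1 / (total permissive-plate CFU over all
  cultures)` — the literal whole-culture reading; differences in selective
  plating volume do not enter this rule, a documented limitation.
  `foldChange()` against a censored strain returns a "> x" lower bound.
* **RT-PCR**: a transcript amplifying `d` cycles earlier is
  `E^d`-fold more abundant (efficiency `E` fixed at 2, the conservative
  perfect-doubling assumption; configurable); equal band intensity for
  amplicons of lengths `L_ref` vs `L_target` implies a
  `L_target/L_ref` molar excess; the combined fold multiplies the two and
  `100/combined` is the target's percentage of the reference. With the
  defaults (d = 5, 200 bp vs 3 kb) this gives 32 x 15 = 480-fold,
  i.e. ~0.21%. The genomic-DNA control amplifying at the target's average
  cycle number is treated as a qualitative validity gate, not a numeric
  correction.
* **Densitometry**: `(target/loading) / (reference target/reference
  loading)`, vectorized over a band table with `densitometryTable()`.

```{r rtpcr}
combinedAbundance(deltaCycles = 5, efficiency = 2,
                  refAmpliconLen = 200, targetAmpliconLen = 3000)
```

# Problem sizes, tolerances, degenerate inputs

The bundled synthetic study uses an 8-full-copy, 12-solo genome on two
120 kb chromosomes with 100,000-fragment IP and control libraries — large
enough that the body of a control metaprofile is flat to CV < 0.1 and
peak centroids are stable to a few bp, small enough to run in well under
a minute; the estimator-calibration study uses 200 simulated assays at a
true frequency of 1e-6. Key numeric behaviours at the edges:

* `normalizeToControl(x, x, eps)` is exactly 1 wherever coverage is
  positive, for any pseudocount.
* A zero pseudocount with a zero-coverage control base is an error
  directing the caller to a positive pseudocount.
* Empty fragment sets pass through deduplication and assignment as empty;
  an empty candidate list is an error naming the fragment.
* All simulators are bit-reproducible under a seed, which is restored
  after use (callers' RNG streams are untouched).

# Known limitations

* Copies are identical by construction; real Ty1 copies diverge slightly,
  and aligner mismatch tolerance at diverged copies is not modelled.
* No read sequences: alignment, mapping quality and blacklist filtering
  are out of scope.
* Mobility is a per-culture *frequency*, not a Luria-Delbruck mutation
  rate; jackpot cultures inflate the mean, as they do in the underlying
  assay.
* The profile reports family-average occupancy only; per-element behaviour
  is intentionally not a primary output, since reads cannot be attributed
  to individual copies.
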