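---
title: "Measuring melodic replication and improvisation from MIDI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring melodic replication and improvisation from MIDI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midilearn)
```

## What the package measures

`midilearn` scores two complementary musical skills from monophonic MIDI
note sequences. *Replication fidelity* asks how faithfully a performance
reproduces a reference melody the player heard; *improvisation* asks how
much structured variation a free elaboration of a short prompt contains.
Both families of measures are fully computational, so learning can be
tracked objectively across a longitudinal teaching study without expert
raters.

The representation is deliberately minimal: a performance is an ordered
list of notes, each a `(pitch, onset, offset, velocity)` quadruple in
semitones and seconds. All measures work on this representation; MIDI tick
arithmetic exists only at the file boundary (`read_midi()`, `write_midi()`).
Overlapping notes are resolved by truncating the earlier note at the next
onset — truncation rather than deletion, because the pitch *sequence* is
the primary object of every measure and must survive extraction.

## Replication scoring

### Subsequence DTW

The heart of the replication measures is dynamic time warping between the
performed and reference pitch sequences. Because learners often render only
part of a melody — and a correct fragment should not be punished twice —
the alignment is *subsequence* DTW: open at both ends on the reference
axis, while the performance must be consumed in full. The local cost
between two notes is `min(|pitch difference|, 12)` semitones; the octave
cap stops a single wild slip from dominating the whole alignment.

Three numerical choices deserve a precise statement, since different DTW
conventions give different numbers:

* **Step pattern.** Diagonal, vertical and horizontal unit-weight steps;
  each visited cell contributes its local cost once.
* **Optimal path.** The path minimising cumulative cost, with ties broken
  first by *shorter* path length and then by the *rightmost* reference end
  column. Cost-then-length is used because normalising by path length
  inside the optimisation is not decomposable for dynamic programming; the
  lexicographic rule is deterministic and is verified exactly against
  brute-force path enumeration in the test suite. The rightmost-end rule
  matters only for zero-cost ties (repeated pitches) and maximises the
  reference segment credited as rendered.
* **Scaling.** `normalized_distance = cost / (path length × 12)`, which is
  0 for an exact rendition and can never exceed 1. `pitchdtwsim` is one
  minus this distance.

`palignedprop` is the fraction of reference positions that appear on the
optimal path with local cost at or below `match_tol` (default 0: exact
pitch, matching the teaching emphasis on pitch correctness; the tolerance
is a configurable knob). `pitchdtwladj = pitchdtwsim × palignedprop` is the
headline measure: a perfect rendition of 5 notes out of 15 scores
`1 × 5/15 = 1/3`, not 1.

### Joint pitch and timing

The `pioi*` triple repeats the construction on joint features: each note
contributes its pitch and `log2(ioi / median ioi)`. The median
normalisation removes global tempo, so playing the piece uniformly faster
changes nothing. The joint local cost is
`min(|Δpitch|, 12)/12 + w · min(|Δlog ioi|, 2)/2` with `w = 1`: both
components are individually scaled to `[0, 1]` before summing because
nothing in the data dictates a relative weighting of pitch against timing;
the normalising cap is accordingly `path length × (1 + w)`. A reference
position counts as matched when the combined cost is at most 0.1.

### Distributional similarity

`klpitchsim` and `klioisim` ignore order entirely and compare what pitch
and timing material was used. Pitch histograms are over absolute MIDI
pitches (not pitch classes — the material spans under two octaves and
octave folding would destroy register information), built on the union of
the two supports. Timing histograms bin `log2(ioi / median ioi)` into 13
half-open bins spanning [−3, 3], the outer bins catching everything
beyond. Both use additive smoothing with pseudo-count α = 0.5 so disjoint
supports cannot produce an infinite divergence. The divergence is the
symmetrised (Jeffreys) form `J = ½KL(p‖q) + ½KL(q‖p)`, mapped to `(0, 1]`
as `exp(−J)` — identical distributions score exactly 1 and similarity
decays strictly with divergence. The distributional fields are not length
adjusted (a distribution from a short fragment is information-poor rather
than wrong); performances of fewer than 4 notes are flagged as
low-information instead.

A performance of a single note still yields the pitch-based fields; the
timing-based fields are returned as `NA`, never silently zero.

## Improvisation scoring

Eighteen measures quantify the variation devices that were taught:

```{r}
task_score_map()
```

The named constants, all configurable arguments, are: diversity is Shannon
entropy in bits (with a distinct-count alternative); passing notes are
steps of 1–2 semitones from the antecedent; crescendo/diminuendo runs must
be strictly monotone in velocity over at least 3 notes with total change at
least 10; an accent is a velocity at least 15 above the mean of its 5-note
centred window (self excluded, edge-truncated); windowed IOI statistics use
windows of 4 IOIs at step 1; articulation is the duration-to-IOI ratio
capped at 1, with `M12VaryStaccLeg` its population standard deviation (the
population convention is fixed by the measure's worked example);
retrograde/sequence segments need at least 3 notes.

The retrograde and sequence detectors are deliberately strict and
deterministic: contiguous segments, exact pitch reversal (or exact interval
pattern at a non-zero uniform transposition), scanned greedily left to
right with longest-match-first at each position, counting only the notes of
the later occurrence and never letting counted occurrences overlap. This
exact-greedy definition is checkable against exhaustive enumeration, which
the tests do for every sequence up to length 8 on a 3-pitch alphabet. A
literal repeat at zero transposition is intentionally *not* a sequence.

Measures whose preconditions fail on short inputs are returned as `NA`:
silently substituting 0 would bias the standardised composites downstream.

## Composite scores

Heterogeneous measures are made comparable by unit-interval rescaling
(replication) or z-standardisation (improvisation; population SD). The
combination rule is *variance sharing*: columns are weighted by the squared
loadings of the first principal axis of their correlation matrix,
normalised to sum to one, so measures that share variance with the common
axis dominate and a pure-noise column is down-weighted. This definition is
isolated in a single internal function so it can be swapped. Two caveats
are worth recording: for genuinely independent columns the first
eigenvector is sampling noise, so individual weight draws are arbitrary
even though they are symmetric in expectation; and the combined replication
score applies the weights to the *rescaled* (not standardised) columns so
the composite stays on the 0–1 scale of its ingredients.

Posterior summaries are intentionally minimal: `evidence_ratio()` counts
draws on either side of zero (draws exactly at zero split evenly), so 95%
of draws in favour gives exactly 19 — the conventional strong-evidence
threshold — and unanimous draws give infinity; `credibility_interval()` is
equal-tailed quantiles plus the median. Fitting the multilevel models that
produce such draws is outside the package's scope.

## The synthetic generator

The generator exists so that every measure, and the learning-trajectory
logic built on top of them, can be exercised end to end with no study
data. It emulates the study conditions: references of 3–30 notes built
from 3–5-note fragments on the 20-key C4–G5 span with steps biased to ≤ 2
semitones and IOIs from {0.25, 0.5, 1} s; improvisations on 3–5-note
prompts capped at 30 notes; a cohort of 68 participants in 10
counterbalanced groups, five performance sessions with five items each
(items 1–3 replication with item 1 rehearsed and item 2 unpractised,
items 4–5 improvisation).

Learner error is modelled with single-parameter families chosen for
controllability, not perceptual realism: per-note substitution (geometric
magnitude decay over ±1..4 semitones), deletion, insertion, partial
completion, lognormal IOI jitter and Gaussian velocity noise. Learning is
expressed as log-linear decline of the replication error parameters per
completed replication block (`exp(-0.6 · repct)` by default) and as
planted-task intensity rising with improvisation blocks
(`0.15 + 0.3 · imprct`); the keyboard instrument gets a 0.85 error
multiplier relative to the touchscreen. Timing-learning defaults to zero —
rhythm improvement is deliberately not planted. Each task's injector
plants the structure its designated measure detects (repeats, passing
notes, widened intervals, IOI diversity, velocity ramps and spikes, rests,
a mid-piece tempo change, articulation contrasts, an appended retrograde or
transposed copy), with counts proportional to intensity, and logs what it
planted so tests can compare detector output against ground truth.

What passing tests therefore show is that the measures detect and rank the
behaviours they claim to measure, with the right monotonicities, on
idealised performances. They do not show calibration against real novice
playing: real errors are correlated in time, expressive timing is not
lognormal jitter, and none of the generator constants are claimed to match
real learners.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the caller's
RNG state; cohorts derive per-performance child seeds from one master
seed, so reruns are byte-identical (the pipeline writes MD5s of its
outputs to make this checkable). The test suite verifies the DTW
implementation exhaustively against path enumeration for all sequence
pairs up to length 2 over a 5-pitch alphabet plus several hundred sampled
pairs up to length 6 (enumeration over *all* pairs up to length 6 — some
4 × 10^8 — is not a feasible check anywhere); detector oracles run
exhaustively to length 8 on 3 pitches; degradation and task-recovery
properties use 100 seeds per condition; cohort sign-recovery uses 20
design seeds of the default 68-participant design.

## Known limitations

* The SMF reader handles type 0/1 metrical-division files, merges channels
  and ignores percussion (channel 10); SMPTE division, pitch-bend and
  controller data are out of scope, and touch-position loudness is assumed
  to arrive as velocity.
* Subsequence DTW credits the single best reference segment; a performance
  that renders two disjoint fragments correctly will have one of them
  absorbed as errors.
* The variance-sharing composite is a first-principal-axis definition;
  alternative composites (rotated factors, multi-factor) are intentionally
  not offered.
* Diversity measures treat values as unordered symbols; two near-identical
  IOIs falling either side of a bin edge count as distinct.
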