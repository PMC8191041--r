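---
title: "Methods: single-molecule replication fork mapping from base-analogue signals"
author: "forktrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule replication fork mapping from base-analogue signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`forktrace` maps DNA replication on single nanopore-sequenced molecules.
When S-phase cells take up the thymidine analogue BrdU, replication forks
write the analogue into nascent DNA; because BrdU perturbs the ionic current
of the pore, its genomic positions can be decoded from raw signal. The
package implements the full chain:

1. **Signal alignment** — raw current samples are segmented into events and
   aligned to the reference k-mer sequence by banded Viterbi passes through
   a profile HMM, producing one feature row per reference 6-mer.
2. **BrdU detection** — a small residual convolutional network converts the
   15-k-mer window around each thymidine into the probability that the
   thymidine carries BrdU, written as a per-read table.
3. **Fork sense** — a convolutional encoder-decoder reads each molecule's
   BrdU-probability track and emits, per position, the probability that a
   leftward- or rightward-moving fork passed during the analogue pulse;
   diverging fork pairs are matched into replication origin calls and
   converging pairs into termination calls, written as BED intervals.

Because no real sequencing data ships with the package, a first-class
synthetic-signal generator provides training material and ground truth. All
coordinates are 0-based half-open except the 1-based primer-extension
construct positions quoted for single-nucleotide-resolution checks.

# The synthetic pore model and signal generator

## Pore model

The bundled pore model (`default_pore_model()`) is built deterministically
from a fixed internal seed: each of the 4096 canonical 6-mers receives a
mean current drawn uniformly on 60–120 pA and a spread on 1–2 pA. Analogue
variants are spelled with `B` replacing a substituted `T`. Their current
shift is *systematic in sequence context*: a BrdU at pore position $p$
contributes a fixed positional shift $s_p$ (drawn once; magnitudes 5–9 pA,
mixed signs), shifts of multiple analogues in one 6-mer add, and each
variant carries an extra N(0, 0.7 pA) k-mer-specific perturbation; variant
shifts are floored at 1.5 pA in magnitude.

Two aspects of this design deserve justification. First, halogenated-base
current shifts in a real pore are driven by the analogue's position in the
sensing region and are therefore strongly structured, not independent per
k-mer; an independent-per-k-mer shift table (10k+ free values) would be
unlearnable for any compact network and would make overlapping substitution
patterns undecodable in principle. Second, the shift magnitude is the
knob that sets the separability of the whole benchmark; 5–9 pA keeps BrdU
"detectable but noisy" — single-sample observations still misclassify, and
the detection network has to integrate all six windows covering a
thymidine. Smaller shift families (2–4.5 and 3–6 pA) were evaluated and rejected:
they leave per-window evidence so close to the event-measurement noise
floor that desk-scale training cannot reach the package's accuracy bar.

## Reads, dwell and noise

A read is synthesised by replaying the expected level of each reference
6-mer (analogue levels wherever a substituted thymidine falls in the
window) for a geometric dwell (mean `dwell_mean = 8` samples, minimum 1 —
nanopore-like event statistics) and adding Gaussian noise with the level's
own spread (`noise_sd_scale = 1`). Noise scale and dwell were fixed once at
realistic values and are not tuned. Seeded runs are bit-reproducible; every
cohort routine derives one child seed per read.

## Experimental protocols

* `uniform` — per-thymidine Bernoulli substitution at a stated rate (0,
  0.26, 0.38, 0.49, 0.69 or 0.80 in the study conditions).
* `primer_extension` — a fixed 80 bp construct whose thymidines at 1-based
  positions 30 and 36 always carry BrdU and all others never do.
* `g1_release` — every origin fires at the start of the pulse; each fork's
  local substitution probability ramps from 0 to `p_max = 0.8` over
  `rise_length = 2 kb` (analogue uptake), then declines gently with
  characteristic length `depletion_length = 20 kb` as the intracellular
  BrdU pool is consumed. The decline matters: a perfectly flat plateau
  leaves fork direction in its interior *exactly* ambiguous — no
  estimator, however good, could orient it — whereas a mild gradient makes
  direction identifiable everywhere, which is also what pool dilution does
  in real release experiments.
* `pulse_chase` — the plateau lasts one pulse (4 min at 1800 bp/min =
  7.2 kb per fork) and then decays exponentially with
  `chase_decay_length = 3 kb` along the fork's direction of travel.

Converging forks from adjacent origins stop at their midpoint (equal
speeds). Truth labels record, per position, which fork direction's
footprint is *observable* there: the whole replicated path under G1
release, and the pulse plus the chase tail down to 10% of the plateau
under pulse-chase. Molecules without an origin are traversed by a single
fork entering from a random end at pulse start; they carry fork truth but
no origin/termination truth and are the negative controls for origin
calling. Truth origin and termination intervals are 1 kb wide, centred.

Cohort geometry is protocol-aware (`fork_cohort_geometry()`): pulse-chase
origins are spaced 19 kb on 48 kb molecules so each footprint's orienting
decay is visible (origins closer than twice the pulse reach replicate the
whole span *during* the pulse, leaving no gradient at all); G1-release
cohorts use compact 26 kb molecules with 8 kb spacing because the depletion
gradient orients every position.

## What the generator does and does not emulate

It emulates level-coded k-mer signal, analogue level shifts, heavy-tailed
dwell, per-sample Gaussian noise, substitution protocols and fork
footprints. It does not emulate basecalling errors (reads carry their true
sequence), pore-translocation physics, chemistry-specific level tables,
multi-strand effects, or inter-origin firing-time variation (all origins
fire at pulse start). Passing tests therefore demonstrate correct
machinery and recoverability under the stated signal model — not
performance on any particular real chemistry.

# Signal alignment

Events are segmented where a two-window (2-sample) mean-shift statistic
exceeds 2 pA at a local maximum; single-sample jumps above 4 pA also open
events, catching one-sample dwells. Over-segmentation is deliberately
cheap: extra events are absorbed by the HMM as inserts, while a *merged*
event irreversibly corrupts its k-mer's summary.

The coarse alignment is a banded Viterbi pass through a linear profile HMM
with match (advance), insert (extra event, also absorbing the "stay"
self-transition) and skip (missed k-mer) moves; transition probabilities
(0.89/0.06/0.05) are fixed, not trained. The match emission scores the
event mean against the *best of the k-mer's candidate levels* — canonical
or any analogue variant — at the k-mer's own spread. This keeps the
alignment sharp and accurate at any substitution rate while remaining
agnostic about which candidate was present; no BrdU call is implied, and
discrimination is left entirely to the network. The band half-width grows
as `2.2 * sqrt(K)` with the number of reference k-mers `K` (doubled and retried if the coarse path saturates its band), and long reads use a coarse-to-fine pass: a decimated event subsequence is aligned first and anchors a narrow full-resolution band: the true path
drifts from the linear diagonal like a random walk in dwell, so any fixed
band silently saturates on long reads.

A second, sample-level banded Viterbi ("resquiggle",
`refine_alignment()`) then re-assigns every raw sample to a k-mer within
±8 k-mers of the coarse path, each k-mer consuming a geometric run of
samples. This recovers boundaries the mean-shift statistic cannot see and
raises k-mer coverage from ~0.94 to ~0.999 on simulated reads. The refined
occupancy is re-expressed as an event table plus an insert-free alignment
so the downstream contract is unchanged.

Input tensors take the 15 k-mers centred on each thymidine (windows
overhanging the aligned span are excluded and counted). Each row carries
the duration-weighted event mean, pooled spread, summed dwell, expected
canonical level, observed-minus-canonical level difference, a missing
flag for skipped k-mers, a one-hot of the 6 bases, the matched-filter
column (the shift predicted if the *centre* thymidine were substituted)
and the row's full local shift design (the predicted shift for a single
analogue at each of the 6 offsets) — the latter let the network solve the
small linear system that attributes observed shifts to individual
thymidines. Levels are standardised around the pore's 60–120 pA range.

# The detection network

Six residual blocks, each a depthwise convolution (kernel 5) along the
window followed by a pointwise convolution over 16 channels, batch
normalisation, ReLU and an identity shortcut. Because no nonlinearity
separates the depthwise and pointwise steps, they are computed as one
matrix product against a composite weight matrix. The readout flattens the
window axis into a position-aware linear softmax head rather than pooling
it: the rows covering the centre thymidine must be weighted differently
from context rows, and mean pooling destroys exactly that information
(measured: a pooled head plateaus several accuracy points lower). The
model has ~3,300 parameters.

Training uses cross-entropy, Adam (3e-3), batches of 512, a 15% validation
split, early stopping (patience 4) and at most 8 epochs, on 2,000
simulated reads of 3–7 kb (half unsubstituted, half 80% substituted; each
250-read chunk draws a fresh random contig so the network cannot memorise
one sequence context), subsampling 24 thymidine tensors per read. Labels
are per-thymidine simulator truth, so unsubstituted thymidines inside
BrdU-rich reads are genuine negatives — a luxury real training data does
not offer. Inference folds batch normalisation into the composite
convolution and runs in a compiled kernel; the pure-R forward pass is kept
and cross-checked in the test suite. The default decision threshold is
0.5; evaluation sweeps the full ROC.

# Fork sense

The fork-direction network is a fully convolutional 1-D encoder-decoder:
four 4× average-pooling stages with kernel-9 convolutions (8 outer / 16
inner channels), skip connections at each resolution on the way up, and a
two-channel sigmoid head (leftward / rightward fork). Its input is the
per-thymidine BrdU-probability track viewed at a stride of 4 thymidines
plus a bounded spacing channel; outputs are restored to every thymidine by
piecewise-constant upsampling, so a `ForkTrack` keeps one probability pair
per detect-record row. The receptive field at the bottleneck spans roughly
±20 kb — wide enough to see both decay tails flanking an origin's central
plateau, which is what localises the left→right transition at the origin
itself (with a narrower field the transition point is systematically
biased toward whichever tail leaves the field last).

Training is supervised per-position binary cross-entropy on both channels
against simulator fork labels (one read per Adam step, 15% held-out reads,
early stopping). The encoder-decoder is trained as a sequence-to-sequence
labeller rather than by unsupervised reconstruction: per-position
left/right outputs are the function being learned, and supervised training
on simulator truth is the reproducible desk-scale reading of that design.

Calling is deliberately tuning-free: fork segments are maximal runs of
probability > 0.5, closed over gaps ≤ 500 bp and discarded under 1 kb;
a leftward segment immediately followed by a rightward segment brackets an
origin call on the gap between them (overlapping segments collapse to the
overlap midpoint ± 1), and the converse pattern brackets a termination.
Reads enter calling only with mapped length ≥ 20 kb and MAPQ ≥ 20 (both
inclusive). These constants are frozen defaults, not exposed flags.

# Evaluation machinery

Confusion counts use the strict rule "call = probability > threshold".
Balanced accuracy is (TPR + TNR)/2 and is computed per-thymidine (not
per-read-averaged). ROC sweeps 101 even thresholds plus the empirical
probability set when ≤ 10⁴ distinct values, so small cohorts are swept
exactly. The primer-extension profile is the per-position median across
reads, reported 1-based. Origin distances are measured from the call
interval's midpoint to the nearest known-origin interval (0 if inside;
signed, negative leftward). Pileups count call intervals per fixed-width
bin. Origin recovery against simulator truth reports both the fraction of
truth intervals overlapped by a call on the same read and the fraction of
those calls containing the true origin midpoint.

# Numerical choices and degenerate inputs

Log-space Viterbi throughout; traceback ties prefer the insert move and the
fewest skips. Events partition the signal exactly; an empty signal, a
single-class training set, a single-truth-class ROC, an empty
primer cohort and undefined balanced-accuracy denominators are hard
errors rather than silent zeros. A read whose band admits no path is
reported unalignable and dropped with a count. Batch-norm inference uses
running statistics (momentum 0.1); the folded inference path is bit-equal
to the reference forward pass. All writers are byte-deterministic; the
detect-table dialect stores probabilities at 6 decimals and one optional
per-read MAPQ field beyond the five positional fields, which lets the
fork-calling stage apply its read filter from the table alone.

# Problem sizes

The package's standard recipes, used verbatim by the worked examples and
the acceptance script: detection training on 2,000 reads of 3–7 kb
(~48,000 tensors, ≤ 8 epochs); held-out detection evaluation on 120–200
reads; primer-extension cohorts of 273 reads; fork-sense training on 24
molecules per protocol and evaluation on 200 molecules per protocol (180
origin-bearing with three origins each, 20 origin-free).
These sizes were chosen once as the package's desk-scale study conditions.

# Known limitations

Reverse-strand analogue detection is handled only by mapping reads into
reference coordinates (the simulator emits forward-strand reads); no
basecalling simulation; origin firing is synchronous within a molecule, so
the generator does not probe asynchronous-firing confounds; fork stalls
are not called (the footprint machinery could simulate them, but calling
is out of scope); and all accuracy statements are with respect to the
synthetic signal model described above.
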