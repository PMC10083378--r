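---
title: "Modeling dual-stream lexical mappings from cochleagram input"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dual-stream lexical mappings from cochleagram input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the modeling strategy

Spoken language is processed along two broad cortical streams: a dorsal
pathway that maps sound onto articulation, and a ventral pathway that maps
sound onto meaning. If each stream maintains its own interface with the
mental lexicon, a natural computational question is *why*: do the two
mappings exert different pressures on what a useful featural representation
of a word form looks like?

`duallex` investigates this with a controlled in-silico experiment. Three
recurrent networks receive the *identical* acoustic input — cochleagrams of
multi-talker spoken word tokens — and differ only in their output targets:

* the **dorsal** network maps each token to a slot-based articulatory
  vector of its phonological form;
* the **ventral** network maps each token to a sparse indicator of the
  lexical co-occurrence contexts (trigram templates) the word occurs in;
* the **fused** network maps to the concatenation of both.

After training, the hidden layers are interrogated: can word classes
defined by articulation (seven onset manner classes) or by syntax/semantics
(nine part-of-speech classes) be decoded from the hidden activations by
unsupervised clustering? Do single hidden units become selective for
phonemes or for morphemes? The expected signature is a double dissociation:
each specialist network supports its own generalization task and not the
other's, while the fused network sits in between on both.

## The synthetic corpus

No audio or corpus tables are redistributed with the package; the
`synthdata` functions generate the full study corpus from seeds.

**Lexicon.** `generate_lexicon()` samples monomorphemic roots from a
(C)(C)V(C)(C)(+CV(C)) skeleton with a legal-onset table, stratifying root
onsets over the seven onset classes and enforcing that all 39 phonemes of
the inventory are attested. Words are derived with the 20-affix table
(`affix_table()`: 15 suffixes, 5 prefixes, each with a part-of-speech
transformation), a small fraction carrying a prefix+suffix pair, and a
2–10-phoneme form-length filter is applied. At full scale (252 roots) this
yields roughly 950 words of mean length 5.5 phonemes; the desk-scale
profile uses 24 roots and one derivation per affix (about 48 words, all
nine POS classes and all seven onset classes attested).

**Speech.** `synthesize_token()` is a parametric source–filter
synthesizer: sonorants are a sawtooth glottal source shaped by second-order
formant resonators (talker-scaled), fricatives are band-shaped noise, stops
are closure + burst (with a voice bar when voiced), affricates closure +
frication, diphthongs two-target formant glides. Talkers
(`generate_talkers()`) split into a higher-f0 and a lower-f0 group with
distinct vocal-tract scale factors, so tokens of one word vary realistically
across talkers while phoneme identity stays recoverable. Utterance
durations scale sublinearly with phoneme count (about 222·L^0.69 ms,
clamped to 300–1,200 ms), giving a mean around 650–700 ms. What this
generator deliberately does **not** emulate: coarticulation and reduction,
prosody beyond f0 declination, and unit-selection naturalness. Passing
tests therefore show that the *pipeline logic and learning dynamics* behave
as designed — not that results transfer verbatim to natural recordings.

**Semantics.** `generate_cooccurrence()` emulates trigram-template counts:
each template admits one 4-way POS and draws a Dirichlet preference
(concentration `pos_affinity`, default 0.25 — strongly selective, as real
trigram contexts are) over the 9-way subclasses; word totals follow a Zipf
law with a floor so every word stays attested after filtering. Words of the
same 9-way class thereby have systematically more similar template profiles,
which is exactly the structure the ventral mapping must discover.

## The cochleagram front end

`build_filterbank()` constructs half-cosine magnitude responses on an
ERB-number scale (E(f) = 21.4·log10(1 + 0.00437 f)): 203 bandpass filters
with centers between 50 and 8,000 Hz, spanning four spacings to each side,
so the interior summed squared response is constant; four low-pass and four
high-pass filters carry the band-edge residual, making the summed squared
response exactly flat (211 filters in total). The low/high-pass filters
split the edge residual evenly; this keeps the tiling identity exact for
any filter count, including degenerate banks.

`compute_cochleagram()` filters zero-phase in the frequency domain, takes
the magnitude of the analytic signal per subband, compresses with a power
law, and averages into frames. Implementation note: each subband envelope
is recovered by an inverse FFT over only that filter's spectral support at
a small decimated length. Because the analytic subband signal is
band-limited to that support, the decimated envelope samples are exact;
this makes the front end fast without approximating the envelope.

Two front-end constants are design decisions, exposed as configuration:

* **Envelope frame rate 200 Hz.** The full-scale batch geometry (226
  frames for the longest 1,130 ms token) pins the rate at 200 Hz; the
  desk-scale profile halves it to 100 Hz.
* **Compression exponent 0.3**, standard cochleagram practice in the
  front-end lineage this follows; `compression = 1` disables it (the
  pre-compression envelope is linear in the waveform, which the tests
  exploit).

Silence is trimmed at −20 dB relative to the peak 25 ms RMS, with the RMS
window zero-padded outside the signal so that prepended digital silence
shifts the trim point exactly.

## Targets

**Dorsal (slot) encoding.** `encode_dorsal()` places 29-component binary
feature vectors into a fixed grid: three initial-onset consonant slots plus
five VVCCC syllable blocks — 28 slots, hence 812 components. Syllabification
follows the maximal-onset principle; the consonant slots of block *i* hold
all consonants between nucleus *i* and nucleus *i+1*. Monophthongs fill the
first vowel slot, diphthongs both (so a filled-block count equals phoneme
count plus diphthong count). The feature chart itself (8 place, 7 manner,
voicing, syllabicity; 3 height, 3 backness, tenseness, rounding, diphthong;
3 reserved zeros) is the package's own — the architecture only requires a
29-bit injective chart, which the tests verify.

**Ventral encoding.** Templates admitting fewer than 160 words are dropped
and words attested in fewer than 20 surviving templates are flagged,
iterated to a fixed point (`build_template_set()`; the desk profile scales
the thresholds to 5/3). A word's target is its binary attestation
indicator over surviving templates — identical for all its tokens, so the
network must collapse talker variation. Counts remain available; the
indicator reading makes targets sigmoid-compatible.

## Networks

`stream_net()` fits the model: masking → fully recurrent LSTM → dense
sigmoid layer, read out at each token's final valid frame, trained by Adam
on mean squared error with a constant learning rate. Masking uses *clamp*
semantics: frames at or beyond a token's valid length leave hidden and cell
state unchanged, so the final-frame readout and the padded readout coincide
exactly (the tests assert bit-level invariance to trailing padding), and
hidden trajectories repeat the last valid state over the padding.

The full-scale configuration is 512 hidden units, 10,000 epochs, batch 100,
learning rate 1e-4, checkpoints every 100 epochs with the best-validation
weights retained. Validation holds out every token of one talker — the same
talker across words — so validation accuracy measures generalization to an
unheard voice; a per-word random holdout is available as an option.

The desk-scale (mini) profile keeps the architecture and epoch count (64
units, 300 epochs) but runs orders of magnitude fewer optimizer steps than
the full schedule, so its optimizer settings were calibrated in pilot
trainability runs: batch 4 and learning rate 3e-3 bring the dorsal network
past 0.9 training cosine within the fixed 300-epoch budget. Weight
initialization follows the common recurrent-network defaults — Glorot
uniform kernels, orthogonal per-gate recurrent matrices, zero biases with
a unit forget-gate bias — which in the pilot runs proved decisive for
stable training under short schedules. The trainer is
compiled (RcppArmadillo, single precision, batched GEMM over time steps) so
a full mini iteration — corpus, cochleagrams, three networks, and all
analyses — runs in a few minutes on one CPU.

## Analyses

**Identification.** A token is identified correctly when the cosine of its
prediction to the true target strictly exceeds the cosine to every other
word's target; ties count as errors. Mean cosine and identification
accuracy are reported separately — they are different quantities.

**Decoding.** Hidden trajectories (best-validation weights) are subsampled
by `time_stride`, flattened time-major, columnwise standardized
(zero-variance columns are set to zero rather than dropped, preserving
alignment), clustered by Ward-linkage agglomeration on Euclidean distance,
cut at the true class count, and scored with adjusted mutual information.
AMI uses the hypergeometric (permutation-model) expected MI and arithmetic
mean normalization, so random labelings score about 0; the implementation
is checked against an exhaustive permutation oracle. Cutting at the true
class count is a design decision; `ami_profile()` sweeps k ± 2 around it.

**Selectivity.** Diphone probes (CV and VC, two frame phonemes per target,
all talkers) give each hidden unit's mean response in a 0–100 ms window
after target onset; morpheme selectivity uses the mean response of
root-plus-one-affix tokens over the full padded window, where clamped
frames repeat the final state and so weight the whole-word representation.
The selectivity index scores how often target tokens drive a unit at least
δ = 0.3 activation units above the item's competitors, normalized by
target token count. Two competitor readings are implemented behind the
`competitor` argument. The default compares each target token against the
strongest token of *each* non-target class (per-class counting, as in the
selectivity-index lineage this analysis descends from). The alternative —
beating the single strongest token across *all* non-target classes — is
measurably degenerate: on a fully trained desk-scale network the largest
attainable margin over the global competitor is about 0.16 for tanh
units, so at δ = 0.3 that reading yields an all-zero matrix, and it is
therefore not the default. Item dendrograms (Ward, Euclidean) are compared by
cophenetic correlation to reference hierarchies constructed by the package:
phonemes nested by sonority class, morphemes grouped by the part of speech
of the words they create.

**Errors.** Identification errors are scored for phonological similarity
with a weighted Levenshtein ratio — insertion/deletion cost 1, substitution
cost 2, ratio (|a|+|b|−d)/(|a|+|b|) — the unique weighting under which the
standard worked examples come out at 0.73 (*acted*/*active*) and 0.62
(*killed*/*killing*). The ratio is computed on phoneme strings by default
(one internal symbol per phoneme); an orthographic mode reproduces the
worked examples. Semantic similarity is the cosine of distributional
embeddings built from the synthetic co-occurrence table by PPMI + truncated
SVD (50 dimensions at full scale) — a deliberately self-contained stand-in
for large pretrained embeddings, preserving the distributional-similarity
contract without external data.

## Numerical choices and degenerate inputs

* Training runs in single precision; reported metrics are double. Fixed
  seeds drive weight initialization, batch shuffling, and every generator,
  so reruns reproduce results exactly on one machine.
* Identification ties (exactly equal cosines) are flagged and scored as
  errors; rescaling predictions never changes identification.
* All-silent audio, vowel-free phoneme strings, slot-grid overflows,
  filtered-out words, unattested affixes, and all-padded inputs raise
  errors naming the offending item rather than degrading silently.
* Zero-variance feature columns standardize to zero; identical selectivity
  rows merge at height zero; an all-zero selectivity matrix yields an
  undefined (NA) cophenetic correlation rather than a fabricated value.

## Problem sizes used by the test suite

The shipped tests run the complete study at the mini profile (three seeds:
about 48 words × 4 talkers = 192 tokens, 64 hidden units, 300 epochs per
network, nine trained networks in total) plus micro configurations for the
pipeline smoke tests, keeping the default suite within a desk budget while
exercising every stage at full fidelity. The full-scale `"paper"` profile
(883-word lexicon, 10 talkers, 512 units, 10,000 epochs) runs the
identical code path; its runtime is a multi-day workstation job and is not
part of the test suite.

## Known limitations

* The qualitative dissociation at mini scale is a directional property of
  a small, synthetic corpus; AMI and cophenetic magnitudes are not
  comparable to full-scale values.
* At the desk scale the dissociation is *asymmetric*. In the shipped
  three-seed runs the part-of-speech direction holds in every seed
  (ventral AMI about 0.34–0.51 against dorsal 0.16–0.21, fused in
  between), and both selectivity directions hold in at least two of the
  three seeds (dorsal PSI trees closer to the sonority hierarchy, ventral
  MSI trees closer to the morpheme hierarchy). The onset direction, however, inverts: with only 48 words,
  Ward clusters of the stacked trajectories are dominated by word identity
  for *both* specialists (cluster-versus-word AMI about 0.48), and any
  sound-mapping LSTM at this scale carries strong phonological prefix
  (cohort) structure — the ventral network decodes onsets above both its
  own target-structure ceiling and the raw-cochleagram baseline, while the
  dorsal network's target advantage (onset fills 3 of 28 slots) is too
  dilute to dominate. Word-level clustering pressure shrinks roughly with
  lexicon size, so this is a scale artifact of the 48-word profile, not a
  property of the full-scale study design.
* The parametric synthesizer's phoneme cues are cleaner than natural
  speech; decoding scores at mini scale are accordingly optimistic for
  acoustically cued classes (morphologically marked POS classes are partly
  audible, which the full-scale lexicon dilutes far more than 48 words
  can).
* The lexicon is distributionally matched to the target study (sizes,
  affix inventory, length constraint), not lexically: no claim is made
  about specific English words.
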