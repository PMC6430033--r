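---
title: "Methods: sentence memory and question answering with theta-gamma codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sentence memory and question answering with theta-gamma codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripletQA)
```

This vignette documents the model implemented by `tripletQA`, its
assumptions, the parameters that matter, and the design decisions taken
where the architecture leaves choices open.

## Word vectors and similarity

Every word is a sparse nonnegative rate vector over `N` units. The *active
set* (units with positive rate) carries lexical identity; rates carry
modifiers. Defaults `N = 1000`, `a = 10` active units per word: small enough
that the whole test suite runs on a laptop, large enough that two random
words share an active unit only with probability about `a^2/N = 0.1` and the
chance of a spurious half-overlap is negligible. All stochastic constructors
take explicit seeds; per-symbol streams are derived from the lexicon seed
with a rolling string hash, so a lexicon is a pure function of its
specification and seed.

Two different normalizations of active-set overlap are used deliberately:

* **Similarity** (synonymy, alignment, cancellation, pointer targeting) is
  `|A(u) ∩ A(v)| / min(|A(u)|, |A(v)|)`. Min-normalization lets a
  superposition pointer *contain* a word fully (overlap 1), which is what
  makes a pointer respond to each of its constituents.
* **Lexicality** (`is_lexical()`) is probe-normalized:
  `|A(v) ∩ A(w)| / |A(v)|` for probe `v` against entry `w`. Under
  min-normalization every pointer would trivially "match" each word inside
  it; probe-normalization instead asks how much of the probe a single entry
  explains, so a word (however rate-modified) scores 1 while a three-word
  superposition scores about 1/3 against its best entry and is recognized
  as a pointer. Both thresholds default to 0.5.

Synonyms are modeled as assemblies sharing 60% of their active units
(configurable `synonym_shared_frac`; it must exceed the similarity
threshold). Modifier transforms are *diagonal positive* rate scalings: a
general matrix could change the active set and thereby break the
rate-remapping account, so composition is restricted to what the coding
scheme actually claims.

## Chunking and buffers

`chunk_triplet()` concatenates the three element vectors into a length-`3N`
spatial pattern; `dechunk_triplet()` is its exact inverse (a property test
checks the round trip). The abstract buffer (`theta_gamma_state()`) holds at
most 7 chunked triplets, one per gamma slot; slot order persists across
theta cycles absent input. The element stream of the comparator runs at
three times the buffer's gamma frequency (90 Hz at the default 30 Hz), so
exactly one element is active at a time.

### Spiking mode

`simulate_buffer()`/`align_buffers()` implement the buffers as
integrate-to-threshold units: a neuron fires when

```
theta(t) + ADP(t - t_last_spike) + synaptic input >= threshold.
```

Parameters with published values keep them: `A_ADP = 6.7` mV (reading the
"6, 7 mV" decimal comma as 6.7; the headline alignment result holds for any
value in 6.5-7.0, while at 6.0 the last gamma slot sits at the edge of the
suprathreshold window and can drop out), cross-buffer excitation
`A_exc = 6` mV with `t_exc = 7` ms, cross-buffer inhibition
`A_inh_cross = -2` mV and inhibitory decay `t_inh = 3` ms ("t_ihn" is
presumed a typo). The remaining constants are this package's choices, set so
that the *stated behavior* — stable slots, alignment of misaligned
ensembles, no recruitment of silent neurons — emerges:

| parameter | default | why |
|---|---|---|
| `theta_period` | 140 ms | about 7 gamma slots of about 20 ms |
| `A_theta` | 4 mV | subthreshold theta drive |
| `threshold` | 8.5 mV above rest | see the recruitment bound below |
| `tau_ADP` | 4 ms | logistic ADP rise saturating near `t_ADP_peak` = one theta period; steep enough to pin each ensemble's phase, shallow enough that inhibition-induced delays recover in about 2 ms |
| `t_ADP_fall`, `tau_ADP_fall` | +40 ms, 8 ms | slow ADP decay: an ensemble silent for a couple of cycles loses its slot |
| `A_fb` | -2.5 mV | within-buffer feedback inhibition; keeps the equilibrium slot pitch at or above `t_inh` |
| `dt`, refractory | 0.05 ms, 2 ms | deterministic Euler stepping; `dt < t_inh` enforced |

Two modeling decisions matter most:

1. **Ensemble-normalized inhibition.** "All other neurons inhibit" is
   implemented as one `A_inh_cross` kick per synchronously firing ensemble
   (and likewise for feedback inhibition). With per-neuron summation a
   10-neuron ensemble would deliver -18 mV alongside the +6 mV counterpart
   EPSP, making the net cross-buffer input negative everywhere and
   alignment impossible.
2. **The recruitment bound.** The net kick a qWM neuron receives when its
   counterpart ensemble fires is `A_exc - (9/10)|A_inh_cross|` = 4.2 mV.
   The threshold must exceed the theta peak plus this kick (else silent
   neurons would be recruited and alignment would *add* patterns to the
   question buffer, violating content conservation) and lie below theta
   peak plus saturated ADP (else active ensembles stop re-firing). 8.5 mV
   sits between those bounds with about 0.3 mV margin on the recruitment
   side and a roughly 50 ms suprathreshold window, in which seven 4 ms
   slots fit comfortably.

In the alignment scenario (`fig5_scenario()`) the answer buffer holds A-D in
four consecutive slots and the question buffer holds B and D in the two
adjacent slots after them. Each question ensemble's counterpart volley then
arrives *before* its own crossing, and the +4.2 mV net kick fires it in
synchrony immediately: convergence at theta cycle 2, final B-D separation 2
gamma slots, measured against the answer buffer's own slot grid. (Starting
the question ensembles *before* their counterparts also aligns, but by slow
inhibition-led drift over more cycles; the scenario default is the
configuration that reproduces the published outcome within 4 cycles.)
Gamma-slot assignment in the diagnostics maps each question ensemble to the
nearest answer-ensemble firing time, so the measured separation is an
integer and insensitive to the slow common phase drift of the grid.

Slot-mode and spiking-mode alignment agree on the fixture scenarios (a test
encodes the ensembles as indicator chunks and compares slot maps).

## Episodic memory

`eltm_state()` builds 7 modules x 3 element subregions (21 in all). Storage
is one-shot: triplet k becomes an attractor of module k and all pairs of a
sentence's triplets get directed priming links. Retrieval is
*prime-then-excite*:

* a broadcast activates, per module, the best stored match with chunked
  overlap at or above `match_threshold` (default **0.6**: a triplet
  matching on two of three elements, overlap 2/3, must count as close —
  otherwise a question with one wrong or substituted element could never
  retrieve the memory it asks about and every mismatch question would come
  back "I do not know" instead of "No"; single-element coincidences at 1/3
  stay below);
* an incumbent attractor is displaced only by a challenger that is both
  *primed* and *strongly driven* (overlap at or above
  `full_match_threshold`, default **0.8**, separating exact/synonym-level
  evocations at 1.0/0.87 from partial ones at 0.67 given the
  representation geometry). A weak partial evocation never overturns an
  established attractor;
* priming spreads from active *cells*, not sentence labels: when two
  sentences store the same triplet in the same module they share that
  assembly, so its activation primes both sentences' mates;
* statuses (active/primed) are transient query state, cleared by
  `begin_query()`; stored patterns and weights are read-only during
  retrieval.

Finalization switches synapses to excitatory mode and selects the sentence
with the greatest number of query triplets whose full-match evidence was
instantiated as an active pattern in the right module at any point of the
search — later displacement does not erase that evidence (synaptic traces of
transient attractor activity). Fully shared triplets dominate; partial
evocations break ties; remaining ties go to the earliest-stored sentence.
This evidence-based coalition is what makes network retrieval equal the
exhaustive symbolic oracle on randomized corpora, including corpora where
shared triplets land in the *same* module and naive label-based counting
loses evidence to attribution races. Priming safety holds throughout: a
triplet not in the query is never activated before finalization (checked on
every fixture trace and broadcast order).

## Comparator

After retrieval the memory is dechunked into the answer buffer in module
order, the question buffer is conceptually aligned to it (greedy
highest-overlap assignment at threshold 0.5; on ties the higher-overlap
pair wins and the loser falls to its next-best slot; unmatched question
triplets pack into the lowest free slots in original order), and both
buffers stream element by element.

* **Y/N:** subtraction as subsumption — the answer element cancels the
  question element when it covers at least the similarity threshold of the
  question element's active units, so synonyms cancel and rate-level
  modifiers never block a match. Verdict "yes" requires all co-filled slots
  to cancel on all three roles *and* every question slot to have an answer
  counterpart; empty-against-empty slots are not compared. Zero co-filled
  slots with a nonempty question raises an error: alignment was skipped.
* **WH:** exactly one typed placeholder is required (multiple placeholders
  are rejected with a clear error — only single-gap questions are
  modeled). The answer element at the placeholder's slot and role must be
  category-compatible: `person_WH` to person, `place_WH` to place,
  `time_WH` to time, `manner_WH` to manner, `something_WH` to thing or
  event — and only `something_WH` accepts a pointer, since only "what" can
  ask about a whole event. Compatibility is a category-table check rather
  than a vector overlap against the placeholder's pattern; how a
  placeholder's vector should be built so that overlap does that work is
  left open by the architecture, and the table is the deterministic
  equivalent.
* **Unpacking:** a pointer candidate is resolved against the answer-buffer
  triplets in slots after its host triplet (embedded clauses always follow
  their pointer, which also guarantees termination). The target maximizes
  min-normalized overlap of superpositions, with Jaccard overlap as the
  tie-break: containment makes min-overlap saturate at 1 for both the true
  target and deeper triplets, and Jaccard prefers the tightest
  superposition. Remaining ties go to the earliest slot.

Rendering is an explicit stub for a language generator: verdict word plus
space-joined symbols with compositional-word hyphens expanded, no
morphology, tense or agreement.

## Synthetic corpora and the oracle

`generate_corpus()` emulates the conditions of the worked examples at scale:
symbolic vocabularies split 30% persons / 30% verbs / 40% things (default 24
base words), sentences of up to 7 subject-verb-object clauses, clause
sharing between sentences with probability `overlap_rate = 0.2`, synonym
twins for 25% of each pool, and optional embedded-clause pointer chains
(depth up to 3). For each sentence three question types are derived — a
shuffled verbatim sub-selection, a synonym-substituted variant, and a
variant with one element corrupted *across* synonym-group boundaries so the
expected verdict is unambiguous. Expected answers come from
`oracle_answer()`, an exhaustive symbolic search independent of the vector
pipeline: two elements are similar when identical or in one synonym group; a
clause supports a sentence at a two-of-three match (retrievability) and
matches it fully at three of three; the closest sentence maximizes full
matches, then partial matches, then storage order.

What the generator does *not* emulate: natural language (vocabulary is
symbolic), graded semantic relatedness beyond flat synonym groups,
taxonomic relations, noisy or correlated word vectors, and questions with
placeholders (WH behavior is covered by the fixture scenarios). Passing the
generated-corpus properties therefore demonstrates the retrieval and
comparison machinery, not robustness to realistic language.

Problem sizes in the test suite are desk-scale by design: corpora of 2-6
sentences x 2-5 triplets, 100 seeded corpora for the oracle-equivalence
property, vocabulary of about 30 words, `N = 400` for unit tests and
`N = 1000` for the pipeline properties; the spiking simulations run 4 theta
cycles (560 ms) at `dt = 0.05` ms.

## Known limitations

* Retrieval scoring counts *evidence*, not a biophysical settling process;
  the attractor dynamics are contract-level (pattern completion above
  threshold), with no noise, forgetting, or consolidation.
* The spiking buffer is deterministic and noise-free; its free constants
  realize the documented behavioral contract and are not fits to
  physiology.
* Alignment correspondence between buffers is hard-wired identity (neuron
  i to neuron i); how that correspondence would be learned during encoding
  is outside the model.
* The element comparator treats rate-modified words as matching their base
  word (cancellation is active-set based), so Y/N questions cannot
  distinguish `nice-meal` from `meal`.
* Questions with more triplets than the stored memory answer "no" by the
  no-counterpart rule; only single-placeholder WH questions are supported.
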