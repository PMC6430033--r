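# tripletQA

How could a brain store a sentence and later answer a question about it?
`tripletQA` implements a network-level model of exactly that pipeline, for
computational neuroscientists who want to probe its mechanisms and for
modelers who need a working reference of theta–gamma buffer codes, modular
attractor retrieval, and sparse vector pointers in one place.

## The model

A sentence is parsed (parsing itself is treated as a black box; the package
reads a canonical triplet notation) into up to 7 clauses, each a triplet
`<subject, verb, object>`. Every word `w` is a sparse vector **V**(w) of N
units (defaults N = 1000, 10 active units); adjectives and adverbs do not get
their own triplets but rescale the rates of their noun or verb — a
compositional word such as `nice-meal` keeps `meal`'s active units
(rate-remapping), so `"John ate a nice meal"` needs one triplet, not two.

* **First chunking.** A triplet becomes a single spatial pattern
  **T** = **V**(subj) ⊕ **V**(verb) ⊕ **V**(obj) (concatenation, length 3N).
* **Working memory.** A theta–gamma buffer holds up to 7 chunked triplets,
  one per gamma subcycle of each theta cycle. A spiking implementation
  (after-depolarization ramps plus feedback inhibition) maintains the slots
  and, with one-to-one excitatory and ensemble-wise inhibitory connections
  between two buffers, performs *conceptual alignment*: question triplets
  migrate into the gamma slots of their most similar answer triplets.
* **Second chunking / episodic memory.** The 7 triplets of a sentence are
  laid out across 7 attractor modules (3 element subregions each, 21 in
  all) and linked pairwise by one-shot Hebbian priming connections.
* **Retrieval.** Each question triplet is broadcast to all modules in
  parallel. Matching stored triplets become active attractors; active
  triplets *prime* their sentence-mates (priming alone never activates); a
  primed, strongly driven triplet can displace an incumbent attractor. A
  final synaptic mode switch (prime-only → excitatory) completes the single
  closest memory — the stored sentence sharing the most question triplets —
  even its never-queried clauses.
* **Comparator.** The retrieved memory is dechunked into the answer buffer,
  aligned with the question buffer, then streamed element by element at 3×
  the gamma frequency. Yes/No questions are answered by subtraction
  (inhibitory cancellation; synonyms cancel), WH questions by reading the
  element aligned with a typed placeholder (`something_WH`, `person_WH`,
  ...). An embedded clause is stored as a *pointer* — the superposition
  **V**([J+h+B]) = **V**(John)+**V**(hit)+**V**(Boris) — recognized by
  matching no lexicon entry, and unpacked recursively at answer time.

## Worked example

```r
library(tripletQA)

lex  <- fixture_lexicon()                 # demo vocabulary, seeded sparse vectors
eltm <- eltm_state()
eltm <- encode_sentence("<John,eat,cake> <Boris,drink,tea>", eltm, lex)

answer_question("<Boris,drink,tea>",          eltm, lex)$rendered
#> "Yes."
answer_question("<Boris,drink,beer>",         eltm, lex)$rendered
#> "No, Boris drink tea."
answer_question("<Boris,drink,something_WH>", eltm, lex)$rendered
#> "Tea."
```

`"Yes."` means every question triplet cancelled element-wise against the
retrieved memory; the `"No"` answer names the mismatching stored clause
(`beer` vs `tea`); the WH answer returns the element aligned with the
placeholder. Nested clauses unpack through pointers:

```r
eltm2 <- encode_sentence(
  "<[N+s+J+h+B],bother,Marco> <Natasha,see,[J+h+B]> <John,hit,Boris>",
  eltm_state(), lex)
answer_question("<something_WH,bother,Marco>", eltm2, lex)$rendered
#> "Natasha see John hit Boris."
```

The spiking alignment simulation (question buffer holding ensembles B and D
misaligned against an answer buffer holding A–D):

```r
al <- do.call(align_buffers, fig5_scenario())
al
#> spiking buffer alignment: 4 theta cycles
#>   converged at theta cycle: 2
#>   final qWM slots:
#>  pattern   time slot cycle
#>        B 452.50    2     4
#>        D 464.15    4     4
```

B and D end in their answer-buffer counterparts' slots, 2 gamma cycles
apart. `run_demo()` executes the bundled scenarios (`"fig2"`, `"fig3a"` ...
`"fig5"`) end to end; `tqa_main()` (or the `inst/cli/tripletqa` script)
exposes `store`, `ask`, `demo`, `generate` and `simulate-alignment`
subcommands, e.g.

```sh
Rscript inst/cli/tripletqa ask \
  --corpus inst/extdata/example_corpus.jsonl \
  --question "<Boris,eat,chocolate> <John,cook,scallop>"
```

## Package layout

| Area | Files |
|---|---|
| sparse coding, pointers, chunking | `R/representation.R` |
| triplet notation reader/writer | `R/notation.R` |
| theta–gamma buffers (slot + spiking modes) | `R/wm-buffers.R`, `R/spiking-buffer.R` |
| episodic attractor memory | `R/eltm.R` |
| element comparator and unpacking | `R/comparator.R` |
| pipelines, rendering, demos, CLI | `R/qa-engine.R`, `R/cli.R` |
| fixtures, corpus generator, oracle | `R/scenarios.R` |

The methods vignette (`vignettes/triplet-qa-methods.Rmd`) documents the
model assumptions, every tunable parameter, and the design decisions.
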