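Package: tripletQA
Title: Theta-Gamma Working Memory and Attractor Retrieval Model of
    Sentence Question Answering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A neural-network-level model of how sentences can be stored
    and questions about them answered. Sentences are parsed into
    subject-verb-object triplets over sparse distributed word vectors,
    chunked into spatial patterns, held in theta-gamma working-memory
    buffers (up to seven triplets, one per gamma slot), and stored
    one-shot in a modular attractor episodic long-term memory. Questions
    are answered by a prime-then-excite parallel memory search, conceptual
    alignment of the question and answer buffers (including a spiking
    buffer simulation of the alignment dynamics), and an element-wise
    comparator supporting Yes/No questions, WH questions with typed
    placeholders, and recursive unpacking of superposition pointers that
    encode embedded clauses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
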