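---
title: "A dual-stream masked language model for codon optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-stream masked language model for codon optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A protein of length $L$ can be encoded by an enormous number of synonymous
coding sequences, and the choice among synonymous codons affects expression
and stability. Classical "one amino acid–one codon" optimizers always pick
each family's most frequent codon in a reference usage table; by
construction their output has a codon adaptation index (CAI) of exactly 1
but discards all contextual preference (bicodon structure, local variation)
present in naturally highly expressed transcripts. `codonlm` instead learns
codon choice from a training corpus with a sequence model and decodes codon
sequences from protein input alone.

## The model

The encoder processes two aligned token streams of the same length: an
amino-acid stream (vocabulary: 20 residues + PAD + MASK) and a codon stream
(64 codons + PAD + MASK), with learned absolute position embeddings shared
between streams so position $i$ of both refers to the same residue. Each of
the $B$ stacked blocks applies, with pre-normalization, residual
connections around every sublayer:

1. self-attention within the amino-acid stream;
2. self-attention within the codon stream (the codon side mirrors the
   amino-acid encoder block for block);
3. **cross-attention in which the amino-acid stream provides the queries
   and the codon stream the keys and values** — the defining wiring: the
   protein positions interrogate the codon context;
4. a position-wise feed-forward sublayer on each stream.

Two linear heads close the network: the codon head reads the *amino-acid*
(query) stream's final states — the stream that must name a codon for every
residue — and the amino-acid head reads the codon stream's final states.
Both streams are randomly masked during training and both heads are
trained, with the loss equal to the sum of the mean masked cross-entropies
of the two heads.

The forward and backward passes are implemented in C++ (RcppArmadillo) and
verified against finite differences in the test suite. Evaluation-mode
forwards are deterministic, batch rows do not interact, and a sequence
whose codon stream is "zeroed" embeds to an all-zero placeholder (not a
learned MASK vector), so its output is a pure function of the protein.

## The sequence-masking curriculum

Masked-token training alone never forces the model to work without the
codon stream, so training follows a curriculum over whole sequences: for
the first `warmup_epochs` (default 15) every codon sequence is fed intact;
thereafter the fraction of codon sequences per batch replaced by the zero
placeholder rises by `increment` (default 5%) every `step_epochs` (default
15), reaching 100% after `full_mask_epoch` (default 300). The fraction at
epoch $e$ is

$$f(e) = \min\!\bigl(1,\; \mathrm{increment}\cdot\lceil (e -
\mathrm{warmup})/\mathrm{step}\rceil\bigr),\qquad f(e) = 1 \text{ for } e >
\mathrm{full\_mask\_epoch},$$

which is monotone, 0 through the warmup, 0.95 at epoch 300 and 1 beyond it
with the default constants. Zeroed sequences are labeled at *every*
position (the whole codon sequence must be predicted); non-zeroed rows get
conventional random token masking (default rate 0.15 per stream; masked
tokens are always replaced by MASK — we deliberately drop the 80/10/10
random-replacement scheme for simplicity). The schedule is fully
parametric: desk-scale runs use a compressed schedule (warmup 1, step 1,
increment 0.2, full mask by epoch 6) that preserves its shape.

Decoding (`predict()`) runs one evaluation-mode forward pass with the
codon stream fully zeroed — the regime the curriculum trains towards — and
takes the per-position argmax over the 64 real codons. With
`constrain = TRUE` the argmax is restricted to the residue's synonymous
family, which guarantees exact back-translation for any parameters;
unconstrained decoding reports what the model actually believes, and its
amino-acid fidelity is a separate evaluation output.

## Choices a user can tune

| parameter | default | meaning |
|---|---|---|
| `embed_dim`, `n_blocks`, `n_heads`, `ff_dim` | 64, 2, 4, 128 ("tiny") | encoder size; the "tiny" preset is a desk-scale choice, `"base"` (256/6/8/512) a starting point for real corpora |
| `dropout` | 0 | sublayer-output dropout; useful on large corpora |
| `codon_mask_rate`, `aa_mask_rate` | 0.15 | per-position token-mask probability per stream |
| `learning_rate` | 1e-3 | Adam step size |
| `tpm_threshold` | 5 | expression filter keeps records with TPM strictly greater |
| `pseudo` | 0.5 | count floor for never-observed codons, keeps CAI finite |
| `jcat_proportion` presets | 0, 0.1, 0.25, 0.5 | shipped default admixture proportions of one-codon-optimized sequences (this package's defaults, not values from any external study) |

CAI is the geometric mean of relative adaptiveness $w$ over coding codons;
we include single-codon families ($w = 1$; they change the length
normalization but not the deficit) and exclude stop codons, matching the
EMBOSS `cai` convention. Ties in the one-codon optimizer are broken by the
lexicographically smallest codon so results are platform-independent.

## The synthetic corpus generator

Real corpora of highly expressed transcripts are large and external, so
experiments run on a generator that emulates their two key statistical
features: a planted within-family codon-usage bias and a first-order
(neighbour-conditioned) component of synonymous choice.

Proteins are uniform over the 20 residues with lengths uniform in
`length_range`. The planted usage default skews each family geometrically
(ratio 0.6) along a fixed wobble-base preference order (C > G > T > A, the
broad pattern of highly expressed human genes). Synonymous choice mixes
the planted family distribution with a *conditional* component of weight
`pair_dependence`: a fixed, uniformly stratified hash of the (current,
previous) residue context mapped through the planted within-family
quantile function. Two properties of this construction matter:

* **identifiability** — the conditional component is a function of context
  the decoder can observe (the neighbouring residues). If the dependence
  were keyed instead on hidden features of the previous codon (say its
  wobble base), no decoder working from protein input alone — not even the
  exact posterior argmax — could reproduce the corpus statistics, and the
  usage-recovery experiment would measure nothing about the model;
* **marginal preservation** — because the hash is uniformly stratified
  over contexts, the rule's codon marginal over random proteins equals the
  planted usage, so the corpus usage stays close to the planted table at
  any `pair_dependence`.

With `deterministic_rule = TRUE` the choice is the pure rule (the
`pair_dependence` $\to 1$ limit): a noiseless, fully learnable
synonymous-choice signal used for accuracy experiments.

What the generator does *not* emulate: real amino-acid composition and
length distributions, GC-content gradients, higher-order codon context,
and expression-correlated usage. Passing the desk-scale experiments
therefore demonstrates that the architecture, curriculum and decoder work
end to end — not that the shipped presets reach publication-grade
performance on biological corpora.

## Desk-scale experiments and their sizes

The test suite and the acceptance script run two experiments, sized to a
single CPU:

* **accuracy** — 500 training and 100 held-out sequences of 30–60 codons
  with the deterministic rule, tiny preset, compressed curriculum, 25
  epochs; the median per-sequence codon accuracy of unconstrained decoding
  is the reported statistic. After the curriculum reaches full masking at
  epoch 6, the remaining epochs train the pure protein-to-codon regime.
* **usage recovery** — 500 training sequences with `pair_dependence = 0.5`,
  trained for 40 epochs at learning rate 2e-3 (the stochastic conditional
  needs more optimization than the noiseless rule to pin every context's
  posterior mode), then the *training proteins* are decoded and the codon
  and bicodon frequency vectors of the decoded set are correlated against
  the training corpus. Decoding the corpus's own proteins is the direct
  reading of "does the model reproduce the corpus statistics": it shares
  the amino-acid composition between the two vectors, so the correlation
  measures codon choice rather than composition sampling noise, and at
  desk scale some memorization of training sequences contributes —
  acceptable here because the statistic under test is corpus-level usage,
  while generalization is certified separately by the held-out accuracy
  experiment. The held-out alternative is noise-limited at this corpus
  size: the bicodon vector has 3,721 live cells against roughly 22,000
  corpus bicodons, and the exact posterior decoder applied to held-out
  proteins of this generator measures about 0.88–0.89 bicodon correlation
  — below the 0.90 band — purely from multinomial sampling noise in the
  two empirical vectors.

## Numerical choices

* Layer normalization uses $\varepsilon = 10^{-5}$; softmax subtracts the
  row maximum before exponentiation.
* Parameters initialize as $\mathcal N(0, 0.02^2)$, unit gains and zero
  biases; Adam uses $\beta = (0.9, 0.999)$, $\varepsilon = 10^{-8}$.
* All randomness flows through seeds: parameter initialization, epoch
  shuffling, curriculum sampling and token masking fork per-epoch streams
  from the master seed, so a fit is bitwise reproducible on one device and
  stable under resumption.
* `round()` (banker's rounding) fixes the zeroed-row count per batch and
  the admixture subset size; subsets are drawn uniformly without
  replacement.
* A batch in which masking produced no labels at all is skipped rather
  than divided by zero; a non-finite loss aborts with a diagnostic error.
* Decoding argmax is restricted to the 64 real codons (the PAD/MASK logits
  are never eligible).

## Known limitations

* The encoder caps sequence length at `max_len` (128 codons for the tiny
  preset); longer CDSs must be trained with a larger preset, there is no
  windowing.
* Tissue-specific corpora, genome-annotation/expression-atlas ingestion and
  alternative genetic codes by NCBI table id are out of scope; a custom
  codon-to-amino-acid map can be supplied to `genetic_code()`.
* Minimum free energy is an adapter around an external folding engine
  (`RNAfold`); the package never computes thermodynamics itself, and an
  absent provider is a detectable error, never a silent zero.
* Decoding is single-pass argmax; no iterative refinement or beam search.
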