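---
title: "Predicting RBP binding sites from k-mer embeddings of sequence and structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RBP binding sites from k-mer embeddings of sequence and structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

RNA-binding proteins (RBPs) recognize short sequence motifs on RNA, and for
many RBPs the recognition depends on the structural context in which the
motif sits — a motif presented in a hairpin loop may be bound while the same
motif buried in a stem is not. CLIP-seq experiments provide genome-wide
catalogues of bound sites; the computational task is the standard binary
one: given an RNA fragment, predict whether it contains a binding site.
`kmerbind` implements a classifier for this task whose two ideas are

1. **distributed k-mer representations**: overlapping 3-mers of both the
   nucleotide sequence and a per-position structural annotation are embedded
   with a skip-gram model, replacing one-hot encodings, and
2. **a hybrid convolutional/recurrent architecture**: two convolution
   branches (sequence, structure), a joint convolution over their
   concatenation, a bidirectional LSTM, and a sigmoid read-out.

## Input representation

**Sequence.** FASTA input is normalized to `{A,C,G,U}` (T silently becomes
U; ambiguity codes are rejected by default or resampled in permissive mode).
A sequence of length $L$ becomes $L-2$ overlapping 3-mers; the sequence
vocabulary is the complete enumeration, $4^3 = 64$ tokens.

**Structure.** Each position is annotated with one of six loop types derived
from a dot-bracket secondary structure: stem (S), multiloop (M), hairpin
loop (H), internal loop (I), 3' dangling end (T), 5' dangling start (F).
The annotator classifies a paired position as S and an unpaired position by
its innermost enclosing pair: zero branch helices inside that pair means H,
one means I, two or more means M; unpaired positions outside all pairs are F
before the first paired position and T otherwise, and a fully unpaired
sequence is all T. These rules are declared conventions of this package:
published pipelines delegate the annotation to external folding tools whose
per-position rules are not stated, so we define them explicitly to be
reproducible without those tools, and accept precomputed shape strings from
any source as an alternative input path. Shape strings tokenize exactly like
sequences; with the six-letter alphabet the structure vocabulary has
$6^3 = 216$ tokens (a five-letter convention giving $5^3 = 125$ is supported
for compatibility with pipelines that merge one class).

## Skip-gram embeddings

For a token sequence $s_1 \dots s_n$ the skip-gram objective maximizes, over
all center positions $t$ and offsets $0 < |j| \le m$,
$\log p(s_{t+j} \mid s_t)$, with the softmax replaced by negative sampling:

$$\log\sigma(w_o^\top u_c) \;+\; \sum_{i=1}^{k}
  \mathbb{E}_{s_i\sim P_n}\!\left[\log\sigma(-w_{s_i}^\top u_c)\right],$$

where $u$ are input (center) vectors, $w$ output (context) vectors, and
$P_n$ the unigram distribution raised to 0.75 and renormalized. Defaults
follow standard word2vec practice on small vocabularies: window $m=5$,
dimension $d=30$, five negatives, ten epochs, initial learning rate 0.025
with linear decay, input vectors initialized uniform in $(-0.5/d, 0.5/d)$
and output vectors at zero. Sequence and structure embeddings are two
independent models over disjoint vocabularies, and the downstream
representation uses the input vectors only. To avoid test-set leakage the
corpus is by default the training split.

Two implementation choices deserve notice:

* **Mini-batch aggregation with per-row clipping.** Updates are applied in
  chunks (default 512 pairs): the per-pair gradients are summed per distinct
  k-mer row — the exact mini-batch gradient, which preserves the objective's
  frequency weighting (a per-row *average* would not: it distorts the
  learned geometry measurably against a per-pair SGD oracle) — and each
  row's aggregated step is clipped in norm (default 1). Without the clip,
  on highly repetitive corpora such as shape strings a single row can
  collect hundreds of coherent gradient terms per chunk and the summed step
  overshoots catastrophically.
* **Conditioning.** A skip-gram solution carries a component shared by all
  token vectors; on low-information corpora (uniform random background) that
  shared direction is the optimum itself and dominates the vectors — all
  pairwise cosines exceed 0.99 while the relational part is a few percent of
  the norm. `train_embeddings()` therefore mean-centers the input vectors
  across the vocabulary and rescales to unit mean row norm
  (`condition_embedding()`). This is a linear transformation that leaves
  relative geometry intact and gives the classifier a well-conditioned
  input; without it the network cannot extract the (real) signal buried in
  the near-constant vectors.

## Architecture

For an embedded sequence (length $n$ tokens, $d$ channels) and its embedded
shape string (same grid):

```
seq  -> conv(width 8)  -> ReLU -> maxpool(2) --+
                                               +--> concat channels
shape-> conv(width 16) -> ReLU -> maxpool(2) --+
  -> conv(width 32, joint) -> ReLU -> maxpool(2)
  -> BiLSTM(32 units/direction) -> per-position [h_fwd, h_bwd] (64 features)
  -> max over positions -> dense(64, ReLU) -> dropout -> dense(1) -> sigmoid
```

The kernel widths 8/16/32 are read as one width per module in listing
order; filter counts are not dictated by the architecture description and
default to 64 per convolution. The LSTM follows the standard gated update
(forget/input/output gates, candidate cell); `lstm_step()` is a didactic
single-step reference implementation that the production layer is tested
against. With 32 units per direction the concatenated bidirectional feature
is 64-dimensional.

Design choices where the architecture description is genuinely open:

* **'Same' convolutions.** The two branches use different kernel widths; a
  'valid' convolution would give them different output lengths and break
  position-wise channel concatenation. Zero-padded length-preserving
  convolutions keep the grids aligned. Padding is masked: positions past an
  example's true length are zeroed before every pooling step, the recurrence
  carries state through them, and the global max excludes them — so a
  prediction is invariant (to floating-point exactness) to how far its batch
  happens to be padded, and variable-length input needs no truncation.
* **Recurrent read-out.** The BiLSTM emits its per-position hidden states,
  and the read-out is a max over positions, the convention of the
  DanQ/iDeepS model family. We initially used the alternative read-out (the
  final hidden state of each direction): it trains to memorization of the
  training set without ever generalizing an implanted motif, because the
  convolution filters receive gradient only through the sequence-end states
  of an untrained recurrence. With the per-position read-out the recurrent
  layer sits on a direct gradient path and the same architecture learns.
  The recurrent weight matrices are initialized at a tenth of the Glorot
  scale so the untrained layer is nearly feed-forward.
* **Branch scale equalization.** Shape strings are long runs of a single
  k-mer, so the structure convolution sums coherent inputs and its output is
  several-fold larger than the sequence branch's, drowning the sequence
  signal in the joint module. Before training, the structure convolution is
  rescaled once, on a reference batch, to match the sequence branch's output
  standard deviation (`calibrate = TRUE` in `train_config()`).

**Ablation variants** (shared splits, embeddings and seeds so differences
are attributable to the removed component): `no_structure` drops the
structure branch (the joint convolution consumes the sequence branch alone);
`one_hot` additionally replaces the embedding with the 4-channel identity
code; `cnn_only` removes the BiLSTM, max-pooling the joint convolution
output directly.

## Training

Adam on binary cross-entropy, default learning rate $10^{-3}$, batch 128,
at most 50 epochs, early stopping on validation AUC with patience 5 and
best-validation weights restored. A decoupled weight decay of $10^{-4}$
applies to weight matrices (never biases). Splits are stratified by label;
the conventional split reserves one third of the training data for
validation. Embedding matrices are frozen during classifier training; we do
not implement fine-tuning of the embeddings, since the representation
claims under test do not require it. AUC is computed by the Mann–Whitney
midrank formula, which equals the trapezoidal area under the ROC curve and
is verified against exhaustive pair counting in the tests.

## The synthetic benchmark generator

`generate_dataset()` emulates GraphProt-style two-file benchmarks with exact
ground truth. Positives are i.i.d. background (default uniform composition)
with a consensus motif implanted at a uniformly random admissible position,
each motif position independently mutated to a different base with a stated
probability. Negatives are, configurably: dinucleotide-shuffled positives
(an Eulerian-walk shuffle preserving all adjacent-pair counts — the
composition-matched stand-in for the coordinate-shuffled negatives of CLIP
benchmarks), pure background, or motif-bearing sequences whose structural
context is broken (`motif_out_of_context`), which isolates structure as the
only reliable signal. With a hairpin-loop context, each positive receives a
shape string produced by annotating a constructed stem-loop whose loop
covers the implant window (with the stated coupling probability; otherwise
the hairpin is placed independently); negative shape strings carry a hairpin
at a random position. The generator does not emulate folding
thermodynamics, transcript-level composition bias, CLIP cross-link artifacts
or read coverage; a test passing on this generator demonstrates that the
pipeline can extract the stated signal class, not performance on real
CLIP-seq data.

## Problem sizes used by the tests and the acceptance script

Chosen as desk-scale study conditions and kept fixed. All runs use skip-gram
dimension 16 (5 epochs), minibatch 32, learning rate $5\times10^{-3}$:

* *End-to-end learnability*: 500 positives + 500 negatives, lengths 100–150
  nt, the 7-nt motif UGCAUGU at mutation rate 0.05 inside a hairpin loop,
  shuffled negatives; full variant, 16 filters, at most 20 epochs. The
  label-shuffled control reuses the same sequences with permuted labels.
* *Structure ablation*: 500+500 at 60–100 nt, motif in both classes but in
  the hairpin loop only in positives (`motif_out_of_context` decoys, loop
  never covering the decoy motif); 32 filters, at most 30 epochs.
* *Context-free control and representation ablation*: 500+500 at 60–100 nt,
  hairpin placed independently of the motif (`coupling = 0`), shuffled
  negatives; 32 filters, at most 40 epochs (the full variant converges more
  slowly here because its structure channels carry no signal).
* *Recurrence ablation*: 500+500 at 140–180 nt, two motifs (UGCAUGU,
  GACGUAG) separated by 70–100 nt — beyond the convolution stack's ~64-nt
  receptive field — against `decoy_pair` negatives carrying both motifs at
  unconstrained spacing; 32 filters, at most 26 epochs. A first design with
  30–50-nt gaps fit inside the receptive field and the convolution-only
  variant matched the full model, so the gap was widened to realize the
  long-range construction.

The package defaults (64 filters, $d=30$) serve real-data scale; the desk
configurations are smaller solely in capacity, not in architecture.

## Known limitations

* The structure annotator defines external-loop positions between two
  helices as T (dangling end); external tools may use another convention —
  the adapter path accepts their strings unchanged.
* Pseudoknots are outside dot-bracket semantics and are rejected.
* The skip-gram trainer is mini-batch, not per-pair; with very large chunk
  sizes high-frequency tokens would see fewer effective updates.
* Embeddings are frozen during classifier training.
* On corpora with near-zero co-occurrence structure the embedding carries
  little information by construction; the conditioning step exposes what is
  there but cannot create signal.
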