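# kmerbind

Predicting RNA-binding-protein (RBP) binding sites from RNA sequence *and*
secondary structure, for computational biologists who work with CLIP-seq
derived site catalogues (GraphProt-style positive/negative FASTA pairs) or
who need a fully controlled synthetic benchmark for sequence-structure
classifiers.

## The method

A fragment's nucleotide sequence and its per-position structural context —
the six loop types stem (S), multiloop (M), hairpin (H), internal loop (I),
dangling end (T), dangling start (F) derived from a dot-bracket structure —
are each split into overlapping 3-mers. Both 3-mer streams are embedded with
a skip-gram model trained by negative sampling,

```
log σ(w_o·u_c) + Σ_{i=1..k} E_{s_i~P_n}[ log σ(−w_{s_i}·u_c) ],
```

replacing one-hot encodings with dense distributed representations (complete
vocabularies: 4³ = 64 sequence 3-mers; 6³ = 216 shape 3-mers, or 5³ = 125
under the five-letter convention). The embedded streams feed a hybrid
network: a convolution branch per stream (kernel widths 8 and 16), channel
concatenation, a joint convolution (width 32) capturing sequence–structure
interplay, max-pooling (width 2) after every convolution, a bidirectional
LSTM (32 units per direction; 64 concatenated features per position), a
max over positions, two dense layers and a sigmoid that outputs the binding
probability. Performance is measured as AUROC via the Mann–Whitney rank
statistic. Ablation variants — `no_structure`, `one_hot`, `cnn_only` —
isolate the contribution of the structure branch, the distributed
representation, and the recurrent layer.

Everything is implemented natively in R (the network, its exact
backpropagation, Adam, and the skip-gram trainer), seeded end to end, with
variable-length input handled by masked padding so predictions are
independent of batch composition.

## Worked example

```r
library(kmerbind)

# a synthetic GraphProt-style dataset with exact ground truth:
# positives carry UGCAUGU inside a hairpin loop, negatives are
# dinucleotide-shuffled positives
spec <- synthetic_spec(n_pos = 250, n_neg = 250, length_range = c(100, 150),
                       motif = "UGCAUGU", per_position_mutation_rate = 0.05,
                       structural_context = "hairpin_loop", seed = 101)
gen <- generate_dataset(spec)
gen$dataset
#> <labeled_dataset> 500 examples (250 positive, 250 negative), shapes: present
#> provenance: synthetic(motif=UGCAUGU, context=hairpin_loop, neg=shuffle, seed=101)

splits <- split_dataset(gen$dataset, val_fraction = 1/3, test_fraction = 0.25,
                        seed = 7)
emb <- train_embeddings(splits$train,
                        skipgram_config(dim = 16, epochs = 5, seed = 3),
                        skipgram_config(dim = 16, epochs = 5, seed = 4))

cfg <- model_config(variant = "full", filters = 16,
                    input_dim_seq = 16, input_dim_struct = 16, seed = 5)
tcfg <- train_config(epochs = 30, batch_size = 32, lr = 5e-3, patience = 8,
                     seed = 9)
model <- train_model(cfg, tcfg, splits, emb)

pred <- predict_dataset(model, splits$test, emb)
compute_auc(pred$label, pred$score)
#> [1] 0.9721644
```

The held-out AUC of 0.97 says the full model recovered the implanted
motif-in-hairpin signal almost perfectly; a label-shuffled control trained
the same way stays near 0.5. `run_ablation()` trains several variants on
identical splits, embeddings and seeds and returns one evaluation report per
variant, so AUC differences are attributable to the removed component.

Structure annotation from dot-bracket input:

```r
annotate_shapes(parse_dot_bracket("..((((...)))).."))
#> [1] "FFSSSSHHHSSSSTT"
```

A command-line front end over the same functions (subcommands `simulate`,
`annotate`, `embed`, `train`, `predict`, `evaluate`, `ablate`) is installed
at `inst/cli/kmerbind.R`.

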