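# afmid

Molecular identification from high-resolution AFM image stacks, cast as
image captioning.

HR-AFM with CO-functionalized tips resolves the internal structure of
individual quasiplanar organic molecules. A stack of ten constant-height
images (tip heights 2.8–3.7 Å, 0.1 Å apart) carries enough joint
structural and chemical information to name the molecule outright. `afmid`
implements the two-stage multimodal recurrent architecture that does so:

1. **M-RNN<sub>A</sub>** — a CNN encodes the stack into a feature vector
   *v*; an LSTM summarizes the padded semantic input (length 19:
   `startseq` + up to 17 attribute slots); a fusion head
   `concat(v, h) → dense → softmax` greedily emits the set of *attributes*
   (moiety-denoting IUPAC terms such as `brom`, `nitr`) until `endseq`.
2. **AM-RNN** — the same architecture conditioned on the attribute set
   (semantic input length 76: 18 attribute slots + `startseq` + 57 term
   history slots) generates the full IUPAC name term by term.

Around the models, the package ships everything needed to exercise the
pipeline end to end on synthetic data: an IUPAC *term* tokenizer (greedy
longest-match with backtracking) with dataset admission filters (≤ 57
terms, ≤ 17 distinct attributes), a constrained nomenclature grammar
(benzene / naphthalene / pyridine scaffolds, eight substituent types,
exact lowest-locant naming), a physics-inspired constant-height stack
simulator with species-dependent contrast (near-invisible H, halogen
σ-hole ovals, sharpened N vertices), the 6 × 4 operational-parameter
augmentation grid, stack-coherent image deformations (IDG), teacher-forced
two-stage training, and BLEU *n*-gram evaluation with a term-level error
taxonomy and embedding-space neighbor analysis. The networks, including
backpropagation through time and Adam, are implemented directly in
vectorized R and validated against finite differences.

Who this is for: researchers prototyping scanning-probe identification
pipelines, and anyone who wants a fully controlled, desk-scale testbed for
attribute-conditioned sequence decoding on image stacks.

## Worked example

```r
library(afmid)
vocab <- default_vocabulary()

lay <- build_layout("naphthalene",
                    data.frame(position = c(1, 6), sub = c("bromo", "nitro")))
lay
#> <molecule_layout> 1-bromo-6-nitronaphthalene (20 atoms, scaffold naphthalene)

seq <- tokenize_name(lay$name, vocab)
seq
#> <term_sequence> 11 terms: 1 | - | brom | o | - | 6 | - | nitr | o | naphthal | ene
extract_attributes(seq, vocab)
#> <attribute_set> {brom, nitr, naphthal}

stack <- render_stack(lay, params = parameter_grid()[1, ], molecule_id = "demo")
stack
#> <image_stack> 128x128 px, 10 planes (2.8..3.7 A), combo (a=1, k=1)

# how the metric scores a near miss (locant 5 instead of 6):
cumulative_bleu(tokenize_name("1-bromo-5-nitronaphthalene", vocab), seq)
#> <bleu_report> p1..p4 = 0.909 0.800 0.667 0.500 | BP = 1.0000 | cumulative-4 = 0.7017
```

The layout is named by exact systematic nomenclature (lowest locants over
the ring symmetry group, alphabetical citation), tokenized into the term
vocabulary, and rendered into the ten-plane stack the networks consume.
The BLEU report shows the clipped n-gram precisions, the brevity penalty,
and the cumulative 4-gram score: a single wrong locant still leaves large
correct name segments, which is exactly what the metric is meant to
credit.

Training and free-running prediction at mini scale:

```r
man <- generate_dataset(70, seed = 11,
                        fractions = c(train = 50/70, val = 0, test = 20/70))
fit <- train_two_stage(man, train_config(epochs_attr = 300,
                                         epochs_name = 400, seed = 1))
preds <- predict_manifest(fit, man, default_vocabulary(), split = "train")
mean(preds$exact)
#> [1] 1
```

A CPU-only run (a few minutes) memorizes its 50 training molecules
exactly — the end-to-end identifiability check — and on the 20 held-out
molecules, conditioning the name network on true attribute sets beats
deliberately shuffled ones on the cumulative 4-gram, the mechanism the
two-stage design rests on.

A thin command-line wrapper is installed under
`system.file("cli", "afmid.R", package = "afmid")` with subcommands
`simulate`, `train`, `predict`, `evaluate`, `embed-neighbors`.

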