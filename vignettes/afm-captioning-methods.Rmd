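---
title: "Methods: molecular identification from HR-AFM stacks as image captioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular identification from HR-AFM stacks as image captioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-resolution atomic force microscopy with CO-functionalized tips resolves
the internal structure of individual quasiplanar organic molecules. A stack
of constant-height frequency-shift images -- here ten planes spanning tip
heights 2.8 to 3.7 Å in 0.1 Å steps -- carries enough joint structural and
chemical information to identify the molecule. `afmid` treats identification
as *image captioning*: the stack is the image, and the molecule's systematic
IUPAC name is the caption, generated token by token.

IUPAC names are concatenations of *terms* (morphemes such as `chlor`, `yl`,
`ene`, locant digits, hyphens and commas). A designated subset of terms, the
*attributes*, denote functional groups and moieties. Prediction is staged:

1. an attribute network (a multimodal CNN + LSTM + fusion model) reads the
   stack and emits the *set* of attributes present, one per time step, until
   it emits `endseq`;
2. a name network reads the stack *and* the attribute set and emits the full
   term sequence the same way.

Conditioning on the attribute set prunes the name network's hypothesis space
drastically: the functional-group inventory is decided before spelling
begins, so the second stage mostly orders moieties and fills in locants and
connectives.

## Semantic inputs and decoding

Both networks consume a fixed-length integer "semantic input" that encodes
the decoding state, padded with zeros (id 0 is reserved for padding and is
never a term id):

* attribute network: length 19 = `startseq` + up to 17 attributes +
  a slot that forces the loop to close with `endseq`;
* name network: length 76 = 18 attribute slots + `startseq` + 57 term
  history slots (57 is the admission bound on decomposition length; 17 the
  bound on distinct attributes).

Decoding is greedy: at each step the fusion head produces a probability
vector over the vocabulary, the argmax is appended to the history (ties
broken toward the lowest vocabulary id, for determinism), and the loop stops
at `endseq` or at the cap. Attributes emitted twice occupy a loop slot but
are deduplicated in the returned set, which is re-sorted by the canonical
comparator before it conditions the name network.

## Architecture choices

The published description fixes the component structure (CNN encoder,
embedding + recurrent semantic branch, concatenating fusion head with fully
connected layers and softmax output) but not layer-level detail, so the
tower here is a package design choice: two 3x3 stride-2 convolutions
(`same` padding, ReLU) over the ten planes treated as input channels,
a flatten, and a dense layer to the feature vector `v` (default 64). The
recurrent cell is an LSTM (width 64 by default) run over the non-zero tokens
of the semantic input; the embedding has 32 dimensions, matching the
embedding space used for the nearest-neighbor term analysis. The fusion head
is `concat(v, h) -> dense(128, ReLU) -> dense(|vocab|) -> softmax`. Dropout
is available on `v` and the fusion hidden layer but defaults to 0: the mini
benchmarks are deliberate overfitting exercises.

No deep-learning framework is involved: layers, backpropagation (including
backprop through time) and Adam are implemented directly in vectorized R and
verified against finite differences in the test suite.

## Tokenization

The tokenizer segments a name into vocabulary terms by greedy longest-match
from the left with backtracking, which finds a segmentation whenever one
exists and is deterministic. Names are processed verbatim; hyphens and
commas are vocabulary terms in their own right. The packaged working
vocabulary (37 terms, 15 attribute-flagged) covers everything the grammar
emits plus a few literature names used in examples; a second packaged file
is a *synthetic* full-schema example with 199 terms and 100 attribute flags
showing how a complete list drops in. Admission filters reject names longer
than 57 terms or with more than 17 distinct attributes.

The attribute comparator sorts by term length and then alphabetically
(byte order). Ascending length is the package's reading of the convention;
descending is available behind a flag (`length_order = "desc"`) because the
convention cannot be pinned down from the published description alone.

## The synthetic grammar and simulator

Training data is fully synthetic, which provides exact ground truth at desk
scale. What passing tests on it demonstrates is therefore *mechanism*, not
field performance: the networks can extract species/position information
from this simulator's contrast model and spell admissible names; results do
not transfer claims to DFT-simulated or experimental images.

**Grammar.** Scaffolds: benzene, naphthalene, pyridine (standard planar
ring geometry; pyridine exercises substitutional-N contrast). Substituents:
F, Cl, Br, I, methyl, amino, nitro, hydroxy, one to four per molecule by
default. Naming is exact systematic substitutive nomenclature for this
family: alphabetical citation ignoring multiplying prefixes, and the lowest
locant rule resolved by exhaustive enumeration of the ring symmetry group
(12 operations for benzene, 4 for naphthalene, 2 for pyridine) -- rings are
small enough that correctness beats cleverness. A lone substituent on
benzene is cited without a locant. The grammar's distinct-name capacity is
computed with Burnside's lemma (cycle-index polynomial per symmetry
operation), and dataset generation rejection-samples unique names under a
seed. With ≤ 4 substituents on these scaffolds, names stress exactly the
term classes that dominate reported error taxonomies: locant digits,
hyphens, commas, multiplying prefixes.

**Simulator.** Each atom contributes an anisotropic super-Gaussian kernel
scaled by `amplitude * exp(-(z - z_atom) / lambda)`. The species table
encodes the contrast phenomenology the classifier exploits: H amplitude is
~8% of C (H on sp² C nearly invisible); halogens get eccentric kernels
elongated along the bond axis (the sigma-hole oval), growing from F to I;
N gets a sharpening exponent > 1 (sharper vertex). This is deliberately
*not* a probe-particle or DFT simulation -- only the species-discriminative,
height-dependent statistical structure matters for the learning problem,
and a closed-form model keeps the ground truth fully controlled. Lateral
kernels are shared across the ten heights (only the exponential weights
differ), which makes the noise-free signal provably non-increasing in z --
a tested invariant. Stacks are normalized to [0, 1] with a single affine
map per stack, preserving inter-plane ordering.

Operational-parameter variation is a 6 x 4 grid (oscillation amplitude x
CO tilt stiffness), modeled as smooth global modulations: amplitude index
scales kernel amplitudes (1.00 down to 0.80), stiffness index scales widths
(0.92 to 1.10). All 24 combos are distinct; per training epoch each molecule
is rendered under one uniformly drawn combo. The IDG applies one
stack-coherent affine deformation (rotation ±5°, shift ±2 px, zoom ±5%,
shear ±0.03 by default -- declared values, the published ranges being
unavailable), optional additive Gaussian noise, and occasional bright
diagonal line artifacts. All ranges may be zero; the identity transform is
exactly reachable and tested.

Nonplanarity is a knob: substituent heavy atoms can receive uniform z
offsets that feed the per-atom decay term, reproducing the degradation
mechanism reported for corrugated molecules. The default is 0 (quasiplanar).

## Training protocol

Teacher forcing: each molecule contributes one example per prefix of its
sorted attribute set and per prefix of its term sequence, with the true
prefix as input and the next token (or `endseq`) as target. Loss is
categorical cross-entropy; padding positions are never scored because
examples are per-prefix. The optimizer is full-batch Adam (the mini
benchmarks have only hundreds of examples; full-batch keeps the run
bitwise-reproducible and fast in vectorized R). The attribute network is
trained first; the name network trains on ground-truth attribute sets and
is evaluated with predicted, true, or deliberately shuffled sets to expose
error propagation and the value of conditioning.

**Problem sizes.** The packaged mini benchmark uses 70 molecules (50
training, 20 held out), rendered at 32 x 32 px over a 12.8 Å field of view,
with 300 attribute epochs and 400 name epochs at learning rate 2e-3. These
sizes were chosen so a CPU-only run converges to zero training loss in a
few minutes while still exercising every pipeline stage; they are quality
floors for the mechanism, not performance claims. At these sizes the fixed
seed run reaches 100% exact match on its training set, and held-out
cumulative 4-gram with true attributes exceeds the shuffled-attribute
baseline in at least 4 of 5 seeds.

## Evaluation conventions

BLEU operates on term tokens. Modified n-gram precisions are clipped
against the single reference; the brevity penalty is
`exp(1 - |ref|/|cand|)` for short candidates and 0 for empty ones. The
cumulative score is the geometric mean of p_1..p_N times BP, with two
declared conventions:

* *no smoothing by default*: any zero precision zeroes the score, so
  errors in short names are penalized harshly (a known property of the
  metric); a smoothing variant (zero counts replaced by `1/(2|cand|)`) sits
  behind a flag for diagnostics only;
* *auto-reweighting*: for candidates shorter than N the order is capped at
  the candidate length, so an exact prediction scores 1.00 regardless of
  length. Without this, a perfect 3-term name would score 0, contradicting
  the defining property that identical sequences score 1.

Attribute accuracy is reported both ways the published figure can be read:
as the mean attribute 1-gram score (equality of sets gives 1.0, otherwise
clipped unigram precision with brevity penalty over the sorted sequences)
and as the exact-set-match rate.

The error taxonomy aligns prediction and reference by minimum edit distance
over terms (unit costs; substitution preferred over insert+delete on ties --
a declared choice, since no alignment is published) and classifies each
operation by the reference term (predicted term for insertions) into:
pure-digit `number`, `hyphen`, `parenthesis`, literal `yl`, square
`bracket`, `other`. Planted-error recovery is exact and tested.

Embedding neighbors: terms are projected into the 32-dimensional embedding
of the name network and ranked by L2 distance (ties by vocabulary id, query
excluded). On mini-scale models only coarse structure (e.g. halogen terms
clustering) can be expected; published neighbor lists require full-scale
training and are out of scope.

## Numerical and degenerate-input notes

* Argmax ties in decoding break toward the lowest vocabulary id.
* Both decoding loops terminate for any fusion head (caps 17 and 57),
  verified with adversarial constant-output heads.
* The kernel renderer restricts each atom to a ±4σ window (with a small
  epsilon so exact boundary pixels land symmetrically); wider tails are
  below 3e-4 of the peak.
* An all-zero stack encodes to a finite feature vector; empty attribute
  sets and empty term sequences are legal everywhere in evaluation.
* `generate_dataset` refuses requests beyond the grammar capacity and
  reports the capacity; rejection sampling aborts with a diagnostic if it
  stalls close to capacity.

## Known limitations

* The simulator is a statistical stand-in: no frequency-shift physics, no
  CO-tilt dynamics, no attractive/repulsive crossover. Conclusions about
  real HR-AFM data require real simulations or experiments.
* The grammar covers single and fused double rings with four substituent
  positions at most; general IUPAC nomenclature (fused polycycles, chains,
  stereodescriptors) is out of scope, as is converting names to structures.
* Mini-scale training demonstrates identifiability and the value of
  attribute conditioning; it does not estimate attainable accuracy at
  dataset scale.
* Checkpoints are serialized R objects; they are portable across platforms
  but not across incompatible model configurations (the loader refuses
  mismatches).
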