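---
title: "Predicting protein function from structure with hierarchical graph attention"
author: "profun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein function from structure with hierarchical graph attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profun)
```

## The problem

Protein function prediction assigns scored Gene Ontology (GO) terms to a
protein, one probability per term, so a single protein can carry many labels
at once. Sequence alone misses the fact that functional sites are *spatial*:
residues that act together are often far apart in sequence but close in the
folded structure. `profun` therefore works on residue graphs derived from 3D
structure and scores GO terms with a graph neural network whose pooling stage
is built around learnable "super-nodes" that can aggregate residues across
the whole graph in one hop, regardless of sequence or graph distance.

## From structure to graph

A chain is reduced to its C-alpha trace (`parseStructure()`, backed by
bio3d's PDB and mmCIF readers). Two residues are connected when their
C-alpha distance is *strictly less than* 10 Angstrom — a pair at exactly the
cutoff is not a contact. Self-loops are not stored in the contact map; the
graph-convolution layer adds them itself when it forms its propagation
operator. Node features are the 21-way one-hot residue identity (20 standard
residues plus `X` for anything else, columns in the order of
`RESIDUE_ALPHABET`), optionally concatenated with precomputed per-residue
language-model embeddings supplied by a file-backed provider
(`fileEmbeddingProvider()`); the language model itself is never bundled or
run, and one-hot-only operation is the tested default.

Parsing choices the upstream data do not dictate are ours: alternate
conformers keep the highest-occupancy location, residues lacking a C-alpha
atom are dropped (with a message), insertion codes are preserved in the
author numbering used by all per-residue exports, and chains with fewer than
two resolved residues are rejected because no meaningful graph exists.

## The network

With node features $X \in \mathbb{R}^{L\times F}$ and contact map $A$:

1. **Encoder.** $N$ graph-convolution layers
   $H^{(n+1)} = \mathrm{ReLU}(\tilde D^{-1/2}\tilde A\tilde D^{-1/2} H^{(n)} W^{(n)})$
   with $\tilde A = A + I$, giving hidden embeddings $H \in \mathbb{R}^{L\times D}$.
2. **Super-node attention.** $K$ learnable query vectors
   $Q \in \mathbb{R}^{K\times D}$ attend over residues. Keys and values are
   themselves graph convolutions of $H$ (one layer each), so attention
   weights respect topology: per head,
   $\Gamma = \mathrm{softmax}(QK^\top/\sqrt D)\,V$, the softmax running over
   residues so each super-node's weights sum to one. Head outputs are
   concatenated and mixed per super-node by a two-layer ReLU MLP into
   $U \in \mathbb{R}^{K\times D}$.
3. **Attention pooling.** A single query $Q_P$ scores the super-nodes,
   $z = \mathrm{softmax}(Q_P (U K_P)^\top/\sqrt D)\, U V_P$.
4. **Head.** A two-layer MLP with elementwise sigmoid maps $z$ to term
   probabilities in $(0,1)$.

Because pooling happens through attention over *all* residues, the network
output is invariant to node relabelling, and the super-nodes can bind
together residues whose only relationship is spatial proximity — the
long-range signal a fixed-depth convolution stack cannot carry along the
backbone.

Dimensions the architecture description leaves open were fixed once:
defaults $D = 512$, $K = 8$ super-nodes, $H = 4$ heads, $N = 4$ layers, all
configurable; each head uses the full width $D$ with distinct parameters and
the scaled dot-product uses $\sqrt D$; the per-super-node mixer and the
prediction head are two-layer ReLU MLPs of width $D$. Initialisation is
seedable Glorot-uniform. There is no deep-learning framework dependency:
forward passes *and* reverse-mode gradients are written directly in base R
matrix algebra, and the analytic gradients are pinned to central finite
differences in the test suite.

## Training

The loss is the unit-weight sum $L = L_{sup} + L_{reg}$.

* $L_{sup}$ is mean binary cross-entropy over the $M \times C$ minibatch
  entries (predictions clamped to $[10^{-7}, 1-10^{-7}]$ inside the logs).
* $L_{reg}$ is an InfoNCE contrastive term: each graph's hidden embeddings
  are perturbed per node by noise of exact Euclidean norm $\varepsilon$
  applied along $\mathrm{sign}(h)$ (zero coordinates stay zero, so the
  ReLU sparsity pattern survives), pooled through the *same* attention
  parameters into a second view $z'$, and
  $L_{reg} = -\tfrac1M\sum_m \log \frac{e^{\cos(z_m, z'_m)/\tau}}{\sum_{m'} e^{\cos(z_m, z'_{m'})/\tau}}$
  with $\tau = 0.5$. Predictions are always taken from the unperturbed
  branch. Cosine similarity is undefined for a zero-norm embedding; a batch
  containing one (possible under the max-pool ablation early in training)
  falls back to the supervised loss alone for that step.

Optimisation is Adam, by default at learning rate $10^{-4}$, batch size 64,
at most 100 epochs, with early stopping after 5 epochs without improvement
of the *total* validation loss; the best-validation parameters are returned.
The validation contrastive term draws its perturbations from a fixed RNG
substream so that successive epochs are compared under identical noise —
otherwise early stopping tracks perturbation noise rather than model
improvement. $\varepsilon$ defaults to 0.1, chosen once as a small fraction
of typical hidden-embedding norms. Batches are iterated graph by graph with
gradients accumulated; for this architecture (attention and pooling are
per-graph) that is algebraically identical to disjoint-union batching, so
per-graph results equal batched results by construction.

## Ontology and evaluation

GO handling follows CAFA conventions. `is_a` and `part_of` both count as
parent edges (configurable); truth sets are ancestor-propagated within each
term's namespace; prediction scores propagate upward by taking the maximum
over descendants; namespace roots are excluded from metrics (configurable)
because a root annotates everything. Information content is
$IC = -\log_2(\text{count}/n)$ in bits from training-set term frequencies;
zero-count terms have no defined IC and are excluded, with a warning, from
semantic-distance sums.

Metrics sweep thresholds $t = 0, 0.01, \ldots, 1$; a term counts as
predicted at $t$ when its score is $\ge t$ *and* positive, so an empty or
all-zero prediction set yields Fmax 0 rather than a degenerate perfect
recall at $t = 0$. Protein-centric Fmax averages precision over proteins
with at least one prediction and recall over all annotated proteins, and
reports the lowest threshold attaining the maximum. Smin is
$\min_t \sqrt{ru(t)^2 + mi(t)^2}$ with $ru$/$mi$ the average IC mass of
false negatives/false positives. "Function-centric" AUPR is computed
micro-averaged over all pooled (protein, term) pairs (macro-per-term is
offered as an option); equal scores enter the precision-recall curve as one
block, so a constant classifier scores exactly the positive prevalence.
Every metric is checked against an independent brute-force oracle in the
tests.

## Residue saliency

Grad-CAM treats the encoder output (the last graph-convolution activations,
$F \in \mathbb{R}^{L\times D}$) as the feature map, computes
$W_{ij} = \partial y / \partial F_{ij}$ by reverse mode, and scores residue
$i$ as $\mathrm{ReLU}(\sum_j W_{ij}F_{ij}/D)$. The derivative is taken with
respect to the pre-sigmoid logit by default — the sigmoid saturates exactly
on the confident predictions one most wants to explain — with the
probability output available as an option. Scores are min-max scaled to
0–100 per protein (a constant map scales to all zeros by convention), and
can be compared against binding-site masks by midrank AUROC, exported as
TSV, or written into the B-factor column of a C-alpha PDB for colouring in
structure viewers.

## The synthetic benchmark

Real corpora for this task require bulk downloads of structures and
annotations, so the package ships a generator whose outputs exercise every
stage end to end. Chains are self-avoiding random walks with exact 3.8
Angstrom C-alpha steps, a 3.6 Angstrom clash floor, and local direction
persistence (stiffness 0.7) so that 10 Angstrom neighbourhoods hold roughly
6–12 residues, as in folded chains, rather than the dense blob an
uncorrelated walk produces. A *motif* is a triplet of one reserved residue
letter (C, H or W by default) planted at positions pairwise at least 10
apart in sequence and pulled mutually within 10 Angstrom by iterative
constraint relaxation — the relaxation preserves consecutive spacing to
within 0.2 Angstrom and the clash floor, and the resulting contacts are
long-range by construction. Each motif drives one term; motifs are planted
independently with probability 0.5; labels are then flipped with probability
0.05 (both settable). Reserved letters are excluded from the background
sequence, and each chain additionally receives isolated decoy copies of the
motif letters that never have a same-letter spatial neighbour: letter
content alone therefore does not decide a label, spatial clustering does. A
brute-force geometric re-detector confirms that planted motifs — and only
they — are present.

What the generator does *not* emulate: secondary structure, side chains,
realistic packing density beyond the spacing/clash/stiffness constraints,
evidence codes, or a deep GO hierarchy. Passing the synthetic benchmarks
shows the pipeline is correct and that the architecture can learn spatial
multi-label rules at small scale; it does not certify performance on real
proteomes.

## Desk-scale experiment settings

The tested benchmark uses 300 proteins of length 40–60, three terms, label
noise 0.05 and an 8:1:1 train/valid/test split, with a small model
($D = 32$, $K = 4$, $H = 2$, $N = 4$). At this scale the optimiser settings
were fixed once as learning rate $5\times10^{-3}$, batch 64, at most 60
epochs, patience 10 — a small model on a small corpus tolerates and needs a
larger step than the full-scale default of $10^{-4}$/100 epochs, and with
noisier epoch-level losses a slightly longer patience is the matched choice.
Held-out Fmax is computed against the held-out split's own (noise-carrying)
labels. The memorisation check (ten noiseless graphs driven below training
loss 0.05) runs with the contrastive term disabled: InfoNCE has a positive
floor in any finite batch of distinct graphs, so "training loss" in a
memorisation limit is the supervised component. The contrastive term's own
effect is verified separately: after training, paired views are more similar
than mismatched ones.

## Known limitations

* Pure-R tensor math is fine at desk scale but not at proteome scale; the
  design isolates all heavy algebra behind the forward/backward helpers, so
  a compiled backend could replace them without interface changes.
* Single chains only: no multi-chain complex graphs, no all-atom or C-beta
  contact definitions.
* The Smin normalisation follows common CAFA practice (average over all
  evaluated proteins, roots excluded); other conventions exist.
* Checkpoints store plain R objects; they are versioned and loading refuses
  an incompatible file, but they are not a cross-language format.
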