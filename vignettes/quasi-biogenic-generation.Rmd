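---
title: "Generating quasi-biogenic compound libraries with a GRU SMILES model"
author: "molgru"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating quasi-biogenic compound libraries with a GRU SMILES model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Biogenic compounds — primary and secondary metabolites — occupy regions of
chemical space that synthetic screening libraries cover poorly, and a large
share of approved drugs trace back to them. `molgru` trains a
character-level language model on the SMILES strings of a biogenic compound
library and then samples it autoregressively to produce *quasi-biogenic*
molecules: novel structures whose token statistics, physicochemical
profile, and scaffold population resemble the biogenic training
distribution, with stereochemistry generated explicitly. Re-training the
fitted model on a small chemotype-focused subset (transfer learning) biases
generation toward that chemotype, which is how focused libraries for lead
optimization are built.

## Molecular representation

Molecules are handled as canonical SMILES throughout; canonicalization,
parse validation, SMARTS matching and the LogP/MW/HBD/HBA/TPSA descriptors
delegate to OpenBabel (via the `obabel` executable and
ChemmineR/ChemmineOB). Every set-level statement in the package —
uniqueness, novelty, reproduction of held-out molecules — is exact set
algebra on these canonical strings, so results are only comparable within
one toolkit version; `toolkitVersion()` is recorded in curation metadata
for that reason. Note that OpenBabel's valence model is more permissive
than some other toolkits, so the package's "validity" means "parses under
OpenBabel".

Tokenization is bracket-aware: an entire bracket-atom expression such as
`[C@@H]` or `[NH3+]` is one token, as are the two-letter halogens `Cl`/`Br`
and `%NN` ring closures; every other character stands alone. Chirality and
charge therefore travel as single alphabet symbols instead of being
scattered over four or five characters, which both shortens sequences and
prevents the sampler from emitting syntactically impossible fragments of a
bracket atom. The `%NN` rule (the grammar's two-digit ring-closure form) is
treated as one token for the same reason: splitting it would allow a
dangling `%`. The vocabulary is the sorted set of tokens observed in the
training corpus plus three reserved markers: `<START>` (id 1), `<END>` (id
2) and `<PAD>` (id 0). The network's output layer spans the corpus tokens
plus the two sequence markers; padding is masked out of the loss and never
predicted. This is the only arithmetic under which a corpus alphabet of
size *k* yields a *k* + 2-way output.

## Model

The generator is a stacked GRU language model: an embedding layer (default
64 units) maps each token id to a dense vector, three GRU layers of 512
units process the sequence, and a linear layer with softmax produces the
next-token distribution. The gate equations use the update-gate convention

$$r_t = \sigma(W_r x_t + U_r h_{t-1}),\quad
  z_t = \sigma(W_z x_t + U_z h_{t-1}),$$
$$\tilde h_t = \tanh(W x_t + U(r_t \odot h_{t-1})),\quad
  h_t = (1 - z_t)\odot h_{t-1} + z_t \odot \tilde h_t,$$

so $z_t \to 1$ replaces the state with the candidate and $z_t \to 0$
preserves memory exactly; both limits are asserted in the tests. Training
minimizes the sequence negative log-likelihood

$$J(\theta) = -\sum_{t=1}^{T} \log P(x^t \mid x^{t-1},\ldots,x^1)$$

with ADAM (learning rate 0.001, $\beta_1 = 0.9$, $\beta_2 = 0.999$, batch
size 128 by default). Variable-length sequences are padded into random
(sort-free) minibatches and the padded positions are masked, so $J(\theta)$
is exact; gradients are normalized per scored token, which makes the
learning rate insensitive to sequence length. The forward pass, full
backpropagation through time and the sampler are compiled (RcppArmadillo);
the analytic gradients are verified in the test suite against
central-difference numerical gradients, and the batched kernel against an
independent plain-R single-step implementation (`gruStep`).

"Trained until convergence" is operationalized as a plateau rule: stop
when the epoch mean loss improves by less than `minDelta` (default 1e-3)
for `patience` (default 3) consecutive epochs, under a hard epoch cap.
Optionally 512 strings are sampled after each epoch and their validity
rate logged, which mirrors the usual monitoring protocol for this model
family. A non-finite loss aborts with a diagnostic. A single integer seed
drives initialization, shuffling and sampling, making runs reproducible;
checkpoints restore bit-identical outputs.

Sampling feeds `<START>`, draws each next token from the unmodified
softmax distribution (temperature 1), feeds it back, and stops at `<END>`
or at `maxLen` = 140 tokens (about the training mean plus three standard
deviations of token counts at full scale); truncated sequences are marked
invalid. `collectUnique()` repeats sampling until a requested number of
valid, mutually unique molecules outside an exclusion set is reached,
within a bounded attempt budget. Uniqueness is defined on canonical
SMILES, so stereoisomers stay distinct while formatting variants collapse.

## Transfer learning

`fineTuneGruModel()` continues optimization from a trained state on a
focused corpus sharing a chemotype. The vocabulary is frozen (out-of-alphabet
molecules are an error) and all parameters are updated — freezing lower
layers is a known alternative, but with corpus-scale alphabets and a small
focused set, whole-model fine-tuning is the simpler choice and matches the
protocol this package follows. The transfer driver compares three arms:
the pre-trained model, a model trained directly on the focused corpus
alone (its vocabulary built from the focused corpus only — the arms are
deliberately asymmetric in that respect), and the fine-tuned model, each
sampled to the same library size with the focused and pre-training
corpora excluded.

## Validation battery

* **Reproduction (RP/RPP).** A k-fold protocol: train on k−1 folds, sample
  a unique library excluding the training folds, count held-out molecules
  reproduced; RPP = RP / |test fold|. `reproductionCurve()` reports RPP at
  growing library sizes; cumulative sample sets grow, so the curve is
  non-decreasing by construction.
* **Scaffolds.** Framework (Murcko-style) scaffolds: ring systems plus
  connecting linkers, side chains removed, substituents double- or
  triple-bonded to the retained core kept, acyclic molecules mapping to an
  empty marker. Absolute scaffold counts are method-sensitive; the
  package's claims are set-algebra relations (new / shared-with-train /
  shared-with-test-only), which are robust to that choice.
* **Similarity.** Hashed circular fingerprints of radius 3 over 2048 bits
  (the ECFP6 setting) compared by Tanimoto similarity; for each scaffold
  the nearest neighbour in the comparison set is recorded and binned.
* **NP-likeness.** A Bayesian log-odds score over atom-centered circular
  fragments (radius 2): fragments are counted in a natural-product
  reference corpus and a synthetic reference corpus, each fragment scores
  the Laplace-smoothed log-odds of the two relative frequencies, and a
  molecule scores the sum over its distinct fragments normalized by heavy
  atoms, with tails softly compressed beyond ±4. The package builds score
  tables from user-supplied reference corpora only; no pre-fitted table
  ships with it, and scores are comparable only within one table. This
  reproduces the *form* of the published score, not its exact constants.
* **Descriptors and maps.** The seven-descriptor panel (cLogP, MW, HBD,
  HBA, rotatable bonds, aromatic ring systems counted as fused systems,
  TPSA) feeds an exact-gradient t-SNE (perplexity 30 by default, fixed
  seed, early exaggeration for the first quarter of the iterations). The
  exact O(n²) algorithm is used deliberately: the profiling sets here are
  hundreds to a few thousands of molecules.

## The synthetic fixture corpus

`fixtureCorpus()` makes the whole pipeline testable offline: a stochastic
grammar chains 2–4 fragments from fixed pools (alkyl and functionalized
chains; benzene, pyridine, furan, thiophene, piperidine, cyclohexane,
naphthalene and coumarin ring systems; amino-acid-like stereocentre
fragments; `[NH3+]`/`[O-]`/quaternary-N charged fragments) with a 30%
branching probability, keeps the unique canonical survivors of the
standard curation filters, and is bit-reproducible per seed. Coumarin is
in the ring pool precisely so the transfer-learning direction can be
tested against the same chemotype the full-scale protocol uses.

What the fixtures emulate: token-class coverage (all bracket forms,
halogens, ring closures), realistic lengths (10–40 heavy atoms), and a
learnable but non-trivial grammar. What they do not emulate: the fragment
statistics, ring-assembly idioms and stereochemical density of real
metabolites. Passing the desk-scale tests therefore demonstrates that the
machinery — tokenization, optimization, sampling, set algebra — behaves
correctly and that learning improves validity and chemotype bias in the
asserted directions; it does not certify full-scale quantitative results,
which require the real biogenic library and hours of training.

## Numerical and design choices

* Curation bounds are inclusive: 10 and 100 heavy atoms survive. "Metal"
  means any element outside {H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I}.
  Duplicates are removed after canonicalization.
* Fold remainders are dealt one per fold, so fold sizes differ by at most
  one.
* Fragment/fingerprint hashing uses a 31-ary polynomial hash modulo
  2^31 − 1; collisions are possible as in any hashed fingerprint and
  irrelevant to the set-algebra guarantees.
* The degenerate inputs each operation handles are part of its contract:
  empty survivor sets, out-of-vocabulary tokens, missing end markers,
  exhausted sampling budgets and invalid SMARTS all raise informative
  errors rather than propagating silently.
* Desk-scale problem sizes used by the test suite and the acceptance
  script (package choices): memorization uses 50 molecules with a
  2×128-unit model; the validity study trains a 3×128-unit model on
  5000 fixture molecules for 20 epochs; transfer fine-tunes that model on
  the coumarin-bearing subset of its own training corpus. The full-scale
  defaults (3×512 units, 128 batch) remain the configuration defaults.

## Known limitations

OpenBabel validity is permissive (some hypervalent strings parse);
canonical SMILES and scaffold strings are toolkit-version-dependent; the
NP-likeness table must be rebuilt by each user from reference corpora;
exact t-SNE scales quadratically; and absolute scaffold counts depend on
the scaffold definition. None of these affect the internal consistency of
the reported comparisons.
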