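---
title: "Multi-objective sequence design with ensemble predictors and QUBO annealing"
author: "quboseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective sequence design with ensemble predictors and QUBO annealing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Machine-learning-guided design of short functional protein regions —
here, the concatenated CDR loops of a VHH (single-domain antibody) —
suffers from a basic difficulty: activity predictors trained on a few
thousand labeled variants are unreliable exactly where design wants to
go, far from the training data.  Ranking candidates by a single
predictor's score therefore concentrates the candidate list in regions
where the score is most likely to be wrong.

`quboseq` treats prediction *instability* as a first-class objective.
An ensemble of k classifiers is trained on k variations of the
training set; for any sequence the ensemble gives a mean predicted
binding probability and a standard deviation across members.  Design
is then a multi-objective problem — maximize the mean, maximize
stability (the negated standard deviation), and maximize a solubility
score — whose Pareto front spans the whole spectrum from adventurous
(high mean, unstable) to conservative (stable) candidates.  Domain
experts pick from that spectrum instead of trusting one acquisition
strategy.

## From counts to labels

The input is a two-pool phage-display count table: reads per variant in
the target-eluted pool and in the non-specifically bound (N.S.) pool
after the final selection round.  The enrichment score of a variant is

    Score = freq_eluted / freq_ns

with frequencies computed from the full table's column totals.
Variants with more than `min_reads = 3` reads in either pool are
retained (strictly greater; the threshold is exposed).  `Score >= 5` is
the positive class, `Score < 1` the negative class.  Three decisions
here were genuinely open and are fixed as follows:

* frequencies are computed **before** the read filter, so a variant's
  score does not depend on which other variants survive filtering;
* records with `1 <= Score < 5` belong to neither class and are
  dropped from training (their count is reported);
* a variant absent from the N.S. pool but present in the eluted pool
  has infinite enrichment and is labeled positive.

The negatives are then shuffled (seeded) and sliced into k = 5 equal
subsets (sizes differ by at most one); each training split is all
positives plus one subset.  Subsampling only the negatives keeps every
split's positive information intact while making members disagree —
this disagreement is the signal the stability objective measures.

## The predictor ensemble

Two architectures sit behind one interface:

* `"birnn"` — a bidirectional recurrent network over the one-hot
  sequence with one hidden layer of size 10, trained for 25 epochs at
  learning rate 0.001 (Adam, minibatches).  This mirrors the kind of
  recurrent classifier typically used for this assay.
* `"logistic"` — ridge-penalized logistic regression on the same
  one-hot features, fitted by iteratively reweighted least squares
  capped at `epochs` iterations.  It is fast, exactly deterministic,
  and is the default for desk-scale runs and the test suite.

For the logistic architecture the toy protocol uses ridge strength
`l2 = 1` rather than a vanishing penalty.  On subsampled splits that
are nearly separable, an unpenalized fit drives predicted
probabilities to saturate at 0/1, which makes "the best predicted
score" a tie among many sequences and the ensemble spread collapse;
the ridge keeps probabilities graded so both the mean and the
instability objective carry information.

The ensemble standard deviation uses divisor k (population form): the
ensemble is a complete, finite set of models, not a sample from a
larger population.  The sample form is available via a flag.

## Objectives

`evaluateObjectives()` returns, per sequence, a maximize-all vector:
`f_mean` (ensemble mean, in [0,1]), `f_stab` (negated ensemble sd, in
[-0.5, 0]) and `f_sol` (solubility).  The sd is negated rather than
inverted so that all three objectives share one convention and the
Pareto machinery needs no special cases.  External solubility
predictors are not re-implemented: any tool that can emit a
(sequence, score) TSV plugs in through `tableScorer()`, and a
deterministic hydropathy-based toy scorer (`toySolubility`, the
sign-flipped mean Kyte–Doolittle index) ships for self-contained runs.
The solubility *objective* and the solubility *selection filter* are
distinct scorer slots, since practice uses different tools for the
two roles.

## Pareto machinery

Dominance, archive maintenance and hypervolume follow the standard
maximize-all definitions.  Hypervolume is exact for up to three
objectives (a sweep over the third coordinate with an exact 2-D
union-of-boxes measure per slab, implemented in C++); beyond three a
seeded Monte-Carlo estimate is used.  The archive's reference point is
fixed once per run — the per-objective minimum over the initial pool
minus a 1e-6 margin — so the hypervolume history is monotone and
comparable within the run.  Candidates whose objective vector exactly
duplicates an archived one are kept in a side list rather than the
front: fronts are sets of points, and the sequences mapping to a point
are reported separately.  Absolute hypervolume values depend on the
reference point and are not comparable across studies that do not
state one.

## The generation loop

Sequence search runs in a binary latent space:

1. **Binary autoencoder.**  One affine encoder layer maps the one-hot
   sequence to d latent logits; the code is the hard threshold
   (logit > 0) and a linear decoder maps bits back to per-position
   residue logits (argmax decoding, ties broken by alphabet order).
   Training uses the straight-through estimator — the forward pass
   uses the same hard bits generation uses — with full-batch Adam
   (default 1500 steps at rate 0.02).  Determinism of encode and
   decode is required for reproducible search.  The latent width must
   be at least the sequence entropy (length × log2 |alphabet|) if the
   decoder is to span sequence space; the length-12, 4-letter toy
   protocol uses d = 32 (about 2.7 bits per position).

2. **Acquisition.**  Every evaluated sequence gets a scalar target:
   its hypervolume contribution if it is on the current front
   (leave-one-out), zero if dominated — equivalently, the hypervolume
   improvement each point offers over the front formed by the others.
   Contributions are measured after range-normalizing the objectives
   over the initial pool, because raw scales are arbitrary (the
   solubility scale is an order of magnitude wider than the
   probability scale) and would otherwise dominate the acquisition.
   A negated Pareto-rank scalarization is available behind the
   `acquisition = "rank"` flag.

3. **Surrogate.**  A second-order factorization machine (rank r,
   default 6–8) is fitted to (latent code, acquisition) pairs by
   alternating least squares: each FM parameter is linear in the model
   given the others, so coordinate updates are closed-form,
   deterministic given the seeded factor initialization, and converge
   quickly (the factor initialization scale matters — near-zero inits
   sit at a saddle of the alternating updates; the default sd is 0.1).

4. **QUBO + annealing.**  The FM is compiled exactly into a QUBO
   (`Q[i,i] = -w_i`, `Q[i,j] = -<v_i,v_j>`, offset `-w0`; the sign is
   flipped once so that the annealer's energy minimization maximizes
   the surrogate).  Sampling uses single-flip Metropolis simulated
   annealing with geometric cooling, restarted independently; each
   restart reports the best state it visited.  The QUBO interface is
   sampler-agnostic, so a hardware annealer could be substituted
   without touching the rest of the loop.

5. **Batch assembly.**  Each iteration proposes `batchSize` (default
   20) unseen sequences: decoded annealer samples and random bit-flip
   neighborhoods of the lowest-energy codes (surrogate-guided global
   moves, about 40% of the batch), plus local refinement of the
   incumbent extremes — single and double point mutations and uniform
   crossovers of a small Hamming-diverse parent set, cycling through
   the three objectives across iterations.  If the batch is still
   short (the decoder maps many codes to few sequences), seeded random
   sequences fill the remainder, so the search cannot stall.  The
   local-refinement operators were a deliberate addition: with a
   desk-scale evaluation budget the surrogate alone concentrates
   proposals near the current front, and direct refinement of the
   front's extremes is what pushes the spectrum outward.  Evaluated
   sequences are never re-scored, and the budget counts unique
   generated evaluations only (the seeded initial pool — the labeled
   training sequences plus 100 decoded random latents — is free).

Ten independent runs with seeds `seed_base + 1 … seed_base + 10`
reproduce a full-scale ten-run protocol; each run's archive carries the
hypervolume history and per-objective best-so-far traces that make the
usual progress curves, and `mergeRuns()` deduplicates the union by
exact string identity (first occurrence kept, conflicting duplicates
reported).

## Selection funnel

Five filters, each with an audit flag: exact combined-CDR length (39
for the VHH protocol, segments 13/10/16); no homopolymer run of five
or more identical residues ("repetitive amino acids" is read as a
homopolymer run — the most common usage — with a tandem-repeat reading
behind a flag); ensemble mean strictly above 0.6; filter-solubility
strictly above 0.0; and each CDR segment at Hamming distance ≥ 3 from
the wild-type segment.  Thresholds are read as strict inequalities and
are configurable.  Mean score and solubility are recomputed at
selection time (identical to optimization-time values when the models
are unchanged).  `noveltyReport()` attaches the minimum Hamming
distance to the training set — the novelty number that matters when
asking whether the method designs beyond its data.

## The synthetic study

The generator emulates the data-generating process the package
consumes, with known ground truth.  A `ToyLandscape` assigns fitness =
baseline + bonus × (motif positions matched) + seeded per-sequence
Gaussian noise; the optimum is known in closed form.
`simulatePanning()` draws the N.S. pool multinomially with uniform
weights and the eluted pool with weights ∝ exp(fitness) (softmax
selection), so the expected enrichment score is log-linear in true
fitness; pool totals are exact.  The four experimental selection
rounds are collapsed into one effective enrichment, and no PCR or
sequencing error model is included — passing tests show the machinery
recovers a planted signal under multinomial sampling noise, not that
it is robust to amplification artifacts or to the epistasis of real
binding landscapes.

The reference toy study used throughout the tests and the acceptance
script: length 12, alphabet {A,C,D,E}, six motif positions, bonus 1.5
per match, noise sd 0.1, 400 variants, 40,000 reads per pool.  These
were chosen once as a realistic desk-scale miniature — enrichment
spans about two orders of magnitude and the labeled set has the
positives-scarce imbalance typical of panning data (a few dozen
positives against a few hundred negatives).  Optimization runs use
budget 400 (20 iterations of 20), against a random-generation baseline
of 400 sequences at the same evaluation cost; problem sizes keep the
full ten-pair comparison under ten minutes on one CPU.

## Numerical choices and degenerate inputs

* Ties in argmax decoding go to the first residue in alphabet order.
* The annealer's temperature schedule is geometric from 10× to 0.01×
  the largest absolute QUBO coefficient.
* `Score` with both frequencies zero is undefined (`NA`) and excluded;
  empty tables, single-class splits, mixed-length inputs and unknown
  residues raise errors naming the offending input.
* All randomness flows through explicit integer seeds; re-running any
  stage with the same configuration is byte-identical, which the test
  suite asserts on the written CSV artifacts.

## Limitations

* The recurrent architecture is a compact bidirectional Elman network,
  not an LSTM; at these sequence lengths the difference is immaterial
  to the method, but transferring learned weights from other tools is
  out of scope.
* Exact hypervolume stops at three objectives (the protocol's case);
  more objectives fall back to Monte Carlo.
* The toy solubility scorer ranks sequences by mean hydrophilicity
  only; real developability predictions must come through the table
  adapter.
* The latent autoencoder is linear; for much longer sequences or
  larger alphabets a deeper encoder (behind the same interface) may be
  needed to keep reconstruction usable.
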