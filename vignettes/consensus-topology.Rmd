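---
title: "Consensus membrane-protein topology: model, grammar and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus membrane-protein topology: model, grammar and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoconsensus)
library(dplyr)
```

## The problem

The topology of an α-helical membrane protein — how many helices cross the
membrane, where they sit in the sequence, and which loops face the cytoplasm
("inside", `i`) versus the other side ("outside", `o`) — is the basic
structural annotation for the 20–30% of proteins in a typical genome that
live in membranes. Individual topology predictors disagree with each other,
and all of them struggle with one specific confusion: a cleavable N-terminal
signal peptide (`S`) looks, hydrophobically, very much like a first
transmembrane helix (`M`), so signal peptides are predicted as helices and
vice versa. Combining several predictors into a consensus both averages out
idiosyncratic errors and, when the ensemble includes methods that model
signal peptides, lets the consensus arbitrate the SP-versus-helix call.

`topoconsensus` implements that consensus step. It does **not** run any
topology predictor: its input is the per-residue label strings (`S`, `M`,
`i`, `o`) that predictors emit, in a plain TSV.

## The consensus model

Given `N` predictions for a protein of length `L`, the package builds a
**topology profile**: an `L × 4` matrix whose column for residue `c` holds
the fraction of methods voting for each label at `c` (`topo_profile()`).
The consensus topology is the **grammar-valid** label string `t` maximising
the geometric mean of the profile values along the path,

> score(t) = (1/L) · Σ_c log p̃_c(t_c),

where `p̃` is the profile after pseudocount smoothing
(`p̃ = (p + ε)/(1 + 4ε)`, default `ε = 1e-6`). The maximiser is found by a
Viterbi-style dynamic program over a topology state machine
(`decode_consensus()`). Each state emits exactly its own label (emission 1
for the state's own structural category, 0 for the others), and every
permitted transition has weight 1, so the grammar — not any trained
parameter — carries all the structure; there is nothing to train. Minimum
segment lengths are encoded by state expansion: a membrane helix is a chain
of `min_helix_len` sub-states whose last state self-loops, and analogously
for the signal peptide.

Because the profile columns are rational vote counts, exact ties happen.
Ties are broken deterministically toward the lowest-indexed state (loop
states before helix chains before the signal-peptide chain), which prefers
fewer membrane segments and makes output byte-reproducible.

**Why the pseudocount.** With five methods, mutually inconsistent one-hot
columns are common (e.g. all methods say `i` at `c` and all say `o` at
`c+1`); without smoothing *every* grammar-valid path would then score
`-∞` somewhere and the maximiser would be meaningless. `ε` keeps every path
finite without measurably disturbing clear majorities. For profiles with no
zeros and a clear optimum, `ε = 1e-6` and `ε = 0` give identical paths (a
tested property); in razor-thin near-ties the pseudocount can act as a
tie-break of its own, which is why optimality is always stated for the
smoothed score the decoder reports.

## The topology grammar

The state machine accepts exactly the strings a biologist would call a
well-formed topology; the rules live in `grammar_config()` and are enforced
identically by `validate_topology()` (used on output and in tests) and by
the decoder's transition structure:

* at most one `S` run, starting at residue 1, with length in
  `[min_sp_len, max_sp_len]` = `[5, 70]` by default, followed immediately by
  the non-cytoplasmic side `o` (cleaved signal peptides leave the mature
  N-terminus outside; the side is configurable);
* `i` and `o` loops never touch — a membrane crossing must separate them —
  and the two sides of every `M` run differ (`i–M–o` or `o–M–i`);
* every `M` run is at least `min_helix_len = 15` residues (roughly the
  minimum to span the hydrocarbon core as an α-helix; no upper bound by
  default);
* strings start and end with a loop label (or `S` at the start). An `M` run
  touching a terminus has no flanking loop, so neither side alternation nor
  the benchmark's terminus-orientation criterion would be defined for it;
  we therefore treat it as ungrammatical rather than guess. For the same
  reason an all-`S` string is invalid.

Two genuinely open choices, surfaced as options: the post-SP side is forced
to `o` but configurable (`post_sp_side`); and `allow_globular_paths = FALSE`
makes the decoder insist on at least one membrane segment (implemented with
pre-/post-membrane copies of the loop states; in that mode SP-only paths
are excluded too, since the flag is about forcing a membrane protein). The
validator deliberately ignores this flag — an all-`i` string is still a
well-formed label string. Internal signal peptides
(`sp_must_start_at_nterm = FALSE`) are honoured by the validator but
rejected by the decoder: supporting them would require a second
signal-peptide chain per membrane-parity context for a case with no
biological reading here.

Raw predictor output is *not* required to be grammar-valid — real predictors
may emit anything — only the consensus output is.

## Free energy of membrane insertion

Independently of the consensus, `dg_track()` slides a window (default 21
residues, about one membrane crossing) along the sequence and sums
per-residue contributions from a hydrophobicity scale, giving the predicted
free energy of membrane insertion (kcal/mol) at every full-window centre;
low values flag candidate helices. The shipped scale
(`default_dg_scale()`) is the published biological (translocon) scale of
Hessa et al. (2007), position-independent contributions only; a
position-dependent profile across the window can be supplied via
`positional_weights`, and any user scale can be loaded with
`read_dg_scale()`. Incomplete windows at the termini are not computed
rather than padded — edge values would be artefacts of the padding choice.
Non-standard letters (`X`, `B`, `Z`) contribute the mean of the 20 standard
values with a warning by default, or raise an error
(`unknown = "error"`).

## Benchmark evaluation

`topology_correct()` implements the standard correctness criterion: equal
number of membrane segments, each predicted segment overlapping its
reference counterpart (k-th to k-th, in order) by at least `min_overlap = 5`
residues, matching N- and C-terminal sides, and matching signal-peptide
presence. Design readings the criterion itself leaves open, fixed here and
tested:

* the N-terminal side is read *after* any signal peptide (the first `i`/`o`
  label), so an SP+TM prediction with a slightly different SP length is not
  penalised on orientation;
* references with no membrane segment are judged only on the absence of
  membrane segments and on SP agreement — the `i`/`o` identity of a
  globular protein's single "loop" is not meaningful;
* with equal counts, in-order one-to-one pairing of segments is used; a
  crossing pairing cannot produce more overlapping pairs when both segment
  lists are ordered.

`judge_topology()` assigns each failure to one error kind: cross-prediction
(`TM_SP_CONFUSION`) when the S run of one string overlaps an `M` run of the
other and that helix touches the N-terminal 70 residues (signal-peptide
territory — the taxonomy distinguishes the N-terminal confusion from other
errors but states no positional rule, so the grammar's maximum SP length is
reused); otherwise SP-presence disagreements are `SP_NONTM_CONFUSION`,
membrane-presence disagreements are `TM_NONTM_CONFUSION`, and
class-preserving failures are `WRONG_TOPOLOGY`. The cascade makes the kinds
mutually exclusive and exhaustive. `topology_benchmark()` aggregates
outcomes into per-class accuracies, a row-normalised 4 × 4 class confusion
matrix and an error-kind breakdown.

## The synthetic-data generator

Real benchmarking needs solved topologies and runs of external predictors;
for development and testing the package generates its own ground truth
(`simulate_proteins()`) and noisy predictions (`perturb_predictions()`).
The defaults define the study conditions and are not tuned per test:

* **class mix** 313 : 752 : 2194 : 3597 (TM : SP+TM : SP-only : globular),
  the composition of a representative benchmark of solved topologies —
  mostly non-membrane proteins, as in a proteome-wide scan;
* **structure** 1–7 helices of 15–30 residues, loops 5–60, signal peptides
  10–40; proteins without membrane segments are 50–300 residues (no
  canonical source prescribes a soluble-protein length range; this covers
  typical small single-domain proteins);
* **sequences** are sampled with composition tied to the topology:
  hydrophobic-weighted residues in `M` runs, polar-leaning loops, a milder
  hydrophobic tilt in signal peptides (their h-region resembles a short TM
  helix — which is exactly why the cross-prediction problem exists). This
  makes insertion-energy tracks dip inside true helices, so `dg_track()`
  output is statistically checkable;
* **noise per method**: boundary shifts up to ±3 residues, helix drop 0.05,
  helix invention 0.02 per loop, SP↔helix swap 0.05, SP miss 0.02,
  orientation inversion 0.02. The SP-miss mode is included because without
  it an ensemble can never produce an `SP_NONTM_CONFUSION` outcome;
  inversion is only applied to proteins without an SP, whose orientation
  the grammar pins down (an "inverted" SP protein is ungrammatical, and
  repair would undo it).

Perturbation operates on the structural representation (SP length, loop
lengths, helix lengths, first side — sides are implied by alternation, so
this round-trips losslessly with the label string) and ends with a repair
step that restores grammar validity: under-length helices grow into their
flanking loops or are dropped when the loops cannot spare the residues, the
SP length is clamped, every run keeps at least one residue, and total
length is always conserved. The repair is part of the noise model, not a
hidden correction; with all noise at zero, perturbation is exactly the
identity (tested).

What the generator does *not* emulate: the correlated, method-specific
biases of real predictors (simulated methods err independently),
re-entrant/membrane-dipping regions (unrepresentable in the four-letter
alphabet; callers must pre-collapse such annotations), and real sequence
statistics beyond coarse composition. Passing the ensemble-recovery tests
therefore shows the consensus machinery works as specified, not that any
particular accuracy will be achieved on real proteins.

## Numerical and testing choices

* Coordinates are 1-based and inclusive everywhere, the R/Bioconductor
  convention.
* The decoder is validated against exhaustive enumeration of the
  grammar-valid language on random profiles of length ≤ 10 with 3–7
  methods. These checks use a reduced grammar (minimum helix 3, SP length
  2–6): under the default grammar no string of length ≤ 10 can contain a
  membrane segment, so the default would leave most rules unexercised at
  that size. The enumerator itself is cross-checked against brute-force
  filtering of the full `4^L` space at small `L`.
* Ensemble experiments use 500 proteins × 5 methods, identity-recovery 100
  proteins, window-sum checks 100 random 60-mers — sizes at which the
  checked properties are already fully exercised.
* Scores are compared to `1e-12`; the reported consensus score is, by
  construction and by test, exactly `score_topology()` of the reported
  path.

## Limitations

The consensus is only as good as its inputs: with a single method it
reproduces (a grammar-repaired version of) that method. Methods are equally
weighted; there is no per-method reliability model, and the per-residue
`agreement` track is a descriptive convenience, not a calibrated
confidence. The four-letter alphabet cannot express re-entrant regions,
interfacial helices or SP cleavage-site uncertainty. The ΔG track uses the
position-independent scale contributions; the full position-dependent
model of the original scale is only available through user-supplied
positional weights.
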