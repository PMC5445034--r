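---
title: "The voting/consensus model and metadata boosting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The voting/consensus model and metadata boosting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the two-level voting/consensus model for combining in silico MS/MS
fragmentation rankings, the sensitivity calibration, the spectral
dot-product gate, the metadata boosting equation, and the synthetic
benchmark generator — with the assumptions, defaults, numerical choices
and limitations a user should know before trusting the output.

## Structure identity

Everything operates on the first 14 characters of the standard InChIKey
(the connectivity block). Two candidates sharing this block are the same
structure: enantiomers and diastereomers collapse, because tandem mass
spectra cannot distinguish them. Candidate rows whose InChIKey does not
parse (salt/isotope/radical conversion artifacts in upstream databases)
are dropped and counted, never repaired: structure clean-up belongs to the
upstream database, and an auditable drop count beats a silent fix.
Duplicate blocks within one candidate list collapse to a single entry
keeping the lowest ChemSpider ID, so rankings are over structures, not
database rows.

## The two-level voting/consensus model

Each tool contributes one ordered candidate list per challenge. For a
candidate $c$:

* **primary score** — the number of tools whose list contains $c$;
* **secondary score** — $S(c) = \sum_A \mathrm{rank}_A(c) / \omega_A(k)$,
  summed over exactly the tools that ranked $c$.

Candidates sort by primary descending, then $S$ ascending, then
lexicographically by key block. The lexicographic tail is our own
deterministic tie-break: with continuous $\omega$ values genuine
$(primary, S)$ ties are rare but possible (identical tool placements), and
reproducibility requires a total order. Candidates no tool ranked are
appended after all voted candidates in ID-sorted order rather than
dropped, so top-20 evaluation always has a total ranking to inspect; how
the original study ordered its zero-vote candidates is not stated, and
this choice only matters below the last voted candidate.

Tools may rank only a subset of candidates — real tools skip structures
they cannot fragment. A missing tool contributes nothing to either score:
the primary tier already penalizes the missing vote, and inventing a
default rank for a tool that expressed no opinion would let one tool's
coverage gaps reorder another tool's evidence.

The sensitivity
$\omega = \text{correct} / (\text{correct} + \text{false})$ is the
fraction of training challenges where the tool placed the truth within the
top $k$; since every challenge has exactly one true structure, the
denominator is the challenge count. $\omega$ is calibrated at
$k \in \{1, 5, 10, 20\}$ and the secondary score divides by the $k = 10$
column by default — the top-10 window is what a practitioner actually
inspects, and it is the calibration that worked best in the benchmark this
model derives from. $\omega$ is monotone in $k$ by construction (nested
events). A tool with $\omega(k_{use}) = 0$ is rejected at calibration time
with guidance to enlarge $k$, because $S$ divides by it. Calibration and
application sets are tracked by label; applying weights to their own
training set is legal but should be seen for what it is.

## When does voting help?

A point this package's synthetic experiments make measurable: the
consensus model's *top-1* accuracy only matches or beats the best single
tool when tool errors are **correlated** — when tools tend to succeed and
fail on the same challenges, as real in silico tools do (they all struggle
with sparse spectra and fluorinated compounds). Under conditionally
*independent* tool errors with uniformly shuffled decoys, the minimum over
many decoys' average ranks undercuts the truth's average rank, and
aggregation trades top-1 hits for a stronger top-10/top-20 tail. The
generator therefore exposes a `correlation` knob ([simulate_tools()]):
with probability `correlation` a tool reuses a shared per-challenge draw
(the truth-placement band and the decoy shuffle), leaving every tool's
marginal top-k rates untouched while inducing shared mistakes. The test
suite asserts the top-1 property on correlated ensembles and the top-10
gain on independent ones; both are properties of the model, not of a tuned
seed.

## The dot-product gate

The spectral similarity score is a weighted cosine scaled to the
conventional 0–999 match-factor range. Peaks are paired greedily
one-to-one within the fragment tolerance, closest m/z difference first —
deterministic, standard, and order-independent. Each peak is weighted
$I^{p} \cdot (m/z)^{q}$ with defaults $p = 0.5$, $q = 0$ (square-root
intensity scaling, the robust default for collision-energy-mismatched
comparisons); unmatched peaks count in their own spectrum's norm, so
missing peaks are penalized. The score of a spectrum against itself is
999; disjoint spectra score 0; the score is symmetric. The original
evaluation delegated this scoring to an external library-search program
and printed no formula — only the observable contract (0–999 range,
perfect match 999, a gate at >400). This implementation keeps that
contract exact and exposes every exponent and tolerance in
`similarity_config()`.

Defaults, with units and reasons:

| parameter | default | why |
|---|---|---|
| `precursor_tol_ppm` | 5 ppm | the candidate-retrieval and library-search window of the source benchmark; Orbitrap-class accuracy |
| `fragment_tol` | 0.01 Da | high-resolution product-ion tolerance; Da rather than ppm so low-mass fragments are not over-constrained |
| `intensity_power` | 0.5 | square-root weighting tempers dominant base peaks |
| `mz_power` | 0 | no mass weighting; m/z-weighted variants exist for unit-resolution data |
| `hit_threshold` | 400, strict `>` | the cut that separated true from false library matches on the training data of the source benchmark |

Only the *existence* of a >400 hit propagates downstream (a 0/1 flag per
structure, aggregated by maximum over library entries): query and library
spectra come from different instruments and collision energies, so the
continuous score is not comparable across challenges. Matching is per
structure — the library hit must carry the candidate's own key block, not
merely any hit for the query spectrum.

## Metadata boosting

$$\text{final score} = \frac{1}{\text{consensus rank}} + 1 \cdot
\text{DB presence} + 2 \cdot \text{DB}_{\text{STOFF-IDENT}} + 4 \cdot
\text{DB}_{\text{MS/MS}}$$

sorted descending. The "consensus rank" term of the published equation has
no stated numeric form; this package reads it as the **reciprocal rank**.
That reading makes the integer boost terms dominant (any flag difference
outweighs any rank difference), keeps the score in a bounded range
$(0, 8]$, and automatically enforces the published tie rule — among
candidates with equal flags, the better in silico rank wins — without a
second sort key. An explicit consensus-rank-ascending guard is kept in the
comparator anyway: under the default factors $1/r$ differences can never
equal an integer flag difference, but user-supplied fractional factors can
create exact ties, and one unit test exercises precisely that boundary.

`DB presence` is binary (membership in at least one database of the
declared vocabulary), not a member count: the equation names a single
presence term. STOFF-IDENT membership *adds* its term on top of presence
(total +3), since the equation sums independent terms. The factors
(1, 2, 4) are configurable: they encode that a spectral-library match is
stronger evidence than database membership, and environmental relevance
sits in between — a study of endogenous metabolites should re-weight
toward biochemical databases instead.

## Evaluation harness

`topk_counts()` counts challenges with the truth at rank ≤ k for
k ∈ {1, 5, 10, 20}; a truth absent from a ranking is a miss at every k. A
challenge whose truth is absent from its own candidate list (erroneous
metadata upstream) is flagged unsolvable (`challenge_solvable()`) and by
default still counts as a miss in every denominator — accuracy then
reflects the whole pipeline including candidate retrieval; exclusion is
available via `allow_missing`-style filtering but changes the question
being asked. `percent()` reports integer percentages with a
round/floor switch, because published tables in this field mix both
conventions. `combination_sweep()` evaluates an explicit specification of
ranker subsets × boost modes (single members bypass consensus;
`default_combinations()` ships the historical 57-row enumeration) and
reports rows sorted by top-1 count. Boosting with adversarial flags
(decoys flagged, truths not) *lowers* counts, and the harness reports that
faithfully — a test asserts no clamping.

## The synthetic generator

What it emulates: challenges with one true structure plus 5–50 mass-matched
decoys inside a ±5 ppm window (candidate masses derive from the drawn
precursor via the proton mass, by ion mode); collision-free synthetic key
blocks; ChemSpider-like integer IDs; tools with controlled
$p_{top1}$/$p_{top10}$ placement and a coverage knob; query/library
spectrum pairs with controlled peak overlap on an m/z grid whose
off-grid offset guarantees non-shared peaks can never match within the
default tolerance; truthful-by-default database and MS/MS flags (truths
flagged with high probability, decoys with low).

What it does not emulate: real fragmentation chemistry, mass-dependent
candidate-list sizes (real lists grow toward 8000 near popular masses),
tool-score distributions, library spectra of decoy structures' real
spectra, retention behaviour. Passing tests therefore demonstrate the
*aggregation and boosting machinery* is correct and directionally
faithful; they do not certify accuracy numbers on real contest data.

One calibration artifact worth knowing: for challenges with ≤ 10
candidates every placement is inside the top 10, so $\omega(10)$ exceeds
$p_{top1} + p_{top10}$ when small candidate lists are common.
Parameter-recovery tests therefore use ≥ 20 decoys per challenge, where
the identity is exact.

## Numerical choices and degenerate inputs

* Ranks are 1-based everywhere; rank 1 is best.
* Single-candidate challenges are legal (the benchmark's pentabromophenol
  case) and rank their only structure first under every ranker.
* `randomize_ranking()` and all generators restore the caller's RNG state
  (`withr::with_seed`); datasets are pure functions of (parameters, seed).
* Peak lists are stored raw and sorted by m/z at construction;
  normalization happens only inside the scorer, keeping I/O lossless.
* MGF blocks without peaks are dropped with a logged count; a block
  without PEPMASS is an error naming the block. MSP records declaring a
  wrong peak count are errors naming the record. Writers emit full
  precision so write-then-read is the identity.
* Zero matched peaks score 0, not NaN; an all-zero weight vector also
  scores 0.
* `final_score()` rejects rank 0; flags outside {0, 1} are rejected.

## Problem sizes in the shipped tests

The test suite checks the consensus implementation against an independent
brute-force oracle on random instances of ≤ 6 candidates × ≤ 4 tools
(10,000 instances in the acceptance tier), dot-product self-match and
symmetry on 1,000 generated spectra, boost monotonicity on 10,000 random
records, parameter recovery at 5,000 challenges against a 99% binomial
interval, and the end-to-end study at 600 challenges with a 300/300
train/hold-out split. These sizes were chosen to make binomial confidence
bands tight relative to the effects under test while keeping the whole
suite comfortably interactive.

## Known limitations

* The consensus uses ranks only, never the tools' native scores — faithful
  to the model it implements, but score fusion could use more information.
* Sensitivity weights are global per tool, not conditioned on compound
  class or spectrum quality.
* The dot-product implementation is one member of the match-factor family;
  scores from other implementations (different pairing or weighting) are
  not numerically interchangeable, though the >400/999 contract is.
* No hybrid/neutral-loss or precursor-free library search; no retention
  time or citation-frequency metadata.
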