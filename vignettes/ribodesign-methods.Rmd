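---
title: "Energy-gap guided rRNA design: model, constraints and Monte Carlo engine"
author: "RiboDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-gap guided rRNA design: model, constraints and Monte Carlo engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RiboDesign)
```

## The design problem

Large structured RNAs such as the bacterial 16S (1542 nt) and 23S (2904 nt)
ribosomal RNAs have experimentally known secondary structures that their
function depends on. A redesign task asks for sequences, a bounded number of
mutations away from wild type, for which that *target* structure remains an
energetically optimal fold. RiboDesign implements the computational machinery
for this task: an energy-gap score, a constraint system mirroring the rules
under which such designs are made (mutation budgets, locked residues,
conservation masks, protein-contact annotations), a Metropolis Monte Carlo
design engine, deterministic design operators modelled on the strategies
human designers use, and a synthetic benchmark generator.

## The energy-gap ("delta") score

For a sequence $s$ and a target structure $T$,

$$\Delta(s) \;=\; E(s, T)\; -\; E_{\mathrm{MFE}}(s),$$

where $E(s, T)$ is the energy the model assigns to $s$ folded into $T$ and
$E_{\mathrm{MFE}}(s)$ is the energy of $s$'s minimum free energy structure.
$\Delta = 0$ means the target is (one of) the optimal folds of $s$;
minimising $\Delta$ is the design objective. $\Delta \ge 0$ always: removing
the non-canonical pairs from the target yields a valid structure with energy
no higher than $E(s,T)$, and the MFE is no higher than that.

### The built-in energy model

Full nearest-neighbour (Turner-style) parameter sets bring thousands of
tabulated terms and are already excellently served by existing engines. The
design algorithm, the constraint system and every invariant in this package
are engine-independent, so the built-in model is deliberately minimal and
fully certifiable: each canonical pair contributes a fixed energy

| pair | energy |
|------|--------|
| G–C / C–G | $-3$ |
| A–U / U–A | $-2$ |
| G–U / U–G (wobble) | $-1$ |

unpaired residues contribute $0$, and a pair the sequence cannot form
canonically costs $+6$. The units are arbitrary; only the ordering
(GC strongest, wobble weakest) and the sign structure matter. The MFE is the
exact minimum over all nested canonical structures with hairpin loops of at
least `minLoop = 3` residues, computed by an $O(n^3)$ interval dynamic
program (`mfeFold()`), and `enumerateStructures()` provides an exhaustive
oracle (guarded at 22 nt) that certifies the DP exactly. Pseudoknots are out
of scope throughout — `parseDotBracket()` rejects bracket families other
than `()` with a dedicated error — because the energy models this package
emulates omit them.

Two numerical choices deserve a note:

* **Finite incompatibility penalty.** A forced non-canonical pair costs a
  finite $+6$ rather than $+\infty$, so Monte Carlo trajectories can pass
  through intermediate states in which a target pair is temporarily broken.
  `energyParams(strict = TRUE)` turns such pairs into errors for users who
  want hard failures.
* **Deterministic traceback.** Ties in the DP are broken by preferring a
  position unpaired, then the smallest pairing partner. Identical inputs
  therefore always give identical MFE structures, which keeps trajectories
  reproducible. Equality comparisons in the traceback use a $10^{-9}$
  tolerance so user-supplied fractional energies behave.

### External engines

`FoldEngine` is an adapter contract (`foldFun`, `evalFun`) making the rest
of the package engine-agnostic. `builtinEngine()` routes the built-in model
through it (bit-identical to `deltaScore()`), and `viennaEngine()` wraps the
ViennaRNA `RNAfold`/`RNAeval` programs when they are installed; if they are
absent the constructor raises an explicit capability error rather than
silently falling back. Energies from different engines are not comparable in
magnitude, but $\Delta \ge 0$ holds for any engine.

## The constraint system

`ConstraintSet` bundles four mechanisms that coexist because different
design rounds relied on different ones:

* **Mutation budget** (hard): at most `budget` mutations from wild type,
  with `mutationBudget(L, 0.05)` encoding the 5%-of-length convention
  (76 for the 1534-nt 16S puzzle, 145 for the 2904-nt 23S). The floor
  is computed as `floor(fraction * L + 1e-9)` to keep exact products such
  as $0.05 \times 20$ from landing a hair below their integer value in
  binary arithmetic.
* **Locked positions** (hard): residues that must keep their wild-type
  identity.
* **IUPAC mask** (reported, not enforced): per-position degenerate symbols
  (`Y` = C/U, `W` = A/U, ...) encoding which substitutions are observed
  across related organisms. `buildIupacMask()` derives a mask from a
  multiple alignment: per reference position, the IUPAC symbol of the set
  of nucleotides observed in the column, gaps ignored. The default
  `minFreq = 0` admits any observed nucleotide, since no conservation
  threshold is canonical; the parameter is exposed for stricter masks.
  A mutated position whose design nucleotide falls outside the mask is an
  *IUPAC violation*; unmutated positions are exempt by definition (the
  wild-type residue itself may sit outside a strict mask — that is reported
  on designs only, never an error).
* **Contact positions** (advisory): residues contacting ribosomal proteins.
  Mutations there are counted and reported, never rejected — avoiding them
  proved beneficial in practice but is a designer's judgement call.

`checkDesign()` reports all four aspects separately so that a design with
many mutations but few IUPAC violations is distinguishable from one that
tramples conserved positions.

## The Metropolis Monte Carlo designer

A trajectory starts at the wild-type sequence and repeatedly proposes
single-nucleotide substitutions: a uniformly random legal
(position, alternative nucleotide) pair. Legality is enforced at proposal
time — locked positions are never drawn, and when the Hamming distance to
wild type has reached the budget only already-mutated positions may change
(which can only keep or lower the distance). Hard constraints are therefore
invariants of the chain, not rejection penalties. If no legal move exists
(everything locked, or a zero budget), the trajectory ends gracefully,
flagged `exhausted`.

Moves that do not increase $\Delta$ are accepted unconditionally; a move
increasing it by $d$ is accepted with probability $e^{-d/T}$. Design
choices, each of which was genuinely open:

* **Temperature**: default $T = 1.0$ in built-in-model units, constant along
  the trajectory. No annealing schedule is applied — the plain Metropolis
  criterion is the simplest faithful reading, and $T$ is an exposed
  parameter for anyone who wants schedules.
* **Proposal modes**: `"free"` offers all three alternative nucleotides;
  `"iupac_restricted"` limits alternatives to the mask's set, always
  augmented with the wild-type nucleotide so reverting stays possible.
* **Seeding**: trajectory $k$ of a campaign uses `baseSeed + k` with R's
  default RNG; seeds are recorded in every trajectory and pool record.
* **Pool membership**: every *accepted* state of every trajectory enters the
  `DesignPool`, not only endpoints — the selection protocol
  (`selectBestPerMutationCount()`: lowest $\Delta$ per mutation count, ties
  broken by lexicographically smallest sequence, absent counts reported as
  missing) operates over all states visited.

One uniform random number is consumed per acceptance decision regardless of
direction, which keeps the random stream — and hence whole trajectories —
bit-reproducible for a fixed seed.

## Design operators and mutation classes

The deterministic operators encode the moves that dominated successful
human-made designs: `flipPair()` (swap the two partners of a target pair),
`switchPairType()` (rewrite a pair as AU/UA/CG/GC),
`wobbleToWcProposals()` (the two single-nucleotide fixes G–U → G–C and
G–U → A–U per wobble pair), and `breakRepeatProposals()` (break runs of
identical nucleotides found by `findRepeats()`, default threshold $k = 4$ —
the repeat-breaking strategy comes without a canonical threshold, and runs
of four are the shortest that read as homopolymer stretches at rRNA scale).
All operators are pure functions returning new sequences, so they compose
and can serve as proposal kernels.

`classifyMutations()` inverts the operator view: each mutated position gets
exactly one of six classes (`PAIR_FLIP`, `PAIR_TYPE_SWITCH`,
`WOBBLE_TO_WC`, `WC_TO_WOBBLE`, `PAIR_BROKEN`, `UNPAIRED_SUBSTITUTION`),
with a mutated pair classified once and reported at its 5′ partner. Flips
take precedence (a G–C → C–G change is a flip, not a type switch). One edge
case falls outside the natural class list: a wild-type pair that is already
non-canonical and becomes canonical in the design. It is classified by the
resulting pair type (`PAIR_TYPE_SWITCH` if Watson–Crick, `WC_TO_WOBBLE` if
wobble), keeping the six classes a partition.

## The synthetic puzzle generator

`generateToyInstance()` stands in for the full-length rRNA puzzles, whose
target structures are experiment-specific inputs rather than package data.
It emulates the *shape* of the design problem — a nested target structure, a
wild type some mutations away from a perfect solution, a budget, optional
locks — at certifiable scale:

1. a random nested target with `nPairs` pairs is sampled by uniform legal
   pair insertion (with restarts, since a greedy pass can fragment the free
   positions; a single helix bound $\lfloor (L - \texttt{minLoop})/2
   \rfloor$ decides true infeasibility);
2. a witness sequence realises every pair as G–C and fills unpaired
   positions with A. Under the built-in model no alternative structure of
   that sequence can beat the target (alternatives can only repair G–C
   pairs, of which the target already has all), so the witness has
   $\Delta = 0$ — this is verified by `mfeFold()` at generation time, not
   assumed;
3. between 1 and `budget` paired positions are corrupted to random other
   nucleotides to produce the "wild type" starting point, so the witness
   stays within budget and solvability is certified. Locked positions are
   drawn from uncorrupted positions only.

With `nPairs = 0` the target is the open chain and the sequence is drawn
over {A, C}, which admits no canonical pair, so every sequence reachable in
that alphabet has $\Delta = 0$ — the flat landscape used to check that the
chain's stationary distribution is uniform.

What the generator does **not** emulate: full-length rRNA (instances in the
test suite are 20–200 nt, with the solver benchmarks at 30 nt), Turner
energetics, pseudoknots (the 16S h2 helix is properly a pseudoknot and is
excluded along with all crossing pairs), tertiary contacts, and of course
any wet-lab behaviour. Passing the solver benchmarks therefore shows that
the engine correctly optimises its objective under its constraints — not
that a $\Delta$-optimal sequence yields an assembling, translating ribosome.
Experimental activities enter only as user-supplied tables, to which
`filterRobustDesigns()` applies the robustness cut (≥ 6 mutations and
≥ 80% of wild-type activity by default).

## Problem sizes and tolerances in the checks

The test suite certifies the fold against exhaustive enumeration on 500
random sequences of 8–18 nt; checks the Metropolis rate for a $+1$ gap at
$T = 1$ against $e^{-1}$ within $\pm 0.005$ over $10^5$ draws; verifies
constraint safety across 50 seeded 100-step trajectories; and requires at
least 80% of trajectories to reach $\Delta = 0$ within $10 L$ steps on 50
generated solvable 30-nt instances with a 10% budget. The flat-landscape
uniformity check runs $10^5$ steps on a 6-mer and applies a $\chi^2$
goodness-of-fit test to thinned samples. All stochastic checks run under
fixed seeds.

## Worked example

```{r example}
toy <- generateToyInstance(L = 30, nPairs = 8, seed = 3, nLocked = 2)
toy
deltaScore(toy@wt, toy@target)

tr <- runTrajectory(toy@wt, toy@target, toy@constraints,
                    mcParams(steps = 300), seed = 11)
tr
checkDesign(toy@wt, tr@finalSequence, toy@constraints)
```

## Known limitations

* The built-in model has no stacking, loop-size, or dangle terms; its MFE
  structures are cruder than Turner-model folds. Use `viennaEngine()` (or
  any `FoldEngine`) where realistic energetics matter; the design engine
  currently scores with the built-in model only.
* The Monte Carlo engine proposes single-nucleotide moves; compensatory
  double mutations (pair rewrites) appear only through two accepted single
  moves or via the strategy operators used as external kernels.
* `enumerateStructures()` is exponential and guarded at 22 nt by design.
* Structures are strictly nested; any pseudoknotted input must be encoded
  with its crossing pairs removed.
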