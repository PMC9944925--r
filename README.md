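# RiboDesign

Energy-gap guided Monte Carlo design of ribosomal RNA secondary structure.

## The problem

The 16S and 23S ribosomal RNAs are large structured RNAs (1542 and 2904 nt
in *E. coli*) whose experimentally known secondary structures are essential
to ribosome assembly and function. Redesigning them means finding sequences
— a bounded number of mutations away from wild type — for which that known
*target* structure remains an energetically optimal fold, while respecting
the constraints under which such designs are made: a mutation budget (5% of
the length by convention), residues locked to their wild-type identity,
sequence-conservation masks expressed in IUPAC degenerate symbols, and
advisory lists of protein-contacting residues.

RiboDesign is for computational RNA designers and method developers who
want this machinery as a tested, scriptable library: the scoring function,
the constraint system, a Metropolis Monte Carlo design engine, the
deterministic design operators human designers rely on, design-pool
selection and curation utilities, and a synthetic benchmark generator that
makes the whole pipeline reproducible without any external data.

## The score

For a sequence *s* and target structure *T* the central quantity is the
energy gap ("delta")

    Δ(s) = E(s, T) − E_MFE(s)

the energy *s* assigns to the target minus the energy of its minimum free
energy structure. Δ = 0 means the target is an optimal fold of *s*;
minimising Δ is the design objective, and Δ ≥ 0 always. The built-in energy
model is pair-additive (G–C −3, A–U −2, G–U wobble −1, forced non-canonical
pair +6, hairpin loops ≥ 3 nt) with an exact O(n³) MFE fold and an
exhaustive enumeration oracle that certifies it; a `FoldEngine` adapter
plugs in external engines (`viennaEngine()` wraps ViennaRNA's
`RNAfold`/`RNAeval` when installed). Designs are generated by
Metropolis-criterion Monte Carlo: moves lowering Δ are accepted
unconditionally, moves raising it by *d* pass with probability
exp(−d/T), and locked positions and the budget are hard proposal filters —
illegal states are never visited.

See the methods vignette (`vignettes/ribodesign-methods.Rmd`) for the full
model, the constraint semantics, and every numerical choice.

## Worked example

```r
library(RiboDesign)

## a certified-solvable 30-nt puzzle: 8-pair target, 10% budget, 2 locks
toy <- generateToyInstance(L = 30, nPairs = 8, seed = 3, nLocked = 2)
toy
#> ToyInstance (seed 3): 30 nt, 8 target pairs, budget 3, solvable (witness stored)

deltaScore(toy@wt, toy@target)
#> DeltaScore: delta 6.000 (target -15.000, MFE -21.000, 1 incompatible pairs)

tr <- runTrajectory(toy@wt, toy@target, toy@constraints,
                    mcParams(steps = 300), seed = 11)
tr
#> Trajectory (seed 11): 300 proposals, 176 accepted, final delta 0.000

checkDesign(toy@wt, tr@finalSequence, toy@constraints)
#> ConstraintReport: 3 mutations (budget ok), locked violations: none,
#>   IUPAC violations: none, contact mutations: none

mutationsBetween(toy@wt, tr@finalSequence)
#>   position wt new
#> 1        4  A   U
#> 2        7  A   C
#> 3       14  G   U
```

The wild type starts 6 energy units away from making its target optimal
(one target pair is not even canonically formable); 300 Monte Carlo steps
find a three-mutation design with Δ = 0 that respects the locks and the
budget. The same functions scale to user-supplied full-length rRNA
sequences and target structures (FASTA + dot-bracket or CT input;
`readDotBracket()`, `parseCT()`, `readPositionList()`,
`buildIupacMask()`).

A thin command-line front end with subcommands `score`, `design`,
`evaluate`, `mask`, `fixtures` and `select` ships at
`inst/cli/ribodesign.R`; small synthetic demonstration inputs live in
`inst/extdata/` (all generated by the package itself, see filenames
prefixed `synthetic_`).

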