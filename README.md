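# grnctl

Branching-time model checking for Boolean gene regulatory networks.

## The problem

A Boolean gene regulatory network (GRN) assigns each gene a value in
{0, 1} and one update rule per gene giving its next value from the current
values of its regulators. Three things make the time structure of such
models *branching* rather than linear:

* **asynchronous update** — one gene changes per step, and which one is
  not determined;
* **incomplete knowledge** — an experiment may not settle what a rule does
  in some background, so a truth-table row is marked `*`
  (an *indetermination*: both next values are admissible);
* **environment interaction** — an external signal outside the model can
  push a gene either way.

A simulator following one trajectory at a time cannot prove properties of
such a system, because a single branching state on a cycle already yields
infinitely many paths. `grnctl` instead treats the state-transition graph
as a Kripke structure (a finite total transition relation over the
2^n states) and *model-checks* it: a temporal-logic formula is evaluated
to the **full set of states** at which it holds, exactly, no matter how
many paths exist.

The logic is CTL (Computation-Tree Logic: path quantifiers **E**/**A**
over the modalities **X**, **F**, **G**, **U**) extended with:

* hybrid state variables and the downarrow binder `↓s.φ` (written
  `down s . φ`), which binds `s` to the state of evaluation — this makes
  steady states and attractors expressible, which plain CTL cannot do;
* the past operator **EY** ("exists yesterday"), the converse of **EX**;
* numeric state literals `#k`, naming the state whose binary expansion
  over the genes in lexicographic order (first gene = most significant
  bit) equals `k`.

Key recipes, as hybrid-CTL formulas:

| query | formula |
|---|---|
| stable steady states | `down s . AX s` |
| stable ∪ unstable steady states | `down s . EX s` |
| states on an attractor cycle of any size | `down s . EX EF s` |
| states in a two-cycle | `down s . EX ((not s) and EX s)` |
| basin of attraction of a target | `EF target` |
| reach `s2` avoiding `s1` | `E[(not s1) U s2]` |
| reach `s2` only through `s1` | `not E[(not s1) U s2] and EF s2` |

Evaluation uses the standard labeling algorithm over a symbolic backend:
state sets are Boolean characteristic functions stored as reduced ordered
binary decision diagrams (BDDs), and the transition relation is a BDD over
twice as many variables (current and next state bits). `EX` is one
predecessor-image computation; `EF`/`EG`/`EU` iterate it to a fixpoint; a
binder is evaluated once per state, except for a table of special-cased
patterns (self-loops, stable states, cycle membership, two-cycles,
multi-successor states) answered by direct relation inspection in time
linear in the size of the graph. An explicit-state backend and an
independent brute-force oracle back every result with differential tests.

## Worked example: the *A. thaliana* root stem-cell niche

The package ships the nine-gene Boolean model of the root stem-cell-niche
GRN (`root_scn.eq`; genes ARF, AUXINS, IAA, JKD, MGP, PLT, SCR, SHR, WOX)
plus two truth-table variants carrying indeterminations in the SCR rule.

```r
library(grnctl)
library(dplyr)

grn <- read_grn(system.file("extdata", "root_scn.eq", package = "grnctl"))
model <- grn_model(grn, mode = "asynchronous")
report <- steady_states(model)
report
#> Steady states (asynchronous mode): 7 stable, 0 unstable

tidy(report) |> filter(AUXINS == 1)
#> # A tibble: 4 × 11
#>   state_index   ARF AUXINS   IAA   JKD   MGP   PLT   SCR   SHR   WOX stability
#>         <dbl> <int>  <int> <int> <int> <int> <int> <int> <int> <int> <chr>
#> 1         392     1      1     0     0     0     1     0     0     0 stable
#> 2         394     1      1     0     0     0     1     0     1     0 stable
#> 3         431     1      1     0     1     0     1     1     1     1 stable
#> 4         446     1      1     0     1     1     1     1     1     0 stable
```

The model has seven fixed points; the four with the hormone input
(AUXINS) active are exactly the expected expression profiles of the four
cell types of the niche — epidermis/root-cap initials (392), vascular
initials (394), the quiescent centre (431), and cortex/endodermis
initials (446). The basin of attraction of the quiescent-centre state:

```r
basin(model, "#431")
#> <grn_query> basin
#>   formula: EF <target>  (asynchronous mode)
#>   48 satisfying state(s)
```

Perturbations clamp a gene (`mutant_screen(model, "JKD", 0)` for a *jkd*
loss of function), indeterminate variants load from
`root_scn_scr_star.tables` (one starred SCR row) and
`root_scn_fas0.tables` (the *fas*-mutant all-star SCR table), and
`autoplot()` on any result draws the gene-activation profiles. The same
analyses run from a shell through the installed script:

```sh
Rscript <pkg>/exec/grnctl.R check --model root_scn.eq \
    --recipe stable-steady-states --mode async --format json
Rscript <pkg>/exec/grnctl.R random-net --genes 8 --k 3 --star-prob 0.1 --seed 1
```

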