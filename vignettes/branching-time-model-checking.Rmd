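---
title: "Branching-time model checking of Boolean gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branching-time model checking of Boolean gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnctl)
```

## The model

A Boolean GRN over genes $g_1 < g_2 < \dots < g_n$ (sorted
lexicographically, byte order, case-sensitively — the ordering fixes the
state numbering and is therefore part of the model's definition) assigns
each gene a *rule*. A rule is either one or more Boolean expression bodies
over gene names, or a complete truth table over a declared regulator list
with outputs in $\{0, 1, *\}$. The semantic object behind both forms is
the **allowed-next-value function**: at state $s$, gene $g$ may move to
any value in $\mathrm{allowed}(s, g) \subseteq \{0, 1\}$, which is the set
of body values (equations) or $\{o\}$ for a determinate row and
$\{0, 1\}$ for a starred row (tables). Multiple equation bodies and stars
are the two spellings of an *indetermination* — a point where the model
deliberately underspecifies the next value, whether because an experiment
has not settled it or because an external signal outside the model can
push it either way. The function is total by construction, so every state
has at least one successor and the usual CTL fixpoint characterisations
are sound without extra fairness assumptions.

Two update semantics turn a network into a transition relation:

* **synchronous** — $s \to s'$ iff $s'(g) \in \mathrm{allowed}(s, g)$ for
  every $g$; indeterminate genes branch independently, so the successor
  count is the product of the per-gene choice counts;
* **asynchronous** — for every gene $g$ and every allowed value
  $v \ne s(g)$ there is a transition to $s[g := v]$, and $s$ carries a
  self-loop iff *every* gene may keep its value.

The asynchronous self-loop convention deserves a note, because the
definition of an asynchronous step does not force one. We add the
self-loop exactly at states where all genes can hold. This makes the three
notions the queries rely on simultaneously realizable: a *fixed point*
self-loops (stable steady state, `down s . AX s`); a state on a starred
row whose other genes can hold gets a self-loop *plus* exits (unstable
steady state, in `down s . EX s` but not stable); and a deterministic
transient state — where some gene must change — gets no spurious
self-loop, so basins and cycle queries are not polluted. Flooding every
state with self-loops would make `down s . EX s` trivially true
everywhere; omitting them everywhere would make fixed points
successor-less and the relation non-total.

## The logic and its evaluation

Formulas are CTL (Boolean connectives; `EX AX EF AF EG AG`, `E[. U .]`,
`A[. U .]`) extended with the past operator `EY`, numeric state literals
`#k`, and the hybrid binder `down s . phi`, which binds the state variable
`s` to the state of evaluation. The concrete ASCII grammar (precedence
`not`/temporal > `and` > `or` > `implies`; the binder body extends
maximally to the right) is fixed by this package; an identifier is the
innermost enclosing bound variable of that name if any, and a gene atom
otherwise, so a binder can shadow a gene name.

Evaluation is the standard labeling algorithm. Universal operators are
rewritten first (`AX p = not EX not p`, `AG p = not EF not p`,
`AF p = not EG not p`, and the usual `A[p U q]` expansion), leaving the
primitive core: atoms, literals, variables, `not/and/or`, `EX`, `EY`,
`EU`, `EF`, `EG`, and the binder. `F` and `G` include the present, so
`EF p` holds at a `p`-state itself. Sets are combined bottom-up; `EX` is
one predecessor image, `EY` one successor image, and the fixpoints
iterate images until stable.

A binder `down s . phi` is evaluated naively — `phi` once per state with
`s` bound to it — except when the (rewritten) formula matches one of five
patterns, up to renaming of bound variables: self-loop states
(`down s . EX s`), stable states (`down s . AX s`), cycle membership
(`down s . EX EF s`), two-cycles (`down s . EX ((not s) and EX s)`), and
the multi-successor formula
(`down s . EX down t . EY (s and EX (not t))`). These plans read the
relation directly (self-loop set, out-degree tally, strongly connected
components via an iterative Tarjan, a mutual-edge scan) in time linear in
the number of states plus transitions, instead of the quadratic — or for
the nested binder cubic — per-state loop. Pattern matching is purely
syntactic: a semantically equivalent but differently shaped formula falls
back to the naive plan. That trade favours predictability; the
differential tests hold the optimized and naive routes equal on random
networks.

Subformula results are memoised on (formula text, bindings of its free
variables), which is what keeps nested binders tractable: the inner
formula's parts that do not mention the outer variable are computed once,
not once per outer state.

## Backends

The default backend stores every state set as a reduced ordered binary
decision diagram — a canonical DAG representation of its characteristic
function — and the transition relation as a BDD over $2n$ variables. The
variable order interleaves current and next bits gene by gene
($x_1, x_1', x_2, x_2', \dots$), the standard choice for transition
relations: it keeps the relation small and makes the current↔next rename
order-preserving, so renaming never restructures the diagram. The engine
(hash-consed unique table, memoised apply, existential quantification,
satisfying-assignment counting and bounded enumeration) is compiled code
under `src/`.

A second, explicit backend stores sets as logical vectors over all $2^n$
states and the relation as successor/predecessor adjacency lists. Both
backends implement one state-set contract, and the test suite holds them
equal image-for-image and query-for-query on random networks.

Separately from both, an explicit-state *oracle* re-implements the
semantics in the most literal way possible — adjacency scans, plain
Tarski iteration, universal operators written directly rather than via
rewriting, binders by literal substitution, sets as sorted index vectors,
its digraph enumerated state by state from the rules rather than from the
relation builder. It shares no traversal or set-algebra code with the
engine, which is what makes the differential suite meaningful. Its cycle
cross-check uses igraph's strong components, while the engine's optimized
cycle plan uses its own Tarjan, so even that pair stays independent.

## Parameters that matter

* `mode` (`"asynchronous"`/`"synchronous"`): asynchronous is the default
  throughout, including for the perturbation recipes, as the biologically
  cautious choice (no two genes are forced to switch in lockstep).
* `backend` (`"bdd"`/`"explicit"`): results are identical; explicit is
  capped at 20 genes, the oracle at 12.
* `cap` (default 10 000): enumeration cap on result rows; counts are
  exact regardless, via BDD model counting.
* Random generator (`random_grn(n_genes, k, star_prob, seed)`): each gene
  draws `k` regulators uniformly without replacement (self-loops
  allowed), a uniform random output column, and stars each row
  independently with probability `star_prob`. The differential batteries
  use `k <= 3` and `star_prob` in {0, 0.1} — sparse regulation with
  occasional indeterminations, the regime the shipped root-niche model
  itself lives in.

## What the tests do and do not show

The generator produces unbiased random truth tables; real GRNs are not
random (they are canalising, sparse, and redundant), so passing the
differential suite certifies the *engine* — that symbolic evaluation
implements the declared semantics — not any biological claim. The
biological content is carried by the shipped nine-gene root
stem-cell-niche model, where the tests pin the full worked analysis: the
seven fixed points, the four Auxin-active cell-type profiles, the
starred-SCR and all-star (fas) variants, and the SHR/JKD knockouts.

Problem sizes were chosen to keep the whole suite comfortably
interactive: the oracle-equivalence battery runs 200 random networks of
3–5 genes under both modes through a 27-formula battery (every operator,
binder nesting to depth two), the optimizer battery 100 networks, the
invariant battery 30; the root-niche model itself has $2^9 = 512$ states
and every query on it completes in well under a second.

## Numerical and design choices

* State numbering: most significant bit = lexicographically first gene.
  This is fixed, not configurable, so `#k` literals are reproducible
  across machines and sessions.
* Fixpoints are frontier-based in the engine (only newly added states are
  expanded per round) and bounded by $2^n$ iterations structurally; the
  oracle deliberately uses plain full-set iteration.
* Equation serialization of a starred table emits two bodies: one true on
  the rows allowing 1, one true on the rows forcing 1; their disagreement
  set is exactly the starred rows. Constant rules (from `perturb()`)
  serialize as tautologies/contradictions over the target gene
  (`G | ~G`, `G & ~G`), keeping the equation dialect closed under
  perturbation without extending the grammar with constants.
* Genes referenced but never defined are an error, never implicit inputs:
  the shipped model writes its inputs explicitly (`SHR := SHR;`,
  `AUXINS := AUXINS;`), and silent defaults would mask typos in gene
  names. Likewise a truth table must be complete — no default outputs.
* More than two bodies per gene are allowed; the allowed-value set is the
  union over bodies.
* The SCR rule of the root-niche model ships in three forms, because the
  two natural resolutions of its starred row differ: the printed
  equations (`root_scn.eq`, pointwise equal to the star-resolved-to-0
  table, shipped also as `root_scn_scr_star0.eq`), the starred table
  itself (`root_scn_scr_star.tables`), and the star-resolved-to-1 variant
  (`root_scn_scr_star1.eq`, where the table collapses to
  `SCR := SHR & SCR`). Analyses in this package that cite "the" root
  model use the printed equations.
* "Attractor" in `attractor_states()` means the cycle-membership formula
  `down s . EX EF s` — which also captures non-terminal cycles — because
  that is the formula-level notion the logic expresses;
  `terminal_attractor_states()` provides the terminal-SCC notion under a
  deliberately different name so the two are never conflated.
* Results are tibbles (or carry `tidy()`/`glance()` methods) and plots
  are `autoplot()` methods, so analyses compose with dplyr/ggplot2
  pipelines; the core objects (network, relation, formula, state set)
  remain opaque S3 classes since they are not tabular.
* The command-line front end (`exec/grnctl.R`) is a thin wrapper over
  `run_check()`/`run_random_net()`; it exists because a model checker is
  naturally also a shell tool, but the R API is the primary surface.

## Known limitations

* No multi-valued genes, no priority classes or partially asynchronous
  schedules, no fairness constraints, no counterexample/witness paths,
  and no `@` (at) operator — only `down` and state variables.
* The naive binder loop visits all $2^n$ states; nested binders beyond
  the optimized patterns are practical only for small networks (the
  memoisation helps, but the worst case is inherently exponential in
  nesting depth).
* The optimized cycle and two-cycle plans materialise the edge list, so
  on very large symbolic models they cost $O(|R|)$ memory; the remaining
  plans stay fully symbolic.

```{r example}
grn <- read_grn(system.file("extdata", "root_scn.eq", package = "grnctl"))
model <- grn_model(grn, mode = "asynchronous")
steady_states(model)
```
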