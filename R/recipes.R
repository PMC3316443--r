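#' Run a query and package its result
#'
#' Evaluates a formula on a model and wraps the satisfying set together with
#' provenance (query name, formula text, update mode, a fingerprint of the
#' model) and a capped enumeration of member states. The count is always
#' exact even when the enumeration is capped.
#'
#' @param model A [grn_model()].
#' @param f Formula text or AST.
#' @param name Query name recorded in the result (defaults to the formula).
#' @param env Optional state-variable bindings.
#' @param cap Maximum number of states to enumerate (default 10000);
#'   negative means no cap.
#' @return A `grn_query` object.
#' @export
run_query <- function(model, f, name = NULL, env = NULL, cap = 10000) {
  ast <- if (is.character(f)) parse_formula(f) else f
  text <- format_formula(ast)
  set <- eval_formula(model, ast, env = env)
  query_from_set(model, set, name %||% text, text, cap = cap)
}

query_from_set <- function(model, set, name, formula_text, cap = 10000) {
  count <- ss_size(set)
  idx <- ss_members(set, cap = cap)
  structure(
    list(
      query = name, formula = formula_text, mode = model$mode,
      backend = model$backend, count = count, state_indices = idx,
      states = state_tibble(model$genes, idx), genes = model$genes,
      n = model$n, model_hash = model_fingerprint(model), set = set
    ),
    class = "grn_query"
  )
}

model_fingerprint <- function(model) {
  rlang::hash(list(model$grn$genes, model$grn$rules, model$mode))
}

#' @export
print.grn_query <- function(x, ...) {
  cat("<grn_query> ", x$query, "\n", sep = "")
  cat("  formula: ", x$formula, "  (", x$mode, " mode)\n", sep = "")
  cat("  ", format(x$count), " satisfying state(s)\n", sep = "")
  if (x$count > 0 && x$count <= 20) print(x$states)
  invisible(x)
}

#' Canned attractor and reachability queries
#'
#' These mirror the standard hybrid-CTL analyses of Boolean networks:
#'
#' * `attractor_states()`: `down s . EX EF s` -- all states lying on some
#'   cycle of the transition graph (any-size attractor in the cycle sense;
#'   this includes cycles that are not terminal).
#' * `two_cycle_states()`: `down s . EX ((not s) and EX s)` -- states in a
#'   size-two attractor with a distinct partner state.
#' * `small_attractor_basin_complement()`:
#'   `not (EF (down s . EX EX s))` -- the complement of the basins of all
#'   one- and two-state attractors.
#'
#' For terminal behaviour in the strongly-connected-component sense, use
#' [terminal_attractor_states()], which is deliberately named differently.
#'
#' @param model A [grn_model()].
#' @param cap Enumeration cap, passed to [run_query()].
#' @return A `grn_query`.
#' @export
attractor_states <- function(model, cap = 10000) {
  run_query(model, "down s . EX EF s", name = "attractor-states", cap = cap)
}

#' @rdname attractor_states
#' @export
two_cycle_states <- function(model, cap = 10000) {
  run_query(model, "down s . EX ((not s) and EX s)",
    name = "two-cycle-states", cap = cap
  )
}

#' @rdname attractor_states
#' @export
small_attractor_basin_complement <- function(model, cap = 10000) {
  run_query(model, "not (EF (down s . EX EX s))",
    name = "small-attractor-basin-complement", cap = cap
  )
}

# resolve a target given as a state set, query result, formula text/AST, or
# numeric state indices
as_target_set <- function(model, target) {
  if (inherits(target, "state_set")) {
    return(target)
  }
  if (inherits(target, "grn_query")) {
    return(target$set)
  }
  if (is.numeric(target)) {
    stopifnot(all(target >= 0), all(target < 2^model$n))
    return(ss_from_indices(model$space, target))
  }
  eval_formula(model, target)
}

#' Basins of attraction and conditional reachability
#'
#' `basin()` is `EF target`: every state from which the target set is
#' reachable (the target itself included). `reach_avoiding()` is
#' `E[(not s1) U s2]`: states from which `s2` is reachable while avoiding
#' `s1`. `reach_through()` is `not E[(not s1) U s2] and EF s2`: states from
#' which `s2` is reachable, but only through `s1`.
#'
#' @param model A [grn_model()].
#' @param target,s1,s2 A target: a `state_set`, a `grn_query`, numeric
#'   state indices, or formula text (e.g. a `#k` state literal).
#' @param cap Enumeration cap.
#' @return A `grn_query`.
#' @export
basin <- function(model, target, cap = 10000) {
  tset <- as_target_set(model, target)
  set <- lfp_reach(model$relation, tset)
  query_from_set(model, set, "basin", "EF <target>", cap = cap)
}

#' @rdname basin
#' @export
reach_avoiding <- function(model, s2, s1, cap = 10000) {
  set2 <- as_target_set(model, s2)
  set1 <- as_target_set(model, s1)
  set <- lfp_reach(model$relation, set2, guard = ss_complement(set1))
  query_from_set(model, set, "reach-avoiding", "E[(not s1) U s2]", cap = cap)
}

#' @rdname basin
#' @export
reach_through <- function(model, s2, s1, cap = 10000) {
  set2 <- as_target_set(model, s2)
  avoiding <- reach_avoiding(model, s2, s1)$set
  set <- ss_diff(lfp_reach(model$relation, set2), avoiding)
  query_from_set(model, set, "reach-through", "not E[(not s1) U s2] and EF s2", cap = cap)
}

#' Terminal attractors by strongly connected components
#'
#' Finds the terminal strongly connected components of the transition graph
#' (components with no edge leaving them), i.e. the attractors in the
#' long-run sense. This is distinct from [attractor_states()], whose
#' cycle-membership formula also captures non-terminal cycles.
#'
#' @param model A [grn_model()].
#' @return A list of numeric vectors, one per terminal component, each the
#'   sorted state indices of one attractor.
#' @export
terminal_attractor_states <- function(model) {
  ed <- relation_edges(model$relation)
  g <- igraph::graph_from_edgelist(cbind(ed$from + 1, ed$to + 1), directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  cross <- memb[ed$from + 1] != memb[ed$to + 1]
  non_terminal <- unique(memb[ed$from + 1][cross])
  terminal <- setdiff(seq_len(comp$no), non_terminal)
  out <- lapply(terminal, function(cid) sort(which(memb == cid) - 1))
  out[order(vapply(out, min, numeric(1)))]
}

#' Screen a loss- or gain-of-function mutant
#'
#' Clamps a gene with [perturb()], rebuilds the model under the same mode
#' and backend, and reports the mutant's steady states, the basin of its
#' stable set, and the one-step backward (`EX`) and forward (`EY`) images
#' of the stable set for inspection of the surrounding transitions.
#'
#' @param model A [grn_model()].
#' @param gene Gene to clamp.
#' @param clamp `0` (loss of function) or `1` (gain of function).
#' @return A `mutant_screen` list with elements `model`, `steady`,
#'   `stable`, `unstable`, `basin_of_stable`, `ex_of_stable`,
#'   `ey_of_stable`.
#' @export
mutant_screen <- function(model, gene, clamp) {
  pg <- perturb(model$grn, gene, clamp)
  pm <- grn_model(pg, mode = model$mode, backend = model$backend)
  report <- steady_states(pm)
  stable_q <- query_from_set(pm, report$stable, "stable-steady-states", "down s . AX s")
  unstable_q <- query_from_set(
    pm, report$unstable, "unstable-steady-states",
    "down s . EX s and not down s . AX s"
  )
  structure(
    list(
      gene = gene, clamp = clamp, model = pm, steady = report,
      stable = stable_q, unstable = unstable_q,
      basin_of_stable = basin(pm, report$stable),
      ex_of_stable = query_from_set(
        pm, preimage(pm$relation, report$stable),
        "ex-of-stable", "EX <stable>"
      ),
      ey_of_stable = query_from_set(
        pm, postimage(pm$relation, report$stable),
        "ey-of-stable", "EY <stable>"
      )
    ),
    class = "mutant_screen"
  )
}

#' @export
print.mutant_screen <- function(x, ...) {
  cat("Mutant screen: ", x$gene, " clamped to ", x$clamp, " (", x$model$mode,
    " mode)\n",
    sep = ""
  )
  print(x$steady)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
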