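#' Build a checkable model from a network
#'
#' Couples a [grn] with the transition relation built from it under the
#' requested update mode and backend. All evaluation functions take such a
#' model.
#'
#' @inheritParams build_transitions
#' @return A `grn_model`.
#' @export
grn_model <- function(grn, mode = c("asynchronous", "synchronous"),
                      backend = c("bdd", "explicit")) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  relation <- build_transitions(grn, mode, backend)
  structure(
    list(
      grn = grn, relation = relation, space = relation$space,
      mode = mode, backend = backend, n = grn$n, genes = grn$genes
    ),
    class = "grn_model"
  )
}

#' @export
print.grn_model <- function(x, ...) {
  cat("<grn_model> ", x$n, " gene(s), ", x$mode, " mode, ", x$backend,
    " backend\n",
    sep = ""
  )
  invisible(x)
}

# annotate each node with a canonical key and its free variables, so that
# subformula results can be memoised on (formula, relevant bindings)
annotate_formula <- function(f) {
  kids <- intersect(names(f), c("x", "y", "body"))
  for (k in kids) f[[k]] <- annotate_formula(f[[k]])
  f$key <- format_formula(f)
  f$fv <- free_vars(f)
  f
}

#' Evaluate a formula to its satisfying state set
#'
#' The standard labeling algorithm, bottom-up over the primitive operators
#' produced by [rewrite_derived()]: gene atoms come straight from the state
#' encoding, Boolean connectives are set algebra, `EX` is one reverse
#' (predecessor) traversal, `EY` one forward traversal, and `EF`/`EG`/`EU`
#' are least/greatest fixpoints iterating those traversals (frontier-based,
#' so each iteration only expands newly added states). A binder
#' `down s . phi` is evaluated per state -- phi is checked once for each
#' state with `s` bound to it -- except when the formula matches one of the
#' special-cased patterns of [optimize_plan()], which are answered by
#' direct relation inspection.
#'
#' @param model A [grn_model()].
#' @param f Formula text or a `ctl_formula` AST.
#' @param env Optional named vector/list binding state-variable names to
#'   state indices.
#' @param optimize Use the pattern table for hybrid binders (default);
#'   `FALSE` forces the naive per-state loop.
#' @return A `state_set`; its `"eval_log"` attribute records, per evaluated
#'   temporal/hybrid subformula, the plan chosen and fixpoint iteration
#'   counts.
#' @export
eval_formula <- function(model, f, env = NULL, optimize = TRUE) {
  if (is.character(f)) f <- parse_formula(f)
  rf <- annotate_formula(rewrite_derived(f))
  env <- if (is.null(env)) numeric(0) else unlist(env)
  unknown <- setdiff(rf$fv, c(model$genes, names(env)))
  if (length(unknown) > 0L) {
    stop("unknown gene or unbound state variable '", unknown[[1L]], "'",
      call. = FALSE
    )
  }
  st <- new.env(parent = emptyenv())
  st$memo <- new.env(parent = emptyenv())
  st$log <- list()
  res <- eval_node(rf, model, env, optimize, st)
  if (isTRUE(getOption("grnctl.verbose", FALSE))) {
    for (entry in st$log) {
      message(
        "[grnctl] ", entry$op, " ", entry$formula,
        if (!is.null(entry$plan)) paste0(" plan=", entry$plan) else "",
        if (!is.null(entry$iterations)) paste0(" iterations=", entry$iterations) else "",
        " size=", entry$size
      )
    }
  }
  attr(res, "eval_log") <- st$log
  res
}

log_eval <- function(st, op, node, plan = NULL, iterations = NULL, size = NA) {
  st$log[[length(st$log) + 1L]] <- list(
    op = op, formula = node$key, plan = plan, iterations = iterations,
    size = size
  )
}

eval_node <- function(node, model, env, optimize, st) {
  fv <- node$fv
  mk_key <- paste0(
    node$key, "||",
    paste(fv, env[fv], sep = "=", collapse = ";")
  )
  hit <- st$memo[[mk_key]]
  if (!is.null(hit)) {
    return(hit)
  }
  space <- model$space
  relation <- model$relation
  ev <- function(x, env2 = env) eval_node(x, model, env2, optimize, st)
  res <- switch(node$kind,
    true = ss_full(space),
    false = ss_empty(space),
    name = {
      if (node$name %in% names(env)) {
        ss_from_indices(space, env[[node$name]])
      } else if (node$name %in% model$genes) {
        gene_atom_set(model, node$name)
      } else {
        stop("unknown gene or unbound state variable '", node$name, "'",
          call. = FALSE
        )
      }
    },
    lit = {
      if (node$index >= 2^model$n) {
        stop("state literal #", format(node$index, scientific = FALSE),
          " out of range for a ", model$n, "-gene model",
          call. = FALSE
        )
      }
      ss_from_indices(space, node$index)
    },
    not = ss_complement(ev(node$x)),
    and = ss_intersect(ev(node$x), ev(node$y)),
    or = ss_union(ev(node$x), ev(node$y)),
    EX = {
      r <- preimage(relation, ev(node$x))
      log_eval(st, "EX", node, size = ss_size(r))
      r
    },
    EY = {
      r <- postimage(relation, ev(node$x))
      log_eval(st, "EY", node, size = ss_size(r))
      r
    },
    EF = {
      seed <- ev(node$x)
      out <- lfp_reach(relation, seed, guard = NULL, st = st, node = node)
      out
    },
    EU = {
      guard <- ev(node$x)
      seed <- ev(node$y)
      lfp_reach(relation, seed, guard = guard, st = st, node = node)
    },
    EG = {
      z <- ev(node$x)
      iter <- 0L
      repeat {
        iter <- iter + 1L
        z2 <- ss_intersect(z, preimage(relation, z))
        if (ss_equal(z2, z)) break
        z <- z2
      }
      log_eval(st, "EG", node, iterations = iter, size = ss_size(z))
      z
    },
    bind = {
      plan <- if (optimize) match_plan(node) else NULL
      r <- if (!is.null(plan)) {
        run_plan(plan, relation)
      } else {
        naive_bind(node, model, env, optimize, st)
      }
      log_eval(st, "bind", node,
        plan = if (is.null(plan)) "naive" else plan,
        size = ss_size(r)
      )
      r
    },
    stop("formula must be rewritten to primitives before evaluation: ", node$kind)
  )
  assign(mk_key, res, envir = st$memo)
  res
}

gene_atom_set <- function(model, gene) {
  space <- model$space
  i <- match(gene, model$genes)
  if (model$backend == "bdd") {
    new_state_set(space, node = bdd_var_node(space$mgr, space$cur_vars[[i]]))
  } else {
    idx <- 0:(2^model$n - 1)
    new_state_set(space, bits = (idx %/% 2^(model$n - i)) %% 2 == 1)
  }
}

# least fixpoint Z = seed | (guard & pre(Z)) with a frontier: only states
# added in the previous round are expanded
lfp_reach <- function(relation, seed, guard = NULL, st = NULL, node = NULL) {
  z <- seed
  front <- seed
  iter <- 0L
  while (!ss_is_empty(front)) {
    iter <- iter + 1L
    p <- preimage(relation, front)
    if (!is.null(guard)) p <- ss_intersect(p, guard)
    front <- ss_diff(p, z)
    z <- ss_union(z, front)
  }
  if (!is.null(st)) {
    log_eval(st, if (is.null(guard)) "EF" else "EU", node,
      iterations = iter, size = ss_size(z)
    )
  }
  z
}

naive_bind <- function(node, model, env, optimize, st) {
  n <- model$n
  hits <- numeric(0)
  for (s in 0:(2^n - 1)) {
    env2 <- env
    env2[[node$var]] <- s
    r <- eval_node(node$body, model, env2, optimize, st)
    if (ss_contains(r, s)) hits <- c(hits, s)
  }
  ss_from_indices(model$space, hits)
}

# ---- the pattern table ------------------------------------------------------

# structural match up to renaming of bound variables; `vars` maps pattern
# slots to the concrete variable names seen
is_var <- function(node, name) node$kind == "name" && node$name == name

#' Choose an evaluation plan for a hybrid formula
#'
#' Certain downarrow formulas are answered by direct inspection of the
#' transition relation instead of the naive per-state loop. The table is
#' purely syntactic, applied after [rewrite_derived()] and up to renaming of
#' the bound variables:
#'
#' * `down s . EX s` -- states with a self-loop;
#' * `down s . AX s` -- self-loop states with out-degree exactly one
#'   (stable steady states);
#' * `down s . EX EF s` -- states on a cycle (strongly connected component
#'   of size two or more, or a self-loop);
#' * `down s . EX ((not s) and EX s)` -- states on a two-cycle with a
#'   distinct partner;
#' * `down s . EX down t . EY (s and EX (not t))` -- states with at least
#'   two successors, found in one pass over states and transitions instead
#'   of a per-state-pair loop.
#'
#' Anything else evaluates naively.
#'
#' @param f Formula text or AST.
#' @return The plan name: one of `"self-loop"`, `"stable"`, `"cycle"`,
#'   `"two-cycle"`, `"multi-successor"`, `"naive"`.
#' @export
optimize_plan <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  rf <- rewrite_derived(f)
  if (rf$kind != "bind") {
    return("naive")
  }
  p <- match_plan(rf)
  if (is.null(p)) "naive" else p
}

match_plan <- function(node) {
  if (node$kind != "bind") {
    return(NULL)
  }
  v <- node$var
  b <- node$body
  # down v . EX v
  if (b$kind == "EX" && is_var(b$x, v)) {
    return("self-loop")
  }
  # down v . not EX not v   (rewritten AX v)
  if (b$kind == "not" && b$x$kind == "EX" && b$x$x$kind == "not" &&
    is_var(b$x$x$x, v)) {
    return("stable")
  }
  # down v . EX EF v
  if (b$kind == "EX" && b$x$kind == "EF" && is_var(b$x$x, v)) {
    return("cycle")
  }
  # down v . EX ((not v) and EX v), either operand order
  if (b$kind == "EX" && b$x$kind == "and") {
    ops <- list(b$x$x, b$x$y)
    for (perm in list(c(1, 2), c(2, 1))) {
      a1 <- ops[[perm[[1]]]]
      a2 <- ops[[perm[[2]]]]
      if (a1$kind == "not" && is_var(a1$x, v) &&
        a2$kind == "EX" && is_var(a2$x, v)) {
        return("two-cycle")
      }
    }
  }
  # down s . EX down t . EY (s and EX not t), either operand order
  if (b$kind == "EX" && b$x$kind == "bind") {
    t <- b$x$var
    inner <- b$x$body
    if (inner$kind == "EY" && inner$x$kind == "and") {
      ops <- list(inner$x$x, inner$x$y)
      for (perm in list(c(1, 2), c(2, 1))) {
        a1 <- ops[[perm[[1]]]]
        a2 <- ops[[perm[[2]]]]
        if (is_var(a1, v) && a2$kind == "EX" && a2$x$kind == "not" &&
          is_var(a2$x$x, t)) {
          return("multi-successor")
        }
      }
    }
  }
  NULL
}

run_plan <- function(plan, relation) {
  switch(plan,
    "self-loop" = self_loop_states(relation),
    "stable" = ss_diff(self_loop_states(relation), out_degree_at_least(relation, 2)),
    "cycle" = {
      ed <- relation_edges(relation)
      on_scc <- scc_nontrivial(
        2^relation$n, as.integer(ed$from),
        as.integer(ed$to)
      )
      ss_union(
        ss_from_indices(relation$space, which(on_scc) - 1),
        self_loop_states(relation)
      )
    },
    "two-cycle" = {
      ed <- relation_edges(relation)
      key_fwd <- ed$from * 2^relation$n + ed$to
      key_rev <- ed$to * 2^relation$n + ed$from
      mutual <- (key_fwd %in% key_rev) & ed$from != ed$to
      ss_from_indices(relation$space, unique(ed$from[mutual]))
    },
    "multi-successor" = out_degree_at_least(relation, 2),
    stop("unknown plan: ", plan)
  )
}

relation_edges <- function(relation) {
  if (relation$backend == "bdd") {
    pr <- bdd_sat_pairs(
      relation$mgr, relation$node, relation$cur_vars,
      relation$nxt_vars, -1
    )
    list(from = pr[, 1], to = pr[, 2])
  } else {
    list(from = relation$from, to = relation$to)
  }
}

#' Stable and unstable steady states
#'
#' A *stable* steady state has its self-loop as its only transition
#' (`down s . AX s`); an *unstable* steady state has a self-loop plus
#' transitions to other states (in `down s . EX s` but not stable). The two
#' sets are disjoint by construction.
#'
#' @param model A [grn_model()].
#' @return A `steady_state_report` with elements `stable` and `unstable`
#'   (state sets).
#' @export
steady_states <- function(model) {
  stable <- eval_formula(model, "down s . AX s")
  looping <- eval_formula(model, "down s . EX s")
  structure(
    list(
      stable = stable, unstable = ss_diff(looping, stable),
      mode = model$mode, genes = model$genes, n = model$n
    ),
    class = "steady_state_report"
  )
}

#' @export
print.steady_state_report <- function(x, ...) {
  cat("Steady states (", x$mode, " mode): ", format(ss_size(x$stable)),
    " stable, ", format(ss_size(x$unstable)), " unstable\n",
    sep = ""
  )
  invisible(x)
}
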