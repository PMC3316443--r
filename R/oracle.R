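# Explicit-state reference evaluator. This module is the independent oracle
# the differential tests compare the main engine against: it enumerates the
# digraph directly from the network's rules (not via build_transitions),
# represents state sets as plain sorted index vectors, implements every
# operator -- including the universal ones -- straight from its semantics
# with no derived-operator rewriting, no frontier fixpoints, no
# memoisation, and evaluates binders by literal per-state substitution.

#' Enumerate the transition digraph of a network
#'
#' Builds successor and predecessor adjacency lists by evaluating
#' [allowed_next_values()] state by state. Deliberately naive; capped at 12
#' genes.
#'
#' @param grn A [grn].
#' @param mode `"asynchronous"` or `"synchronous"`.
#' @return A list with `succ` and `pred` (lists of 0-based index vectors)
#'   and `n`.
#' @export
oracle_digraph <- function(grn, mode = c("asynchronous", "synchronous")) {
  mode <- match.arg(mode)
  n <- grn$n
  if (n > 12L) stop("oracle is limited to 12 genes", call. = FALSE)
  nstates <- 2L^n
  weights <- 2^(n - seq_len(n))
  succ <- vector("list", nstates)
  for (s in 0:(nstates - 1)) {
    bits <- state_bits(s, n)
    allowed <- lapply(grn$genes, function(g) allowed_next_values(grn, s, g))
    if (mode == "asynchronous") {
      targets <- numeric(0)
      for (i in seq_len(n)) {
        for (v in allowed[[i]]) {
          if (v != bits[[i]]) {
            targets <- c(targets, s + (v - bits[[i]]) * weights[[i]])
          }
        }
      }
      if (all(vapply(seq_len(n), function(i) bits[[i]] %in% allowed[[i]], logical(1)))) {
        targets <- c(targets, s)
      }
      succ[[s + 1]] <- sort(unique(targets))
    } else {
      combos <- expand.grid(allowed, KEEP.OUT.ATTRS = FALSE)
      succ[[s + 1]] <- sort(unique(as.numeric(as.matrix(combos) %*% weights)))
    }
  }
  pred <- vector("list", nstates)
  for (s in 0:(nstates - 1)) pred[[s + 1]] <- numeric(0)
  for (s in 0:(nstates - 1)) {
    for (t in succ[[s + 1]]) pred[[t + 1]] <- c(pred[[t + 1]], s)
  }
  list(succ = succ, pred = pred, n = n)
}

#' Brute-force formula evaluation
#'
#' Evaluates a formula over the enumerated digraph of a model, returning the
#' sorted indices of satisfying states. Used to validate the main engine;
#' shares no set-algebra or traversal code with it.
#'
#' @param model A [grn_model()] (only its network and mode are used).
#' @param f Formula text or AST.
#' @param env Named vector of state-variable bindings.
#' @param digraph Optional pre-built [oracle_digraph()] result, to reuse
#'   across formulas.
#' @return Numeric vector of satisfying state indices, ascending.
#' @export
oracle_eval <- function(model, f, env = NULL, digraph = NULL) {
  if (is.character(f)) f <- parse_formula(f)
  dg <- digraph %||% oracle_digraph(model$grn, model$mode)
  n <- dg$n
  nstates <- 2L^n
  all_states <- 0:(nstates - 1)
  genes <- model$genes
  env <- if (is.null(env)) numeric(0) else unlist(env)

  in_set <- function(set) {
    memb <- rep(FALSE, nstates)
    memb[set + 1] <- TRUE
    memb
  }
  states_where <- function(pred_fn) all_states[vapply(all_states, pred_fn, logical(1))]

  ev <- function(node, env) {
    k <- node$kind
    if (k == "true") {
      return(all_states)
    }
    if (k == "false") {
      return(numeric(0))
    }
    if (k == "name") {
      if (node$name %in% names(env)) {
        return(env[[node$name]])
      }
      if (node$name %in% genes) {
        i <- match(node$name, genes)
        return(all_states[(all_states %/% 2^(n - i)) %% 2 == 1])
      }
      stop("unknown gene or unbound state variable '", node$name, "'",
        call. = FALSE
      )
    }
    if (k == "lit") {
      if (node$index >= nstates) {
        stop("state literal #", format(node$index, scientific = FALSE),
          " out of range",
          call. = FALSE
        )
      }
      return(node$index)
    }
    if (k == "not") {
      return(setdiff(all_states, ev(node$x, env)))
    }
    if (k == "and") {
      return(intersect(ev(node$x, env), ev(node$y, env)))
    }
    if (k == "or") {
      return(sort(union(ev(node$x, env), ev(node$y, env))))
    }
    if (k == "implies") {
      return(sort(union(setdiff(all_states, ev(node$x, env)), ev(node$y, env))))
    }
    if (k == "EX") {
      memb <- in_set(ev(node$x, env))
      return(states_where(function(s) any(memb[dg$succ[[s + 1]] + 1])))
    }
    if (k == "AX") {
      memb <- in_set(ev(node$x, env))
      return(states_where(function(s) all(memb[dg$succ[[s + 1]] + 1])))
    }
    if (k == "EY") {
      memb <- in_set(ev(node$x, env))
      return(states_where(function(s) any(memb[dg$pred[[s + 1]] + 1])))
    }
    if (k == "EF") {
      z <- ev(node$x, env)
      repeat {
        memb <- in_set(z)
        z2 <- sort(union(z, states_where(function(s) any(memb[dg$succ[[s + 1]] + 1]))))
        if (identical(z2, z)) {
          return(z)
        }
        z <- z2
      }
    }
    if (k == "AF") {
      z <- ev(node$x, env)
      repeat {
        memb <- in_set(z)
        z2 <- sort(union(z, states_where(function(s) all(memb[dg$succ[[s + 1]] + 1]))))
        if (identical(z2, z)) {
          return(z)
        }
        z <- z2
      }
    }
    if (k == "EG") {
      phi <- ev(node$x, env)
      z <- phi
      repeat {
        memb <- in_set(z)
        z2 <- intersect(phi, states_where(function(s) any(memb[dg$succ[[s + 1]] + 1])))
        if (identical(z2, z)) {
          return(z)
        }
        z <- z2
      }
    }
    if (k == "AG") {
      phi <- ev(node$x, env)
      z <- phi
      repeat {
        memb <- in_set(z)
        z2 <- intersect(phi, states_where(function(s) all(memb[dg$succ[[s + 1]] + 1])))
        if (identical(z2, z)) {
          return(z)
        }
        z <- z2
      }
    }
    if (k == "EU" || k == "AU") {
      a <- ev(node$x, env)
      b <- ev(node$y, env)
      amemb <- in_set(a)
      z <- b
      agg <- if (k == "EU") any else all
      repeat {
        memb <- in_set(z)
        step <- states_where(function(s) amemb[s + 1] && agg(memb[dg$succ[[s + 1]] + 1]))
        z2 <- sort(union(b, step))
        if (identical(z2, z)) {
          return(z)
        }
        z <- z2
      }
    }
    if (k == "bind") {
      return(states_where(function(s) {
        env2 <- env
        env2[[node$var]] <- s
        s %in% ev(node$body, env2)
      }))
    }
    stop("unknown formula node kind: ", k)
  }
  as.numeric(sort(ev(f, env)))
}

#' Cycle states by strongly connected components
#'
#' The independent cross-check for the cycle formula `down s . EX EF s`:
#' states in a strongly connected component of size two or more, plus
#' self-loop states, computed with igraph on the oracle's digraph.
#'
#' @inheritParams oracle_eval
#' @return Numeric vector of state indices, ascending.
#' @export
cycle_states_scc <- function(model, digraph = NULL) {
  dg <- digraph %||% oracle_digraph(model$grn, model$mode)
  nstates <- 2L^dg$n
  from <- rep(0:(nstates - 1), lengths(dg$succ))
  to <- unlist(dg$succ, use.names = FALSE)
  g <- igraph::graph_from_edgelist(cbind(from + 1, to + 1), directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  nontrivial <- which(comp$csize[comp$membership] >= 2) - 1
  selfloop <- from[from == to]
  sort(union(nontrivial, selfloop))
}
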