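#' State numbering
#'
#' A state assigns 0/1 to every gene. Its index is the integer whose binary
#' expansion lists the gene values in canonical (lexicographic) gene order,
#' most significant bit first: for genes A < B < C, state index 6 = `110` is
#' A=1, B=1, C=0.
#'
#' @param grn A [grn] (or anything with `$genes`).
#' @param values Named 0/1 vector (any order), or unnamed 0/1 vector in
#'   canonical gene order.
#' @return `state_index()`: a numeric scalar index. `state_bits()`: an
#'   integer 0/1 vector in canonical order.
#' @export
state_index <- function(grn, values) {
  bits <- as_state_bits(grn, values)
  sum(bits * 2^(grn$n - seq_len(grn$n)))
}

#' @param index State index, `0 <= index < 2^n`.
#' @param n Number of genes.
#' @rdname state_index
#' @export
state_bits <- function(index, n) {
  stopifnot(index >= 0, index < 2^n)
  as.integer((index %/% 2^(n - seq_len(n))) %% 2)
}

# tibble of decoded states, one row per index, genes as columns
state_tibble <- function(genes, indices) {
  n <- length(genes)
  cols <- lapply(seq_len(n), function(i) {
    as.integer((indices %/% 2^(n - i)) %% 2)
  })
  names(cols) <- genes
  out <- tibble::as_tibble(cols)
  dplyr::bind_cols(tibble::tibble(state_index = indices), out)
}

# ---- state-set algebra ------------------------------------------------------
# A state set is a characteristic function over the 2^n states. The symbolic
# backend stores it as a BDD node over the current-state variables; the
# explicit backend as a logical vector of length 2^n. All checker code goes
# through this small algebra, so both backends satisfy one contract.

new_state_set <- function(space, node = NULL, bits = NULL) {
  structure(
    list(
      backend = space$backend, n = space$n, genes = space$genes,
      space = space, node = node, bits = bits
    ),
    class = "state_set"
  )
}

ss_empty <- function(space) {
  if (space$backend == "bdd") {
    new_state_set(space, node = 0L)
  } else {
    new_state_set(space, bits = rep(FALSE, 2^space$n))
  }
}

ss_full <- function(space) {
  if (space$backend == "bdd") {
    new_state_set(space, node = 1L)
  } else {
    new_state_set(space, bits = rep(TRUE, 2^space$n))
  }
}

ss_from_indices <- function(space, indices) {
  if (space$backend == "bdd") {
    new_state_set(space, node = bdd_from_states(space$mgr, space$cur_vars, as.numeric(indices)))
  } else {
    bits <- rep(FALSE, 2^space$n)
    bits[indices + 1] <- TRUE
    new_state_set(space, bits = bits)
  }
}

ss_union <- function(x, y) {
  if (x$backend == "bdd") {
    new_state_set(x$space, node = bdd_or(x$space$mgr, x$node, y$node))
  } else {
    new_state_set(x$space, bits = x$bits | y$bits)
  }
}

ss_intersect <- function(x, y) {
  if (x$backend == "bdd") {
    new_state_set(x$space, node = bdd_and(x$space$mgr, x$node, y$node))
  } else {
    new_state_set(x$space, bits = x$bits & y$bits)
  }
}

ss_complement <- function(x) {
  if (x$backend == "bdd") {
    new_state_set(x$space, node = bdd_not(x$space$mgr, x$node))
  } else {
    new_state_set(x$space, bits = !x$bits)
  }
}

ss_diff <- function(x, y) ss_intersect(x, ss_complement(y))

ss_size <- function(x) {
  if (x$backend == "bdd") {
    bdd_satcount(x$space$mgr, x$node, x$space$cur_vars)
  } else {
    sum(x$bits)
  }
}

ss_is_empty <- function(x) {
  if (x$backend == "bdd") x$node == 0L else !any(x$bits)
}

ss_equal <- function(x, y) {
  if (x$backend == "bdd") x$node == y$node else identical(x$bits, y$bits)
}

ss_contains <- function(x, index) {
  if (x$backend == "bdd") {
    bdd_contains_state(x$space$mgr, x$node, x$space$cur_vars, as.numeric(index))
  } else {
    x$bits[[index + 1]]
  }
}

# member state indices, ascending; cap < 0 means no cap
ss_members <- function(x, cap = -1) {
  if (x$backend == "bdd") {
    sort(as.numeric(bdd_sat_states(x$space$mgr, x$node, x$space$cur_vars, cap)))
  } else {
    idx <- which(x$bits) - 1
    if (cap >= 0 && length(idx) > cap) idx <- idx[seq_len(cap)]
    idx
  }
}

#' @export
print.state_set <- function(x, ...) {
  cat(
    "<state_set> backend=", x$backend, ", ", format(ss_size(x)),
    " of ", format(2^x$n), " states\n",
    sep = ""
  )
  invisible(x)
}

# ---- transition relation ----------------------------------------------------

#' Build the state-transition relation of a network
#'
#' Constructs the total transition relation (the Kripke structure) of a
#' Boolean GRN under one of two update semantics.
#'
#' *Synchronous*: `s -> s'` iff for every gene g, `s'(g)` is an allowed next
#' value of g at s; indeterminate genes branch independently (Cartesian
#' product of choices).
#'
#' *Asynchronous*: for every gene g and allowed value `v != s(g)` there is a
#' transition to `s` with g flipped; in addition `s` has a self-loop iff
#' every gene may keep its current value. Fixed points therefore self-loop,
#' indeterminate rows can create self-loop-plus-exit states (unstable steady
#' states), and deterministic transient states get no spurious self-loop.
#'
#' The relation is represented either symbolically, as a binary decision
#' diagram over twice as many Boolean variables as genes (current and next
#' state bits, interleaved), or explicitly as successor/predecessor lists.
#'
#' @param grn A [grn].
#' @param mode `"asynchronous"` or `"synchronous"`.
#' @param backend `"bdd"` (symbolic, default) or `"explicit"`.
#' @return A `grn_transitions` object.
#' @export
build_transitions <- function(grn, mode = c("asynchronous", "synchronous"),
                              backend = c("bdd", "explicit")) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  if (backend == "bdd") {
    build_transitions_bdd(grn, mode)
  } else {
    build_transitions_explicit(grn, mode)
  }
}

body_to_bdd <- function(mgr, body, varmap) {
  switch(body$kind,
    atom = bdd_var_node(mgr, varmap[[body$name]]),
    not = bdd_not(mgr, body_to_bdd(mgr, body$x, varmap)),
    and = bdd_and(
      mgr, body_to_bdd(mgr, body$x, varmap),
      body_to_bdd(mgr, body$y, varmap)
    ),
    or = bdd_or(
      mgr, body_to_bdd(mgr, body$x, varmap),
      body_to_bdd(mgr, body$y, varmap)
    ),
    const = if (body$value) 1L else 0L
  )
}

# f1/f0: BDDs over current-state variables marking the states at which next
# value 1 (resp. 0) is allowed for the gene
rule_allow_bdds <- function(mgr, rule, varmap) {
  if (rule$type == "equations") {
    vals <- lapply(rule$bodies, body_to_bdd, mgr = mgr, varmap = varmap)
    f1 <- Reduce(function(a, b) bdd_or(mgr, a, b), vals)
    f0 <- Reduce(
      function(a, b) bdd_or(mgr, a, b),
      lapply(vals, function(v) bdd_not(mgr, v))
    )
    list(f1 = f1, f0 = f0)
  } else {
    k <- length(rule$regulators)
    row_cube <- function(ri) {
      idx <- ri - 1L
      acc <- 1L
      for (j in seq_len(k)) {
        v <- bdd_var_node(mgr, varmap[[rule$regulators[[j]]]])
        bit <- (idx %/% 2^(k - j)) %% 2
        acc <- bdd_and(mgr, acc, if (bit == 1) v else bdd_not(mgr, v))
      }
      acc
    }
    orred <- function(rows) {
      acc <- 0L
      for (ri in rows) acc <- bdd_or(mgr, acc, row_cube(ri))
      acc
    }
    list(
      f1 = orred(which(rule$outputs >= 1L)),
      f0 = orred(which(rule$outputs != 1L))
    )
  }
}

build_transitions_bdd <- function(grn, mode) {
  n <- grn$n
  mgr <- bdd_mgr_new(2L * n)
  cur_vars <- as.integer(2 * (seq_len(n) - 1))
  nxt_vars <- cur_vars + 1L
  varmap <- stats::setNames(as.list(cur_vars), grn$genes)
  space <- list(backend = "bdd", n = n, genes = grn$genes, mgr = mgr, cur_vars = cur_vars)

  allow <- lapply(grn$genes, function(g) rule_allow_bdds(mgr, grn$rules[[g]], varmap))
  names(allow) <- grn$genes
  cur_node <- lapply(seq_len(n), function(i) bdd_var_node(mgr, cur_vars[[i]]))
  nxt_node <- lapply(seq_len(n), function(i) bdd_var_node(mgr, nxt_vars[[i]]))

  # per-gene next-value relation: (g' & f1) | (~g' & f0)
  gene_rel <- lapply(seq_len(n), function(i) {
    bdd_or(
      mgr,
      bdd_and(mgr, nxt_node[[i]], allow[[i]]$f1),
      bdd_and(mgr, bdd_not(mgr, nxt_node[[i]]), allow[[i]]$f0)
    )
  })
  keep_i <- lapply(seq_len(n), function(i) {
    bdd_not(mgr, bdd_xor(mgr, cur_node[[i]], nxt_node[[i]]))
  })
  id_node <- Reduce(function(a, b) bdd_and(mgr, a, b), keep_i)
  # change possible for gene i (over current vars only)
  chg <- lapply(seq_len(n), function(i) {
    bdd_or(
      mgr,
      bdd_and(mgr, allow[[i]]$f1, bdd_not(mgr, cur_node[[i]])),
      bdd_and(mgr, allow[[i]]$f0, cur_node[[i]])
    )
  })
  # every gene may keep its value (over current vars only)
  hold <- Reduce(function(a, b) bdd_and(mgr, a, b), lapply(seq_len(n), function(i) {
    bdd_or(
      mgr,
      bdd_and(mgr, cur_node[[i]], allow[[i]]$f1),
      bdd_and(mgr, bdd_not(mgr, cur_node[[i]]), allow[[i]]$f0)
    )
  }))

  if (mode == "synchronous") {
    node <- Reduce(function(a, b) bdd_and(mgr, a, b), gene_rel)
  } else {
    node <- 0L
    for (i in seq_len(n)) {
      frame <- Reduce(
        function(a, b) bdd_and(mgr, a, b),
        keep_i[-i],
        accumulate = FALSE
      )
      if (n == 1L) frame <- 1L
      flip <- bdd_and(
        mgr,
        bdd_and(mgr, gene_rel[[i]], bdd_xor(mgr, cur_node[[i]], nxt_node[[i]])),
        frame
      )
      node <- bdd_or(mgr, node, flip)
    }
    node <- bdd_or(mgr, node, bdd_and(mgr, hold, id_node))
  }

  structure(
    list(
      mode = mode, backend = "bdd", n = n, genes = grn$genes, space = space,
      mgr = mgr, node = node, cur_vars = cur_vars, nxt_vars = nxt_vars,
      allow = allow, chg = chg, hold = hold, id_node = id_node
    ),
    class = "grn_transitions"
  )
}

build_transitions_explicit <- function(grn, mode) {
  n <- grn$n
  if (n > 20L) stop("explicit backend is limited to 20 genes", call. = FALSE)
  nstates <- 2L^n
  idx <- 0:(nstates - 1)
  values <- all_state_values(grn)
  allow <- lapply(grn$genes, function(g) gene_allow(grn, g, values))
  weights <- 2^(n - seq_len(n))

  from <- numeric(0)
  to <- numeric(0)
  if (mode == "asynchronous") {
    for (i in seq_len(n)) {
      cur <- values[[i]]
      up <- which(allow[[i]]$a1 & !cur) - 1
      down <- which(allow[[i]]$a0 & cur) - 1
      from <- c(from, up, down)
      to <- c(to, up + weights[[i]], down - weights[[i]])
    }
    hold <- Reduce(`&`, lapply(seq_len(n), function(i) {
      ifelse(values[[i]], allow[[i]]$a1, allow[[i]]$a0)
    }))
    self <- which(hold) - 1
    from <- c(from, self)
    to <- c(to, self)
  } else {
    both <- Reduce(`+`, lapply(allow, function(a) as.integer(a$a1 & a$a0)))
    base <- Reduce(`+`, lapply(seq_len(n), function(i) {
      as.numeric(allow[[i]]$a1) * weights[[i]]
    }))
    det <- which(both == 0L)
    from <- idx[det]
    to <- base[det]
    for (s in which(both > 0L)) {
      free <- which(vapply(allow, function(a) a$a1[s] && a$a0[s], logical(1)))
      fixed <- sum(vapply(
        setdiff(seq_len(n), free),
        function(i) as.numeric(allow[[i]]$a1[s]) * weights[[i]], numeric(1)
      ))
      combos <- expand.grid(rep(list(c(0, 1)), length(free)))
      targets <- as.numeric(as.matrix(combos) %*% weights[free]) + fixed
      from <- c(from, rep(idx[[s]], length(targets)))
      to <- c(to, targets)
    }
  }
  o <- order(from, to)
  from <- from[o]
  to <- to[o]
  lev <- factor(from, levels = idx)
  succ <- split(to, lev)
  pred <- split(from, factor(to, levels = idx))
  space <- list(backend = "explicit", n = n, genes = grn$genes)
  structure(
    list(
      mode = mode, backend = "explicit", n = n, genes = grn$genes,
      space = space, from = from, to = to, succ = succ, pred = pred
    ),
    class = "grn_transitions"
  )
}

#' @export
print.grn_transitions <- function(x, ...) {
  cat("<grn_transitions> ", x$mode, " mode, ", x$backend, " backend, ",
    x$n, " gene(s), ", format(n_transitions(x)), " transition(s)\n",
    sep = ""
  )
  invisible(x)
}

n_transitions <- function(relation) {
  if (relation$backend == "bdd") {
    bdd_satcount(
      relation$mgr, relation$node,
      sort(c(relation$cur_vars, relation$nxt_vars))
    )
  } else {
    length(relation$from)
  }
}

# ---- images -----------------------------------------------------------------

#' Predecessors, successors and images under the transition relation
#'
#' `preimage()` returns all states with at least one successor in `x` (the
#' reverse-traversal step of the labeling algorithm, i.e. the semantics of
#' EX); `postimage()` returns all states reachable from `x` in one step
#' (the semantics of EY); `successors()` is the postimage of a single state.
#'
#' @param relation A `grn_transitions`.
#' @param x A state set.
#' @param state A single state index.
#' @return A state set.
#' @export
preimage <- function(relation, x) {
  if (relation$backend == "bdd") {
    mgr <- relation$mgr
    xn <- bdd_rename(mgr, x$node, relation$cur_vars, relation$nxt_vars)
    new_state_set(
      relation$space,
      node = bdd_exists(mgr, bdd_and(mgr, relation$node, xn), relation$nxt_vars)
    )
  } else {
    members <- which(x$bits) - 1
    bits <- rep(FALSE, 2^relation$n)
    if (length(members) > 0) {
      bits[unique(unlist(relation$pred[members + 1], use.names = FALSE)) + 1] <- TRUE
    }
    new_state_set(relation$space, bits = bits)
  }
}

#' @rdname preimage
#' @export
postimage <- function(relation, x) {
  if (relation$backend == "bdd") {
    mgr <- relation$mgr
    img <- bdd_exists(mgr, bdd_and(mgr, relation$node, x$node), relation$cur_vars)
    new_state_set(
      relation$space,
      node = bdd_rename(mgr, img, relation$nxt_vars, relation$cur_vars)
    )
  } else {
    members <- which(x$bits) - 1
    bits <- rep(FALSE, 2^relation$n)
    if (length(members) > 0) {
      bits[unique(unlist(relation$succ[members + 1], use.names = FALSE)) + 1] <- TRUE
    }
    new_state_set(relation$space, bits = bits)
  }
}

#' @rdname preimage
#' @export
successors <- function(relation, state) {
  postimage(relation, ss_from_indices(relation$space, state))
}

#' States with at least k successors
#'
#' Computed by direct inspection of the relation's structure, never by
#' nested per-state hybrid evaluation: for `k = 2` the symbolic backend
#' combines the per-gene change/hold predicates, and the explicit backend
#' tallies out-degrees in one pass over the edge list (the returned set
#' carries a `touches` attribute counting the states plus transitions
#' inspected).
#'
#' @param relation A `grn_transitions`.
#' @param k `1` or `2`.
#' @return A state set.
#' @export
out_degree_at_least <- function(relation, k) {
  stopifnot(k %in% c(1, 2))
  if (k == 1) {
    return(ss_full(relation$space)) # the relation is total
  }
  if (relation$backend == "bdd") {
    mgr <- relation$mgr
    if (relation$mode == "synchronous") {
      acc <- 0L
      for (a in relation$allow) acc <- bdd_or(mgr, acc, bdd_and(mgr, a$f1, a$f0))
      new_state_set(relation$space, node = acc)
    } else {
      some <- 0L
      two <- 0L
      for (c_i in relation$chg) {
        two <- bdd_or(mgr, two, bdd_and(mgr, some, c_i))
        some <- bdd_or(mgr, some, c_i)
      }
      node <- bdd_or(mgr, two, bdd_and(mgr, relation$hold, some))
      new_state_set(relation$space, node = node)
    }
  } else {
    deg <- tabulate(relation$from + 1, nbins = 2^relation$n)
    out <- new_state_set(relation$space, bits = deg >= 2)
    attr(out, "touches") <- 2^relation$n + length(relation$from)
    out
  }
}

# states with a self-loop
self_loop_states <- function(relation) {
  if (relation$backend == "bdd") {
    mgr <- relation$mgr
    node <- bdd_exists(
      mgr, bdd_and(mgr, relation$node, relation$id_node),
      relation$nxt_vars
    )
    new_state_set(relation$space, node = node)
  } else {
    bits <- rep(FALSE, 2^relation$n)
    bits[relation$from[relation$from == relation$to] + 1] <- TRUE
    new_state_set(relation$space, bits = bits)
  }
}

#' Export the transition relation as an edge list
#'
#' @param relation A `grn_transitions`.
#' @return A tibble with `source_index` and `target_index` columns.
#' @export
edge_list <- function(relation) {
  if (relation$backend == "bdd") {
    pr <- bdd_sat_pairs(
      relation$mgr, relation$node, relation$cur_vars,
      relation$nxt_vars, -1
    )
    out <- tibble::tibble(source_index = pr[, 1], target_index = pr[, 2])
    dplyr::arrange(out, .data$source_index, .data$target_index)
  } else {
    tibble::tibble(
      source_index = as.numeric(relation$from),
      target_index = as.numeric(relation$to)
    )
  }
}

relation_is_total <- function(relation) {
  if (relation$backend == "bdd") {
    bdd_exists(relation$mgr, relation$node, relation$nxt_vars) == 1L
  } else {
    all(lengths(relation$succ) >= 1L)
  }
}
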