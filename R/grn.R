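#' Boolean gene regulatory networks with indeterminations
#'
#' A `grn` object holds an ordered list of genes together with exactly one
#' update rule per gene. Rules come in two forms, mirroring the two input
#' dialects: *equation* rules hold one or more Boolean expression bodies
#' (several bodies for the same gene encode an indetermination: every body
#' value is an allowed next value), and *table* rules hold a complete truth
#' table over a declared regulator list whose outputs are 0, 1 or `*`
#' (star = both values allowed).
#'
#' Genes are kept in canonical order: lexicographic ascending by name, in
#' ASCII byte order, case-sensitively. State numbering (see
#' [state_index()]) follows this order, most significant bit first.
#'
#' @name grn
NULL

new_grn <- function(rules) {
  genes <- sort(names(rules), method = "radix")
  stopifnot(length(genes) >= 1L, !anyDuplicated(genes))
  structure(
    list(genes = genes, rules = rules[genes], n = length(genes)),
    class = "grn"
  )
}

#' @export
print.grn <- function(x, ...) {
  cat("Boolean GRN with", x$n, "gene(s):", paste(x$genes, collapse = ", "), "\n")
  for (g in x$genes) {
    r <- x$rules[[g]]
    if (r$type == "equations") {
      for (b in r$bodies) cat("  ", g, " := ", format_rule_body(g, b), "\n", sep = "")
    } else {
      stars <- sum(r$outputs == 2L)
      cat("  ", g, ": table over {", paste(r$regulators, collapse = ", "),
        "} with ", stars, " starred row(s)\n",
        sep = ""
      )
    }
  }
  invisible(x)
}

# constant rules print/serialise as tautologies over the target gene,
# keeping the equation dialect closed under perturbation
format_rule_body <- function(target, body) {
  if (body$kind == "const") {
    if (body$value) paste0(target, " | ~", target) else paste0(target, " & ~", target)
  } else {
    format_bool(body)
  }
}

validate_grn <- function(rules) {
  declared <- names(rules)
  for (g in declared) {
    r <- rules[[g]]
    refs <- if (r$type == "equations") {
      unique(unlist(lapply(r$bodies, body_genes)))
    } else {
      r$regulators
    }
    missing <- setdiff(refs, declared)
    if (length(missing) > 0L) {
      stop("unknown gene '", missing[[1L]], "' referenced in the rule for '",
        g, "'",
        call. = FALSE
      )
    }
  }
  invisible(rules)
}

# For each gene, the states at which next-value 1 (a1) and next-value 0 (a0)
# are allowed, evaluated over parallel logical vectors (one entry per state).
# `values` is a named list of logical vectors in canonical gene order.
gene_allow <- function(grn, gene, values) {
  r <- grn$rules[[gene]]
  if (r$type == "equations") {
    vals <- lapply(r$bodies, eval_bool, values = values)
    list(
      a1 = Reduce(`|`, vals),
      a0 = Reduce(`|`, lapply(vals, `!`))
    )
  } else {
    k <- length(r$regulators)
    len <- length(values[[1L]])
    ri <- rep(1L, len)
    for (j in seq_len(k)) {
      ri <- ri + as.integer(values[[r$regulators[[j]]]]) * 2L^(k - j)
    }
    out <- r$outputs[ri]
    list(a1 = out >= 1L, a0 = out != 1L)
  }
}

#' Allowed next values of a gene at a state
#'
#' With indeterminations a gene may have more than one admissible value at
#' the next time step. For equation rules the set is the set of body values
#' at `state`; for table rules it is `{0}` or `{1}` for determinate rows and
#' `{0, 1}` for starred rows. The set is never empty.
#'
#' @param grn A [grn] object.
#' @param state A state: either a single state index (see [state_index()])
#'   or a 0/1 vector over the genes in canonical order (names optional).
#' @param gene Gene name.
#' @return Integer vector: `0`, `1`, or `c(0, 1)`.
#' @export
allowed_next_values <- function(grn, state, gene) {
  if (!gene %in% grn$genes) stop("unknown gene '", gene, "'", call. = FALSE)
  bits <- as_state_bits(grn, state)
  values <- lapply(seq_len(grn$n), function(i) as.logical(bits[[i]]))
  names(values) <- grn$genes
  al <- gene_allow(grn, gene, values)
  sort(unique(c(if (al$a0) 0L, if (al$a1) 1L)))
}

as_state_bits <- function(grn, state) {
  n <- grn$n
  if (length(state) == 1L && is.numeric(state) && is.null(names(state))) {
    return(state_bits(state, n))
  }
  if (!is.null(names(state))) {
    stopifnot(setequal(names(state), grn$genes))
    state <- state[grn$genes]
  }
  stopifnot(length(state) == n, all(state %in% c(0, 1)))
  as.integer(state)
}

#' Clamp a gene to a constant value
#'
#' Models a loss-of-function (`clamp = 0`) or gain-of-function (`clamp = 1`)
#' perturbation: the returned network is a copy in which the rule for `gene`
#' is the constant `clamp`; all other rules are untouched. Clamping the same
#' gene twice keeps only the last clamp.
#'
#' @inheritParams allowed_next_values
#' @param clamp `0` or `1`.
#' @return A perturbed [grn].
#' @export
perturb <- function(grn, gene, clamp) {
  if (!gene %in% grn$genes) stop("unknown gene '", gene, "'", call. = FALSE)
  stopifnot(clamp %in% c(0, 1))
  grn$rules[[gene]] <- list(
    type = "equations",
    bodies = list(bx_const(clamp == 1))
  )
  grn
}

#' Does a network have any indetermination?
#'
#' @inheritParams allowed_next_values
#' @return `TRUE` iff some (state, gene) pair allows both next values.
#' @export
is_deterministic <- function(grn) {
  values <- all_state_values(grn)
  for (g in grn$genes) {
    al <- gene_allow(grn, g, values)
    if (any(al$a1 & al$a0)) return(FALSE)
  }
  TRUE
}

# named list of logical vectors, one per gene, over all 2^n states
all_state_values <- function(grn) {
  n <- grn$n
  idx <- 0:(2^n - 1)
  values <- lapply(seq_len(n), function(i) {
    (idx %/% 2^(n - i)) %% 2 == 1
  })
  names(values) <- grn$genes
  values
}

#' Convert a rule to truth-table form
#'
#' The regulator list is the set of genes the rule references, in canonical
#' order; outputs are `0`, `1` or `*` (star whenever the bodies disagree).
#'
#' @inheritParams allowed_next_values
#' @return The [grn] with the rule for `gene` replaced by a table rule that
#'   allows exactly the same next values at every state.
#' @export
rule_as_table <- function(grn, gene) {
  if (!gene %in% grn$genes) stop("unknown gene '", gene, "'", call. = FALSE)
  r <- grn$rules[[gene]]
  regs <- if (r$type == "table") {
    r$regulators
  } else {
    sort(unique(unlist(lapply(r$bodies, body_genes))), method = "radix")
  }
  k <- length(regs)
  rows <- 2L^k
  idx <- 0:(rows - 1)
  values <- stats::setNames(
    lapply(seq_len(k), function(j) (idx %/% 2^(k - j)) %% 2 == 1),
    regs
  )
  # genes outside the regulator list are irrelevant to the bodies
  al <- gene_allow_over(grn$rules[[gene]], values, rows)
  outputs <- ifelse(al$a1 & al$a0, 2L, ifelse(al$a1, 1L, 0L))
  grn$rules[[gene]] <- list(type = "table", regulators = regs, outputs = outputs)
  grn
}

gene_allow_over <- function(rule, values, len) {
  if (rule$type == "equations") {
    vals <- lapply(rule$bodies, function(b) {
      if (b$kind == "const") rep(b$value, len) else eval_bool(b, values)
    })
    list(a1 = Reduce(`|`, vals), a0 = Reduce(`|`, lapply(vals, `!`)))
  } else {
    k <- length(rule$regulators)
    ri <- rep(1L, len)
    for (j in seq_len(k)) {
      ri <- ri + as.integer(values[[rule$regulators[[j]]]]) * 2L^(k - j)
    }
    out <- rule$outputs[ri]
    list(a1 = out >= 1L, a0 = out != 1L)
  }
}
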