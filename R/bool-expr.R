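# Boolean rule bodies as small ASTs: atom / not / and / or / const.
# Evaluation is vectorised over parallel logical vectors so a body can be
# evaluated at one state or at all 2^n states in one pass.

bx_atom <- function(name) list(kind = "atom", name = name)
bx_not <- function(x) list(kind = "not", x = x)
bx_and <- function(x, y) list(kind = "and", x = x, y = y)
bx_or <- function(x, y) list(kind = "or", x = x, y = y)
bx_const <- function(value) list(kind = "const", value = isTRUE(value))

#' @noRd
eval_bool <- function(node, values) {
  switch(node$kind,
    atom = values[[node$name]],
    not = !eval_bool(node$x, values),
    and = eval_bool(node$x, values) & eval_bool(node$y, values),
    or = eval_bool(node$x, values) | eval_bool(node$y, values),
    const = rep(node$value, length(values[[1L]])),
    stop("unknown boolean node kind: ", node$kind)
  )
}

body_genes <- function(node) {
  switch(node$kind,
    atom = node$name,
    not = body_genes(node$x),
    and = c(body_genes(node$x), body_genes(node$y)),
    or = c(body_genes(node$x), body_genes(node$y)),
    const = character(0)
  )
}

# precedence: ~ > & > |
format_bool <- function(node, parent = "or") {
  prec <- c(or = 1L, and = 2L, not = 3L, atom = 4L, const = 4L)
  txt <- switch(node$kind,
    atom = node$name,
    const = if (node$value) "1" else "0", # never emitted; placeholder
    not = paste0("~", format_bool(node$x, "not")),
    and = paste0(format_bool(node$x, "and"), " & ", format_bool(node$y, "and")),
    or = paste0(format_bool(node$x, "or"), " | ", format_bool(node$y, "or"))
  )
  if (prec[[node$kind]] < prec[[parent]]) paste0("(", txt, ")") else txt
}
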