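#' Temporal-logic formulas
#'
#' Formulas are ASTs over gene atoms, numeric state literals (`#k`), state
#' variables, Boolean connectives, the CTL temporal operators, the past
#' operator `EY`, and the hybrid downarrow binder (`down s . phi`), which
#' binds the state variable `s` to the state of evaluation.
#'
#' The ASCII grammar accepted by [parse_formula()]:
#' \preformatted{
#'   phi := phi2 ("->" | "implies") phi        (right associative)
#'   phi2 := phi3 (("|" | "or") phi3)*
#'   phi3 := phi4 (("&" | "and") phi4)*
#'   phi4 := ("~" | "not") phi4
#'         | (EX|AX|EF|AF|EG|AG|EY) phi4
#'         | "down" IDENT "." phi              (binder body extends right)
#'         | "E" "[" phi "U" phi "]"
#'         | "A" "[" phi "U" phi "]"
#'         | "(" phi ")" | "#" INT | "true" | "false" | IDENT
#' }
#' An identifier denotes the state variable of the innermost enclosing
#' binder of that name, if any, and otherwise a gene atom; the distinction
#' is resolved against the model at evaluation time.
#'
#' @name ctl_formula
NULL

f_node <- function(kind, ...) structure(list(kind = kind, ...), class = "ctl_formula")

TEMPORAL_UNARY <- c("EX", "AX", "EF", "AF", "EG", "AG", "EY")

ctl_tokenize <- function(text) {
  toks <- list()
  pos <- 1L
  len <- nchar(text)
  while (pos <= len) {
    ch <- substr(text, pos, pos)
    if (grepl("^\\s$", ch)) {
      pos <- pos + 1L
      next
    }
    rest <- substr(text, pos, len)
    if (grepl("^[A-Za-z_]", ch)) {
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
      toks[[length(toks) + 1L]] <- list(type = "ident", text = m, pos = pos)
      pos <- pos + nchar(m)
      next
    }
    if (ch == "#") {
      m <- regmatches(rest, regexpr("^#[0-9]+", rest))
      if (length(m) == 0L) {
        stop("formula syntax error at position ", pos,
          ": '#' must be followed by a state number",
          call. = FALSE
        )
      }
      toks[[length(toks) + 1L]] <- list(
        type = "lit",
        text = m, k = as.numeric(substr(m, 2, nchar(m))), pos = pos
      )
      pos <- pos + nchar(m)
      next
    }
    if (substr(text, pos, pos + 1L) == "->") {
      toks[[length(toks) + 1L]] <- list(type = "->", text = "->", pos = pos)
      pos <- pos + 2L
      next
    }
    if (ch %in% c("(", ")", "[", "]", ".", "~", "&", "|")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, pos = pos)
      pos <- pos + 1L
      next
    }
    stop("formula syntax error at position ", pos, ": unexpected character '",
      ch, "'",
      call. = FALSE
    )
  }
  toks
}

#' Parse a temporal-logic formula
#'
#' @param text Formula as an ASCII string; see [ctl_formula] for the
#'   grammar.
#' @return A `ctl_formula` AST.
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  toks <- ctl_tokenize(text)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  advance <- function() i <<- i + 1L
  fail <- function(tok, expected) {
    if (is.null(tok)) {
      stop("formula syntax error at end of input: expected ", expected,
        call. = FALSE
      )
    }
    stop("formula syntax error at position ", tok$pos, ": expected ", expected,
      ", found '", tok$text, "'",
      call. = FALSE
    )
  }
  expect <- function(type, expected = paste0("'", type, "'")) {
    tok <- peek()
    if (is.null(tok) || tok$type != type) fail(tok, expected)
    advance()
    tok
  }
  is_kw <- function(tok, kw) !is.null(tok) && tok$type == "ident" && tok$text == kw

  p_implies <- function() {
    l <- p_or()
    tok <- peek()
    if (!is.null(tok) && (tok$type == "->" || is_kw(tok, "implies"))) {
      advance()
      return(f_node("implies", x = l, y = p_implies()))
    }
    l
  }
  p_or <- function() {
    x <- p_and()
    repeat {
      tok <- peek()
      if (!is.null(tok) && (tok$type == "|" || is_kw(tok, "or"))) {
        advance()
        x <- f_node("or", x = x, y = p_and())
      } else {
        return(x)
      }
    }
  }
  p_and <- function() {
    x <- p_unary()
    repeat {
      tok <- peek()
      if (!is.null(tok) && (tok$type == "&" || is_kw(tok, "and"))) {
        advance()
        x <- f_node("and", x = x, y = p_unary())
      } else {
        return(x)
      }
    }
  }
  p_unary <- function() {
    tok <- peek()
    if (is.null(tok)) fail(tok, "a formula")
    if (tok$type == "~" || is_kw(tok, "not")) {
      advance()
      return(f_node("not", x = p_unary()))
    }
    if (tok$type == "ident" && tok$text %in% TEMPORAL_UNARY) {
      advance()
      return(f_node(tok$text, x = p_unary()))
    }
    if (is_kw(tok, "down")) {
      advance()
      v <- expect("ident", "a state-variable name")$text
      expect(".")
      return(f_node("bind", var = v, body = p_implies()))
    }
    if (tok$type == "ident" && tok$text %in% c("E", "A") &&
      !is.null(toks[i + 1][[1]]) && i + 1L <= length(toks) &&
      toks[[i + 1L]]$type == "[") {
      q <- tok$text
      advance()
      expect("[")
      a <- p_implies()
      utok <- peek()
      if (!is_kw(utok, "U")) fail(utok, "'U'")
      advance()
      b <- p_implies()
      expect("]")
      return(f_node(if (q == "E") "EU" else "AU", x = a, y = b))
    }
    if (tok$type == "(") {
      advance()
      x <- p_implies()
      expect(")")
      return(x)
    }
    if (tok$type == "lit") {
      advance()
      return(f_node("lit", index = tok$k))
    }
    if (is_kw(tok, "true")) {
      advance()
      return(f_node("true"))
    }
    if (is_kw(tok, "false")) {
      advance()
      return(f_node("false"))
    }
    if (tok$type == "ident") {
      advance()
      return(f_node("name", name = tok$text))
    }
    fail(tok, "a formula")
  }

  out <- p_implies()
  if (!is.null(peek())) fail(peek(), "end of formula")
  out
}

#' Pretty-print a formula
#'
#' Inverse of [parse_formula()] up to whitespace and parenthesisation.
#'
#' @param f A `ctl_formula`.
#' @return A single string.
#' @export
format_formula <- function(f, .prec = 0L) {
  prec <- function(kind) {
    switch(kind,
      implies = 1L, bind = 1L, or = 2L, and = 3L,
      5L
    )
  }
  wrap <- function(txt, p) if (p < .prec) paste0("(", txt, ")") else txt
  k <- f$kind
  if (k %in% c("true", "false")) {
    return(k)
  }
  if (k == "name") {
    return(f$name)
  }
  if (k == "lit") {
    return(paste0("#", format(f$index, scientific = FALSE)))
  }
  if (k == "not") {
    return(paste0("not ", format_formula(f$x, 4L)))
  }
  if (k %in% TEMPORAL_UNARY) {
    return(paste0(k, " ", format_formula(f$x, 4L)))
  }
  if (k == "and") {
    return(wrap(paste0(
      format_formula(f$x, 3L), " and ",
      format_formula(f$y, 4L)
    ), 3L))
  }
  if (k == "or") {
    return(wrap(paste0(
      format_formula(f$x, 2L), " or ",
      format_formula(f$y, 3L)
    ), 2L))
  }
  if (k == "implies") {
    return(wrap(paste0(
      format_formula(f$x, 2L), " implies ",
      format_formula(f$y, 1L)
    ), 1L))
  }
  if (k == "EU" || k == "AU") {
    return(paste0(
      substr(k, 1, 1), "[", format_formula(f$x, 0L), " U ",
      format_formula(f$y, 0L), "]"
    ))
  }
  if (k == "bind") {
    return(wrap(paste0("down ", f$var, " . ", format_formula(f$body, 1L)), 1L))
  }
  stop("unknown formula node kind: ", k)
}

#' @export
print.ctl_formula <- function(x, ...) {
  cat("<ctl_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Unbound identifiers of a formula
#'
#' Returns the identifiers not captured by any enclosing `down` binder.
#' Such a name is resolved against the model at evaluation time: it must be
#' either a gene of the model or a variable bound in the supplied
#' environment.
#'
#' @param f A `ctl_formula`.
#' @param bound Names to treat as already bound (used in recursion).
#' @return Character vector of names.
#' @export
free_vars <- function(f, bound = character(0)) {
  switch(f$kind,
    name = if (f$name %in% bound) character(0) else f$name,
    bind = free_vars(f$body, c(bound, f$var)),
    {
      kids <- f[names(f) %in% c("x", "y", "body")]
      unique(unlist(lapply(kids, free_vars, bound = bound), use.names = FALSE))
    }
  )
}

#' Rewrite derived operators into the primitive core
#'
#' The labeling algorithm treats universal operators through equivalences:
#' `AX p = not EX not p`, `AG p = not EF not p`, `AF p = not EG not p`,
#' `A[p U q] = not(E[not q U (not p and not q)] or EG not q)`, and
#' `implies` through `not`/`or`. The result contains only atoms, literals,
#' variables, `not`, `and`, `or`, `EX`, `EY`, `EF`, `EG`, `EU` and binders;
#' rewriting is idempotent.
#'
#' @param f A `ctl_formula`.
#' @return A `ctl_formula` over the primitive operators.
#' @export
rewrite_derived <- function(f) {
  rw <- rewrite_derived
  switch(f$kind,
    name = ,
    lit = ,
    true = ,
    false = f,
    not = f_node("not", x = rw(f$x)),
    and = f_node("and", x = rw(f$x), y = rw(f$y)),
    or = f_node("or", x = rw(f$x), y = rw(f$y)),
    implies = f_node("or", x = f_node("not", x = rw(f$x)), y = rw(f$y)),
    EX = f_node("EX", x = rw(f$x)),
    EY = f_node("EY", x = rw(f$x)),
    EF = f_node("EF", x = rw(f$x)),
    EG = f_node("EG", x = rw(f$x)),
    EU = f_node("EU", x = rw(f$x), y = rw(f$y)),
    AX = f_node("not", x = f_node("EX", x = f_node("not", x = rw(f$x)))),
    AG = f_node("not", x = f_node("EF", x = f_node("not", x = rw(f$x)))),
    AF = f_node("not", x = f_node("EG", x = f_node("not", x = rw(f$x)))),
    AU = {
      nx <- f_node("not", x = rw(f$x))
      ny <- f_node("not", x = rw(f$y))
      f_node("not", x = f_node("or",
        x = f_node("EU", x = ny, y = f_node("and", x = nx, y = ny)),
        y = f_node("EG", x = ny)
      ))
    },
    bind = f_node("bind", var = f$var, body = rw(f$body)),
    stop("unknown formula node kind: ", f$kind)
  )
}

#' Export a formula AST as JSON
#'
#' @param f A `ctl_formula`.
#' @export
formula_to_json <- function(f) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (inherits(v, "ctl_formula") || is.list(v)) strip(v) else v)
  }
  jsonlite::toJSON(strip(f), auto_unbox = TRUE)
}
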