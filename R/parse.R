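#' Read a Boolean GRN from a file
#'
#' Two plain-text dialects are supported. The *equation* dialect has one
#' statement per rule, `X := boolexpr;`, with operators `&` (and), `|` (or),
#' `~` (not) and parentheses; writing two (or more) equations with the same
#' left-hand side encodes an indetermination. The *table* dialect gives one
#' complete truth table per gene with outputs `0`, `1` or `*` (star =
#' indetermination). `//` starts a comment in both dialects. Every gene
#' referenced on a right-hand side must have a rule of its own; constants
#' are written explicitly (e.g. `A := A;` for an input held at its value).
#'
#' @param path File path.
#' @param dialect `"equations"`, `"tables"`, or `"auto"` (detect from
#'   content: a line starting with `table` selects the table dialect).
#' @return A [grn] object.
#' @export
read_grn <- function(path, dialect = c("auto", "equations", "tables")) {
  dialect <- match.arg(dialect)
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (dialect == "auto") {
    stripped <- sub("//.*$", "", strsplit(text, "\n")[[1L]])
    dialect <- if (any(grepl("^\\s*table\\b", stripped))) "tables" else "equations"
  }
  if (dialect == "tables") parse_tables(text) else parse_equations(text)
}

# ---- equation dialect -------------------------------------------------------

eq_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(lines) == 0L) lines <- ""
  toks <- list()
  for (ln in seq_along(lines)) {
    s <- sub("//.*$", "", lines[[ln]])
    pos <- 1L
    len <- nchar(s)
    while (pos <= len) {
      ch <- substr(s, pos, pos)
      if (grepl("^\\s$", ch)) {
        pos <- pos + 1L
        next
      }
      if (grepl("^[A-Za-z0-9_]$", ch)) {
        rest <- substr(s, pos, len)
        m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
        if (length(m) == 0L) {
          stop("syntax error at line ", ln, ", column ", pos,
            ": identifiers must start with a letter or underscore",
            call. = FALSE
          )
        }
        toks[[length(toks) + 1L]] <- list(type = "ident", text = m, line = ln, col = pos)
        pos <- pos + nchar(m)
        next
      }
      two <- substr(s, pos, pos + 1L)
      if (two == ":=") {
        toks[[length(toks) + 1L]] <- list(type = "assign", text = ":=", line = ln, col = pos)
        pos <- pos + 2L
        next
      }
      if (ch %in% c(":", "=", "&", "|", "~", "(", ")", ";")) {
        toks[[length(toks) + 1L]] <- list(type = ch, text = ch, line = ln, col = pos)
        pos <- pos + 1L
        next
      }
      stop("syntax error at line ", ln, ", column ", pos,
        ": unexpected character '", ch, "'",
        call. = FALSE
      )
    }
  }
  toks
}

#' Parse the equation dialect
#'
#' @param text Equation-dialect source as a single string.
#' @return A [grn] object.
#' @rdname read_grn
#' @export
parse_equations <- function(text) {
  toks <- eq_tokenize(text)
  if (length(toks) == 0L) stop("empty network description", call. = FALSE)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  fail <- function(tok, expected) {
    if (is.null(tok)) {
      stop("syntax error at end of input: expected ", expected, call. = FALSE)
    }
    stop("syntax error at line ", tok$line, ", column ", tok$col,
      ": expected ", expected, ", found '", tok$text, "'",
      call. = FALSE
    )
  }
  take <- function(type, expected = type) {
    tok <- peek()
    if (is.null(tok) || tok$type != type) fail(tok, expected)
    i <<- i + 1L
    tok
  }
  parse_or <- function() {
    x <- parse_and()
    while (!is.null(peek()) && peek()$type == "|") {
      take("|")
      x <- bx_or(x, parse_and())
    }
    x
  }
  parse_and <- function() {
    x <- parse_unary()
    while (!is.null(peek()) && peek()$type == "&") {
      take("&")
      x <- bx_and(x, parse_unary())
    }
    x
  }
  parse_unary <- function() {
    tok <- peek()
    if (is.null(tok)) fail(tok, "an expression")
    if (tok$type == "~") {
      take("~")
      return(bx_not(parse_unary()))
    }
    if (tok$type == "(") {
      take("(")
      x <- parse_or()
      take(")", "')'")
      return(x)
    }
    if (tok$type == "ident") {
      return(bx_atom(take("ident")$text))
    }
    fail(tok, "an expression")
  }

  bodies <- list() # target -> list of bodies
  while (!is.null(peek())) {
    target <- take("ident", "a gene name")$text
    tok <- peek()
    if (!is.null(tok) && tok$type == "assign") {
      take("assign")
    } else if (!is.null(tok) && tok$type == ":") {
      take(":") # the printed-listing spelling ': ='
      take("=", "'=' after ':'")
    } else {
      fail(tok, "':='")
    }
    body <- parse_or()
    take(";", "';'")
    bodies[[target]] <- c(bodies[[target]], list(body))
  }
  rules <- lapply(bodies, function(bs) list(type = "equations", bodies = bs))
  validate_grn(rules)
  new_grn(rules)
}

# ---- table dialect ----------------------------------------------------------

#' Parse the table dialect
#'
#' Each block starts with `table <gene> : <regulator> ...` (no regulators for
#' a constant gene) followed by exactly `2^k` rows `b1 ... bk : o` with
#' `o` one of `0`, `1`, `*`; the first listed regulator is the most
#' significant input bit.
#'
#' @param text Table-dialect source as a single string.
#' @rdname read_grn
#' @export
parse_tables <- function(text) {
  raw <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- sub("//.*$", "", raw)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0L) stop("empty network description", call. = FALSE)
  rules <- list()
  j <- 1L
  while (j <= length(keep)) {
    ln <- keep[[j]]
    s <- trimws(lines[[ln]])
    m <- regmatches(
      s,
      regexec("^table\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", s)
    )[[1L]]
    if (length(m) == 0L) {
      stop("syntax error at line ", ln, ": expected 'table <gene> : <regulators>'",
        call. = FALSE
      )
    }
    target <- m[[2L]]
    regs <- strsplit(trimws(m[[3L]]), "\\s+")[[1L]]
    regs <- regs[regs != ""]
    bad <- regs[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", regs)]
    if (length(bad) > 0L) {
      stop("syntax error at line ", ln, ": bad regulator name '", bad[[1L]], "'",
        call. = FALSE
      )
    }
    if (!is.null(rules[[target]])) {
      stop("duplicate table for gene '", target, "' at line ", ln, call. = FALSE)
    }
    k <- length(regs)
    nrows <- 2L^k
    outputs <- rep(NA_integer_, nrows)
    for (r in seq_len(nrows)) {
      j <- j + 1L
      if (j > length(keep)) {
        stop("table for '", target, "' is missing rows: expected ", nrows,
          ", found ", r - 1L,
          call. = FALSE
        )
      }
      ln <- keep[[j]]
      s <- trimws(lines[[ln]])
      rm <- regmatches(s, regexec("^([01[:space:]]*):\\s*([01*])$", s))[[1L]]
      if (length(rm) == 0L) {
        stop("syntax error at line ", ln, ": expected a table row 'b1 ... bk : 0|1|*'",
          call. = FALSE
        )
      }
      bits <- strsplit(trimws(rm[[2L]]), "\\s+")[[1L]]
      bits <- bits[bits != ""]
      if (length(bits) != k) {
        stop("syntax error at line ", ln, ": expected ", k, " input bit(s), found ",
          length(bits),
          call. = FALSE
        )
      }
      ri <- if (k == 0L) 1L else sum(as.integer(bits) * 2L^(k - seq_len(k))) + 1L
      if (!is.na(outputs[[ri]])) {
        stop("duplicated table row at line ", ln, " for gene '", target, "'",
          call. = FALSE
        )
      }
      outputs[[ri]] <- switch(rm[[3L]], "0" = 0L, "1" = 1L, "*" = 2L)
    }
    rules[[target]] <- list(type = "table", regulators = regs, outputs = outputs)
    j <- j + 1L
  }
  validate_grn(rules)
  new_grn(rules)
}

# ---- serialization ----------------------------------------------------------

#' Serialize a network
#'
#' `as_equations_text()` renders every rule as one or more equations (table
#' rules are translated to disjunctive normal form; a starred table becomes
#' two bodies that disagree exactly on the starred rows). `as_tables_text()`
#' renders every rule as a complete truth table over its referenced genes.
#' Both serializations preserve the allowed-next-value function pointwise.
#'
#' @param grn A [grn].
#' @return A single string in the corresponding dialect.
#' @export
as_equations_text <- function(grn) {
  out <- character(0)
  for (g in grn$genes) {
    r <- grn$rules[[g]]
    bodies <- if (r$type == "equations") r$bodies else table_to_bodies(r)
    for (b in bodies) {
      out <- c(out, paste0(g, " := ", format_rule_body(g, b), ";"))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

# bodies (one or two) whose value sets reproduce a table rule: the first is
# true on rows with output 1 or *, the second on rows with output 1 only
table_to_bodies <- function(rule) {
  k <- length(rule$regulators)
  if (k == 0L) {
    out <- rule$outputs[[1L]]
    if (out == 2L) {
      return(list(bx_const(TRUE), bx_const(FALSE)))
    }
    return(list(bx_const(out == 1L)))
  }
  dnf <- function(rows) {
    if (length(rows) == 0L) {
      return(bx_const(FALSE))
    }
    terms <- lapply(rows, function(ri) {
      idx <- ri - 1L
      lits <- lapply(seq_len(k), function(j) {
        bit <- (idx %/% 2^(k - j)) %% 2
        a <- bx_atom(rule$regulators[[j]])
        if (bit == 1) a else bx_not(a)
      })
      Reduce(bx_and, lits)
    })
    Reduce(bx_or, terms)
  }
  may <- dnf(which(rule$outputs >= 1L))
  must <- dnf(which(rule$outputs == 1L))
  if (any(rule$outputs == 2L)) list(may, must) else list(may)
}

#' @rdname as_equations_text
#' @export
as_tables_text <- function(grn) {
  out <- character(0)
  for (g in grn$genes) {
    tg <- rule_as_table(grn, g)
    r <- tg$rules[[g]]
    k <- length(r$regulators)
    out <- c(out, paste0("table ", g, " : ", paste(r$regulators, collapse = " ")))
    for (ri in seq_along(r$outputs)) {
      idx <- ri - 1L
      bits <- if (k == 0L) {
        character(0)
      } else {
        vapply(seq_len(k), function(j) {
          as.character((idx %/% 2^(k - j)) %% 2)
        }, character(1))
      }
      o <- c("0", "1", "*")[r$outputs[[ri]] + 1L]
      out <- c(out, paste0(paste(bits, collapse = " "), " : ", o))
    }
    out <- c(out, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Export a network as JSON
#'
#' @param grn A [grn].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
grn_to_json <- function(grn, path = NULL) {
  rules <- lapply(grn$genes, function(g) {
    r <- grn$rules[[g]]
    if (r$type == "equations") {
      list(
        target = g,
        bodies = vapply(r$bodies, function(b) format_rule_body(g, b), character(1))
      )
    } else {
      list(
        target = g,
        regulators = r$regulators,
        outputs = c("0", "1", "*")[r$outputs + 1L]
      )
    }
  })
  js <- jsonlite::toJSON(list(genes = grn$genes, rules = rules), auto_unbox = TRUE)
  if (is.null(path)) {
    return(js)
  }
  writeLines(js, path)
  invisible(path)
}
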