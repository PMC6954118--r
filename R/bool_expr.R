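#' @name bool_expr
#' @title Boolean expression trees
#'
#' @description
#' Right-hand sides of all update rules are finite Boolean expression trees
#' over target symbols. Node kinds: `const` (TRUE/FALSE), `ref` (a target
#' symbol), `and`, `or`, `not`. Constructors simplify eagerly so that the
#' identities of the update-rule calculus hold structurally: an empty
#' conjunction is TRUE, an empty disjunction is FALSE, and constants are
#' absorbed. Evaluation is pure.
NULL

bx <- function(kind, ...) structure(list(kind = kind, ...), class = "bool_expr")

#' Boolean expression constructors
#'
#' `bx_const(TRUE)` / `bx_const(FALSE)` are the constant nodes, `bx_ref(sym)`
#' references a model target by symbol, and `bx_and()`, `bx_or()`, `bx_not()`
#' combine expressions. `bx_and()` with no arguments is TRUE (empty
#' conjunction), `bx_or()` with no arguments is FALSE (empty disjunction).
#'
#' @param value logical scalar.
#' @param sym target symbol (character scalar).
#' @param ... expressions (or a single list of expressions).
#' @param e expression to negate.
#' @return A `bool_expr` object.
#' @export
bx_const <- function(value) {
  stopifnot(is.logical(value), length(value) == 1L, !is.na(value))
  bx("const", value = value)
}

#' @rdname bx_const
#' @export
bx_ref <- function(sym) {
  stopifnot(is.character(sym), length(sym) == 1L, nzchar(sym))
  bx("ref", sym = sym)
}

bx_args <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !inherits(args[[1]], "bool_expr"))
    args <- args[[1]]
  stopifnot(all(vapply(args, inherits, logical(1), "bool_expr")))
  args
}

#' @rdname bx_const
#' @export
bx_and <- function(...) {
  args <- bx_args(...)
  out <- list()
  for (a in args) {
    if (a$kind == "const") {
      if (!a$value) return(bx_const(FALSE))
      # TRUE is the neutral element: drop
    } else if (a$kind == "and") {
      out <- c(out, a$args)
    } else {
      out <- c(out, list(a))
    }
  }
  if (length(out) == 0L) return(bx_const(TRUE))
  if (length(out) == 1L) return(out[[1]])
  bx("and", args = out)
}

#' @rdname bx_const
#' @export
bx_or <- function(...) {
  args <- bx_args(...)
  out <- list()
  for (a in args) {
    if (a$kind == "const") {
      if (a$value) return(bx_const(TRUE))
    } else if (a$kind == "or") {
      out <- c(out, a$args)
    } else {
      out <- c(out, list(a))
    }
  }
  if (length(out) == 0L) return(bx_const(FALSE))
  if (length(out) == 1L) return(out[[1]])
  bx("or", args = out)
}

#' @rdname bx_const
#' @export
bx_not <- function(e) {
  stopifnot(inherits(e, "bool_expr"))
  if (e$kind == "const") return(bx_const(!e$value))
  if (e$kind == "not") return(e$arg)
  bx("not", arg = e)
}

#' Evaluate a Boolean expression against a state vector
#'
#' @param e a `bool_expr`.
#' @param v named logical vector, one value per target symbol.
#' @return logical scalar.
#' @export
bx_eval <- function(e, v) {
  switch(e$kind,
    const = e$value,
    ref = {
      idx <- match(e$sym, names(v))
      if (is.na(idx) || is.na(v[[idx]]))
        stop("unresolved reference to target '", e$sym, "'")
      v[[idx]]
    },
    and = {
      for (a in e$args) if (!bx_eval(a, v)) return(FALSE)
      TRUE
    },
    or = {
      for (a in e$args) if (bx_eval(a, v)) return(TRUE)
      FALSE
    },
    not = !bx_eval(e$arg, v),
    stop("unknown expression kind: ", e$kind)
  )
}

#' Symbols referenced by an expression
#' @param e a `bool_expr`.
#' @return character vector of unique target symbols.
#' @export
bx_refs <- function(e) {
  switch(e$kind,
    const = character(0),
    ref = e$sym,
    and = unique(unlist(lapply(e$args, bx_refs))),
    or = unique(unlist(lapply(e$args, bx_refs))),
    not = bx_refs(e$arg)
  )
}

#' Serialise an expression in the BoolNet operator dialect
#'
#' Operators `&`, `|`, `!`, constants `0`/`1`, explicit parentheses around
#' every compound subexpression (precedence is never relied upon).
#'
#' @param e a `bool_expr`.
#' @return character scalar.
#' @export
bx_deparse <- function(e) {
  switch(e$kind,
    const = if (e$value) "1" else "0",
    ref = e$sym,
    and = paste0("(", paste(vapply(e$args, bx_deparse, character(1)),
                            collapse = " & "), ")"),
    or = paste0("(", paste(vapply(e$args, bx_deparse, character(1)),
                           collapse = " | "), ")"),
    not = paste0("!", if (e$arg$kind %in% c("const", "ref"))
      bx_deparse(e$arg) else bx_deparse(e$arg))
  )
}

# --- expression parser (BoolNet dialect: symbols, & | !, parens, 0/1) -------

bx_tokenise <- function(text) {
  pat <- "[A-Za-z0-9_.]+|&+|\\|+|!|\\(|\\)"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  rest <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", gsub("[&|!()[:space:]]", "", rest)))
    stop("unexpected characters in expression: ", text)
  toks
}

#' Parse an expression in the BoolNet operator dialect
#'
#' Inverse of [bx_deparse()] up to simplification. Grammar (standard
#' precedence): `or := and ('|' and)*`, `and := unary ('&' unary)*`,
#' `unary := '!' unary | '(' or ')' | symbol | 0 | 1`.
#'
#' @param text character scalar.
#' @return a `bool_expr`.
#' @export
bx_parse <- function(text) {
  toks <- bx_tokenise(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    parts <- list(parse_and())
    while (!is.na(peek()) && grepl("^\\|+$", peek())) {
      take()
      parts <- c(parts, list(parse_and()))
    }
    bx_or(parts)
  }
  parse_and <- function() {
    parts <- list(parse_unary())
    while (!is.na(peek()) && grepl("^&+$", peek())) {
      take()
      parts <- c(parts, list(parse_unary()))
    }
    bx_and(parts)
  }
  parse_unary <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of expression: ", text)
    if (t == "!") return(bx_not(parse_unary()))
    if (t == "(") {
      e <- parse_or()
      if (!identical(take(), ")")) stop("missing ')' in expression: ", text)
      return(e)
    }
    if (t == "0") return(bx_const(FALSE))
    if (t == "1") return(bx_const(TRUE))
    if (grepl("^[A-Za-z_.][A-Za-z0-9_.]*$", t)) return(bx_ref(t))
    stop("unexpected token '", t, "' in expression: ", text)
  }
  e <- parse_or()
  if (!is.na(peek())) stop("trailing tokens in expression: ", text)
  e
}

#' @export
print.bool_expr <- function(x, ...) {
  cat("<bool_expr> ", bx_deparse(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.bool_expr <- function(x, ...) bx_deparse(x)
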