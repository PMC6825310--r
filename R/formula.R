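# Target-function formula language: parsing, printing, evaluation.
#
# The grammar mirrors the BMA tool's target-function language:
#   expr    := term (('+' | '-') term)*
#   term    := unary (('*' | '/') unary)*
#   unary   := '-' unary | primary
#   primary := number | func '(' expr (',' expr)* ')' | var '(' name ')' | '(' expr ')'
#   func    := avg | min | max | ceil | floor        (case-insensitive)
# var(Name) and var("Name") are both accepted.  Decimal literals are allowed
# (targets are real-valued).  An AST is a nested list with an `op` field:
# const, var, avg, min, max, plus, minus, times, divide, ceil, floor, neg.

f_const <- function(value) list(op = "const", value = as.numeric(value))
f_var <- function(name) list(op = "var", name = as.character(name))
f_call <- function(op, ...) list(op = op, args = list(...))

.f_nargs <- list(
  avg = c(1L, Inf), min = c(2L, Inf), max = c(2L, Inf),
  ceil = c(1L, 1L), floor = c(1L, 1L)
)

#' Tokenize a formula string
#'
#' @param text formula text.
#' @return data.frame with columns `type`, `value`, `pos` (1-based character
#'   offset of the token start).
#' @keywords internal
#' @noRd
formula_tokens <- function(text) {
  pats <- c(
    ws = "\\s+",
    number = "[0-9]+\\.?[0-9]*|\\.[0-9]+",
    name = "[A-Za-z_][A-Za-z0-9_]*",
    string = "\"[^\"]*\"",
    sym = "[-+*/(),]"
  )
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    hit <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(paste0("^(", pats[[ty]], ")"), rest))
      if (length(m) == 1L && nzchar(m)) {
        if (ty != "ws") {
          toks[[length(toks) + 1L]] <- list(type = ty, value = m, pos = i)
        }
        i <- i + nchar(m)
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      stop(sprintf("formula syntax error at position %d: unexpected character '%s'",
                   i, substr(text, i, i)), call. = FALSE)
    }
  }
  toks
}

#' Parse a target-function formula
#'
#' Parses BMA-style formula text into an expression tree.  Standard arithmetic
#' precedence applies (unary minus binds tightest, then `*` `/`, then `+` `-`);
#' function names are case-insensitive.
#'
#' @param text formula text, e.g. `"4 - avg(var(A), var(B))"`.
#' @param scope optional character vector of variable names that `var()`
#'   references must belong to; an out-of-scope reference is an error.
#' @return a formula AST (nested list with an `op` field per node).
#' @examples
#' parse_formula("min(2, var(X) * 2)", scope = "X")
#' @export
parse_formula <- function(text, scope = NULL) {
  toks <- formula_tokens(text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$i <- 1L
  state$text <- text

  peek <- function() if (state$i <= length(state$toks)) state$toks[[state$i]] else NULL
  advance <- function() {
    t <- peek()
    state$i <- state$i + 1L
    t
  }
  fail <- function(msg, tok = peek()) {
    pos <- if (is.null(tok)) nchar(state$text) + 1L else tok$pos
    stop(sprintf("formula syntax error at position %d: %s", pos, msg), call. = FALSE)
  }
  expect_sym <- function(s) {
    t <- peek()
    if (is.null(t) || t$type != "sym" || t$value != s) {
      fail(sprintf("expected '%s'", s))
    }
    advance()
  }

  parse_expr <- function() {
    node <- parse_term()
    repeat {
      t <- peek()
      if (!is.null(t) && t$type == "sym" && t$value %in% c("+", "-")) {
        advance()
        rhs <- parse_term()
        node <- f_call(if (t$value == "+") "plus" else "minus", node, rhs)
      } else {
        return(node)
      }
    }
  }
  parse_term <- function() {
    node <- parse_unary()
    repeat {
      t <- peek()
      if (!is.null(t) && t$type == "sym" && t$value %in% c("*", "/")) {
        advance()
        rhs <- parse_unary()
        node <- f_call(if (t$value == "*") "times" else "divide", node, rhs)
      } else {
        return(node)
      }
    }
  }
  parse_unary <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "sym" && t$value == "-") {
      advance()
      return(f_call("neg", parse_unary()))
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (is.null(t)) fail("unexpected end of formula")
    if (t$type == "number") {
      advance()
      return(f_const(as.numeric(t$value)))
    }
    if (t$type == "sym" && t$value == "(") {
      advance()
      node <- parse_expr()
      expect_sym(")")
      return(node)
    }
    if (t$type == "name") {
      fname <- tolower(t$value)
      advance()
      if (fname == "var") {
        expect_sym("(")
        vt <- peek()
        if (is.null(vt) || !(vt$type %in% c("name", "string", "number"))) {
          fail("expected a variable name inside var()")
        }
        advance()
        vname <- if (vt$type == "string") {
          substr(vt$value, 2L, nchar(vt$value) - 1L)
        } else {
          vt$value
        }
        expect_sym(")")
        if (!is.null(scope) && !(vname %in% scope)) {
          stop(sprintf("formula references variable '%s' outside scope at position %d",
                       vname, vt$pos), call. = FALSE)
        }
        return(f_var(vname))
      }
      if (fname %in% names(.f_nargs)) {
        expect_sym("(")
        args <- list(parse_expr())
        while (!is.null(peek()) && peek()$type == "sym" && peek()$value == ",") {
          advance()
          args[[length(args) + 1L]] <- parse_expr()
        }
        expect_sym(")")
        lim <- .f_nargs[[fname]]
        if (length(args) < lim[1] || length(args) > lim[2]) {
          fail(sprintf("%s() takes %s argument(s), got %d", fname,
                       if (is.finite(lim[2])) paste(lim[1], "to", lim[2])
                       else paste0(lim[1], "+"),
                       length(args)), tok = t)
        }
        node <- list(op = fname, args = args)
        return(node)
      }
      fail(sprintf("unknown function '%s'", t$value), tok = t)
    }
    fail(sprintf("unexpected token '%s'", t$value))
  }

  node <- parse_expr()
  if (!is.null(peek())) fail(sprintf("unexpected trailing token '%s'", peek()$value))
  node
}

#' Print a formula AST back to text
#'
#' Inverse of [parse_formula()]: `parse_formula(formula_to_text(f))` is
#' structurally equal to `f`.  Binary operations are fully parenthesized so the
#' printed form is unambiguous.
#'
#' @param f a formula AST.
#' @return a single string.
#' @export
formula_to_text <- function(f) {
  switch(f$op,
    const = {
      # shortest decimal representation that survives as.numeric() exactly;
      # negative constants print parenthesized (they re-parse as unary minus)
      v <- abs(f$value)
      txt <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
      if (as.numeric(txt) != v) {
        txt <- format(v, digits = 17, scientific = FALSE, trim = TRUE)
      }
      if (f$value < 0) paste0("(-", txt, ")") else txt
    },
    var = sprintf("var(%s)", f$name),
    plus = sprintf("(%s + %s)", formula_to_text(f$args[[1]]), formula_to_text(f$args[[2]])),
    minus = sprintf("(%s - %s)", formula_to_text(f$args[[1]]), formula_to_text(f$args[[2]])),
    times = sprintf("(%s * %s)", formula_to_text(f$args[[1]]), formula_to_text(f$args[[2]])),
    divide = sprintf("(%s / %s)", formula_to_text(f$args[[1]]), formula_to_text(f$args[[2]])),
    neg = sprintf("(-%s)", formula_to_text(f$args[[1]])),
    avg = ,
    min = ,
    max = ,
    ceil = ,
    floor = sprintf("%s(%s)", f$op,
                    paste(vapply(f$args, formula_to_text, character(1)), collapse = ", ")),
    stop(sprintf("unknown formula op '%s'", f$op), call. = FALSE)
  )
}

#' Variables referenced by a formula
#'
#' @param f a formula AST.
#' @return character vector of unique variable names, in first-appearance order.
#' @export
formula_vars <- function(f) {
  if (f$op == "var") return(f$name)
  if (f$op == "const") return(character(0))
  unique(unlist(lapply(f$args, formula_vars), use.names = FALSE))
}

#' Evaluate a formula AST
#'
#' @param f a formula AST.
#' @param values named numeric vector of variable levels; every `var()`
#'   reference in `f` must name an element.
#' @param owner variable name the formula belongs to, used in error messages.
#' @return a real number (not clamped).
#' @export
evaluate_formula <- function(f, values, owner = "<formula>") {
  ev <- function(node) {
    switch(node$op,
      const = node$value,
      var = {
        if (!(node$name %in% names(values))) {
          stop(sprintf("formula for '%s' references unknown variable '%s'",
                       owner, node$name), call. = FALSE)
        }
        values[[node$name]]
      },
      plus = ev(node$args[[1]]) + ev(node$args[[2]]),
      minus = ev(node$args[[1]]) - ev(node$args[[2]]),
      times = ev(node$args[[1]]) * ev(node$args[[2]]),
      divide = {
        den <- ev(node$args[[2]])
        if (den == 0) {
          stop(sprintf("division by zero while evaluating the target function of '%s'",
                       owner), call. = FALSE)
        }
        ev(node$args[[1]]) / den
      },
      neg = -ev(node$args[[1]]),
      avg = mean(vapply(node$args, ev, numeric(1))),
      min = min(vapply(node$args, ev, numeric(1))),
      max = max(vapply(node$args, ev, numeric(1))),
      ceil = ceiling(ev(node$args[[1]])),
      floor = floor(ev(node$args[[1]])),
      stop(sprintf("unknown formula op '%s'", node$op), call. = FALSE)
    )
  }
  ev(f)
}

# Conservative interval evaluation of a formula AST: returns c(lo, hi) such
# that for every assignment with each variable inside its interval the exact
# value lies in [lo, hi].  Monotonicity-aware for avg/min/max/plus/minus/neg;
# widening (all endpoint products) for times; divide errors when the divisor
# interval straddles zero.
interval_eval_formula <- function(f, lo, hi, owner = "<formula>") {
  ev <- function(node) {
    switch(node$op,
      const = c(node$value, node$value),
      var = {
        if (is.na(lo[node$name]) || is.null(lo[[node$name]])) {
          stop(sprintf("formula for '%s' references unknown variable '%s'",
                       owner, node$name), call. = FALSE)
        }
        c(lo[[node$name]], hi[[node$name]])
      },
      plus = {
        a <- ev(node$args[[1]]); b <- ev(node$args[[2]])
        a + b
      },
      minus = {
        a <- ev(node$args[[1]]); b <- ev(node$args[[2]])
        c(a[1] - b[2], a[2] - b[1])
      },
      neg = {
        a <- ev(node$args[[1]])
        c(-a[2], -a[1])
      },
      times = {
        a <- ev(node$args[[1]]); b <- ev(node$args[[2]])
        p <- c(a[1] * b[1], a[1] * b[2], a[2] * b[1], a[2] * b[2])
        range(p)
      },
      divide = {
        a <- ev(node$args[[1]]); b <- ev(node$args[[2]])
        if (b[1] <= 0 && b[2] >= 0) {
          stop(sprintf("possible division by zero while bounding the target function of '%s'",
                       owner), call. = FALSE)
        }
        p <- c(a[1] / b[1], a[1] / b[2], a[2] / b[1], a[2] / b[2])
        range(p)
      },
      avg = {
        vals <- vapply(node$args, ev, numeric(2))
        c(mean(vals[1, ]), mean(vals[2, ]))
      },
      min = {
        vals <- vapply(node$args, ev, numeric(2))
        c(min(vals[1, ]), min(vals[2, ]))
      },
      max = {
        vals <- vapply(node$args, ev, numeric(2))
        c(max(vals[1, ]), max(vals[2, ]))
      },
      ceil = ceiling(ev(node$args[[1]])),
      floor = floor(ev(node$args[[1]])),
      stop(sprintf("unknown formula op '%s'", node$op), call. = FALSE)
    )
  }
  ev(f)
}

# Structural equality of two ASTs (numeric constants compared exactly).
formula_equal <- function(a, b) {
  if (a$op != b$op) return(FALSE)
  if (a$op == "const") return(identical(as.numeric(a$value), as.numeric(b$value)))
  if (a$op == "var") return(identical(a$name, b$name))
  if (length(a$args) != length(b$args)) return(FALSE)
  all(mapply(formula_equal, a$args, b$args))
}
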