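# Qualitative-network model representation and validation.
#
# A QN is a signed directed graph over variables with bounded integer activity
# levels.  Each variable carries a target function: either the DEFAULT
# (average of activating inputs minus average of inhibiting inputs, with a
# constitutive constant when there are no activators) or an explicit formula.

#' Define a QN variable
#'
#' @param id unique integer id.
#' @param name unique variable name.
#' @param range_min,range_max integer activity bounds (`range_min < range_max`).
#' @param formula `NULL` for the default target function, or a formula AST /
#'   formula text (parsed with [parse_formula()]).
#' @param constitutive constitutive activity used by the default target
#'   function when the variable has no activating inputs; defaults to
#'   `range_max` (full constitutive activity).
#' @param pathway free-text pathway tag (used for screen annotation/ordering).
#' @param druggable logical; whether at least one drug is known to target the
#'   node (static annotation).
#' @return a `qn_variable` list.
#' @export
qn_variable <- function(id, name, range_min = 0L, range_max = 4L,
                        formula = NULL, constitutive = range_max,
                        pathway = "", druggable = FALSE) {
  if (is.character(formula)) {
    formula <- if (nzchar(trimws(formula))) parse_formula(formula) else NULL
  }
  structure(list(
    id = as.integer(id), name = as.character(name),
    range_min = as.integer(range_min), range_max = as.integer(range_max),
    formula = formula, constitutive = as.numeric(constitutive),
    pathway = as.character(pathway), druggable = isTRUE(druggable)
  ), class = "qn_variable")
}

#' Define a signed relationship
#'
#' @param from,to variable names or ids.
#' @param sign `"activator"` or `"inhibitor"`.
#' @return a `qn_relationship` list.
#' @export
qn_relationship <- function(from, to, sign = c("activator", "inhibitor")) {
  sign <- match.arg(sign)
  structure(list(from = from, to = to, sign = sign), class = "qn_relationship")
}

#' Construct and validate a qualitative network model
#'
#' @param variables list of [qn_variable()] definitions.
#' @param relationships list of [qn_relationship()] definitions; `from`/`to`
#'   may be names or ids and are resolved here.
#' @param name model name.
#' @param extra opaque list preserved on JSON round-trip (e.g. a layout block).
#' @return a validated `qn_model` object.
#' @export
qn_model <- function(variables, relationships = list(), name = "model",
                     extra = NULL) {
  ids <- vapply(variables, function(v) v$id, integer(1))
  nms <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(ids)) stop("variable ids must be unique", call. = FALSE)
  if (anyDuplicated(nms)) stop("variable names must be unique", call. = FALSE)
  for (v in variables) {
    if (v$range_min >= v$range_max) {
      stop(sprintf("variable '%s': range_min must be < range_max", v$name),
           call. = FALSE)
    }
    if (v$constitutive < v$range_min || v$constitutive > v$range_max) {
      stop(sprintf("variable '%s': constitutive constant %s outside range [%d, %d]",
                   v$name, format(v$constitutive), v$range_min, v$range_max),
           call. = FALSE)
    }
  }
  resolve <- function(x, what) {
    if (is.character(x)) {
      k <- match(x, nms)
      if (is.na(k)) stop(sprintf("relationship %s references unknown variable '%s'",
                                 what, x), call. = FALSE)
    } else {
      k <- match(as.integer(x), ids)
      if (is.na(k)) stop(sprintf("relationship %s references unknown variable id %s",
                                 what, x), call. = FALSE)
    }
    k
  }
  if (length(relationships)) {
    rel <- data.frame(
      from = vapply(relationships, function(r) resolve(r$from, "from"), integer(1)),
      to = vapply(relationships, function(r) resolve(r$to, "to"), integer(1)),
      sign = vapply(relationships, function(r) r$sign, character(1)),
      stringsAsFactors = FALSE
    )
    if (anyDuplicated(rel)) stop("duplicate (from, to, sign) relationship", call. = FALSE)
  } else {
    rel <- data.frame(from = integer(0), to = integer(0), sign = character(0),
                      stringsAsFactors = FALSE)
  }
  m <- structure(list(
    name = name, variables = variables, relationships = rel, extra = extra
  ), class = "qn_model")
  # every formula reference must name an existing variable with an edge into
  # the formula's owner
  for (k in seq_along(variables)) {
    v <- variables[[k]]
    if (!is.null(v$formula)) {
      refs <- formula_vars(v$formula)
      bad <- setdiff(refs, nms)
      if (length(bad)) {
        stop(sprintf("formula of '%s' references unknown variable(s): %s",
                     v$name, paste(bad, collapse = ", ")), call. = FALSE)
      }
      inputs <- nms[rel$from[rel$to == k]]
      noedge <- setdiff(refs, inputs)
      if (length(noedge)) {
        stop(sprintf("formula of '%s' uses variable(s) without a relationship into it: %s",
                     v$name, paste(noedge, collapse = ", ")), call. = FALSE)
      }
    }
  }
  m
}

#' @export
print.qn_model <- function(x, ...) {
  cat(sprintf("Qualitative network '%s': %d variables, %d relationships\n",
              x$name, length(x$variables), nrow(x$relationships)))
  nd <- sum(vapply(x$variables, function(v) is.null(v$formula), logical(1)))
  cat(sprintf("  target functions: %d default, %d explicit\n",
              nd, length(x$variables) - nd))
  invisible(x)
}

qn_names <- function(m) vapply(m$variables, function(v) v$name, character(1))
qn_ids <- function(m) vapply(m$variables, function(v) v$id, integer(1))
qn_range_min <- function(m) vapply(m$variables, function(v) v$range_min, integer(1))
qn_range_max <- function(m) vapply(m$variables, function(v) v$range_max, integer(1))

qn_var <- function(m, name) {
  k <- match(name, qn_names(m))
  if (is.na(k)) stop(sprintf("no variable named '%s'", name), call. = FALSE)
  m$variables[[k]]
}

# ---------------------------------------------------------------------------
# Perturbations: named numeric vector of fixed levels, names = variable names.

#' Perturbations: fix variables at constant levels
#'
#' `pert_inhibit()` fixes each named variable at its range minimum (drug
#' inhibition: the node's target function is replaced by zero).  `pert_force()`
#' fixes variables at given levels (e.g. an oncogene held at its maximum).
#' Perturbation sets are named numeric vectors and combine with `c()`; later
#' fixings of the same variable override earlier ones via [pert_merge()].
#'
#' @param m a `qn_model`.
#' @param names character vector of variable names to inhibit.
#' @return named numeric vector of fixed levels.
#' @export
pert_inhibit <- function(m, names) {
  ks <- match(names, qn_names(m))
  if (anyNA(ks)) {
    stop(sprintf("unknown variable(s): %s",
                 paste(names[is.na(ks)], collapse = ", ")), call. = FALSE)
  }
  stats::setNames(as.numeric(qn_range_min(m)[ks]), names)
}

#' @rdname pert_inhibit
#' @param levels named numeric vector (`name = level`) of forced levels.
#' @export
pert_force <- function(m, levels) {
  nms <- names(levels)
  ks <- match(nms, qn_names(m))
  if (anyNA(ks)) {
    stop(sprintf("unknown variable(s): %s",
                 paste(nms[is.na(ks)], collapse = ", ")), call. = FALSE)
  }
  lo <- qn_range_min(m)[ks]; hi <- qn_range_max(m)[ks]
  if (any(levels < lo | levels > hi)) {
    bad <- nms[levels < lo | levels > hi]
    stop(sprintf("forced level out of range for: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  stats::setNames(as.numeric(levels), nms)
}

#' @rdname pert_inhibit
#' @param ... perturbation vectors; later entries override earlier ones.
#' @export
pert_merge <- function(...) {
  out <- numeric(0)
  for (p in list(...)) {
    if (!length(p)) next
    out <- out[!(names(out) %in% names(p))]
    out <- c(out, p)
  }
  out
}

# ---------------------------------------------------------------------------
# Compilation: preprocess a model for fast repeated evaluation.
#
# Default target functions are linear in the (rescaled) input levels, so all
# default targets are computed at once as W %*% s + b.  When an input's range
# differs from the consumer's, its level is linearly rescaled onto the
# consumer's range before averaging (identity for uniform ranges).

compile_model <- function(m) {
  n <- length(m$variables)
  nms <- qn_names(m)
  lo <- qn_range_min(m); hi <- qn_range_max(m)
  W <- matrix(0, n, n, dimnames = list(nms, nms))
  b <- numeric(n)
  custom <- list()
  rel <- m$relationships
  for (k in seq_len(n)) {
    v <- m$variables[[k]]
    if (is.null(v$formula)) {
      acts <- rel$from[rel$to == k & rel$sign == "activator"]
      inhs <- rel$from[rel$to == k & rel$sign == "inhibitor"]
      span_v <- hi[k] - lo[k]
      add <- function(js, coef) {
        for (j in js) {
          scale <- span_v / (hi[j] - lo[j])
          W[k, j] <<- W[k, j] + coef * scale
          b[k] <<- b[k] + coef * (lo[k] - lo[j] * scale)
        }
      }
      if (length(acts)) {
        add(acts, 1 / length(acts))
      } else {
        b[k] <- b[k] + v$constitutive
      }
      if (length(inhs)) add(inhs, -1 / length(inhs))
    } else {
      support <- match(formula_vars(v$formula), nms)
      custom[[length(custom) + 1L]] <- list(k = k, f = v$formula, support = support)
    }
  }
  custom_idx <- vapply(custom, function(x) x$k, integer(1))
  list(model = m, n = n, names = nms, lo = as.numeric(lo), hi = as.numeric(hi),
       W = W, b = b, custom = custom, custom_idx = custom_idx)
}

# Resolve a perturbation vector against a compiled model: list(idx, levels).
compile_perturbations <- function(cm, perturbs) {
  if (is.null(perturbs) || !length(perturbs)) {
    return(list(idx = integer(0), levels = numeric(0)))
  }
  ks <- match(names(perturbs), cm$names)
  if (anyNA(ks)) {
    stop(sprintf("perturbation names unknown in model: %s",
                 paste(names(perturbs)[is.na(ks)], collapse = ", ")), call. = FALSE)
  }
  if (any(perturbs < cm$lo[ks] | perturbs > cm$hi[ks])) {
    stop("perturbation level outside variable range", call. = FALSE)
  }
  list(idx = ks, levels = as.numeric(perturbs))
}
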