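# Interval-narrowing stability analysis and long-run node summaries.
#
# Narrowing iterates per-variable target-range propagation to a fixpoint: each
# unperturbed variable's interval is replaced by the (floored/ceiled, clamped)
# exact range of its target function over the current box, intersected with
# the current interval.  Every recurrent state reachable from within the
# initial box stays inside the final box; when all intervals collapse to
# points the point is a proven fixed point of the synchronous dynamics.

# Run code with the global RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Exact range of variable k's target over the box [lo, hi] (vectors over all
# variables).  Default targets are monotone linear, so the range is attained
# at interval endpoints.  Explicit formulas are bounded by enumerating the
# level combinations of their support variables, falling back to conservative
# interval arithmetic above `max_combos` combinations.
target_range_k <- function(cm, k, lo, hi, max_combos = 1e5) {
  cf <- NULL
  if (length(cm$custom_idx)) {
    j <- match(k, cm$custom_idx)
    if (!is.na(j)) cf <- cm$custom[[j]]
  }
  if (is.null(cf)) {
    w <- cm$W[k, ]
    tmax <- sum(pmax(w, 0) * hi + pmin(w, 0) * lo) + cm$b[k]
    tmin <- sum(pmax(w, 0) * lo + pmin(w, 0) * hi) + cm$b[k]
    return(c(tmin, tmax))
  }
  sup <- cf$support
  combos <- prod(hi[sup] - lo[sup] + 1)
  if (length(sup) == 0L) {
    v <- evaluate_formula(cf$f, stats::setNames(numeric(0), character(0)),
                          owner = cm$names[k])
    return(c(v, v))
  }
  if (combos <= max_combos) {
    grid <- do.call(expand.grid, lapply(sup, function(j) seq(lo[j], hi[j])))
    vals <- apply(as.matrix(grid), 1L, function(r) {
      evaluate_formula(cf$f, stats::setNames(r, cm$names[sup]), owner = cm$names[k])
    })
    return(range(vals))
  }
  interval_eval_formula(cf$f, stats::setNames(lo, cm$names),
                        stats::setNames(hi, cm$names), owner = cm$names[k])
}

#' Narrow per-variable intervals to a sound bound on long-run behavior
#'
#' Iteratively shrinks each variable's `[lo, hi]` interval using the exact
#' range of its target function over the current box, round-robin in variable
#' order, until a full pass changes nothing.  The result soundly contains
#' every attractor state reachable from within the initial box; if all
#' intervals are points, the point is a fixed point of [qn_step()].
#'
#' @param m a `qn_model`.
#' @param perturbs named numeric perturbation vector; perturbed variables
#'   start (and stay) at point intervals.
#' @param box0 optional initial box as a two-row matrix (`lo`, `hi` rows,
#'   columns named by variable); default: the full variable ranges.
#' @param max_combos enumeration budget for bounding explicit formulas before
#'   falling back to conservative interval arithmetic.
#' @return a `qn_box`: data.frame with columns `variable`, `lo`, `hi` and
#'   attribute `"stable"` (`TRUE` when all intervals are points).
#' @export
narrow_intervals <- function(m, perturbs = NULL, box0 = NULL, max_combos = 1e5) {
  cm <- if (inherits(m, "qn_model")) compile_model(m) else m
  cp <- compile_perturbations(cm, perturbs)
  lo <- cm$lo
  hi <- cm$hi
  if (!is.null(box0)) {
    if (is.data.frame(box0)) {
      ks <- match(box0$variable, cm$names)
      lo[ks] <- box0$lo
      hi[ks] <- box0$hi
    } else {
      ks <- match(colnames(box0), cm$names)
      lo[ks] <- box0["lo", ]
      hi[ks] <- box0["hi", ]
    }
    if (any(lo < cm$lo | hi > cm$hi | lo > hi)) {
      stop("box0 must lie within the variable ranges", call. = FALSE)
    }
  }
  if (length(cp$idx)) {
    lo[cp$idx] <- cp$levels
    hi[cp$idx] <- cp$levels
  }
  free <- setdiff(seq_len(cm$n), cp$idx)
  repeat {
    changed <- FALSE
    for (k in free) {
      tr <- target_range_k(cm, k, lo, hi, max_combos)
      nl <- clamp(floor(round(tr[1], 9)), cm$lo[k], cm$hi[k])
      nh <- clamp(ceiling(round(tr[2], 9)), cm$lo[k], cm$hi[k])
      # intersect with the current interval (recurrent states lie inside it)
      il <- max(nl, lo[k])
      ih <- min(nh, hi[k])
      if (il > ih) { il <- nl; ih <- nh }   # disjoint: no recurrent states here
      if (il != lo[k] || ih != hi[k]) {
        lo[k] <- il
        hi[k] <- ih
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- data.frame(variable = cm$names, lo = lo, hi = hi,
                    stringsAsFactors = FALSE)
  attr(out, "stable") <- all(lo == hi)
  class(out) <- c("qn_box", class(out))
  out
}

#' Stabilize a model: narrowed box, attractor sample, per-node summaries
#'
#' Runs [narrow_intervals()] from the full box.  If every interval is a point
#' the unique fixed point is returned directly.  Otherwise long-run behavior
#' is refined by simulating from a deterministic sample of initial states
#' inside the final box — the all-lo corner, the all-hi corner, the (rounded)
#' midpoint, and `n_samples` seeded uniform draws — and summarizing each node
#' over the union of all attractor states found.  A node that oscillates
#' between levels is summarized by the mean of its minimum and maximum
#' (`midpoint`).
#'
#' @param m a `qn_model`.
#' @param perturbs named numeric perturbation vector.
#' @param n_samples number of random initial states (default 32).
#' @param seed seed for the random initial states (recorded in the result).
#' @param max_combos see [narrow_intervals()].
#' @return a `qn_stability` object: list with `summary` (data.frame
#'   `variable`, `lo`, `hi`, `min`, `max`, `midpoint`), `box`, `attractors`
#'   (list of `qn_attractor`), `proved_stable`, `seed`.
#' @export
qn_stabilize <- function(m, perturbs = NULL, n_samples = 32L, seed = 1L,
                         max_combos = 1e5) {
  cm <- if (inherits(m, "qn_model")) compile_model(m) else m
  box <- narrow_intervals(cm, perturbs, max_combos = max_combos)
  lo <- box$lo
  hi <- box$hi
  if (attr(box, "stable")) {
    summ <- data.frame(variable = cm$names, lo = lo, hi = hi,
                       min = lo, max = hi, midpoint = lo,
                       stringsAsFactors = FALSE)
    att <- structure(list(cycle = matrix(lo, nrow = 1,
                                         dimnames = list(NULL, cm$names)),
                          period = 1L,
                          basin_witness = stats::setNames(lo, cm$names)),
                     class = "qn_attractor")
    out <- list(summary = summ, box = box, attractors = list(att),
                proved_stable = TRUE, seed = seed)
    class(out) <- "qn_stability"
    return(out)
  }
  starts <- list(lo, hi, round((lo + hi) / 2))
  if (n_samples > 0) {
    draws <- with_seed(seed, {
      lapply(seq_len(n_samples), function(i) {
        lo + floor(stats::runif(cm$n) * (hi - lo + 1) * (1 - 1e-12))
      })
    })
    starts <- c(starts, draws)
  }
  attractors <- list()
  seen <- character(0)
  for (s0 in starts) {
    att <- qn_simulate(cm, stats::setNames(s0, cm$names), perturbs)$attractor
    key <- cycle_key(att$cycle)
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      attractors[[length(attractors) + 1L]] <- att
    }
  }
  states <- do.call(rbind, lapply(attractors, function(a) a$cycle))
  mn <- apply(states, 2L, min)
  mx <- apply(states, 2L, max)
  summ <- data.frame(variable = cm$names, lo = lo, hi = hi,
                     min = as.numeric(mn), max = as.numeric(mx),
                     midpoint = (as.numeric(mn) + as.numeric(mx)) / 2,
                     stringsAsFactors = FALSE)
  out <- list(summary = summ, box = box, attractors = attractors,
              proved_stable = FALSE, seed = seed)
  class(out) <- "qn_stability"
  out
}

#' @export
print.qn_stability <- function(x, ...) {
  cat(sprintf("QN stability analysis: %s; %d attractor(s) sampled\n",
              if (x$proved_stable) "unique stable state proven"
              else "bounds only (oscillation or multistability)",
              length(x$attractors)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Long-run summary of a single variable
#'
#' Convenience wrapper around [qn_stabilize()]: returns the `min`, `max` and
#' `midpoint` (mean of min and max) of one node's long-run behavior.
#'
#' @inheritParams qn_stabilize
#' @param name variable name.
#' @return list with `min`, `max`, `midpoint`.
#' @export
summarize_variable <- function(m, name, perturbs = NULL, n_samples = 32L,
                               seed = 1L) {
  st <- qn_stabilize(m, perturbs, n_samples = n_samples, seed = seed)
  row <- st$summary[st$summary$variable == name, ]
  if (nrow(row) != 1L) stop(sprintf("no variable named '%s'", name), call. = FALSE)
  list(min = row$min, max = row$max, midpoint = row$midpoint)
}
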