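# Synchronous QN dynamics: target evaluation, stepping, simulation to an
# attractor, and exhaustive attractor enumeration.

.step_eps <- 1e-9

# Clamp x elementwise to [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Targets of every variable in one state (clamped).  cm: compiled model.
targets_one <- function(cm, s) {
  t <- as.numeric(cm$W %*% s) + cm$b
  if (length(cm$custom)) {
    vals <- stats::setNames(as.numeric(s), cm$names)
    for (cf in cm$custom) {
      t[cf$k] <- evaluate_formula(cf$f, vals, owner = cm$names[cf$k])
    }
  }
  clamp(t, cm$lo, cm$hi)
}

#' Target value of one variable in a state
#'
#' Computes the (clamped) target-function value of variable `name` in state
#' `state`.  Default target functions average activating inputs minus
#' inhibiting inputs; a variable with no activators uses its constitutive
#' constant minus the average of its inhibitors (an empty inhibitor set
#' contributes 0).  Inputs whose range differs from the consumer's are first
#' rescaled linearly onto the consumer's range.
#'
#' @param m a `qn_model` (or compiled model).
#' @param name variable name.
#' @param state named numeric vector, a complete assignment of levels.
#' @return the clamped real target value.
#' @export
target_value <- function(m, name, state) {
  cm <- if (inherits(m, "qn_model")) compile_model(m) else m
  k <- match(name, cm$names)
  if (is.na(k)) stop(sprintf("no variable named '%s'", name), call. = FALSE)
  targets_one(cm, as.numeric(state[cm$names]))[k]
}

step_state <- function(cm, s, cp) {
  t <- targets_one(cm, s)
  nxt <- s + as.numeric(t > s + .step_eps) - as.numeric(t < s - .step_eps)
  nxt <- clamp(nxt, cm$lo, cm$hi)
  if (length(cp$idx)) nxt[cp$idx] <- cp$levels
  nxt
}

#' One synchronous update step
#'
#' Every unperturbed variable moves one level toward its target value (up if
#' the target exceeds the current level, down if below, unchanged otherwise);
#' all targets are computed on the input state, so the update is simultaneous.
#' Perturbed variables take their fixed level.
#'
#' @param m a `qn_model`.
#' @param state named numeric vector of current levels.
#' @param perturbs named numeric vector of fixed levels (see [pert_inhibit()]).
#' @return the successor state (named numeric vector).
#' @export
qn_step <- function(m, state, perturbs = NULL) {
  cm <- if (inherits(m, "qn_model")) compile_model(m) else m
  cp <- compile_perturbations(cm, perturbs)
  s <- as.numeric(state[cm$names])
  if (anyNA(s)) stop("state must assign a level to every variable", call. = FALSE)
  if (any(s < cm$lo | s > cm$hi)) stop("state level outside variable range", call. = FALSE)
  stats::setNames(step_state(cm, s, cp), cm$names)
}

default_max_steps <- function(cm) 10L * as.integer(sum(cm$hi - cm$lo + 1))

#' Simulate until the trajectory closes a cycle
#'
#' Iterates [qn_step()] from `state0`; the dynamics are deterministic over a
#' finite state space, so the trajectory must revisit a state, closing a cycle
#' (the attractor).  A fixed point is a period-1 attractor.
#'
#' @param m a `qn_model`.
#' @param state0 initial state (named numeric vector).
#' @param perturbs named numeric perturbation vector.
#' @param max_steps step budget; exceeding it is an error, never a silent
#'   truncation.  Default: 10 times the sum of all range sizes.
#' @return list with `trajectory` (matrix, one row per visited state, from
#'   `state0` up to just before the revisit) and `attractor`, a `qn_attractor`
#'   with fields `cycle` (matrix of states), `period` and `basin_witness`.
#' @export
qn_simulate <- function(m, state0, perturbs = NULL, max_steps = NULL) {
  cm <- if (inherits(m, "qn_model")) compile_model(m) else m
  cp <- compile_perturbations(cm, perturbs)
  s <- as.numeric(state0[cm$names])
  if (anyNA(s)) stop("state0 must assign a level to every variable", call. = FALSE)
  if (is.null(max_steps)) max_steps <- default_max_steps(cm)
  if (max_steps < 1) stop("max_steps must be >= 1", call. = FALSE)
  seen <- new.env(parent = emptyenv(), size = 256L)
  traj <- matrix(NA_real_, nrow = 64L, ncol = cm$n)
  i <- 0L
  repeat {
    key <- paste(s, collapse = ",")
    hit <- seen[[key]]
    if (!is.null(hit)) {
      cyc <- traj[hit:i, , drop = FALSE]
      colnames(cyc) <- cm$names
      traj <- traj[seq_len(i), , drop = FALSE]
      colnames(traj) <- cm$names
      att <- structure(list(cycle = cyc, period = nrow(cyc),
                            basin_witness = stats::setNames(as.numeric(state0[cm$names]),
                                                            cm$names)),
                       class = "qn_attractor")
      return(list(trajectory = traj, attractor = att))
    }
    if (i >= max_steps) {
      stop(sprintf("simulation budget exceeded: no cycle closed within %d steps",
                   max_steps), call. = FALSE)
    }
    i <- i + 1L
    if (i > nrow(traj)) {
      traj <- rbind(traj, matrix(NA_real_, nrow = nrow(traj), ncol = cm$n))
    }
    traj[i, ] <- s
    seen[[key]] <- i
    s <- step_state(cm, s, cp)
  }
}

#' @export
print.qn_attractor <- function(x, ...) {
  cat(sprintf("QN attractor, period %d\n", x$period))
  print(x$cycle)
  invisible(x)
}

# Canonical key of a cycle matrix: rotate so the lexicographically smallest
# state comes first, then flatten.
cycle_key <- function(cyc) {
  keys <- apply(cyc, 1L, function(r) paste(r, collapse = ","))
  k <- order(keys)[1L]
  idx <- c(seq(k, nrow(cyc)), if (k > 1) seq_len(k - 1))
  paste(keys[idx], collapse = ";")
}

#' Enumerate all attractors by exhaustive search
#'
#' Computes the successor of every state of the (finite) state space and
#' extracts all cycles of the resulting functional graph.  The union of the
#' returned cycles is exactly the set of recurrent states.
#'
#' @param m a `qn_model`.
#' @param perturbs named numeric perturbation vector.
#' @param bound refuse to enumerate if the state space exceeds this many
#'   states (default `1e6`).
#' @return list of `qn_attractor` objects (basin witness: first state found
#'   leading to each), ordered by first discovery; attribute
#'   `"recurrent_states"` holds the matrix of all recurrent states.
#' @export
enumerate_attractors <- function(m, perturbs = NULL, bound = 1e6) {
  cm <- if (inherits(m, "qn_model")) compile_model(m) else m
  cp <- compile_perturbations(cm, perturbs)
  sizes <- cm$hi - cm$lo + 1
  S <- prod(sizes)
  if (S > bound) {
    stop(sprintf("state space has %s states, above the enumeration bound of %s",
                 format(S, big.mark = ","), format(bound, big.mark = ",")),
         call. = FALSE)
  }
  S <- as.integer(S)
  n <- cm$n
  # state matrix, variable 1 is the fastest-cycling digit
  Smat <- matrix(0, nrow = S, ncol = n)
  rep_each <- 1
  for (k in seq_len(n)) {
    Smat[, k] <- rep(seq(cm$lo[k], cm$hi[k]), each = rep_each, length.out = S)
    rep_each <- rep_each * sizes[k]
  }
  # successor of every state, vectorized for the linear default targets
  Tm <- Smat %*% t(cm$W)
  Tm <- sweep(Tm, 2L, cm$b, "+")
  if (length(cm$custom)) {
    for (cf in cm$custom) {
      Tm[, cf$k] <- apply(Smat, 1L, function(r) {
        evaluate_formula(cf$f, stats::setNames(r, cm$names), owner = cm$names[cf$k])
      })
    }
  }
  Tm <- clamp(Tm, matrix(cm$lo, S, n, byrow = TRUE), matrix(cm$hi, S, n, byrow = TRUE))
  Nx <- Smat + (Tm > Smat + .step_eps) - (Tm < Smat - .step_eps)
  Nx <- clamp(Nx, matrix(cm$lo, S, n, byrow = TRUE), matrix(cm$hi, S, n, byrow = TRUE))
  if (length(cp$idx)) Nx[, cp$idx] <- matrix(cp$levels, S, length(cp$idx), byrow = TRUE)
  weights <- cumprod(c(1, sizes[-n]))
  succ <- as.integer(sweep(Nx, 2L, cm$lo, "-") %*% weights) + 1L

  attr_of <- integer(S)            # attractor id reachable from each state
  onpath <- integer(S)             # run id marking the current path
  attractors <- list()
  witnesses <- integer(0)
  for (s0 in seq_len(S)) {
    if (attr_of[s0] != 0L) next
    path <- integer(0)
    cur <- s0
    while (attr_of[cur] == 0L && onpath[cur] != s0) {
      onpath[cur] <- s0
      path[length(path) + 1L] <- cur
      cur <- succ[cur]
    }
    if (attr_of[cur] != 0L) {
      aid <- attr_of[cur]
    } else {
      cyc <- cur
      nx <- succ[cur]
      while (nx != cur) {
        cyc[length(cyc) + 1L] <- nx
        nx <- succ[nx]
      }
      aid <- length(attractors) + 1L
      attractors[[aid]] <- cyc
      witnesses[aid] <- s0
    }
    attr_of[path] <- aid
  }
  out <- lapply(seq_along(attractors), function(a) {
    cyc <- Smat[attractors[[a]], , drop = FALSE]
    colnames(cyc) <- cm$names
    structure(list(cycle = cyc, period = nrow(cyc),
                   basin_witness = stats::setNames(Smat[witnesses[a], ], cm$names)),
              class = "qn_attractor")
  })
  rec <- Smat[unlist(attractors), , drop = FALSE]
  colnames(rec) <- cm$names
  attr(out, "recurrent_states") <- rec
  out
}
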