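# Seeded random QN generators and hand-built fixtures with known attractors.

#' Generate a random qualitative network
#'
#' Draws a signed Erdős–Rényi digraph (no self-loops) with DEFAULT target
#' functions on every node.  Reproducible: the same configuration and seed
#' yield an identical model.
#'
#' @param n_variables number of variables (>= 1).
#' @param edge_probability probability of each directed edge, in (0, 1].
#' @param activator_fraction probability that an edge is activating.
#' @param range_max upper activity bound shared by all variables (lower is 0).
#' @param constitutive constitutive constant policy: `"max"` (default, full
#'   constitutive activity) or a numeric value within range.
#' @param seed RNG seed.
#' @return a validated `qn_model`.
#' @export
random_qn <- function(n_variables, edge_probability = 0.5,
                      activator_fraction = 0.5, range_max = 2L,
                      constitutive = "max", seed = 1L) {
  stopifnot(n_variables >= 1, edge_probability > 0, edge_probability <= 1,
            activator_fraction >= 0, activator_fraction <= 1)
  const_val <- if (identical(constitutive, "max")) range_max else as.numeric(constitutive)
  with_seed(seed, {
    variables <- lapply(seq_len(n_variables), function(i) {
      qn_variable(id = i, name = sprintf("V%d", i), range_min = 0L,
                  range_max = range_max, constitutive = const_val)
    })
    relationships <- list()
    for (i in seq_len(n_variables)) {
      for (j in seq_len(n_variables)) {
        if (i == j) next
        if (stats::runif(1) < edge_probability) {
          sign <- if (stats::runif(1) < activator_fraction) "activator" else "inhibitor"
          relationships[[length(relationships) + 1L]] <-
            qn_relationship(i, j, sign)
        }
      }
    }
    qn_model(variables, relationships,
             name = sprintf("random_qn(n=%d, p=%g, a=%g, r=%d, seed=%d)",
                            n_variables, edge_probability, activator_fraction,
                            range_max, seed))
  })
}

#' Hand-built fixture models with known attractors
#'
#' Returns named fixtures, each a list with `model`, `expected_attractors`
#' (list of cycle matrices, each row a state) and `note`.  Shipped fixtures:
#'
#' * `constant_chain` — a constant-target source feeding a two-step cascade;
#'   unique fixed point with every node at 4.
#' * `fractional_oscillator` — a single node with target 2.5; the step rule
#'   forces a period-2 oscillation between levels 2 and 3 (summary midpoint
#'   2.5 under the mean-of-min-and-max convention).
#' * `toggle` — two mutual inhibitors with full constitutive activity; the
#'   five antidiagonal fixed points (0,4) … (4,0) plus, under the synchronous
#'   update, four period-2 checkerboard cycles adjacent to the antidiagonal.
#' * `negfb_ring` — a three-node negative-feedback ring; one fixed point at
#'   (2,2,2) plus two period-6 rotating waves (verified by exhaustive
#'   enumeration).
#'
#' @return named list of fixtures.
#' @export
qn_fixtures <- function() {
  chain <- qn_model(
    list(
      qn_variable(1, "A", 0, 4, formula = f_const(4)),
      qn_variable(2, "B", 0, 4),
      qn_variable(3, "C", 0, 4)
    ),
    list(qn_relationship("A", "B", "activator"),
         qn_relationship("B", "C", "activator")),
    name = "constant_chain"
  )
  osc <- qn_model(
    list(qn_variable(1, "X", 0, 4, formula = f_const(2.5))),
    name = "fractional_oscillator"
  )
  toggle <- qn_model(
    list(
      qn_variable(1, "A", 0, 4, constitutive = 4),
      qn_variable(2, "B", 0, 4, constitutive = 4)
    ),
    list(qn_relationship("A", "B", "inhibitor"),
         qn_relationship("B", "A", "inhibitor")),
    name = "toggle"
  )
  ring <- qn_model(
    list(
      qn_variable(1, "A", 0, 4, constitutive = 4),
      qn_variable(2, "B", 0, 4),
      qn_variable(3, "C", 0, 4)
    ),
    list(qn_relationship("A", "B", "activator"),
         qn_relationship("B", "C", "activator"),
         qn_relationship("C", "A", "inhibitor")),
    name = "negfb_ring"
  )
  st <- function(...) {
    m <- rbind(...)
    m
  }
  list(
    constant_chain = list(
      model = chain,
      expected_attractors = list(st(c(A = 4, B = 4, C = 4))),
      note = "unique fixed point; every state climbs the cascade to 4"
    ),
    fractional_oscillator = list(
      model = osc,
      expected_attractors = list(st(c(X = 2), c(X = 3))),
      note = "real-valued target 2.5 between integer levels forces a 2-cycle"
    ),
    toggle = list(
      model = toggle,
      # frozen from exhaustive enumeration of the 25-state space: the 5
      # antidiagonal fixed points and 4 period-2 checkerboard cycles
      expected_attractors = c(
        lapply(0:4, function(a) st(c(A = a, B = 4 - a))),
        list(st(c(A = 2, B = 1), c(A = 3, B = 2)),
             st(c(A = 3, B = 0), c(A = 4, B = 1)),
             st(c(A = 1, B = 2), c(A = 2, B = 3)),
             st(c(A = 0, B = 3), c(A = 1, B = 4)))
      ),
      note = "mutual inhibition with constitutive 4: antidiagonal fixed points + synchronous 2-cycles"
    ),
    negfb_ring = list(
      model = ring,
      # frozen from exhaustive enumeration of the 125-state space
      expected_attractors = c(
        list(st(c(A = 2, B = 2, C = 2))),
        negfb_ring_cycles()
      ),
      note = "odd negative-feedback loop: central fixed point plus rotating waves"
    )
  )
}

# Periodic attractors of the negfb_ring fixture, frozen from exhaustive
# enumeration (see tests); kept in code so the fixture is self-describing.
negfb_ring_cycles <- function() {
  cyc <- function(m) {
    colnames(m) <- c("A", "B", "C")
    m
  }
  list(
    cyc(matrix(c(
      3, 2, 1,
      3, 3, 2,
      2, 3, 3,
      1, 2, 3,
      1, 1, 2,
      2, 1, 1
    ), ncol = 3, byrow = TRUE)),
    cyc(matrix(c(
      2, 1, 2,
      2, 2, 1,
      3, 2, 2,
      2, 3, 2,
      2, 2, 3,
      1, 2, 2
    ), ncol = 3, byrow = TRUE))
  )
}
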