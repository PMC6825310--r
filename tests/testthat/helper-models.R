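# Shared helpers: tiny models and a random formula-AST generator.

single_node <- function(formula, range_max = 4L) {
  qn_model(list(qn_variable(1, "X", 0, range_max, formula = formula)),
           name = "single")
}

mutual_inhibitors <- function(const = 4, range_max = 4L) {
  qn_model(
    list(qn_variable(1, "A", 0, range_max, constitutive = const),
         qn_variable(2, "B", 0, range_max, constitutive = const)),
    list(qn_relationship("A", "B", "inhibitor"),
         qn_relationship("B", "A", "inhibitor")),
    name = "toggle"
  )
}

state_of <- function(m, ...) {
  s <- c(...)
  stats::setNames(as.numeric(s), names(s))
}

# canonical key set of a list of attractors (order-independent comparison)
attractor_keys <- function(atts) {
  sort(vapply(atts, function(a) qnscreen:::cycle_key(a$cycle), character(1)))
}

expected_keys <- function(mats) {
  sort(vapply(mats, qnscreen:::cycle_key, character(1)))
}

# random formula AST over a variable scope, depth-bounded
random_ast <- function(scope, depth = 5L) {
  ops <- c("const", "var", "avg", "min", "max", "plus", "minus", "times",
           "neg", "ceil", "floor")
  if (depth <= 0L) ops <- c("const", "var")
  op <- sample(ops, 1L)
  sub <- function() random_ast(scope, depth - 1L)
  switch(op,
    # literal constants are non-negative in the grammar; negation is its own op
    const = qnscreen:::f_const(round(stats::runif(1, 0, 5), 2)),
    var = qnscreen:::f_var(sample(scope, 1L)),
    avg = {
      k <- sample(1:3, 1L)
      args <- replicate(k, sub(), simplify = FALSE)
      c(list(op = "avg"), list(args = args))
    },
    min = list(op = "min", args = list(sub(), sub())),
    max = list(op = "max", args = list(sub(), sub())),
    plus = qnscreen:::f_call("plus", sub(), sub()),
    minus = qnscreen:::f_call("minus", sub(), sub()),
    times = qnscreen:::f_call("times", sub(), sub()),
    neg = qnscreen:::f_call("neg", sub()),
    ceil = qnscreen:::f_call("ceil", sub()),
    floor = qnscreen:::f_call("floor", sub())
  )
}
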