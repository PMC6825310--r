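test_that("default target function averages activators minus inhibitors", {
  m <- qn_model(
    list(qn_variable(1, "A", 0, 4), qn_variable(2, "B", 0, 4),
         qn_variable(3, "C", 0, 4), qn_variable(4, "T", 0, 4),
         qn_variable(5, "N", 0, 4, constitutive = 4)),
    list(qn_relationship("A", "T", "activator"),
         qn_relationship("B", "T", "activator"),
         qn_relationship("C", "T", "inhibitor"),
         qn_relationship("C", "N", "inhibitor"))
  )
  s <- c(A = 4, B = 2, C = 2, T = 0, N = 0)
  expect_equal(target_value(m, "T", s), (4 + 2) / 2 - 2)      # avg(pos) - avg(neg)
  expect_equal(target_value(m, "N", s), 4 - 2)                # constitutive - avg(neg)
  s2 <- c(A = 1, B = 0, C = 0, T = 0, N = 0)
  expect_equal(target_value(m, "T", s2), 0.5)                 # empty neg contributes 0
  s3 <- c(A = 4, B = 4, C = 4, T = 0, N = 0)
  expect_equal(target_value(m, "N", s3), 0)                   # 4 - 4
})

test_that("heterogeneous input ranges are rescaled onto the consumer's range", {
  m <- qn_model(
    list(qn_variable(1, "U", 0, 2), qn_variable(2, "V", 0, 4)),
    list(qn_relationship("U", "V", "activator"))
  )
  # U = 1 is half of its 0..2 range, so it reads as 2 on V's 0..4 scale
  expect_equal(target_value(m, "V", c(U = 1, V = 0)), 2)
  expect_equal(target_value(m, "V", c(U = 2, V = 0)), 4)
})

test_that("synchronous step moves one level toward the target, honoring perturbations", {
  m <- single_node(qnscreen:::f_const(4))
  expect_equal(qn_step(m, c(X = 0)), c(X = 1))
  expect_equal(qn_step(m, c(X = 4)), c(X = 4))

  mo <- single_node(qnscreen:::f_const(2.5))
  expect_equal(qn_step(mo, c(X = 2)), c(X = 3))   # fractional target pulls up
  expect_equal(qn_step(mo, c(X = 3)), c(X = 2))   # ... and back down: a 2-cycle

  expect_equal(qn_step(m, c(X = 3), perturbs = pert_inhibit(m, "X")), c(X = 0))
})

test_that("simulation closes a cycle and never silently truncates", {
  m <- single_node(qnscreen:::f_const(4))
  sim <- qn_simulate(m, c(X = 0))
  expect_equal(as.numeric(sim$trajectory), 0:4)
  expect_equal(sim$attractor$period, 1L)
  expect_equal(unname(sim$attractor$cycle[1, ]), 4)
  expect_error(qn_simulate(m, c(X = 0), max_steps = 2), "budget exceeded")

  mo <- single_node(qnscreen:::f_const(2.5))
  sim2 <- qn_simulate(mo, c(X = 0))
  expect_equal(sim2$attractor$period, 2L)
  expect_setequal(as.numeric(sim2$attractor$cycle), c(2, 3))

  # two mutual inhibitors from (0,0) settle on the central fixed point
  tg <- mutual_inhibitors()
  sim3 <- qn_simulate(tg, c(A = 0, B = 0))
  expect_equal(sim3$attractor$period, 1L)
  expect_equal(sim3$attractor$cycle[1, ], c(A = 2, B = 2))
})

test_that("exhaustive enumeration matches the frozen fixture attractors", {
  for (fx in qn_fixtures()) {
    atts <- enumerate_attractors(fx$model)
    expect_equal(attractor_keys(atts), expected_keys(fx$expected_attractors),
                 info = fx$model$name)
  }
})

test_that("enumeration refuses oversized state spaces with a size report", {
  m <- qn_model(list(qn_variable(1, "X", 0, 100), qn_variable(2, "Y", 0, 100)))
  expect_error(enumerate_attractors(m, bound = 1000), "10,201")
})

test_that("dynamics are deterministic with bounded motion and in-range levels", {
  set.seed(11)
  for (s in 1:20) {
    m <- random_qn(4, 0.5, 0.5, range_max = 2, seed = s)
    for (i in 1:10) {
      st <- stats::setNames(sample(0:2, 4, replace = TRUE), qn_names(m))
      n1 <- qn_step(m, st)
      n2 <- qn_step(m, st)
      expect_identical(n1, n2)
      expect_true(all(abs(n1 - st) <= 1))
      expect_true(all(n1 >= 0 & n1 <= 2))
    }
  }
})

test_that("states with zero clamped movement are exactly the fixed points", {
  set.seed(13)
  for (s in 1:20) {
    m <- random_qn(3, 0.6, 0.5, range_max = 2, seed = 100 + s)
    atts <- enumerate_attractors(m)
    fp <- Filter(function(a) a$period == 1L, atts)
    fp_keys <- sort(vapply(fp, function(a) paste(a$cycle[1, ], collapse = ","),
                           character(1)))
    # brute-force: a state is fixed iff stepping leaves it unchanged
    grid <- expand.grid(V1 = 0:2, V2 = 0:2, V3 = 0:2)
    fixed <- apply(grid, 1L, function(r) {
      st <- stats::setNames(as.numeric(r), qn_names(m))
      all(qn_step(m, st) == st)
    })
    brute_keys <- sort(apply(grid[fixed, , drop = FALSE], 1L, paste, collapse = ","))
    expect_equal(fp_keys, unname(brute_keys))
  }
})
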