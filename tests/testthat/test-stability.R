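test_that("narrowing proves points, brackets oscillations, keeps multistability", {
  b1 <- narrow_intervals(single_node(qnscreen:::f_const(4)))
  expect_equal(c(b1$lo, b1$hi), c(4, 4))
  expect_true(attr(b1, "stable"))

  b2 <- narrow_intervals(single_node(qnscreen:::f_const(2.5)))
  expect_equal(c(b2$lo, b2$hi), c(2, 3))
  expect_false(attr(b2, "stable"))

  tg <- mutual_inhibitors()
  b3 <- narrow_intervals(tg)
  expect_equal(b3$lo, c(0, 0))
  expect_equal(b3$hi, c(4, 4))
  atts <- enumerate_attractors(tg)
  for (a in atts) {
    expect_true(all(t(a$cycle) >= b3$lo & t(a$cycle) <= b3$hi))
  }
})

test_that("perturbed variables start and stay at point intervals", {
  m <- single_node(qnscreen:::f_const(4))
  b <- narrow_intervals(m, perturbs = pert_force(m, c(X = 1)))
  expect_equal(c(b$lo, b$hi), c(1, 1))
})

test_that("narrowed boxes contain every attractor state on random models", {
  for (s in 0:59) {
    m <- random_qn(4, 0.5, 0.5, range_max = 2, seed = s)
    box <- narrow_intervals(m)
    atts <- enumerate_attractors(m)
    rec <- attr(atts, "recurrent_states")
    for (k in seq_along(box$lo)) {
      expect_true(all(rec[, k] >= box$lo[k] & rec[, k] <= box$hi[k]),
                  info = sprintf("seed %d, variable %s", s, box$variable[k]))
    }
    if (all(box$lo == box$hi)) {
      expect_length(atts, 1L)
      expect_equal(atts[[1]]$period, 1L)
      expect_equal(unname(atts[[1]]$cycle[1, ]), box$lo)
    }
  }
})

test_that("the narrowing fixpoint does not depend on variable order", {
  for (s in 1:10) {
    m <- random_qn(4, 0.5, 0.5, range_max = 2, seed = 300 + s)
    rev_model <- qn_model(rev(m$variables),
                          lapply(seq_len(nrow(m$relationships)), function(i) {
                            qn_relationship(qn_names(m)[m$relationships$from[i]],
                                            qn_names(m)[m$relationships$to[i]],
                                            m$relationships$sign[i])
                          }),
                          name = m$name)
    b1 <- narrow_intervals(m)
    b2 <- narrow_intervals(rev_model)
    b2 <- b2[match(b1$variable, b2$variable), ]
    expect_equal(b1$lo, b2$lo)
    expect_equal(b1$hi, b2$hi)
  }
})

test_that("summaries use the mean-of-min-and-max convention and respect the box", {
  st <- summarize_variable(single_node(qnscreen:::f_const(2.5)), "X")
  expect_equal(st$min, 2)
  expect_equal(st$max, 3)
  expect_equal(st$midpoint, 2.5)

  st2 <- summarize_variable(single_node(qnscreen:::f_const(4)), "X")
  expect_equal(st2, list(min = 4, max = 4, midpoint = 4))

  m <- single_node(qnscreen:::f_const(4))
  st3 <- summarize_variable(m, "X", perturbs = pert_force(m, c(X = 2)))
  expect_equal(st3, list(min = 2, max = 2, midpoint = 2))

  # sampled min/max never leave the narrowed interval
  for (s in 1:15) {
    mr <- random_qn(4, 0.6, 0.5, range_max = 2, seed = 500 + s)
    res <- qn_stabilize(mr)
    expect_true(all(res$summary$min >= res$summary$lo - 1e-9))
    expect_true(all(res$summary$max <= res$summary$hi + 1e-9))
    expect_equal(res$summary$midpoint,
                 (res$summary$min + res$summary$max) / 2)
  }
})

test_that("stabilization with identical seeds is exactly reproducible", {
  m <- random_qn(5, 0.5, 0.5, range_max = 3, seed = 9)
  a <- qn_stabilize(m, seed = 4L)
  b <- qn_stabilize(m, seed = 4L)
  expect_identical(a$summary, b$summary)
})
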