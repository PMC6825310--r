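# A small target panel keeps these unit tests fast; the full druggable panel
# is exercised by the acceptance suite.
small_screen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- build_breast_model("in_vivo")
      cl <- clone_configs(m)[c("healthy", "myc_high_mixed", "myc_low_mixed")]
      cache <<- list(
        m = m, cl = cl,
        sc = run_screen(m, cl, c("MEK", "COX2", "Mdm2", "PHD2", "VHL"), seed = 1)
      )
    }
    cache
  }
})

test_that("the table has M + M(M-1)/2 treatments per clone and is seeded-deterministic", {
  ss <- small_screen()
  sc <- ss$sc
  M <- 5
  per_clone <- table(sc$clone)
  expect_true(all(per_clone == M + M * (M - 1) / 2))
  expect_equal(nrow(sc), 3 * (M + M * (M - 1) / 2))
  expect_true(all(sc$apoptosis >= 0 & sc$apoptosis <= 4))
  expect_true(all(sc$proliferation >= 0 & sc$proliferation <= 4))

  sc2 <- run_screen(ss$m, ss$cl, c("MEK", "COX2", "Mdm2", "PHD2", "VHL"), seed = 1)
  expect_identical(as.data.frame(sc)[names(sc)], as.data.frame(sc2)[names(sc2)])
  # ... down to the exported CSV bytes
  d1 <- tempfile(); d2 <- tempfile()
  export_screen(sc, d1); export_screen(sc2, d2)
  expect_identical(readLines(file.path(d1, "screen_conditions.csv")),
                   readLines(file.path(d2, "screen_conditions.csv")))
})

test_that("treatments are sets and cannot touch clone-fixed nodes", {
  ss <- small_screen()
  expect_error(evaluate_condition(ss$m, ss$cl$myc_low_mixed, c("MEK", "MEK")),
               "set")
  expect_error(evaluate_condition(ss$m, ss$cl$myc_high_mixed, "Myc"),
               "conflicts")
  # unordered pairs: one canonical row regardless of input order
  a <- evaluate_condition(ss$m, ss$cl$myc_low_mixed, c("MEK", "COX2"))
  b <- evaluate_condition(ss$m, ss$cl$myc_low_mixed, c("COX2", "MEK"))
  expect_identical(a, b)
})

test_that("the toxicity filter masks strictly above threshold and exempts PHD2+VHL", {
  ss <- small_screen()
  tox <- healthy_toxicity_filter(ss$sc)
  expect_true(tox$masked[tox$treatment == "PHD2"])
  expect_true(tox$masked[tox$treatment == "COX2+PHD2"])
  expect_false(tox$masked[tox$treatment == "PHD2+VHL"])   # mutual-pair exemption
  expect_false(tox$masked[tox$treatment == "COX2+MEK"])
  expect_true(all(tox$reason[tox$masked] == "healthy_toxicity"))
  # boundary: a healthy apoptosis midpoint of exactly 3 is retained
  fake <- data.frame(clone = "healthy", treatment = c("A", "B"),
                     apoptosis = c(3, 3.5), stringsAsFactors = FALSE)
  class(fake) <- c("qn_screen", class(fake))
  ft <- healthy_toxicity_filter(fake)
  expect_false(ft$masked[ft$treatment == "A"])
  expect_true(ft$masked[ft$treatment == "B"])
  # missing healthy rows is an error
  nofh <- ss$sc[ss$sc$clone != "healthy", ]
  expect_error(healthy_toxicity_filter(nofh), "healthy")
})

test_that("raising the toxicity threshold never masks more cells", {
  ss <- small_screen()
  masked_at <- function(th) sum(healthy_toxicity_filter(ss$sc, threshold = th)$masked)
  expect_true(masked_at(2) >= masked_at(3))
  expect_true(masked_at(3) >= masked_at(4))
})

test_that("effective monotherapies require strict improvement in a tumor clone", {
  ss <- small_screen()
  eff <- effective_monotherapies(ss$sc, "apoptosis")
  expect_true(all(c("MEK", "COX2") %in% eff))
  # a large eps drops marginal targets without error
  eff_hard <- effective_monotherapies(ss$sc, "apoptosis", eps = 3.9)
  expect_true(length(eff_hard) <= length(eff))
})

test_that("delta cells are pair-minus-mono means with reasoned masks", {
  ss <- small_screen()
  dm <- delta_matrix(ss$sc, "apoptosis")
  # hand-check one cell against the raw table
  val <- function(clone, tr) ss$sc[ss$sc$clone == clone & ss$sc$treatment == tr,
                                   "apoptosis"]
  expected <- mean(c(val("myc_high_mixed", "COX2+MEK") - val("myc_high_mixed", "COX2"),
                     val("myc_low_mixed", "COX2+MEK") - val("myc_low_mixed", "COX2")))
  expect_equal(dm$delta["COX2", "MEK"], expected)
  # diagonal masked as nonsensical; toxic combos carry the filter's reason
  expect_equal(dm$mask["COX2", "COX2"], "same_node")
  expect_true(is.na(dm$delta["COX2", "COX2"]))
  expect_equal(dm$mask["COX2", "PHD2"], "healthy_toxicity")
  # the exempt mutual pair stays visible when PHD2 is an effective row
  if ("PHD2" %in% rownames(dm$delta)) {
    expect_equal(dm$mask["PHD2", "VHL"], "")
    expect_false(is.na(dm$delta["PHD2", "VHL"]))
  }
  # presentation flag removes the PHD2/VHL rows and columns
  dm2 <- delta_matrix(ss$sc, "apoptosis", drop_phd2_vhl = TRUE)
  expect_false(any(c("PHD2", "VHL") %in% rownames(dm2$delta)))
  expect_false(any(c("PHD2", "VHL") %in% colnames(dm2$delta)))
})

test_that("inhibiting a node already at zero in the stable state changes nothing", {
  m <- build_breast_model("in_vivo")
  cl <- clone_configs(m)
  base <- qn_stabilize(m, cl$myc_high_pure$perturbations, seed = 1)
  expect_equal(base$summary[base$summary$variable == "Wnt1", c("min", "max")],
               data.frame(min = 0, max = 0, row.names = "Wnt1"),
               ignore_attr = TRUE)
  treated <- qn_stabilize(
    m, pert_merge(cl$myc_high_pure$perturbations, pert_inhibit(m, "Wnt1")),
    seed = 1
  )
  expect_equal(base$summary$midpoint, treated$summary$midpoint)
})

test_that("exports are tidy, masked cells empty with a reason column", {
  ss <- small_screen()
  dm <- delta_matrix(ss$sc, "apoptosis")
  d <- tempfile()
  paths <- export_delta(dm, d, heatmap = FALSE)
  csv <- utils::read.csv(paths[["csv"]], stringsAsFactors = FALSE)
  expect_equal(nrow(csv), length(dm$delta))
  expect_setequal(names(csv), c("first", "added", "delta", "masked_reason"))
  expect_true(all(is.na(csv$delta[csv$masked_reason != ""])))
  p <- plot_delta_heatmap(dm, node_annotations(ss$m))
  expect_s3_class(p, "ggplot")
})

test_that("mixed tumors resist monotherapy at least as well as pure clones", {
  m <- build_breast_model("in_vivo")
  res <- resilience_report(m, targets = c("MEK", "COX2", "Mdm2", "Frizzled"),
                           seed = 1)
  expect_gte(attr(res, "fraction_ok"), 0.9)
})
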