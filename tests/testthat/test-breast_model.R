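test_that("model variants swap HER2 signaling for angiogenesis", {
  vivo <- build_breast_model("in_vivo")
  vitro <- build_breast_model("in_vitro")
  expect_true(all(c("Angiogenesis", "VEGF") %in% qn_names(vivo)))
  expect_false("HER2" %in% qn_names(vivo))
  expect_true("HER2" %in% qn_names(vitro))
  expect_false(any(c("Angiogenesis", "VEGF") %in% qn_names(vitro)))
  for (m in list(vivo, vitro)) {
    expect_true(all(vapply(m$variables, function(v) v$range_min == 0L &&
                             v$range_max == 4L, logical(1))))
    expect_true(qnscreen:::qn_model_equal(m, parse_model(serialize_model(m))))
  }
})

test_that("every non-phenotype node lies on a path to a phenotype node", {
  for (variant in c("in_vivo", "in_vitro")) {
    m <- build_breast_model(variant)
    rel <- m$relationships
    pheno <- vapply(m$variables, function(v) v$pathway == "phenotype", logical(1))
    reached <- pheno
    repeat {
      new <- reached
      new[rel$from[reached[rel$to]]] <- TRUE
      if (identical(new, reached)) break
      reached <- new
    }
    expect_true(all(reached), info = variant)
  }
})

test_that("clone configurations encode the documented node fixings", {
  m <- build_breast_model("in_vivo")
  cl <- clone_configs(m)
  expect_named(cl, c("healthy", "myc_low", "myc_low_mixed", "myc_high_pure",
                     "myc_high_mixed"))
  expect_length(cl$healthy$perturbations, 0L)           # no oncogenic fixings
  expect_equal(cl$myc_high_pure$perturbations[["Myc"]], 4)
  expect_equal(cl$myc_high_mixed$perturbations[["Myc"]], 4)
  # mixed = pure plus a raised paracrine Wnt1 source; pure lowers it
  expect_equal(cl$myc_high_mixed$perturbations[["Wnt1_env"]], 4)
  expect_lt(cl$myc_high_pure$perturbations[["Wnt1_env"]], 2)
  # Wnt-driven low clones fix the Wnt1 source high
  expect_equal(cl$myc_low$perturbations[["Wnt1_env"]], 4)
  expect_equal(cl$myc_low_mixed$perturbations[["Wnt1_env"]], 4)
})

test_that("the shipped JSON files match the in-code builders", {
  vivo_path <- system.file("extdata", "breast_in_vivo.json", package = "qnscreen")
  vitro_path <- system.file("extdata", "breast_in_vitro.json", package = "qnscreen")
  clones_path <- system.file("extdata", "clones.json", package = "qnscreen")
  expect_true(nzchar(vivo_path) && nzchar(vitro_path) && nzchar(clones_path))
  expect_true(qnscreen:::qn_model_equal(read_qn_model(vivo_path),
                                        build_breast_model("in_vivo")))
  expect_true(qnscreen:::qn_model_equal(read_qn_model(vitro_path),
                                        build_breast_model("in_vitro")))
  m <- build_breast_model("in_vivo")
  cc <- read_clone_configs(clones_path, m)
  ref <- clone_configs(m)
  expect_equal(names(cc), names(ref))
  for (nm in names(ref)) {
    expect_equal(sort(names(cc[[nm]]$perturbations)),
                 sort(names(ref[[nm]]$perturbations)))
    expect_equal(cc[[nm]]$perturbations[names(ref[[nm]]$perturbations)],
                 ref[[nm]]$perturbations)
  }
})

test_that("the full qualitative-expectation suite passes", {
  rep <- validate_expectations()
  expect_true(all(rep$pass),
              info = paste(rep$id[!rep$pass], collapse = ", "))
})

test_that("the clonal-mutualism circuit behaves as curated", {
  m <- build_breast_model("in_vivo")
  cl <- clone_configs(m)
  mids <- function(clone) {
    st <- qn_stabilize(m, cl[[clone]]$perturbations, seed = 1)
    stats::setNames(st$summary$midpoint, st$summary$variable)
  }
  pure <- mids("myc_high_pure")
  mixed <- mids("myc_high_mixed")
  low <- mids("myc_low")
  healthy <- mids("healthy")
  # pure Myc-high: Wnt signaling collapses, ARF/p53 arm engaged
  expect_lt(pure[["bCatenin"]], 1)
  expect_gt(pure[["p19ARF"]], 3)
  expect_gt(pure[["p53"]], 3)
  # paracrine Wnt lowers ARF and apoptosis while proliferation stays maximal
  expect_lt(mixed[["p19ARF"]], pure[["p19ARF"]])
  expect_lt(mixed[["Apoptosis"]], pure[["Apoptosis"]])
  expect_equal(mixed[["Proliferation"]], 4)
  # untreated phenotype table
  expect_gte(pure[["Proliferation"]], low[["Proliferation"]])
  expect_gte(mixed[["Proliferation"]], low[["Proliferation"]])
  expect_lte(healthy[["Apoptosis"]], 3)
})

test_that("node annotations tag phenotypes exactly and carry drug examples", {
  m <- build_breast_model("in_vivo")
  ann <- node_annotations(m)
  expect_setequal(ann$variable[ann$pathway == "phenotype"],
                  c("Proliferation", "Apoptosis", "Angiogenesis"))
  expect_equal(ann$drugs[ann$variable == "COX2"], "celecoxib")
  expect_match(ann$drugs[ann$variable == "MEK"], "PD0325901")
  expect_true(all(nzchar(ann$drugs[ann$druggable])))
  expect_false(any(ann$druggable[ann$pathway == "phenotype"]))
})
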