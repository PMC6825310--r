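minimal_doc <- function() {
  '{
    "Model": {
      "Name": "mini",
      "Variables": [
        {"Id": 1, "Name": "A", "RangeFrom": 0, "RangeTo": 4, "Formula": ""}
      ],
      "Relationships": []
    }
  }'
}

test_that("a minimal document parses to a DEFAULT-target variable", {
  m <- parse_model(minimal_doc())
  expect_s3_class(m, "qn_model")
  expect_length(m$variables, 1L)
  expect_null(m$variables[[1]]$formula)
  expect_equal(m$variables[[1]]$range_max, 4L)
})

test_that("schema violations report a JSON path", {
  bad <- '{
    "Model": {
      "Name": "bad",
      "Variables": [{"Id": 1, "Name": "A", "RangeFrom": 0, "RangeTo": 4, "Formula": ""}],
      "Relationships": [{"Id": 1, "FromVariable": 99, "ToVariable": 1, "Type": "Activator"}]
    }
  }'
  expect_error(parse_model(bad), "\\$\\.Model.*99")
  bad_type <- sub("Activator", "Sideways", bad)
  expect_error(parse_model(bad_type), "Relationships\\[0\\]\\.Type")
  bad_formula <- sub('"Formula": ""', '"Formula": "avg(("', minimal_doc())
  expect_error(parse_model(bad_formula), "Variables\\[0\\]\\.Formula")
  expect_error(parse_model('{"NotAModel": 1}'), "\\$\\.Model")
})

test_that("formula text in a model file parses to the expected tree", {
  doc <- '{
    "Model": {
      "Name": "f",
      "Variables": [
        {"Id": 1, "Name": "Wnt1", "RangeFrom": 0, "RangeTo": 4, "Formula": ""},
        {"Id": 2, "Name": "Myc", "RangeFrom": 0, "RangeTo": 4, "Formula": ""},
        {"Id": 3, "Name": "T", "RangeFrom": 0, "RangeTo": 4,
         "Formula": "avg(var(Wnt1)) - var(Myc)"}
      ],
      "Relationships": [
        {"Id": 1, "FromVariable": 1, "ToVariable": 3, "Type": "Activator"},
        {"Id": 2, "FromVariable": 2, "ToVariable": 3, "Type": "Inhibitor"}
      ]
    }
  }'
  m <- parse_model(doc)
  f <- m$variables[[3]]$formula
  expected <- list(op = "minus", args = list(
    list(op = "avg", args = list(list(op = "var", name = "Wnt1"))),
    list(op = "var", name = "Myc")
  ))
  expect_true(qnscreen:::formula_equal(f, expected))
})

test_that("models round-trip semantically, and files round-trip byte-identically", {
  models <- c(
    lapply(qn_fixtures(), function(fx) fx$model),
    list(build_breast_model("in_vivo"), build_breast_model("in_vitro")),
    lapply(1:5, function(s) random_qn(5, 0.5, 0.5, range_max = 3, seed = s))
  )
  for (m in models) {
    m2 <- parse_model(serialize_model(m))
    expect_true(qnscreen:::qn_model_equal(m, m2), info = m$name)
  }
  # write -> read -> write is byte-stable (deterministic key order)
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  write_qn_model(models[[1]], p1)
  write_qn_model(parse_model(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("unknown top-level blocks (layout) survive a round-trip", {
  doc <- sub('"Model":', '"Layout": {"Variables": [{"Id": 1, "PositionX": 3.5}]}, "Model":',
             minimal_doc())
  m <- parse_model(doc)
  expect_equal(m$extra$Layout$Variables[[1]]$PositionX, 3.5)
  m2 <- parse_model(serialize_model(m))
  expect_identical(m$extra, m2$extra)
})

test_that("a DEFAULT target function serializes as an empty formula string", {
  m <- parse_model(minimal_doc())
  txt <- serialize_model(m)
  expect_match(txt, '"Formula": ""')
})

test_that("extension fields (pathway, druggable, constitutive) round-trip", {
  m <- qn_model(list(
    qn_variable(1, "A", 0, 4, constitutive = 2.5, pathway = "Wnt", druggable = TRUE)
  ))
  m2 <- parse_model(serialize_model(m))
  v <- m2$variables[[1]]
  expect_equal(v$constitutive, 2.5)
  expect_equal(v$pathway, "Wnt")
  expect_true(v$druggable)
})
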