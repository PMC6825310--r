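# Reading and writing QN models in a BMA-compatible JSON dialect.
#
# Schema (deterministic key order on write):
#   {
#     "Model": {
#       "Name": "...",
#       "Variables": [
#         {"Id": 1, "Name": "A", "RangeFrom": 0, "RangeTo": 4, "Formula": ""}
#       ],
#       "Relationships": [
#         {"Id": 1, "FromVariable": 1, "ToVariable": 2, "Type": "Activator"}
#       ]
#     },
#     "Layout": { ... },                     # optional, semantically ignored,
#                                            # preserved on round-trip
#     "QnscreenExtension": {                 # app-specific, namespaced so the
#       "Variables": [                       # file stays loadable as plain BMA
#         {"Id": 1, "Pathway": "Wnt", "Druggable": false,
#          "ConstitutiveConst": 4}
#       ]
#     }
#   }
# An empty Formula string means the DEFAULT target function.

json_fail <- function(path, msg) {
  stop(sprintf("model JSON error at %s: %s", path, msg), call. = FALSE)
}

need_field <- function(rec, field, path) {
  if (is.null(rec[[field]])) json_fail(paste0(path, ".", field), "missing field")
  rec[[field]]
}

#' Parse a QN model from BMA-style JSON
#'
#' @param text a JSON string, or a path to a JSON file.
#' @return a validated `qn_model`.  Unknown top-level blocks (e.g. a layout)
#'   are preserved in `$extra` and written back by [serialize_model()].
#' @export
parse_model <- function(text) {
  if (length(text) == 1L && !grepl("[{[]", substr(trimws(text), 1L, 1L))) {
    if (!file.exists(text)) {
      stop(sprintf("model file not found: %s", text), call. = FALSE)
    }
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  model <- doc[["Model"]]
  if (is.null(model)) json_fail("$.Model", "missing block")
  vars_json <- model[["Variables"]]
  if (is.null(vars_json) || !length(vars_json)) {
    json_fail("$.Model.Variables", "missing or empty")
  }
  rels_json <- model[["Relationships"]]
  if (is.null(rels_json)) rels_json <- list()

  ext <- doc[["QnscreenExtension"]]
  ext_by_id <- list()
  if (!is.null(ext) && !is.null(ext[["Variables"]])) {
    for (e in ext[["Variables"]]) {
      ext_by_id[[as.character(e[["Id"]])]] <- e
    }
  }

  variables <- vector("list", length(vars_json))
  for (i in seq_along(vars_json)) {
    path <- sprintf("$.Model.Variables[%d]", i - 1L)
    rec <- vars_json[[i]]
    id <- need_field(rec, "Id", path)
    nm <- need_field(rec, "Name", path)
    rf <- need_field(rec, "RangeFrom", path)
    rt <- need_field(rec, "RangeTo", path)
    ftext <- rec[["Formula"]]
    if (is.null(ftext)) ftext <- ""
    e <- ext_by_id[[as.character(id)]]
    variables[[i]] <- tryCatch(
      qn_variable(
        id = id, name = nm, range_min = rf, range_max = rt,
        formula = ftext,
        constitutive = if (!is.null(e[["ConstitutiveConst"]]))
          e[["ConstitutiveConst"]] else as.numeric(rt),
        pathway = if (!is.null(e[["Pathway"]])) e[["Pathway"]] else "",
        druggable = isTRUE(e[["Druggable"]])
      ),
      error = function(err) json_fail(paste0(path, ".Formula"), conditionMessage(err))
    )
  }
  relationships <- vector("list", length(rels_json))
  for (i in seq_along(rels_json)) {
    path <- sprintf("$.Model.Relationships[%d]", i - 1L)
    rec <- rels_json[[i]]
    ty <- tolower(need_field(rec, "Type", path))
    if (!(ty %in% c("activator", "inhibitor"))) {
      json_fail(paste0(path, ".Type"), sprintf("must be Activator or Inhibitor, got '%s'",
                                               rec[["Type"]]))
    }
    relationships[[i]] <- qn_relationship(
      from = as.integer(need_field(rec, "FromVariable", path)),
      to = as.integer(need_field(rec, "ToVariable", path)),
      sign = ty
    )
  }
  nm <- model[["Name"]]
  if (is.null(nm)) nm <- "model"
  extra <- doc[setdiff(names(doc), c("Model", "QnscreenExtension"))]
  if (!length(extra)) extra <- NULL
  tryCatch(
    qn_model(variables, relationships, name = nm, extra = extra),
    error = function(err) json_fail("$.Model", conditionMessage(err))
  )
}

#' Serialize a QN model to BMA-style JSON
#'
#' `parse_model(serialize_model(m))` yields a semantically identical model
#' (same variables, ranges, relationships, formula ASTs).  Key order is
#' deterministic; a DEFAULT target function serializes as an empty formula
#' string; preserved unknown blocks from `$extra` are written back.
#'
#' @param m a `qn_model`.
#' @param pretty pretty-print the JSON (default `TRUE`).
#' @return a JSON string.
#' @export
serialize_model <- function(m, pretty = TRUE) {
  vars <- lapply(m$variables, function(v) {
    list(Id = v$id, Name = v$name, RangeFrom = v$range_min, RangeTo = v$range_max,
         Formula = if (is.null(v$formula)) "" else formula_to_text(v$formula))
  })
  ids <- qn_ids(m)
  rels <- if (nrow(m$relationships)) {
    lapply(seq_len(nrow(m$relationships)), function(i) {
      list(Id = i,
           FromVariable = ids[m$relationships$from[i]],
           ToVariable = ids[m$relationships$to[i]],
           Type = if (m$relationships$sign[i] == "activator") "Activator" else "Inhibitor")
    })
  } else {
    list()
  }
  ext <- list(Variables = lapply(m$variables, function(v) {
    list(Id = v$id, Pathway = v$pathway, Druggable = v$druggable,
         ConstitutiveConst = v$constitutive)
  }))
  doc <- c(list(Model = list(Name = m$name, Variables = vars, Relationships = rels)),
           m$extra,
           list(QnscreenExtension = ext))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = pretty, null = "null"))
}

#' @rdname parse_model
#' @param path file path.
#' @export
read_qn_model <- function(path) parse_model(path)

#' @rdname serialize_model
#' @param path file path to write to.
#' @export
write_qn_model <- function(m, path, pretty = TRUE) {
  writeLines(serialize_model(m, pretty = pretty), path)
  invisible(path)
}

# Semantic model equality: same variables (id, name, range, constitutive,
# pathway, druggable, formula AST) and same relationship set.
qn_model_equal <- function(a, b) {
  if (length(a$variables) != length(b$variables)) return(FALSE)
  ka <- order(qn_ids(a)); kb <- order(qn_ids(b))
  for (i in seq_along(ka)) {
    va <- a$variables[[ka[i]]]; vb <- b$variables[[kb[i]]]
    if (va$id != vb$id || va$name != vb$name ||
        va$range_min != vb$range_min || va$range_max != vb$range_max ||
        va$constitutive != vb$constitutive || va$pathway != vb$pathway ||
        va$druggable != vb$druggable) return(FALSE)
    if (is.null(va$formula) != is.null(vb$formula)) return(FALSE)
    if (!is.null(va$formula) && !formula_equal(va$formula, vb$formula)) return(FALSE)
  }
  keyify <- function(m) {
    nms <- qn_names(m)
    sort(paste(nms[m$relationships$from], nms[m$relationships$to],
               m$relationships$sign, sep = "|"))
  }
  identical(keyify(a), keyify(b))
}
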