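# Curated qualitative network of Myc/Ras/p53/Wnt/HIF signaling in Wnt-driven
# breast tumor cells, with clone configurations for healthy cells and for
# Myc-high / Myc-low tumor subclones grown pure or intermixed, plus a
# qualitative-expectation validation harness.
#
# The network is a literature-constrained reconstruction.  Every variable
# shares the activity range 0..4.  Most nodes use the DEFAULT target function
# (average of activators minus average of inhibitors; constitutive constant
# when a node has no activators); each explicit formula carries a comment
# stating the mechanism that demands it.

breast_drug_table <- function() {
  data.frame(
    variable = c("Wnt1", "Frizzled", "GSK3b", "EGFR", "HER2", "Src", "Raf",
                 "MEK", "COX2", "Mdm2", "PHD2", "VHL", "VEGF"),
    drugs = c("LGK-974 (porcupine)", "vantictumab", "CHIR-99021 / lithium",
              "erlotinib", "lapatinib", "dasatinib", "sorafenib",
              "PD0325901 / trametinib", "celecoxib", "nutlin-3", "roxadustat",
              "VH298", "bevacizumab"),
    stringsAsFactors = FALSE
  )
}

#' Build the curated breast-cancer signaling model
#'
#' Constructs the Myc/Ras/p53/Wnt/HIF qualitative network in one of two
#' variants.  `in_vitro` includes HER2 signaling (cell-line context) and no
#' angiogenesis; `in_vivo` removes the HER2 node and adds VEGF-driven
#' angiogenesis as a third phenotype.
#'
#' Core circuitry: a paracrine/autocrine Wnt1 -> Frizzled -> beta-catenin axis
#' feeding survival and proliferation; EGF -> EGFR (-> HER2 in vitro) -> Ras
#' -> Raf -> MEK -> ERK driving proliferation, COX2 and antiapoptotic
#' signaling; Myc fed by ERK and beta-catenin, driving proliferation and
#' p19ARF while repressing Wnt1 (negative feedback) and p21; the
#' p19ARF -| Mdm2 -| p53 -> {PUMA, NOXA, p21} tumor-suppressor spine with
#' beta-catenin quenching p19ARF (the Wnt survival rescue); and hypoxia
#' signaling where PHD2 hydroxylation and VHL ubiquitination act in series to
#' degrade HIF1a, which induces BNIP3 (hypoxic cell death) and VEGF.
#'
#' @param variant `"in_vivo"` (default; the screened model) or `"in_vitro"`.
#' @return a validated `qn_model`.
#' @export
build_breast_model <- function(variant = c("in_vivo", "in_vitro")) {
  variant <- match.arg(variant)
  vivo <- variant == "in_vivo"
  drugs <- breast_drug_table()
  id <- 0L
  vars <- list()
  rels <- list()
  V <- function(name, pathway, formula = NULL, constitutive = 4,
                druggable = name %in% drugs$variable) {
    id <<- id + 1L
    vars[[length(vars) + 1L]] <<- qn_variable(
      id, name, 0L, 4L, formula = formula, constitutive = constitutive,
      pathway = pathway, druggable = druggable
    )
    invisible(name)
  }
  E <- function(from, to, sign) {
    rels[[length(rels) + 1L]] <<- qn_relationship(from, to, sign)
    invisible(NULL)
  }

  ## microenvironment inputs (levels set per clone configuration)
  V("Wnt1_env", "microenvironment", constitutive = 2)   # paracrine Wnt tone
  V("EGF", "microenvironment", constitutive = 2)        # growth-factor tone
  V("Hypoxia", "microenvironment", constitutive = 0)
  V("Inflammation", "microenvironment", constitutive = 2)

  ## Wnt pathway: cell-intrinsic Wnt1 production is repressed by Myc
  # (Myc negative feedback on Wnt1 transcription); reception of own plus
  # paracrine ligand runs through the redundant Frizzled/LRP6 co-receptors
  V("Wnt1", "Wnt", constitutive = 4)                    # MMTV-driven autocrine drive
  V("Frizzled", "Wnt")
  V("LRP6", "Wnt", druggable = FALSE)
  V("Dishevelled", "Wnt")
  V("GSK3b", "Wnt", constitutive = 4)                   # active absent Wnt input
  V("bCatenin", "Wnt", constitutive = 4)                # stabilized when GSK3b is off
  E("Myc", "Wnt1", "inhibitor")
  E("Wnt1", "Frizzled", "activator")
  E("Wnt1_env", "Frizzled", "activator")
  E("Wnt1", "LRP6", "activator")
  E("Wnt1_env", "LRP6", "activator")
  E("Frizzled", "Dishevelled", "activator")
  E("LRP6", "Dishevelled", "activator")
  E("Dishevelled", "GSK3b", "inhibitor")
  E("GSK3b", "bCatenin", "inhibitor")

  ## EGFR / Ras / MAPK cascade; Src-family input keeps a basal MAPK flux that
  ## is independent of the EGF receptor, so only MEK blockade silences ERK
  V("EGFR", "EGFR/HER2")
  if (!vivo) V("HER2", "EGFR/HER2")
  V("Src", "Ras/MAPK", constitutive = 2)
  V("Ras", "Ras/MAPK", druggable = FALSE)               # no direct Ras drug
  V("Raf", "Ras/MAPK")
  V("MEK", "Ras/MAPK")
  V("ERK", "Ras/MAPK", druggable = FALSE)
  V("COX2", "Ras/MAPK")
  V("Myc", "Ras/MAPK", druggable = FALSE)
  E("EGF", "EGFR", "activator")
  if (!vivo) {
    E("EGFR", "HER2", "activator")
    E("HER2", "Ras", "activator")
  }
  E("EGFR", "Ras", "activator")
  E("Ras", "Raf", "activator")
  E("Src", "Raf", "activator")
  E("Raf", "MEK", "activator")
  E("Ras", "MEK", "activator")     # Raf-independent MAP3K input to MEK
  E("MEK", "ERK", "activator")
  E("ERK", "COX2", "activator")
  E("Inflammation", "COX2", "activator")
  E("ERK", "Myc", "activator")
  E("bCatenin", "Myc", "activator")

  ## p53 tumor-suppressor spine; beta-catenin quenches the ARF trigger and
  ## ERK activity promotes Mdm2-mediated p53 turnover
  V("p19ARF", "p53")
  # Basal Mdm2 expression (the p53-driven transcriptional feedback folded into
  # the basal term; keeps the loop from spurious limit cycles at this
  # granularity) enhanced by ERK signaling and opposed by ARF sequestration.
  V("Mdm2", "p53", formula = "1 + var(ERK) / 2 - var(p19ARF) / 2")
  V("p53", "p53", constitutive = 4, druggable = FALSE)  # stabilized when Mdm2 is off
  # Myc priming licenses the apoptotic (rather than arrest) arm of the p53
  # response: BH3 effector output follows the weaker of p53 and (basally
  # offset) Myc drive.
  V("PUMA", "p53", formula = "min(var(p53), var(Myc) + 1)", druggable = FALSE)
  V("NOXA", "p53", formula = "min(var(p53), var(Myc) + 1)", druggable = FALSE)
  V("p21", "p53")
  E("Myc", "p19ARF", "activator")
  E("bCatenin", "p19ARF", "inhibitor")
  E("ERK", "Mdm2", "activator")
  E("p19ARF", "Mdm2", "inhibitor")
  E("Mdm2", "p53", "inhibitor")
  E("p53", "PUMA", "activator")
  E("Myc", "PUMA", "activator")
  E("p53", "NOXA", "activator")
  E("Myc", "NOXA", "activator")
  E("p53", "p21", "activator")
  E("Myc", "p21", "inhibitor")     # Myc/Miz1 repression of CDKN1A: forced-high
                                   # Myc overrides p53-driven cell-cycle arrest

  ## hypoxia / HIF module
  V("PHD2", "HIF/hypoxia", constitutive = 4)            # O2-dependent hydroxylase
  V("VHL", "HIF/hypoxia", constitutive = 4)
  # PHD2 hydroxylation and VHL ubiquitination act in series on HIF1a, so
  # degradation runs at the rate of the weaker step: losing either stabilizes
  # HIF1a regardless of oxygen.
  V("HIF1a", "HIF/hypoxia",
    formula = "4 - min(var(PHD2), var(VHL))", druggable = FALSE)
  V("BNIP3", "HIF/hypoxia")
  if (vivo) V("VEGF", "HIF/hypoxia")
  E("Hypoxia", "PHD2", "inhibitor")
  E("PHD2", "HIF1a", "inhibitor")
  E("VHL", "HIF1a", "inhibitor")
  E("HIF1a", "BNIP3", "activator")
  if (vivo) {
    E("HIF1a", "VEGF", "activator")
    E("Myc", "VEGF", "activator")  # Myc instructs the angiogenic program
  }

  ## phenotypes
  # Proliferation follows the strongest mitogenic driver (deregulated Myc is
  # sufficient on its own), opposed by p21-mediated arrest.
  V("Proliferation", "phenotype",
    formula = "max(var(Myc), avg(var(ERK), var(bCatenin))) - var(p21)",
    druggable = FALSE)
  # Apoptosis balances p53-effector BH3 pressure (PUMA/NOXA) against the two
  # antiapoptotic survival inputs (ERK-stabilized Mcl1-type signaling and
  # COX2/PGE2 survival signaling); Wnt survival acts upstream by quenching
  # the p19ARF trigger; BNIP3-driven hypoxic death bypasses the balance.
  V("Apoptosis", "phenotype",
    formula = "max(avg(var(PUMA), var(NOXA)) - avg(var(ERK), var(COX2)), var(BNIP3))",
    druggable = FALSE)
  E("Myc", "Proliferation", "activator")
  E("ERK", "Proliferation", "activator")
  E("bCatenin", "Proliferation", "activator")
  E("p21", "Proliferation", "inhibitor")
  E("PUMA", "Apoptosis", "activator")
  E("NOXA", "Apoptosis", "activator")
  E("BNIP3", "Apoptosis", "activator")
  E("ERK", "Apoptosis", "inhibitor")
  E("COX2", "Apoptosis", "inhibitor")
  E("bCatenin", "Apoptosis", "inhibitor")
  if (vivo) {
    V("Angiogenesis", "phenotype", druggable = FALSE)
    E("VEGF", "Angiogenesis", "activator")
  }

  qn_model(vars, rels, name = sprintf("breast_%s", variant))
}

#' Clone configurations
#'
#' Named perturbation bundles encoding each cell population as pure node-level
#' settings on the shared model:
#'
#' * `healthy` — no fixings: physiological Wnt tone, normoxia, dynamic Myc.
#' * `myc_low` — Wnt-driven tumor clone grown pure: abundant autocrine/
#'   paracrine Wnt1 (source fixed at 4) but an indolent, poorly vascularized,
#'   hypoxic lesion (Hypoxia 1).
#' * `myc_low_mixed` — the same clone inside a biclonal tumor: Myc-high
#'   neighbors instruct an angiogenic stroma, relieving hypoxia.
#' * `myc_high_pure` — Myc fixed at maximum; the clone's own Wnt1 is repressed
#'   by Myc and there are no Myc-low neighbors, so the paracrine Wnt1 source
#'   is lowered to 0.
#' * `myc_high_mixed` — Myc fixed at maximum plus a raised paracrine Wnt1
#'   source (4) supplied by neighboring Myc-low cells.
#'
#' @param m the breast model the configurations apply to (used to validate
#'   node names and ranges).
#' @return named list of clone configs: `name`, `description`, `perturbations`
#'   (named numeric vector).
#' @export
clone_configs <- function(m = build_breast_model("in_vivo")) {
  cfg <- function(name, description, perturbations) {
    list(name = name, description = description, perturbations = perturbations)
  }
  list(
    healthy = cfg(
      "healthy", "unmutated mammary cell, physiological Wnt and normoxia",
      pert_force(m, c())
    ),
    myc_low = cfg(
      "myc_low", "Wnt-driven Myc-low clone, pure tumor: hypoxic, Wnt-rich",
      pert_force(m, c(Wnt1_env = 4, Hypoxia = 1))
    ),
    myc_low_mixed = cfg(
      "myc_low_mixed", "Myc-low clone in a biclonal tumor: Wnt-rich, normoxic",
      pert_force(m, c(Wnt1_env = 4))
    ),
    myc_high_pure = cfg(
      "myc_high_pure", "Myc forced to maximum, pure tumor: paracrine Wnt source lost",
      pert_force(m, c(Myc = 4, Wnt1_env = 0))
    ),
    myc_high_mixed = cfg(
      "myc_high_mixed", "Myc forced to maximum with paracrine Wnt1 from Myc-low neighbors",
      pert_force(m, c(Myc = 4, Wnt1_env = 4))
    )
  )
}

# Summary midpoint of `node` for clone `clone` under inhibition of `treat`
# (character vector of node names, possibly empty), with memoisation.
condition_midpoint <- function(m, clones, clone, treat, node, cache, seed = 1L) {
  key <- paste(clone, paste(sort(treat), collapse = "+"), sep = "|")
  st <- cache[[key]]
  if (is.null(st)) {
    pert <- pert_merge(clones[[clone]]$perturbations, pert_inhibit(m, treat))
    st <- qn_stabilize(m, pert, seed = seed)
    cache[[key]] <- st
  }
  st$summary$midpoint[st$summary$variable == node]
}

#' The shipped qualitative-expectation table
#'
#' Each claim compares long-run summary midpoints between clone/treatment
#' conditions (or against a threshold), restating the qualitative behavior the
#' model was curated to reproduce: Myc-high apoptosis sensitivity and its
#' paracrine-Wnt rescue, loss of Wnt signaling and of hypoxic HIF1a signal in
#' Myc-high tumors, arrest resistance of Myc-forced clones, and the clone
#' selectivity of MEK and COX2 inhibition.
#'
#' @return data.frame of claims, consumed by [validate_expectations()].
#' @export
breast_expectations <- function() {
  claim <- function(id, description, node,
                    clone1, treat1, op, clone2 = NA, treat2 = NA,
                    value = NA_real_) {
    data.frame(id = id, description = description, node = node,
               clone1 = clone1, treat1 = treat1, op = op,
               clone2 = clone2, treat2 = treat2, value = value,
               stringsAsFactors = FALSE)
  }
  rbind(
    claim("apoptosis_high_vs_low", "Myc at maximum drives apoptosis above the Myc-low clone",
          "Apoptosis", "myc_high_pure", "", ">", "myc_low", ""),
    claim("apoptosis_rescued_in_mixed", "paracrine Wnt1 suppresses Myc-high apoptosis",
          "Apoptosis", "myc_high_mixed", "", "<", "myc_high_pure", ""),
    claim("hif_low_vs_high", "hypoxic Myc-low lesions carry more active HIF1a than angiogenic Myc-high tumors",
          "HIF1a", "myc_low", "", ">", "myc_high_pure", ""),
    claim("proliferation_high_vs_low", "Myc-high proliferation at least matches Myc-low",
          "Proliferation", "myc_high_pure", "", ">=", "myc_low", ""),
    claim("arrest_resistance", "Myc-forced clones resist p21 arrest even when p53 is restored by Mdm2 inhibition",
          "p21", "myc_high_pure", "Mdm2", "<", "myc_low", "Mdm2"),
    claim("healthy_baseline_viable", "untreated healthy cells stay below the apoptosis toxicity bound",
          "Apoptosis", "healthy", "", "<=", value = 3),
    claim("wnt1_feedback", "Myc feedback shuts down the clone's own Wnt1 expression",
          "Wnt1", "myc_high_pure", "", "<", "myc_low", ""),
    claim("bcatenin_lost_pure", "pure Myc-high tumors lose nuclear beta-catenin signaling",
          "bCatenin", "myc_high_pure", "", "<", "myc_low", ""),
    claim("bcatenin_restored_mixed", "Myc-low neighbors restore Wnt/beta-catenin signaling in Myc-high cells",
          "bCatenin", "myc_high_mixed", "", ">", "myc_high_pure", ""),
    claim("arf_induced", "forced Myc engages the p19ARF trigger",
          "p19ARF", "myc_high_pure", "", ">", "myc_low", ""),
    claim("arf_quenched_mixed", "paracrine Wnt quenches p19ARF in Myc-high cells",
          "p19ARF", "myc_high_mixed", "", "<", "myc_high_pure", ""),
    claim("mek_selectivity", "MEK inhibition adds more apoptosis in Myc-high than Myc-low cells",
          "Apoptosis", "myc_high_mixed", "MEK", "gain>", "myc_low_mixed", "MEK"),
    claim("combo_beats_mek_mono", "MEK+COX2 exceeds MEK monotherapy apoptosis in Myc-low cells",
          "Apoptosis", "myc_low_mixed", "MEK+COX2", ">", "myc_low_mixed", "MEK"),
    claim("combo_beats_cox2_mono", "MEK+COX2 exceeds COX2 monotherapy apoptosis in Myc-low cells",
          "Apoptosis", "myc_low_mixed", "MEK+COX2", ">", "myc_low_mixed", "COX2"),
    claim("mek_halts_low_proliferation", "MEK inhibition drops Myc-low proliferation",
          "Proliferation", "myc_low_mixed", "MEK", "<", "myc_low_mixed", "")
  )
}

split_treat <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "+", fixed = TRUE)[[1]]
}

#' Validate the model against the qualitative-expectation table
#'
#' Evaluates each claim of [breast_expectations()] (or a user table with the
#' same columns) on the given model and clone configurations and reports
#' pass/fail per claim; failures are report content, not errors.
#'
#' The `gain>` operator compares treatment-minus-baseline changes between two
#' clones instead of raw midpoints.
#'
#' @param m a breast `qn_model` (default: the in-vivo variant).
#' @param clones clone configurations from [clone_configs()].
#' @param expectations claim table.
#' @param seed seed passed to [qn_stabilize()].
#' @return data.frame with per-claim `lhs`, `rhs` and `pass`; attribute
#'   `"all_pass"`.
#' @export
validate_expectations <- function(m = build_breast_model("in_vivo"),
                                  clones = clone_configs(m),
                                  expectations = breast_expectations(),
                                  seed = 1L) {
  cache <- new.env(parent = emptyenv())
  mid <- function(clone, treat, node) {
    condition_midpoint(m, clones, clone, split_treat(treat), node, cache, seed)
  }
  out <- expectations
  out$lhs <- NA_real_
  out$rhs <- NA_real_
  out$pass <- NA
  for (i in seq_len(nrow(out))) {
    e <- out[i, ]
    if (e$op == "gain>") {
      lhs <- mid(e$clone1, e$treat1, e$node) - mid(e$clone1, "", e$node)
      rhs <- mid(e$clone2, e$treat2, e$node) - mid(e$clone2, "", e$node)
      pass <- lhs > rhs
    } else {
      lhs <- mid(e$clone1, e$treat1, e$node)
      rhs <- if (!is.na(e$clone2)) mid(e$clone2, e$treat2, e$node) else e$value
      pass <- switch(e$op,
        ">" = lhs > rhs, "<" = lhs < rhs,
        ">=" = lhs >= rhs, "<=" = lhs <= rhs,
        stop(sprintf("unknown claim operator '%s'", e$op), call. = FALSE)
      )
    }
    out$lhs[i] <- lhs
    out$rhs[i] <- rhs
    out$pass[i] <- pass
  }
  attr(out, "all_pass") <- all(out$pass)
  out
}

#' Node annotation table
#'
#' Static pathway and druggability annotation for a breast-model variant,
#' including example interacting drugs (a fixed drug–gene interaction
#' snapshot; never a live database query).
#'
#' @param m a breast `qn_model`.
#' @return data.frame with `variable`, `pathway`, `druggable`, `drugs`.
#' @export
node_annotations <- function(m = build_breast_model("in_vivo")) {
  drugs <- breast_drug_table()
  out <- data.frame(
    variable = qn_names(m),
    pathway = vapply(m$variables, function(v) v$pathway, character(1)),
    druggable = vapply(m$variables, function(v) v$druggable, logical(1)),
    stringsAsFactors = FALSE
  )
  out$drugs <- drugs$drugs[match(out$variable, drugs$variable)]
  out$drugs[is.na(out$drugs)] <- ""
  out
}

#' Write the shipped model and clone files
#'
#' Serializes both model variants (BMA-dialect JSON) and the clone
#' configuration file into a directory.
#'
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_breast_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    in_vivo = file.path(dir, "breast_in_vivo.json"),
    in_vitro = file.path(dir, "breast_in_vitro.json"),
    clones = file.path(dir, "clones.json")
  )
  write_qn_model(build_breast_model("in_vivo"), paths[["in_vivo"]])
  write_qn_model(build_breast_model("in_vitro"), paths[["in_vitro"]])
  m <- build_breast_model("in_vivo")
  cl <- clone_configs(m)
  doc <- lapply(cl, function(x) {
    list(Name = x$name, Description = x$description,
         Perturbations = as.list(x$perturbations))
  })
  writeLines(as.character(jsonlite::toJSON(unname(doc), auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             paths[["clones"]])
  invisible(paths)
}

#' Read a clone configuration file
#'
#' @param path JSON file as written by [write_breast_files()].
#' @param m model to validate node names/ranges against.
#' @return named list of clone configs.
#' @export
read_clone_configs <- function(path, m = build_breast_model("in_vivo")) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(doc, function(x) {
    p <- unlist(x$Perturbations)
    list(name = x$Name, description = x$Description,
         perturbations = if (length(p)) pert_force(m, p) else pert_force(m, c()))
  })
  names(out) <- vapply(out, function(x) x$name, character(1))
  out
}
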