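# Exhaustive single and pairwise in-silico inhibition screening across
# clones, healthy-cell toxicity filtering, and add-a-second-inhibitor delta
# matrices.

utils::globalVariables(c("added", "first", "delta"))

canonical_treatment <- function(treat) paste(sort(treat), collapse = "+")

outcome_label <- function(prolif_mid, apop_mid, margin = 0.5) {
  d <- apop_mid - prolif_mid
  if (d > margin) "net_apoptosis" else if (d < -margin) "net_proliferation" else "balanced"
}

#' Evaluate one clone/treatment condition
#'
#' Applies the clone's perturbations plus inhibit-at-zero perturbations for
#' each treated node, stabilizes the network, and reads the phenotype nodes.
#'
#' @param m a `qn_model` with `Proliferation` and `Apoptosis` phenotype nodes.
#' @param clone a clone config (list with `name` and `perturbations`).
#' @param treatment character vector of 0, 1 or 2 node names to inhibit;
#'   duplicated names are rejected (treatments are sets) and treating a node
#'   already fixed by the clone is a conflict error.
#' @param seed seed for [qn_stabilize()].
#' @return one-row data.frame: clone, treatment, phenotype summaries, outcome.
#' @export
evaluate_condition <- function(m, clone, treatment = character(0), seed = 1L) {
  treatment <- as.character(treatment)
  if (anyDuplicated(treatment)) {
    stop("treatment is a set: the same node cannot be inhibited twice",
         call. = FALSE)
  }
  fixed <- intersect(treatment, names(clone$perturbations))
  if (length(fixed)) {
    stop(sprintf("treatment conflicts with clone '%s' fixings: %s",
                 clone$name, paste(fixed, collapse = ", ")), call. = FALSE)
  }
  pert <- pert_merge(clone$perturbations, pert_inhibit(m, treatment))
  st <- qn_stabilize(m, pert, seed = seed)
  s <- st$summary
  pr <- s[s$variable == "Proliferation", ]
  ap <- s[s$variable == "Apoptosis", ]
  if (nrow(pr) != 1L || nrow(ap) != 1L) {
    stop("model must contain Proliferation and Apoptosis phenotype nodes",
         call. = FALSE)
  }
  data.frame(
    clone = clone$name, treatment = canonical_treatment(treatment),
    n_targets = length(treatment),
    proliferation_min = pr$min, proliferation_max = pr$max,
    proliferation = pr$midpoint,
    apoptosis_min = ap$min, apoptosis_max = ap$max, apoptosis = ap$midpoint,
    outcome = outcome_label(pr$midpoint, ap$midpoint),
    stringsAsFactors = FALSE
  )
}

#' Candidate screen targets
#'
#' @param m a `qn_model`.
#' @param targets `"druggable"` (nodes with a known interacting drug),
#'   `"all"` (every non-phenotype node not fixed by any clone), or an explicit
#'   character vector of node names.
#' @param clones clone configs; clone-fixed nodes are excluded.
#' @return character vector of target names, in model order.
#' @export
screen_targets <- function(m, targets = "druggable", clones = NULL) {
  nms <- qn_names(m)
  sel <- if (identical(targets, "druggable")) {
    nms[vapply(m$variables, function(v) v$druggable, logical(1))]
  } else if (identical(targets, "all")) {
    nms[!vapply(m$variables, function(v) v$pathway == "phenotype", logical(1))]
  } else {
    bad <- setdiff(targets, nms)
    if (length(bad)) {
      stop(sprintf("unknown target(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    nms[nms %in% targets]
  }
  if (!is.null(clones)) {
    fixed <- unique(unlist(lapply(clones, function(cl) names(cl$perturbations))))
    sel <- setdiff(sel, fixed)
  }
  sel
}

#' Run the exhaustive mono + pairwise inhibition screen
#'
#' For M candidate targets, evaluates every monotherapy and every unordered
#' pair (M + M(M-1)/2 treatments) in every clone, plus the untreated baseline
#' per clone (kept separately).  Deterministic for a fixed seed.
#'
#' @param m a `qn_model`.
#' @param clones named list of clone configs (see [clone_configs()]).
#' @param targets see [screen_targets()].
#' @param seed seed for the attractor-sampling stage of stabilization.
#' @return a `qn_screen` data.frame of condition rows with attributes
#'   `"baseline"` (untreated rows), `"targets"` and `"provenance"`.
#' @export
run_screen <- function(m, clones = clone_configs(m), targets = "druggable",
                       seed = 1L) {
  tg <- screen_targets(m, targets, clones)
  if (length(tg) < 1L) stop("no screen targets", call. = FALSE)
  treatments <- c(
    lapply(tg, identity),
    if (length(tg) > 1L) {
      combn(tg, 2L, simplify = FALSE)
    }
  )
  rows <- list()
  base <- list()
  for (cl in clones) {
    base[[length(base) + 1L]] <- evaluate_condition(m, cl, character(0), seed)
    for (tr in treatments) {
      rows[[length(rows) + 1L]] <- evaluate_condition(m, cl, tr, seed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- do.call(rbind, base)
  attr(out, "targets") <- tg
  attr(out, "provenance") <- screen_provenance(m, clones, tg, seed)
  class(out) <- c("qn_screen", class(out))
  out
}

screen_provenance <- function(m, clones, targets, seed) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(serialize_model(m, pretty = FALSE), tmp)
  list(
    model = m$name,
    model_md5 = unname(tools::md5sum(tmp)),
    clones = vapply(clones, function(cl) cl$name, character(1)),
    targets = targets,
    seed = seed,
    package_version = tryCatch(as.character(utils::packageVersion("qnscreen")),
                               error = function(e) "dev")
  )
}

#' Healthy-cell toxicity filter
#'
#' Marks every treatment whose apoptosis midpoint in the healthy clone
#' strictly exceeds `threshold` (a treatment predicted to kill unmutated
#' cells).  The mutual pair of the two HIF-degradation nodes (`PHD2`, `VHL`)
#' is exempt: each is lethal with any other partner but the pair itself is
#' retained.
#'
#' @param screen a `qn_screen` table including healthy-clone rows.
#' @param threshold toxicity bound on the healthy apoptosis midpoint
#'   (default 3; strict inequality, so exactly 3 is retained).
#' @param exempt_pair treatment exempt from masking (default `"PHD2+VHL"`).
#' @return data.frame `treatment`, `healthy_apoptosis`, `masked`, `reason`.
#' @export
healthy_toxicity_filter <- function(screen, threshold = 3,
                                    exempt_pair = c("PHD2", "VHL")) {
  h <- screen[screen$clone == "healthy", c("treatment", "apoptosis")]
  if (!nrow(h)) stop("screen table has no healthy-clone rows", call. = FALSE)
  masked <- h$apoptosis > threshold
  reason <- ifelse(masked, "healthy_toxicity", "")
  ex <- canonical_treatment(exempt_pair)
  keep <- h$treatment == ex
  masked[keep] <- FALSE
  reason[keep] <- ""
  data.frame(treatment = h$treatment, healthy_apoptosis = h$apoptosis,
             masked = masked, reason = reason, stringsAsFactors = FALSE)
}

#' Monotherapies effective against at least one tumor clone
#'
#' A target is effective when its monotherapy moves the metric in the
#' beneficial direction (apoptosis up, proliferation down) versus the
#' untreated baseline by more than `eps`, in at least one tumor (non-healthy)
#' clone.
#'
#' @param screen a `qn_screen` table.
#' @param metric `"apoptosis"` or `"proliferation"`.
#' @param eps strictly-required improvement (default 0).
#' @param tumor_clones clone names to consider (default: all except healthy).
#' @return character vector of effective targets.
#' @export
effective_monotherapies <- function(screen, metric = c("apoptosis", "proliferation"),
                                    eps = 0, tumor_clones = NULL) {
  metric <- match.arg(metric)
  base <- attr(screen, "baseline")
  if (is.null(tumor_clones)) tumor_clones <- setdiff(unique(screen$clone), "healthy")
  mono <- screen[screen$n_targets == 1L & screen$clone %in% tumor_clones, ]
  eff <- character(0)
  for (tg in unique(mono$treatment)) {
    rows <- mono[mono$treatment == tg, ]
    b <- base[match(rows$clone, base$clone), metric]
    gain <- if (metric == "apoptosis") rows[[metric]] - b else b - rows[[metric]]
    if (any(gain > eps)) eff <- c(eff, tg)
  }
  tgt <- attr(screen, "targets")
  tgt[tgt %in% eff]
}

#' Change-on-adding-a-second-inhibitor matrix
#'
#' `delta[a, b]` is the change in the metric when inhibitor `b` is added to
#' monotherapy `a`, averaged over the tumor clones in `clones_mean` (default:
#' the two mixed-tumor clones).  Rows are restricted to monotherapies
#' effective against at least one tumor clone; cells are masked on the
#' diagonal (same node twice is nonsensical) and where the combined treatment
#' fails the healthy-toxicity filter; rows/columns of the HIF-degradation
#' nodes can be dropped for presentation via `drop_phd2_vhl`.
#'
#' @param screen a `qn_screen` table containing healthy and mixed-clone rows.
#' @param metric `"apoptosis"` or `"proliferation"`.
#' @param clones_mean clones averaged over (default both mixed clones).
#' @param first row targets; default [effective_monotherapies()].
#' @param eps effectiveness threshold passed through.
#' @param toxicity_threshold healthy-apoptosis bound (default 3).
#' @param drop_phd2_vhl drop PHD2/VHL rows and columns (presentation flag;
#'   the data are masked, never deleted).
#' @return a `qn_delta` list: `metric`, `delta` (first x added matrix),
#'   `mask` (reason-code character matrix, `""` = unmasked), `clones`.
#' @export
delta_matrix <- function(screen, metric = c("apoptosis", "proliferation"),
                         clones_mean = c("myc_high_mixed", "myc_low_mixed"),
                         first = NULL, eps = 0, toxicity_threshold = 3,
                         drop_phd2_vhl = FALSE) {
  metric <- match.arg(metric)
  targets <- attr(screen, "targets")
  if (is.null(first)) {
    first <- effective_monotherapies(screen, metric, eps = eps,
                                     tumor_clones = clones_mean)
  }
  tox <- healthy_toxicity_filter(screen, threshold = toxicity_threshold)
  missing_cl <- setdiff(clones_mean, unique(screen$clone))
  if (length(missing_cl)) {
    stop(sprintf("screen table lacks clone(s): %s",
                 paste(missing_cl, collapse = ", ")), call. = FALSE)
  }
  val <- function(clone, treat) {
    v <- screen[screen$clone == clone & screen$treatment == treat, metric]
    if (!length(v)) NA_real_ else v
  }
  delta <- matrix(NA_real_, length(first), length(targets),
                  dimnames = list(first = first, added = targets))
  mask <- matrix("", length(first), length(targets),
                 dimnames = dimnames(delta))
  for (a in first) {
    for (b in targets) {
      if (a == b) {
        mask[a, b] <- "same_node"
        next
      }
      pair <- canonical_treatment(c(a, b))
      r <- tox[tox$treatment == pair, ]
      if (nrow(r) == 1L && r$masked) {
        mask[a, b] <- r$reason
        next
      }
      dd <- vapply(clones_mean, function(cl) val(cl, pair) - val(cl, a),
                   numeric(1))
      delta[a, b] <- mean(dd)
    }
  }
  if (drop_phd2_vhl) {
    keep_r <- !(rownames(delta) %in% c("PHD2", "VHL"))
    keep_c <- !(colnames(delta) %in% c("PHD2", "VHL"))
    delta <- delta[keep_r, keep_c, drop = FALSE]
    mask <- mask[keep_r, keep_c, drop = FALSE]
  }
  structure(list(metric = metric, delta = delta, mask = mask,
                 clones = clones_mean),
            class = "qn_delta")
}

#' @export
print.qn_delta <- function(x, ...) {
  cat(sprintf("Delta matrix (%s), mean over: %s\n", x$metric,
              paste(x$clones, collapse = ", ")))
  print(round(x$delta, 3))
  invisible(x)
}

#' Best cell of a delta matrix
#'
#' @param dm a `qn_delta`.
#' @return list `first`, `added`, `delta` for the unmasked cell with the
#'   largest delta (apoptosis) or the most negative (proliferation).
#' @export
top_delta_cell <- function(dm) {
  d <- dm$delta
  if (dm$metric == "proliferation") d <- -d
  k <- which(d == max(d, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(first = rownames(dm$delta)[k[1]], added = colnames(dm$delta)[k[2]],
       delta = dm$delta[k[1], k[2]])
}

#' Clonal-resilience report
#'
#' For every single-inhibitor treatment, compares each mixed clone against
#' the corresponding pure clone: a treatment satisfies the resilience
#' prediction when the mixed clone's proliferation is at least the pure
#' clone's and its apoptosis at most the pure clone's, for both clone pairs.
#'
#' @param m a breast `qn_model`.
#' @param clones clone configs (needs both pure and mixed tumor clones).
#' @param targets see [screen_targets()].
#' @param seed stabilization seed.
#' @return data.frame per treatment with `ok` flag; attribute
#'   `"fraction_ok"`.
#' @export
resilience_report <- function(m, clones = clone_configs(m),
                              targets = "druggable", seed = 1L) {
  tg <- screen_targets(m, targets, clones)
  pairs <- list(c(mixed = "myc_low_mixed", pure = "myc_low"),
                c(mixed = "myc_high_mixed", pure = "myc_high_pure"))
  rows <- list()
  for (tr in tg) {
    ok_p <- ok_a <- TRUE
    for (p in pairs) {
      mx <- evaluate_condition(m, clones[[p[["mixed"]]]], tr, seed)
      pu <- evaluate_condition(m, clones[[p[["pure"]]]], tr, seed)
      ok_p <- ok_p && (mx$proliferation >= pu$proliferation)
      ok_a <- ok_a && (mx$apoptosis <= pu$apoptosis)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      treatment = tr, proliferation_ok = ok_p, apoptosis_ok = ok_a,
      ok = ok_p && ok_a, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "fraction_ok") <- mean(out$ok)
  out
}

# ---------------------------------------------------------------------------
# Export

#' Export screen artifacts
#'
#' Writes the condition table and baselines as CSV, the provenance record as
#' JSON, and (for [export_delta()]) the delta matrix as a tidy CSV — masked
#' cells have an empty delta and a reason code — plus a pathway-ordered
#' heatmap.
#'
#' @param screen a `qn_screen` table.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
export_screen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    conditions = file.path(dir, "screen_conditions.csv"),
    baseline = file.path(dir, "screen_baseline.csv"),
    provenance = file.path(dir, "screen_provenance.json")
  )
  utils::write.csv(as.data.frame(screen), paths[["conditions"]], row.names = FALSE)
  utils::write.csv(attr(screen, "baseline"), paths[["baseline"]], row.names = FALSE)
  writeLines(as.character(jsonlite::toJSON(attr(screen, "provenance"),
                                           auto_unbox = TRUE, digits = NA,
                                           pretty = TRUE)),
             paths[["provenance"]])
  invisible(paths)
}

#' @rdname export_screen
#' @param dm a `qn_delta`.
#' @param annotations node annotation table for pathway-ordered axes
#'   (default [node_annotations()] ordering by pathway tag).
#' @param heatmap also write a PNG heatmap (requires a functional graphics
#'   device).
#' @export
export_delta <- function(dm, dir, annotations = NULL, heatmap = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- expand.grid(first = rownames(dm$delta), added = colnames(dm$delta),
                      stringsAsFactors = FALSE)
  long$delta <- as.vector(dm$delta)
  long$masked_reason <- as.vector(dm$mask)
  long$delta[long$masked_reason != ""] <- NA_real_
  paths <- c(csv = file.path(dir, sprintf("delta_%s.csv", dm$metric)))
  utils::write.csv(long, paths[["csv"]], row.names = FALSE, na = "")
  if (heatmap) {
    paths <- c(paths, png = file.path(dir, sprintf("delta_%s.png", dm$metric)))
    p <- plot_delta_heatmap(dm, annotations)
    ggplot2::ggsave(paths[["png"]], p, width = 7, height = 5.5, dpi = 150)
  }
  invisible(paths)
}

#' Heatmap of a delta matrix
#'
#' Axes are ordered by pathway tag (then name); masked cells are drawn gray.
#'
#' @param dm a `qn_delta`.
#' @param annotations node annotation table (`variable`, `pathway`).
#' @return a ggplot object.
#' @export
plot_delta_heatmap <- function(dm, annotations = NULL) {
  ord <- function(nms) {
    if (is.null(annotations)) return(sort(nms))
    ann <- annotations[match(nms, annotations$variable), ]
    nms[order(ann$pathway, nms)]
  }
  rows <- ord(rownames(dm$delta))
  cols <- ord(colnames(dm$delta))
  long <- expand.grid(first = rows, added = cols, stringsAsFactors = FALSE)
  long$delta <- dm$delta[cbind(long$first, long$added)]
  long$first <- factor(long$first, levels = rows)
  long$added <- factor(long$added, levels = cols)
  ggplot2::ggplot(long, ggplot2::aes(x = added, y = first, fill = delta)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#b2182b", midpoint = 0,
                                  na.value = "grey70") +
    ggplot2::labs(
      x = "added inhibitor", y = "first inhibitor (effective monotherapy)",
      fill = sprintf("Δ %s", dm$metric),
      title = sprintf("Change in %s when adding a second inhibitor", dm$metric),
      subtitle = sprintf("mean over %s; gray = masked", paste(dm$clones, collapse = ", "))
    ) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
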