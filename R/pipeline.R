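#' Experiment grid configuration
#'
#' Describes the full model-comparison experiment: which modalities and
#' sample sets to cross ({NIR, MIR, fused} x {each organ, the joint set}),
#' which preprocessing chains to try in each cell, and the CV settings.
#' With the defaults this yields 12 dataset cells (3 modalities x 4 sample
#' sets), each searched over the chain grid.
#'
#' @param cohort a [generate_cohort()] result, a [cohort_config()] (the
#'   cohort is generated), or `NULL` (default design, seeded from `seed`).
#' @param modalities subset of `c("nir", "mir", "fused")`.
#' @param sample_sets subset of `c("csr", organ names)`; `"csr"` is the
#'   joint all-organ set.
#' @param chains preprocessing chain labels searched per block.
#' @param fused_grid `"matched"` (same chain on both blocks) or
#'   `"product"` (all chain pairs) for the fused modality.
#' @param ncomp latent variables per model.
#' @param mc_fraction,mc_reps Monte Carlo CV holdout fraction and
#'   repetition count.
#' @param threshold decision threshold.
#' @param seed experiment-level seed; every stochastic sub-procedure
#'   derives its own child seed from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = NULL,
                              modalities = c("nir", "mir", "fused"),
                              sample_sets = c("csr", "colon", "stomach", "rectum"),
                              chains = c("none", "snv", "1d", "2d",
                                         "1d+snv", "2d+snv"),
                              fused_grid = c("matched", "product"),
                              ncomp = 5,
                              mc_fraction = 0.10, mc_reps = 100,
                              threshold = 0.5, seed = 1) {
  fused_grid <- match.arg(fused_grid)
  modalities <- match.arg(modalities, c("nir", "mir", "fused"),
                          several.ok = TRUE)
  if (!length(sample_sets) || !length(chains)) stop("empty grid")
  structure(
    list(cohort = cohort, modalities = modalities, sample_sets = sample_sets,
         chains = chains, fused_grid = fused_grid, ncomp = ncomp,
         mc_fraction = mc_fraction, mc_reps = mc_reps,
         threshold = threshold, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

chain_label <- function(modality, cm, cn) {
  if (modality == "fused") paste(cm, cn, sep = " | ")
  else if (modality == "mir") cm else cn
}

chain_steps <- function(modality, cm, cn) {
  nstep <- function(ch) length(preprocess_spec(ch)$steps)
  if (modality == "fused") nstep(cm) + nstep(cn)
  else if (modality == "mir") nstep(cm) else nstep(cn)
}

#' Run the full model-comparison experiment
#'
#' For every (modality, sample set, preprocessing) cell: preprocess,
#' fuse where applicable, fit PLS-DA, and evaluate by calibration
#' statistics, leave-one-out CV and Monte Carlo CV. Within each
#' (modality, sample set) cell the model with maximal LOO accuracy is
#' flagged as best (ties broken by calibration accuracy, then by the
#' shorter preprocessing chain, then by model id — so the selection does
#' not depend on grid enumeration order). Cell failures are recorded and
#' the run continues.
#'
#' @param config an [experiment_config()].
#' @return An object of class `experiment_report`: `table` (one row per
#'   fitted model, percentages on the 0-100 scale), `models` (per-model
#'   detail: spec, calibration fit, `cv_result`s), `failures`, `config`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- config$cohort
  if (is.null(cohort)) cohort <- cohort_config(seed = config$seed)
  if (inherits(cohort, "cohort_config")) cohort <- generate_cohort(cohort)
  mir_all <- average_replicates(cohort$mir)
  nir_all <- average_replicates(cohort$nir)

  organs_present <- unique(mir_all$meta$organ)
  subset_blocks <- function(set) {
    if (set == "csr") return(list(mir = mir_all, nir = nir_all))
    if (!set %in% organs_present)
      stop("sample set '", set, "' not present in the cohort")
    keep_m <- mir_all$meta$organ == set
    keep_n <- nir_all$meta$organ == set
    list(mir = mir_all[keep_m], nir = nir_all[keep_n])
  }

  rows <- list(); models <- list(); failures <- list()
  for (si in seq_along(config$sample_sets)) {
    set <- config$sample_sets[si]
    bl <- subset_blocks(set)
    for (mi in seq_along(config$modalities)) {
      modality <- config$modalities[mi]
      cells <- if (modality == "fused" && config$fused_grid == "product") {
        expand.grid(cm = config$chains, cn = config$chains,
                    stringsAsFactors = FALSE)
      } else if (modality == "fused") {
        data.frame(cm = config$chains, cn = config$chains,
                   stringsAsFactors = FALSE)
      } else if (modality == "mir") {
        data.frame(cm = config$chains, cn = "none", stringsAsFactors = FALSE)
      } else {
        data.frame(cm = "none", cn = config$chains, stringsAsFactors = FALSE)
      }
      for (ci in seq_len(nrow(cells))) {
        cm <- cells$cm[ci]; cn <- cells$cn[ci]
        lab <- chain_label(modality, cm, cn)
        id <- paste(set, modality, gsub(" ", "", lab), sep = "/")
        spec <- pipeline_spec(modality, mir = preprocess_spec(cm),
                              nir = preprocess_spec(cn),
                              ncomp = config$ncomp,
                              threshold = config$threshold)
        res <- tryCatch({
          cal <- fit_pipeline(bl$mir, bl$nir, spec)
          loo <- loo_cv(bl$mir, bl$nir, spec)
          mc <- monte_carlo_cv(bl$mir, bl$nir, spec,
                               fraction = config$mc_fraction,
                               reps = config$mc_reps,
                               seed = seed_child(config$seed, si, mi, ci))
          list(cal = cal, loo = loo, mc = mc)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[id]] <- conditionMessage(res)
          next
        }
        pc <- function(s) 100 * c(s$sensitivity, s$specificity, s$accuracy)
        rows[[id]] <- data.frame(
          id = id, sample_set = set, modality = modality,
          preprocessing = lab, lv = res$cal$model$ncomp,
          steps = chain_steps(modality, cm, cn),
          cal_se = pc(res$cal$stats)[1], cal_sp = pc(res$cal$stats)[2],
          cal_ac = pc(res$cal$stats)[3],
          loo_se = pc(res$loo$stats)[1], loo_sp = pc(res$loo$stats)[2],
          loo_ac = pc(res$loo$stats)[3],
          mc_se = pc(res$mc$stats)[1], mc_sp = pc(res$mc$stats)[2],
          mc_ac = pc(res$mc$stats)[3],
          stringsAsFactors = FALSE)
        models[[id]] <- list(spec = spec, cal = res$cal, loo = res$loo,
                             mc = res$mc)
      }
    }
  }
  if (!length(rows)) stop("every grid cell failed")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  tab$best <- FALSE
  for (set in unique(tab$sample_set)) {
    for (modality in unique(tab$modality)) {
      idx <- which(tab$sample_set == set & tab$modality == modality)
      if (!length(idx)) next
      o <- idx[order(-tab$loo_ac[idx], -tab$cal_ac[idx], tab$steps[idx],
                     tab$id[idx])]
      tab$best[o[1]] <- TRUE
    }
  }
  structure(list(table = tab, models = models, failures = failures,
                 config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, digits = 0, ...) {
  best <- x$table[x$table$best, c("sample_set", "modality", "preprocessing",
                                  "lv", "cal_se", "cal_sp", "cal_ac",
                                  "loo_se", "loo_sp", "loo_ac",
                                  "mc_se", "mc_sp", "mc_ac")]
  num <- vapply(best, is.numeric, logical(1))
  best[num] <- lapply(best[num], round, digits = digits)
  cat("<experiment_report> best model per (sample set x modality), % scale\n")
  print(best, row.names = FALSE)
  if (length(x$failures))
    cat("\n", length(x$failures), " cell(s) failed: ",
        paste(names(x$failures), collapse = ", "), "\n", sep = "")
  invisible(x)
}

best_row <- function(report, set, modality) {
  tab <- report$table
  idx <- which(tab$sample_set == set & tab$modality == modality & tab$best)
  if (!length(idx))
    stop("report has no best model for sample set '", set,
         "', modality '", modality, "'")
  tab[idx, , drop = FALSE]
}

#' Synergy of low-level fusion
#'
#' For each sample set, the accuracy gain of the best fused model over the
#' best single-modality model, in percentage points, reported separately
#' for the calibration, LOO-CV and Monte-Carlo-CV columns.
#'
#' @param report an [run_experiment()] result containing fused and both
#'   single-modality models per sample set.
#' @return data frame with one row per sample set: the fused and best
#'   single accuracies and `delta_* = fused - best single`.
#' @export
synergy_report <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  sets <- unique(report$table$sample_set)
  rows <- lapply(sets, function(set) {
    fu <- best_row(report, set, "fused")
    ni <- best_row(report, set, "nir")
    mi <- best_row(report, set, "mir")
    one <- function(col) {
      single <- max(ni[[col]], mi[[col]])
      c(single = single, fused = fu[[col]], delta = fu[[col]] - single)
    }
    cal <- one("cal_ac"); loo <- one("loo_ac"); mc <- one("mc_ac")
    data.frame(sample_set = set,
               cal_single = cal["single"], cal_fused = cal["fused"],
               delta_cal = cal["delta"],
               loo_single = loo["single"], loo_fused = loo["fused"],
               delta_loo = loo["delta"],
               mc_single = mc["single"], mc_fused = mc["fused"],
               delta_mc = mc["delta"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Local (per-organ) versus global (joint) models
#'
#' For each modality and organ, the accuracy gain of the organ's own best
#' model over the best joint-set ("csr") model, in percentage points.
#' Two readings of the comparison are reported: the organ model against
#' the joint model's overall accuracy (`delta_*`), and — as a secondary,
#' stricter comparison — against the joint model's LOO accuracy computed
#' on that organ's positions only (`delta_loo_local`).
#'
#' @param report an [run_experiment()] result containing the joint set and
#'   at least two organ sets per modality.
#' @return data frame with one row per (modality, organ).
#' @export
local_vs_global_report <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  sets <- unique(report$table$sample_set)
  organs <- setdiff(sets, "csr")
  if (!"csr" %in% sets || length(organs) < 2L)
    stop("local-vs-global comparison needs the joint 'csr' set and at ",
         "least two organ sets (got: ", paste(sets, collapse = ", "), ")")
  rows <- list()
  for (modality in unique(report$table$modality)) {
    glob <- best_row(report, "csr", modality)
    gloo <- report$models[[glob$id]]$loo
    for (organ in organs) {
      own <- best_row(report, organ, modality)
      sel <- gloo$meta$organ == organ
      g_on_organ <- 100 * mean(gloo$pred[sel] == gloo$labels[sel])
      rows[[paste(modality, organ)]] <- data.frame(
        modality = modality, organ = organ,
        organ_cal = own$cal_ac, organ_loo = own$loo_ac, organ_mc = own$mc_ac,
        global_cal = glob$cal_ac, global_loo = glob$loo_ac,
        global_mc = glob$mc_ac,
        delta_cal = own$cal_ac - glob$cal_ac,
        delta_loo = own$loo_ac - glob$loo_ac,
        delta_mc = own$mc_ac - glob$mc_ac,
        global_loo_on_organ = g_on_organ,
        delta_loo_local = own$loo_ac - g_on_organ,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROC ranking of the best models of a report
#'
#' Builds one ROC curve per best model from its pooled LOO-CV held-out
#' scores and ranks the models by proximity to the perfect-classification
#' point (0, 1).
#'
#' @param report an [run_experiment()] result.
#' @return the [rank_models()] data frame.
#' @export
rank_report_models <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  best <- report$table[report$table$best, ]
  curves <- lapply(best$id, function(id) {
    cv <- report$models[[id]]$loo
    roc_curve(cv$labels, cv$scores, model_id = id)
  })
  rank_models(curves, accuracies = best$loo_ac, ids = best$id)
}

#' Write the report table as CSV
#'
#' @param report an [run_experiment()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
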