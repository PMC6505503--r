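# End-to-end orchestration: simulate -> preprocess -> discover -> combine ->
# evaluate -> refine, with one master seed and per-stage provenance.

#' Default pipeline configuration
#'
#' Desk-scale defaults for a full synthetic run: 10,000 analysis peptides
#' (plus 200 controls) under the default multi-cohort study design, with 100
#' planted signature peptides at effect size 1.5.  All stage parameters are
#' exposed so individual selectors can be retuned or disabled; stage seeds
#' derive from the single `seed`.
#'
#' @param seed Master seed.
#' @param n_analysis,n_control,peptide_length Library dimensions.
#' @param n_signature_peptides,effect_size Planted-signal settings, see
#'   [signal_spec()].
#' @param ... Overrides for any `signal_spec()` field.
#' @return A list of class `immunosig_config`.
#' @export
default_config <- function(seed = 1L, n_analysis = 10000L, n_control = 200L,
                           peptide_length = 12L,
                           n_signature_peptides = 100L, effect_size = 1.5,
                           ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_analysis = as.integer(n_analysis),
    n_control = as.integer(n_control),
    peptide_length = as.integer(peptide_length),
    signal = list(n_signature_peptides = as.integer(n_signature_peptides),
                  effect_size = effect_size, ...),
    min_concordance = 0.8,
    selectors = c("spca", "sipca", "gs", "rl", "rf", "en"),
    k_features = 100L,
    n_lists = 10L,
    shave_fraction = 0.10,
    n_permutations = 20L,
    adj_p_threshold = 0.05,
    rf_trees = 1000L,
    en_runs = 100L,
    en_case_drop = 2L,
    en_control_drop = 2L,
    en_freq_threshold = 0.10,
    max_lists = 2L,
    auc_window = 0.02,
    refine_alpha = 0.05,
    winner = "CPS001"
  )
  class(cfg) <- c("immunosig_config", "list")
  cfg
}

#' Write / read a pipeline configuration as JSON
#'
#' Configurations round-trip exactly, so a run is fully reproducible from
#' its stored config.
#'
#' @param config An `immunosig_config` list.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   config list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$selectors <- as.character(cfg$selectors)
  for (f in c("seed", "n_analysis", "n_control", "peptide_length",
              "k_features", "n_lists", "n_permutations", "rf_trees",
              "en_runs", "en_case_drop", "en_control_drop", "max_lists")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.integer(cfg[[f]])
  }
  class(cfg) <- c("immunosig_config", "list")
  cfg
}

#' Run the full discovery-validation-refinement pipeline
#'
#' Executes every stage on synthetic data: simulates the study, preprocesses
#' arrays, runs the enabled selectors on the Discovery partition, assembles
#' panels, builds the candidate signatures, evaluates all non-empty
#' signatures on both partitions, and refines the configured winner through
#' the four-comparison Welch filter.  When the planted truth is available
#' the refined signature's precision and recall against it are reported.
#'
#' @param config An [default_config()] list.
#' @param out_dir Optional directory; when given, matrices, manifests,
#'   panels, signatures and the report tables are written there.
#' @return A list of class `immunosig_report`: `config`, `qc_summary`,
#'   `panel_sizes`, `signature_summary`, `evaluation` (per-signature
#'   discovery/validation AUC), `refinement` (size, precision, recall,
#'   validation AUC of the refined signature), `signatures`, `refined`,
#'   `planted`, and per-stage `digests`.
#' @export
run_full_pipeline <- function(config = default_config(), out_dir = NULL) {
  stages <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  lib <- run_stage("simulate", generate_peptide_library(
    config$n_analysis, config$n_control, config$peptide_length,
    seed = derive_seed(config$seed, 1L)))
  manifest <- run_stage("simulate", generate_design("paper_default"))
  spec <- run_stage("simulate", do.call(signal_spec, c(
    config$signal, list(seed = derive_seed(config$seed, 2L)))))
  sim <- run_stage("simulate", simulate_abundances(lib, manifest, spec))

  prep <- run_stage("preprocess", preprocess_arrays(
    sim$abundance, lib, manifest, config$min_concordance))
  X <- prep$processed
  samples <- prep$samples

  disc <- samples$partition == "discovery"
  Xd <- X[, samples$subject_id[disc], drop = FALSE]
  yd <- samples$group[disc]
  valid <- samples$partition == "validation"
  Xv <- X[, samples$subject_id[valid], drop = FALSE]
  yv <- samples$group[valid]

  sel <- intersect(c("spca", "sipca", "gs", "rl", "rf", "en"),
                   config$selectors)
  if (base::length(sel) == 0) stop("no panels: all selectors are disabled")

  panels <- list()
  if ("spca" %in% sel) {
    ls <- run_stage("discover", sparse_pca_lists(
      Xd, config$k_features, config$n_lists, seed = derive_seed(config$seed, 3L)))
    panels$sPCA_panel <- assemble_panel(ls, Xd, yd, config$max_lists,
                                        config$auc_window, name = "sPCA_panel")
  }
  if ("sipca" %in% sel) {
    ls <- run_stage("discover", sparse_ipca_lists(
      Xd, config$k_features, config$n_lists, seed = derive_seed(config$seed, 4L)))
    panels$sIPCA_panel <- assemble_panel(ls, Xd, yd, config$max_lists,
                                         config$auc_window, name = "sIPCA_panel")
  }
  if ("gs" %in% sel) {
    ls <- run_stage("discover", gene_shaving_lists(
      Xd, config$n_lists, config$shave_fraction, config$n_permutations,
      seed = derive_seed(config$seed, 5L)))
    panels$GS_panel <- assemble_panel(ls, Xd, yd, config$max_lists,
                                      config$auc_window, name = "GS_panel")
  }
  if ("rl" %in% sel) {
    rl <- run_stage("discover", moderated_t_select(Xd, yd,
                                                   config$adj_p_threshold))
    panels$RL_panel <- assemble_panel(list(rl$list), name = "RL_panel")
  }
  if ("rf" %in% sel) {
    rf <- run_stage("discover", random_forest_select(
      Xd, yd, config$rf_trees, seed = derive_seed(config$seed, 6L)))
    panels$RF_panel <- assemble_panel(list(rf), name = "RF_panel")
  }
  if ("en" %in% sel) {
    en <- run_stage("discover", elastic_net_frequency_select(
      Xd, yd, n_runs = config$en_runs, n_case_drop = config$en_case_drop,
      n_control_drop = config$en_control_drop,
      freq_threshold = config$en_freq_threshold,
      seed = derive_seed(config$seed, 7L)))
    panels$EN_panel <- assemble_panel(list(en), name = "EN_panel")
  }

  need <- c("sPCA_panel", "sIPCA_panel", "GS_panel", "RL_panel", "RF_panel",
            "EN_panel")
  if (!all(need %in% names(panels))) {
    # signatures need all six panels; absent selectors contribute empty panels
    for (nm in setdiff(need, names(panels))) {
      panels[[nm]] <- structure(list(name = nm, peptide_ids = character(0),
                                     constituent_lists = character(0),
                                     selection_rule = list(type = "disabled")),
                                class = "peptide_panel")
    }
  }
  sigs <- run_stage("combine", build_candidate_signatures(panels))

  eval_tab <- run_stage("evaluate", {
    d <- evaluate_signatures(sigs, Xd, yd)
    v <- evaluate_signatures(sigs, Xv, yv)
    data.frame(name = d$name, size = d$size, excluded = d$excluded,
               auc_discovery = d$auc, auc_validation = v$auc,
               stringsAsFactors = FALSE)
  })

  winner <- sigs[[config$winner]]
  if (is.null(winner)) stop("configured winner '", config$winner,
                            "' is not a known signature")
  if (winner$excluded) stop("configured winner '", config$winner,
                            "' is empty and cannot be refined")
  cmp <- run_stage("refine", build_refinement_comparisons(X, samples))
  ref <- run_stage("refine", refine_signature(winner, cmp,
                                              alpha = config$refine_alpha))
  refined_ids <- ref$signature$peptide_ids
  planted_ids <- sim$planted$peptide_id
  precision <- if (base::length(refined_ids) == 0) NA_real_ else
    mean(refined_ids %in% planted_ids)
  recall <- mean(planted_ids %in% refined_ids)
  refined_auc <- if (base::length(refined_ids) == 0) NA_real_ else
    signature_score(Xv, refined_ids, yv)$auc

  report <- list(
    config = config,
    qc_summary = list(
      n_arrays = nrow(manifest),
      n_pairs = nrow(prep$qc$pairs),
      removed_pairs = prep$qc$removed_pairs,
      removed_singletons = prep$qc$removed_singletons,
      n_samples = ncol(X),
      n_discovery = sum(disc),
      n_validation = sum(valid),
      n_analysis_peptides = nrow(X),
      max_abs_sample_median = max(abs(apply(X, 2, stats::median)))
    ),
    selector_details = list(
      en_run_sizes = if ("en" %in% sel) en$method_params$run_sizes,
      rf_gini_threshold = if ("rf" %in% sel) rf$method_params$gini_threshold,
      rl_prior_df = if ("rl" %in% sel) rl$d0
    ),
    panel_sizes = vapply(panels, function(p) base::length(p$peptide_ids),
                         integer(1)),
    signature_summary = signature_summary(sigs),
    evaluation = eval_tab,
    refinement = data.frame(
      name = ref$signature$name,
      size = base::length(refined_ids),
      precision = precision, recall = recall,
      auc_validation = refined_auc, stringsAsFactors = FALSE),
    signatures = sigs,
    refined = ref,
    planted = sim$planted,
    samples = samples,
    digests = list(
      processed = object_digest(round(X, 10)),
      signatures = object_digest(lapply(sigs, `[[`, "peptide_ids")),
      refined = object_digest(refined_ids)
    )
  )
  class(report) <- c("immunosig_report", "list")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.json"))
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    utils::write.csv(report$signature_summary,
                     file.path(out_dir, "signature_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(report$evaluation,
                     file.path(out_dir, "evaluation.csv"), row.names = FALSE)
    utils::write.csv(report$refinement,
                     file.path(out_dir, "refinement.csv"), row.names = FALSE)
    utils::write.csv(ref$report, file.path(out_dir, "refinement_report.csv"),
                     row.names = FALSE)
    for (s in sigs) {
      write_panel(s, file.path(out_dir, paste0(s$name, ".json")))
    }
    write_panel(ref$signature, file.path(out_dir, "CPS001A.json"))
  }
  report
}

#' @export
print.immunosig_report <- function(x, ...) {
  cat("Immunosignature pipeline report\n")
  cat("  samples: ", x$qc_summary$n_samples, " (",
      x$qc_summary$n_discovery, " discovery / ", x$qc_summary$n_validation,
      " validation)\n", sep = "")
  cat("  panels:\n")
  print(x$panel_sizes)
  cat("  signatures:\n")
  print(x$evaluation, row.names = FALSE)
  cat("  refinement:\n")
  print(x$refinement, row.names = FALSE)
  invisible(x)
}
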