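#' End-to-end phenotyping pipeline
#'
#' One call runs the full analysis: synthetic-cohort generation (or CSV
#' ingest), contamination, preprocessing, Isolation Forest exclusion,
#' cluster-number sweep, final K-means fit, stability assessment, phenotype
#' characterization and the tier-1 classifier, writing every artifact plus a
#' run manifest to an output directory. A single master seed fans out to
#' per-stage seeds by fixed offsets so reruns are bit-stable.
#'
#' @name pipeline
NULL

#' Build a pipeline configuration
#'
#' @param input Either `NULL` (generate the default synthetic cohort), an
#'   `hd_labeled_cohort`, or a path to a cohort CSV.
#' @param seed Master seed (default 1).
#' @param contamination Isolation Forest contamination (default 0.05).
#' @param inject_contamination Outlier fraction injected into a generated
#'   cohort before screening (default 0.0504, i.e. 64 appended to 1,207).
#' @param kmin,kmax Cluster-number sweep range (defaults 2, 10).
#' @param k_policy Policy list for [select_k()].
#' @param n_init K-means restarts (default 10).
#' @param bootstrap_B Bootstrap iterations (default 500; scale down for
#'   quick runs).
#' @param cv_folds Cross-validation folds (default 10).
#' @param train_fraction Tier-1 split fraction (default 0.7).
#' @param algorithm Tier-1 backend (default `"forest"`).
#' @param missing_rate MCAR missingness injected into a generated cohort
#'   (default 0.0034).
#' @return A `hd_pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, seed = 1L, contamination = 0.05,
                            inject_contamination = 0.0504,
                            kmin = 2, kmax = 10,
                            k_policy = list(type = "default"),
                            n_init = 10, bootstrap_B = 500, cv_folds = 10,
                            train_fraction = 0.7, algorithm = "forest",
                            missing_rate = 0.0034) {
  structure(
    list(input = input, seed = as.integer(seed), contamination = contamination,
         inject_contamination = inject_contamination, kmin = kmin, kmax = kmax,
         k_policy = k_policy, n_init = n_init, bootstrap_B = bootstrap_B,
         cv_folds = cv_folds, train_fraction = train_fraction,
         algorithm = algorithm, missing_rate = missing_rate),
    class = "hd_pipeline_config"
  )
}

# fixed per-stage seed offsets from the master seed
.stage_seed <- function(seed, stage) {
  seed + c(generate = 0L, missing = 11L, outliers = 23L, iforest = 37L,
           cluster = 53L, bootstrap = 71L, crossval = 89L, split = 101L,
           classifier = 113L)[[stage]]
}

#' Run the full phenotyping pipeline
#'
#' @param config An `hd_pipeline_config`.
#' @param out_dir Output directory (created if absent); `NULL` for no file
#'   output.
#' @return An `hd_run` list with every stage result: `cohort_raw`,
#'   `screened_table`, `transform`, `quality`, `k`, `model` (named),
#'   `bootstrap`, `crossval`, `profile`, `split`, `classifier_report`,
#'   `hpcs`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  seed <- config$seed
  # stage 1: ingest or simulate
  if (is.null(config$input)) {
    spec <- default_spec(seed = .stage_seed(seed, "generate"))
    lab <- generate(spec)
    if (config$missing_rate > 0)
      lab <- inject_missing(lab, config$missing_rate, .stage_seed(seed, "missing"))
    if (config$inject_contamination > 0)
      lab <- inject_outliers(lab, config$inject_contamination,
                             seed = .stage_seed(seed, "outliers"))
    table <- lab$table
    true_labels <- lab$true_labels
  } else if (inherits(config$input, "hd_labeled_cohort")) {
    lab <- config$input
    table <- lab$table
    true_labels <- lab$true_labels
  } else {
    if (!file.exists(config$input)) stop("input path not found: ", config$input)
    table <- read_cohort(config$input)
    true_labels <- NULL
  }

  # stage 2: preprocess (fit on the contaminated table, as screening operates
  # in the standardized space)
  transform <- fit_preprocessor(table)
  std <- transform$standardized

  # stage 3: outlier screening
  forest <- iforest_fit(std, seed = .stage_seed(seed, "iforest"))
  scores <- iforest_score(forest, std)
  mask <- flag_outliers(scores, config$contamination)
  screened <- exclude(table, mask, scores)
  if (!is.null(true_labels)) true_labels <- true_labels[!mask]

  # stage 4: refit preprocessing on the screened cohort; sweep and fit
  transform <- fit_preprocessor(screened)
  std <- transform$standardized
  quality <- k_sweep(std, config$kmin, config$kmax,
                     seed = .stage_seed(seed, "cluster"), n_init = config$n_init)
  k <- select_k(quality, config$k_policy)
  model <- attr(quality, "models")[[as.character(k)]]

  # stage 5: stability
  boot <- bootstrap_stability(std, model, B = config$bootstrap_B,
                              seed = .stage_seed(seed, "bootstrap"),
                              n_init = config$n_init)
  cv <- crossval_stability(std, k, folds = config$cv_folds,
                           seed = .stage_seed(seed, "crossval"),
                           n_init = config$n_init)

  # stage 6: characterization on the derived 22-column panel
  panel <- derive_all(impute_median(screened)$table)
  profile <- characterize_phenotypes(panel, model$labels)
  model <- name_phenotypes(model, panel)

  # stage 7: tier-1 classifier
  feats <- extract_tier1_features(screened, transform)
  split <- stratified_split(model$labels, config$train_fraction,
                            seed = .stage_seed(seed, "split"))
  clf <- train_classifier(feats[split$train, , drop = FALSE],
                          model$labels[split$train],
                          algorithm = config$algorithm,
                          seed = .stage_seed(seed, "classifier"))
  report <- evaluate_classifier(clf, feats[split$test, , drop = FALSE],
                                model$labels[split$test])
  hpcs <- derive_hpcs(feats[split$train, , drop = FALSE],
                      model$labels[split$train])

  run <- list(
    cohort_raw = table, true_labels = true_labels,
    outlier_scores = scores, outlier_mask = mask,
    screened_table = screened, transform = transform,
    quality = quality, k = as.integer(k), k_rationale = attr(k, "rationale"),
    model = model, bootstrap = boot, crossval = cv,
    panel = panel, profile = profile,
    split = split, classifier = clf, classifier_report = report, hpcs = hpcs,
    manifest = list(package_version = as.character(utils::packageVersion("hdphenotype")),
                    seed = seed,
                    config = config[setdiff(names(config), "input")],
                    n_input = nrow(table$values),
                    n_excluded = sum(mask),
                    n_analysis = nrow(screened$values))
  )
  class(run) <- "hd_run"
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$quality, file.path(out_dir, "cluster_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(k = run$k, centroids = run$model$centroids,
         name_map = as.list(run$model$name_map), inertia = run$model$inertia,
         seed = run$model$seed),
    file.path(out_dir, "phenotype_model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(bootstrap = run$bootstrap$summary, crossval = run$crossval$summary),
    file.path(out_dir, "stability.json"), auto_unbox = TRUE, digits = NA)
  write_profile(run$profile, file.path(out_dir, "phenotype_profile.csv"))
  jsonlite::write_json(
    list(accuracy = run$classifier_report$accuracy,
         macro_auc = run$classifier_report$macro_auc,
         rand_concordance = run$classifier_report$rand_concordance,
         per_class = as.data.frame(run$classifier_report$per_class)),
    file.path(out_dir, "classifier_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(run$hpcs$weights),
                   file.path(out_dir, "hpcs_weights.csv"))
  utils::write.csv(attr(run$screened_table, "exclusion_log"),
                   file.path(out_dir, "exclusion_log.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summarize a pipeline run (or run directory) as markdown text
#'
#' @param run An `hd_run`, or the path of a directory written by
#'   [run_pipeline()].
#' @return Character vector of markdown lines (also usable with
#'   `writeLines`). When given an incomplete directory, lists the missing
#'   artifacts instead.
#' @export
make_report <- function(run) {
  if (is.character(run)) return(.report_from_dir(run))
  sizes <- tabulate(run$model$labels + 1L, run$k)
  nm <- run$model$name_map
  top <- run$profile$table[order(-run$profile$table$eta_squared), ]
  c(
    "# Phenotyping run summary",
    "",
    sprintf("- Input records: %d; excluded by outlier screening: %d; analysis cohort: %d",
            run$manifest$n_input, run$manifest$n_excluded, run$manifest$n_analysis),
    sprintf("- Chosen k = %d (%s)", run$k, run$k_rationale),
    "- Phenotypes:",
    sprintf("  - %s: n = %d (%.1f%%)", nm[as.character(seq_along(sizes) - 1)],
            sizes, 100 * sizes / sum(sizes)),
    sprintf("- Stability: bootstrap mean ARI %.3f (B = %d); cross-validated pooled ARI %.3f",
            run$bootstrap$summary[["mean_ari"]], run$bootstrap$iterations,
            run$crossval$pooled_ari),
    "- Largest effect sizes (eta-squared):",
    sprintf("  - %s: %.3f (%s)", utils::head(top$indicator, 5),
            utils::head(top$eta_squared, 5), utils::head(top$effect_band, 5)),
    sprintf("- Tier-1 classifier (%s): accuracy %.3f, macro AUC %.3f, Rand concordance %.3f",
            run$classifier$algorithm, run$classifier_report$accuracy,
            run$classifier_report$macro_auc, run$classifier_report$rand_concordance)
  )
}

.report_from_dir <- function(dir) {
  expected <- c("cluster_metrics.csv", "phenotype_model.json", "stability.json",
                "phenotype_profile.csv", "classifier_report.json",
                "hpcs_weights.csv", "manifest.json")
  missing <- expected[!file.exists(file.path(dir, expected))]
  if (length(missing))
    return(c("# Incomplete run directory", "", "Missing artifacts:",
             paste0("- ", missing)))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  model <- jsonlite::read_json(file.path(dir, "phenotype_model.json"))
  stab <- jsonlite::read_json(file.path(dir, "stability.json"))
  clf <- jsonlite::read_json(file.path(dir, "classifier_report.json"))
  c("# Phenotyping run summary",
    "",
    sprintf("- Input records: %d; excluded: %d; analysis cohort: %d",
            manifest$n_input, manifest$n_excluded, manifest$n_analysis),
    sprintf("- k = %s; phenotypes: %s", model$k,
            paste(unlist(model$name_map), collapse = ", ")),
    sprintf("- Bootstrap mean ARI %.3f; CV pooled ARI %.3f",
            stab$bootstrap$mean_ari, stab$crossval$pooled_ari),
    sprintf("- Tier-1 accuracy %.3f, macro AUC %.3f, Rand concordance %.3f",
            clf$accuracy, clf$macro_auc, clf$rand_concordance))
}
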