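# End-to-end orchestration: development/validation split, per-view model
# fitting, dual-view fusion, survival evaluation and saliency, with a
# provenance record proving that validation subjects never enter a
# fitting step.

#' Stratified development/validation split
#'
#' Random split stratified by 1-year event status: disjoint, exhaustive,
#' reproducible from the seed. Falls back to an unstratified draw (with a
#' warning) when a stratum has fewer than 2 subjects.
#'
#' @param subject_ids character vector of ids.
#' @param event_1yr logical 1-year event status per subject.
#' @param split_fraction development fraction (default 0.70).
#' @param seed split seed.
#' @return list with `development` and `validation` id vectors.
#' @export
split_cohort <- function(subject_ids, event_1yr, split_fraction = 0.70, seed = 1) {
  stopifnot(
    length(subject_ids) >= 10, split_fraction > 0, split_fraction < 1,
    length(event_1yr) == length(subject_ids)
  )
  event_1yr <- as.logical(event_1yr)
  set.seed(seed)
  if (min(sum(event_1yr), sum(!event_1yr)) < 2) {
    warning("a 1-year event stratum has < 2 subjects; splitting without stratification")
    dev <- sample(subject_ids, floor(split_fraction * length(subject_ids)))
  } else {
    dev <- character(0)
    for (cl in c(FALSE, TRUE)) {
      ids <- subject_ids[event_1yr == cl]
      dev <- c(dev, sample(ids, floor(split_fraction * length(ids))))
    }
  }
  list(
    development = sort(dev),
    validation = sort(setdiff(subject_ids, dev))
  )
}

#' Configuration for a full synthetic study run
#'
#' @param n_subjects cohort size.
#' @param views views to model.
#' @param effect_size planted image effect per SD of latent risk.
#' @param image_size analysis image side (32, 64, 128 or 256).
#' @param split_fraction development fraction.
#' @param variance_kept MPCA retention.
#' @param cv_rounds,cv_folds cross-validation geometry; set `cv_rounds = 0`
#'   to fit directly (stepwise selection against a tuning set, no CV).
#' @param tuning_size,max_k,cost selection/SVM settings.
#' @param baseline_covariates clinical covariates of the baseline Cox
#'   model.
#' @param seed master seed; every stage seed derives from it.
#' @param ... further arguments to [synthetic_config()].
#' @return a `run_config` list.
#' @export
run_config <- function(n_subjects = 300, views = c("SA", "4Ch"),
                       effect_size = 2, image_size = 64,
                       split_fraction = 0.70, variance_kept = 0.97,
                       cv_rounds = 0, cv_folds = 10,
                       tuning_size = 50, max_k = 30, cost = 1,
                       baseline_covariates = "risk_score",
                       seed = 1, ...) {
  structure(
    list(
      synthetic = synthetic_config(
        n_subjects,
        image_size = max(64, image_size), views = views,
        effect_size = effect_size, seed = derive_seed(seed, 1), ...
      ),
      image_size = image_size,
      split_fraction = split_fraction,
      variance_kept = variance_kept,
      cv_rounds = cv_rounds, cv_folds = cv_folds,
      tuning_size = tuning_size, max_k = max_k, cost = cost,
      baseline_covariates = baseline_covariates,
      seed = seed
    ),
    class = "run_config"
  )
}

# record a fitting event in the provenance ledger
log_fit <- function(provenance, stage, subject_ids) {
  provenance[[length(provenance) + 1]] <- list(stage = stage, subject_ids = subject_ids)
  provenance
}

#' Audit the provenance ledger against the validation firewall
#'
#' Asserts that no validation subject id was consumed by any fitting
#' stage.
#'
#' @param report a report from [run_full_study()] (or a list with
#'   `provenance` and `split` entries).
#' @return `TRUE` invisibly, or an error naming the leaking stage.
#' @export
audit_provenance <- function(report) {
  val <- report$split$validation
  for (p in report$provenance) {
    leaked <- intersect(p$subject_ids, val)
    if (length(leaked)) {
      stop(
        "validation subject(s) entered fitting stage '", p$stage, "': ",
        paste(utils::head(leaked, 5), collapse = ", ")
      )
    }
  }
  invisible(TRUE)
}

# fit one view's model on the development cohort and score everyone
fit_view <- function(cohort, view, dev_ids, all_ids, config, provenance) {
  dev_studies <- cohort_view(cohort, view, dev_ids)
  reference <- fit_reference(
    lapply(dev_studies, `[[`, "landmarks"),
    view = view
  )
  provenance <- log_fit(provenance, paste0("reference_", view), dev_ids)
  pp_dev <- preprocess_studies(dev_studies, config$image_size, reference = reference)
  labels_dev <- cohort$clinical$event_1yr[match(dev_ids, cohort$clinical$subject_id)]

  seed_v <- derive_seed(config$seed, match(view, c("SA", "4Ch")) + 10)
  if (config$cv_rounds > 0) {
    cv <- cross_validate(
      unname(pp_dev$tensors), labels_dev,
      rounds = config$cv_rounds, folds = config$cv_folds, seed = seed_v,
      variance_kept = config$variance_kept, tuning_size = config$tuning_size,
      max_k = config$max_k, cost = config$cost
    )
    mpca <- cv$mpca
    model <- cv$final_model
    report_cv <- cv$report
  } else {
    mpca <- fit_mpca(unname(pp_dev$tensors), config$variance_kept)
    feats_dev <- t(vapply(pp_dev$tensors, function(x) mpca_project(mpca, x),
      numeric(prod(mpca$core_dims))
    ))
    sel <- stepwise_select(feats_dev, labels_dev,
      tuning_size = config$tuning_size, max_k = config$max_k,
      cost = config$cost, seed = seed_v
    )
    model <- train_svm(feats_dev[, sel$indices, drop = FALSE], labels_dev,
      selected = sel, view = view, cost = config$cost, seed = seed_v
    )
    report_cv <- NULL
  }
  model$view <- view
  provenance <- log_fit(provenance, paste0("mpca_svm_", view), dev_ids)

  # score every subject (validation registered to the frozen reference)
  all_studies <- cohort_view(cohort, view, all_ids)
  pp_all <- preprocess_studies(all_studies, config$image_size, reference = reference)
  feats_all <- t(vapply(pp_all$tensors, function(x) mpca_project(mpca, x),
    numeric(prod(mpca$core_dims))
  ))
  rownames(feats_all) <- all_ids
  sel_feats <- feats_all[, model$selected$indices, drop = FALSE]
  list(
    view = view,
    reference = reference,
    mpca = mpca,
    model = model,
    cv_report = report_cv,
    features = sel_feats,
    probabilities = stats::setNames(predict_probability(model, sel_feats), all_ids),
    tensors = pp_all$tensors,
    provenance = provenance
  )
}

#' Run the full prognostic study on a synthetic cohort
#'
#' Executes the whole chain: simulate, split 70:30 stratified by 1-year
#' event status, preprocess and fit per-view MPCA + selection + SVM models
#' on the development cohort, fuse the views with a dual-scan SVM, and
#' evaluate on the held-out validation cohort (univariable Cox screen,
#' nested model comparison with c-index/AIC/LRT, Kaplan-Meier with
#' median-threshold grouping and log-rank, 1-year ROC/AUC) plus saliency
#' maps with cluster localisation against the planted ground truth.
#'
#' @param config a [run_config()].
#' @return a report list with elements `split`, `views`, `combined`,
#'   `evaluation`, `saliency`, `provenance`, `config`.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$synthetic)
  clinical <- cohort$clinical
  ids <- clinical$subject_id
  split <- split_cohort(ids, clinical$event_1yr,
    split_fraction = config$split_fraction,
    seed = derive_seed(config$seed, 2)
  )
  dev <- split$development
  val <- split$validation
  provenance <- list()

  views <- list()
  for (v in config$synthetic$views) {
    fv <- fit_view(cohort, v, dev, ids, config, provenance)
    provenance <- fv$provenance
    fv$provenance <- NULL
    views[[v]] <- fv
  }

  # dual-scan fusion on the development subjects
  combined <- NULL
  prob_tables <- lapply(views, function(fv) fv$probabilities)
  if (length(views) == 2) {
    sa <- views[["SA"]]$features
    fc <- views[["4Ch"]]$features
    lab_dev <- stats::setNames(clinical$event_1yr, ids)[dev]
    combined <- combine_dual_scan(
      sa[dev, , drop = FALSE], fc[dev, , drop = FALSE], lab_dev,
      cost = config$cost, seed = derive_seed(config$seed, 30)
    )
    provenance <- log_fit(provenance, "dual_scan_svm", dev)
    all_feats <- cbind(sa, fc)
    prob_tables$combined <- stats::setNames(
      predict_probability(combined, all_feats), ids
    )
  }

  # covariate standardisation frozen on the development cohort
  covs <- config$baseline_covariates
  clin_dev <- standardize_covariates(
    clinical[match(dev, ids), , drop = FALSE],
    covariates = covs
  )
  scaling <- attr(clin_dev, "scaling")
  provenance <- log_fit(provenance, "covariate_standardization", dev)
  clin_val <- standardize_covariates(
    clinical[match(val, ids), , drop = FALSE],
    stats = scaling
  )

  eval_view <- names(prob_tables)[length(prob_tables)] # combined if present
  p_dev <- prob_tables[[eval_view]][dev]
  p_val <- prob_tables[[eval_view]][val]
  clin_val$mpca_probability <- as.numeric(p_val)

  # univariable Cox screen on the validation cohort
  uni <- lapply(
    stats::setNames(nm = c(covs, "mpca_probability")),
    function(v) {
      d <- clin_val
      d[[v]] <- as.numeric(scale(d[[v]]))
      cox_fit(d, v)
    }
  )

  # nested comparison: baseline covariates vs + MPCA probability
  base_fit <- cox_fit(clin_val, covs)
  full_fit <- cox_fit(clin_val, c(covs, "mpca_probability"))
  comparison <- model_comparison_table(
    list(baseline = base_fit, baseline_plus_mpca = full_fit),
    baseline = "baseline", n_boot = 500, seed = derive_seed(config$seed, 40)
  )

  groups <- median_risk_grouping(p_val, p_dev)
  km <- km_logrank(clin_val$survival_time_years, clin_val$event, groups)
  roc <- roc_auc_1yr(p_val, clin_val$survival_time_years, clin_val$event)

  # saliency of each per-view model, with localisation against the truth
  saliency <- list()
  for (v in names(views)) {
    fv <- views[[v]]
    smap <- feature_weight_map(fv$model, fv$mpca)
    truth <- signal_mask_in_reference(cohort, v, fv$reference, config$image_size)
    loc <- localize_saliency(smap, truth$mask, truth$frames)
    masks <- lapply(
      synthetic_region_masks(v, config$synthetic$image_size, config$synthetic$image_size),
      mask_in_reference,
      canonical_landmarks = cohort$canonical_landmarks[[v]],
      reference = fv$reference, target_size = config$image_size
    )
    # reference-pose warping can make masks touch; keep them disjoint
    masks$LV <- masks$LV & !masks$septum
    masks$RV <- masks$RV & !masks$septum & !masks$LV
    profile <- temporal_regional_profile(
      smap, masks,
      frame_annotations = c(end_diastole = 1L, end_systole = config$synthetic$es_frame)
    )
    sep <- profile[profile$region == "septum", ]
    saliency[[v]] <- list(
      map = threshold_and_cluster(smap), localization = loc, dice = loc$dice,
      profile = profile,
      septal_peak_frame = sep$frame[which.max(sep$weight)],
      truth_frames = truth$frames
    )
  }

  structure(
    list(
      split = split,
      views = lapply(views, function(fv) {
        fv[c("view", "reference", "mpca", "model", "cv_report")]
      }),
      combined = combined,
      probabilities = prob_tables,
      evaluation = list(
        view_used = eval_view,
        univariable = uni,
        baseline_fit = base_fit,
        full_fit = full_fit,
        comparison = comparison,
        lrt = likelihood_ratio_test(base_fit, full_fit),
        km = km,
        roc = roc,
        validation_c_index = concordance_index(
          p_val, clin_val$survival_time_years, clin_val$event
        )
      ),
      saliency = saliency,
      clinical_validation = clin_val,
      provenance = provenance,
      config = config
    ),
    class = "study_report"
  )
}

#' Write the numeric portion of a study report to JSON
#'
#' @param report a `study_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  ev <- report$evaluation
  out <- list(
    n_development = length(report$split$development),
    n_validation = length(report$split$validation),
    validation_auc_1yr = ev$roc$auc,
    validation_c_index = ev$validation_c_index,
    km_logrank_p = ev$km$p,
    lrt_p_baseline_vs_mpca = ev$lrt$p,
    aic_baseline = ev$baseline_fit$aic,
    aic_baseline_plus_mpca = ev$full_fit$aic,
    saliency_dice = lapply(report$saliency, `[[`, "dice")
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
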