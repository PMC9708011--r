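# Fixtures are generated in code and cached for the duration of one test
# run, so expensive cohorts are built once and shared across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small planted-signal cohort used by saliency and classification tests
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(synthetic_config(
      60,
      image_size = 32, n_frames = 10, views = c("SA", "4Ch"),
      effect_size = 3, seed = 101
    ))
  })
}

# survival-only cohort (no images): fast draws for statistical tests
survival_cohort <- function(n, seed, ...) {
  generate_cohort(synthetic_config(n, views = character(0), seed = seed, ...))
}

# the planted-signal study at full conditions (effect 2, n = 500, 64 x 64 x 20,
# SA view), fitted leak-free: reference, MPCA and selection on the
# development split only, scored on the held-out validation split
positive_control <- function() {
  fixture("positive_control", function() {
    cfg <- synthetic_config(
      500,
      image_size = 64, n_frames = 20, views = "SA",
      effect_size = 2, seed = 11
    )
    co <- generate_cohort(cfg)
    ids <- co$clinical$subject_id
    y <- co$clinical$event_1yr
    sp <- split_cohort(ids, y, seed = 21)
    di <- match(sp$development, ids)
    vi <- match(sp$validation, ids)
    dev_studies <- cohort_view(co, "SA", sp$development)
    reference <- fit_reference(lapply(dev_studies, `[[`, "landmarks"), view = "SA")
    pp_dev <- preprocess_studies(dev_studies, 64, reference = reference)
    mp <- fit_mpca(unname(pp_dev$tensors), 0.97)
    Xd <- t(vapply(pp_dev$tensors, function(x) mpca_project(mp, x),
      numeric(prod(mp$core_dims))
    ))
    sel <- stepwise_select(Xd, y[di], tuning_size = 50, max_k = 30, seed = 4)
    model <- train_svm(Xd[, sel$indices, drop = FALSE], y[di], selected = sel, seed = 4)
    pp_val <- preprocess_studies(cohort_view(co, "SA", sp$validation), 64,
      reference = reference
    )
    Xv <- t(vapply(pp_val$tensors, function(x) mpca_project(mp, x),
      numeric(prod(mp$core_dims))
    ))
    p_val <- predict_probability(model, Xv[, sel$indices, drop = FALSE])
    list(
      cohort = co, config = cfg, split = sp, dev_idx = di, val_idx = vi,
      reference = reference, mpca = mp, selection = sel, model = model,
      val_probabilities = p_val, val_labels = y[vi],
      val_clinical = co$clinical[vi, , drop = FALSE],
      truth = signal_mask_in_reference(co, "SA", reference, 64)
    )
  })
}

# brute-force Harrell c-index: explicit double loop over all pairs
brute_force_cindex <- function(risk, time, event) {
  n <- length(time)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (time[i] < time[j] && event[i]) ||
        (time[i] == time[j] && event[i] && !event[j])
      if (!comparable) next
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}

# brute-force AUC: all positive-negative pairs
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg)) {
    return(NA_real_)
  }
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
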