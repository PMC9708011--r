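# Synthetic cine-MRI cohort generator.
#
# Emulates the structure of a two-view cine cohort so the whole prognostic
# pipeline is testable without patient data: a crude two-ellipse "heart"
# template beating over ~20 frames on a smooth random background, three
# view-specific landmarks with jitter, a per-subject latent risk that
# drives both a spatially/temporally localised intensity signal (the
# planted prognostic feature) and survival times from a proportional-
# hazards model with administrative censoring.

#' Configuration for a synthetic cine cohort
#'
#' The defaults define the simulated study conditions: 64 x 64 images, 20
#' frames per cardiac cycle, a 10% 1-year event prevalence, a strongly
#' prognostic latent risk (log hazard ratio 2.5 per SD, giving the latent
#' ground truth a 1-year discrimination ceiling of AUC about 0.93, so the
#' cohort can act as a positive control), and a 5-year administrative
#' censoring horizon. When `baseline_hazard` is `NULL` it is calibrated numerically
#' so that the marginal 1-year event probability over latent risk ~ N(0,1)
#' equals `event_prevalence_1yr`.
#'
#' @param n_subjects number of subjects.
#' @param image_size pixels per side.
#' @param n_frames frames per cardiac cycle (>= 2).
#' @param views character subset of `c("SA", "4Ch")` (may be empty for a
#'   survival-only cohort).
#' @param signal_region optional named list (one entry per view) of
#'   `list(center = c(x, y), radius, frames)` in canonical-template pixel
#'   coordinates; `NULL` places a septal disc spanning the end-systolic
#'   frames.
#' @param effect_size planted intensity shift per unit latent risk, in
#'   units of the voxel noise SD.
#' @param event_prevalence_1yr target marginal 1-year event probability.
#' @param baseline_hazard events per subject-year at latent risk 0
#'   (`NULL` = calibrate from `event_prevalence_1yr`).
#' @param log_hazard_ratio_per_unit_risk log hazard ratio per SD of latent
#'   risk.
#' @param censor_horizon administrative censoring time (years).
#' @param random_censoring_rate optional exponential random-censoring rate
#'   (0 = administrative censoring only).
#' @param landmark_jitter_sd landmark placement jitter SD (pixels).
#' @param pose_angle_sd,pose_shift_sd per-subject rigid pose perturbation
#'   (degrees / pixels).
#' @param noise_sd voxel noise SD (scanner units).
#' @param seed integer seed; fully determines the cohort.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects,
                             image_size = 64,
                             n_frames = 20,
                             views = c("SA", "4Ch"),
                             signal_region = NULL,
                             effect_size = 0,
                             event_prevalence_1yr = 0.10,
                             baseline_hazard = NULL,
                             log_hazard_ratio_per_unit_risk = 2.5,
                             censor_horizon = 5,
                             random_censoring_rate = 0,
                             landmark_jitter_sd = 0.5,
                             pose_angle_sd = 5,
                             pose_shift_sd = 2,
                             noise_sd = 1,
                             seed = 1) {
  stopifnot(
    n_subjects >= 1, image_size >= 16, n_frames >= 2,
    all(views %in% c("SA", "4Ch")),
    event_prevalence_1yr >= 0, event_prevalence_1yr <= 1,
    censor_horizon > 0, noise_sd > 0
  )
  if (!is.null(baseline_hazard) && baseline_hazard <= 0) {
    stop("baseline_hazard must be positive")
  }
  if (is.null(baseline_hazard)) {
    baseline_hazard <- calibrate_baseline_hazard(
      event_prevalence_1yr, log_hazard_ratio_per_unit_risk
    )
  }
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      image_size = as.integer(image_size),
      n_frames = as.integer(n_frames),
      views = views,
      effect_size = effect_size,
      event_prevalence_1yr = event_prevalence_1yr,
      baseline_hazard = baseline_hazard,
      log_hazard_ratio_per_unit_risk = log_hazard_ratio_per_unit_risk,
      censor_horizon = censor_horizon,
      random_censoring_rate = random_censoring_rate,
      landmark_jitter_sd = landmark_jitter_sd,
      pose_angle_sd = pose_angle_sd,
      pose_shift_sd = pose_shift_sd,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
  cfg$es_frame <- round(0.35 * (n_frames - 1)) + 1L
  cfg$signal_region <- resolve_signal_regions(signal_region, cfg)
  cfg
}

#' Baseline hazard matching a target marginal 1-year prevalence
#'
#' Solves `E_Z[1 - exp(-h * exp(beta * Z))] = prevalence` for `h`, with
#' `Z ~ N(0, 1)`, by numerical integration and root finding.
#'
#' @param prevalence target 1-year event probability in (0, 1).
#' @param log_hr log hazard ratio per unit of latent risk.
#' @return baseline hazard (events per subject-year).
#' @export
calibrate_baseline_hazard <- function(prevalence, log_hr) {
  stopifnot(prevalence > 0, prevalence < 1)
  marg <- function(h) {
    stats::integrate(
      function(z) (1 - exp(-h * exp(log_hr * z))) * stats::dnorm(z),
      -8, 8
    )$value - prevalence
  }
  stats::uniroot(marg, c(1e-10, 50), tol = 1e-12)$root
}

# canonical template geometry (coordinates in 0-based pixels, x = col, y = row)
template_geometry <- function(view, S) {
  u <- S / 64
  if (view == "SA") {
    list(
      lv_center = c(38, 34) * u, lv_outer = 11 * u, lv_cavity = 7 * u,
      rv_center = c(22, 30) * u, rv_ax = c(9, 7) * u,
      landmarks = rbind(
        superior_insertion_point = c(30, 23),
        rv_free_wall_inflexion = c(17, 32),
        mid_lv_lateral_wall = c(49, 38)
      ) * u,
      septum_center = c(29.5, 32) * u
    )
  } else {
    list(
      lv_center = c(40, 36) * u, lv_ax = c(8, 15) * u, lv_cavity_ax = c(5, 11) * u,
      rv_center = c(24, 36) * u, rv_ax = c(7, 14) * u,
      landmarks = rbind(
        lv_apex = c(40, 17),
        lateral_mitral_annulus = c(49, 49),
        lateral_tricuspid_annulus = c(16, 49)
      ) * u,
      septum_center = c(32, 36) * u
    )
  }
}

# cavity contraction factor per frame: 1 at end-diastole (frame 1), minimal
# at the configured end-systolic frame.
contraction_profile <- function(n_frames, es_frame, amplitude = 0.35) {
  t <- seq_len(n_frames)
  1 - amplitude * exp(-0.5 * ((t - es_frame) / (n_frames / 6))^2)
}

disc_mask <- function(S, center, radius) {
  xs <- rep(0:(S - 1), each = S) - center[1]
  ys <- rep(0:(S - 1), times = S) - center[2]
  matrix(xs^2 + ys^2 <= radius^2, S, S)
}

ellipse_mask2 <- function(S, center, ax) {
  xs <- rep(0:(S - 1), each = S) - center[1]
  ys <- rep(0:(S - 1), times = S) - center[2]
  matrix((xs / ax[1])^2 + (ys / ax[2])^2 <= 1, S, S)
}

# one canonical template frame (no noise); blood is bright as in bSSFP
template_frame <- function(view, S, contraction) {
  g <- template_geometry(view, S)
  img <- matrix(0, S, S)
  if (view == "SA") {
    myo <- disc_mask(S, g$lv_center, g$lv_outer)
    cav <- disc_mask(S, g$lv_center, g$lv_cavity * contraction)
    rv <- ellipse_mask2(S, g$rv_center, g$rv_ax * c(1, contraction)) & !myo
    img[myo] <- 1.2
    img[cav] <- 3.0
    img[rv] <- 2.5
  } else {
    lv <- ellipse_mask2(S, g$lv_center, g$lv_ax)
    lv_cav <- ellipse_mask2(S, g$lv_center, g$lv_cavity_ax * c(contraction, 1))
    rv <- ellipse_mask2(S, g$rv_center, g$rv_ax * c(contraction, 1)) & !lv
    img[lv] <- 1.2
    img[lv_cav] <- 3.0
    img[rv] <- 2.5
  }
  img
}

resolve_signal_regions <- function(signal_region, cfg) {
  out <- list()
  for (v in cfg$views) {
    S <- cfg$image_size
    spec <- signal_region[[v]]
    if (is.null(spec)) {
      g <- template_geometry(v, S)
      spec <- list(
        center = g$septum_center,
        radius = 0.055 * S,
        frames = intersect(cfg$es_frame + (-1:1), seq_len(cfg$n_frames))
      )
    }
    if (any(spec$center < 0) || any(spec$center > S - 1)) {
      stop(
        "signal region centre (", paste(round(spec$center, 1), collapse = ", "),
        ") outside image bounds [0, ", S - 1, "] for view ", v
      )
    }
    if (any(spec$frames < 1) || any(spec$frames > cfg$n_frames)) {
      stop(
        "signal region frames (", paste(spec$frames, collapse = ", "),
        ") outside 1..", cfg$n_frames, " for view ", v
      )
    }
    spec$mask <- disc_mask(S, spec$center, spec$radius)
    out[[v]] <- spec
  }
  out
}

#' Add a localised intensity shift to a cine tensor
#'
#' @param tensor H x W x T array.
#' @param region logical H x W mask (or H x W x T array) of target voxels.
#' @param frames frame indices to modify (ignored for a 3-D region).
#' @param shift additive intensity shift.
#' @return modified copy; voxels outside the region/frames are unchanged.
#' @export
plant_signal <- function(tensor, region, frames = NULL, shift = 0) {
  d <- dim(tensor)
  if (length(dim(region)) == 3) {
    stopifnot(identical(dim(region), d))
    return(tensor + shift * as.numeric(region))
  }
  stopifnot(identical(dim(region), d[1:2]))
  if (!any(region)) stop("empty signal region")
  if (is.null(frames)) frames <- seq_len(d[3])
  if (any(frames < 1 | frames > d[3])) stop("frames outside 1..", d[3])
  out <- tensor
  for (t in frames) out[, , t] <- out[, , t] + shift * region
  out
}

# smooth random background field: gaussian-weighted row/column mixing
smooth_field <- function(S, sigma) {
  i <- seq_len(S)
  W <- exp(-0.5 * outer(i, i, "-")^2 / sigma^2)
  W <- W / rowSums(W)
  W %*% matrix(stats::rnorm(S * S), S, S) %*% t(W)
}

#' Sample a survival time under the proportional-hazards generator
#'
#' Time to event is exponential with hazard
#' `baseline_hazard * exp(log_hazard_ratio_per_unit_risk * latent_risk)`,
#' administratively censored at `censor_horizon` (plus optional random
#' exponential censoring).
#'
#' @param latent_risk finite latent risk value(s).
#' @param config a `synthetic_config`.
#' @return data.frame with columns `time` (years) and `event` (logical).
#' @export
sample_survival <- function(latent_risk, config) {
  stopifnot(inherits(config, "synthetic_config"), all(is.finite(latent_risk)))
  if (config$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  rate <- config$baseline_hazard *
    exp(config$log_hazard_ratio_per_unit_risk * latent_risk)
  t_event <- stats::rexp(length(latent_risk), rate)
  t_cens <- rep(config$censor_horizon, length(latent_risk))
  if (config$random_censoring_rate > 0) {
    t_cens <- pmin(t_cens, stats::rexp(length(latent_risk), config$random_censoring_rate))
  }
  data.frame(time = pmin(t_event, t_cens), event = t_event <= t_cens)
}

#' Generate a synthetic cine cohort
#'
#' Draws per-subject latent risks, survival outcomes, noisy clinical
#' covariates and, per requested view, a cine tensor: the beating template
#' plus the planted signal (`effect_size * noise_sd * latent_risk` inside
#' the signal region and frames), rigidly perturbed into a random
#' subject pose, with a smooth background field and voxel noise. Landmarks
#' follow the pose with Gaussian jitter. The seed fully determines the
#' cohort.
#'
#' @param config a [synthetic_config()].
#' @return object of class `cine_cohort`: `studies` (named list of
#'   `cine_study`, keys `"<id>_<view>"`), `clinical` (data.frame),
#'   `truth` (latent risks and poses), `config`, plus the canonical
#'   landmarks and signal masks used.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  S <- config$image_size
  T <- config$n_frames
  ids <- sprintf("S%04d", seq_len(n))

  latent <- stats::rnorm(n)
  risk_score <- 0.8 * latent + stats::rnorm(n, sd = 0.6)
  volumetric_index <- 100 + 20 * (0.5 * latent + stats::rnorm(n, sd = 0.87))
  surv <- sample_survival(latent, config)

  clinical <- data.frame(
    subject_id = ids,
    survival_time_years = surv$time,
    event = surv$event,
    risk_score = risk_score,
    volumetric_index = volumetric_index
  )
  clinical$event_1yr <- clinical$event & clinical$survival_time_years <= 1

  contraction <- contraction_profile(T, config$es_frame)
  templates <- list()
  for (v in config$views) {
    frames <- lapply(contraction, function(ct) template_frame(v, S, ct))
    templates[[v]] <- array(unlist(frames), c(S, S, T))
  }

  studies <- list()
  poses <- list()
  for (i in seq_len(n)) {
    for (v in config$views) {
      g <- template_geometry(v, S)
      base <- templates[[v]]
      reg <- config$signal_region[[v]]
      if (config$effect_size != 0) {
        base <- plant_signal(
          base, reg$mask, reg$frames,
          config$effect_size * config$noise_sd * latent[i]
        )
      }
      ang <- stats::rnorm(1, sd = config$pose_angle_sd * pi / 180)
      shift <- stats::rnorm(2, sd = config$pose_shift_sd)
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      ctr <- c(S - 1, S - 1) / 2
      tf <- list(R = R, s = 1, t = as.vector((diag(2) - R) %*% ctr) + shift, angle = ang)
      tensor <- warp_tensor(base, tf)
      tensor <- tensor + as.vector(0.5 * smooth_field(S, S / 16))
      tensor <- tensor + array(stats::rnorm(length(tensor), sd = config$noise_sd), dim(tensor))
      lm_true <- transform_points(g$landmarks, tf)
      lm_obs <- lm_true + matrix(
        stats::rnorm(length(lm_true), sd = config$landmark_jitter_sd),
        nrow(lm_true), 2
      )
      study <- structure(
        list(
          subject_id = ids[i],
          view = v,
          tensor = tensor,
          landmarks = data.frame(
            label = rownames(g$landmarks),
            x = lm_obs[, 1], y = lm_obs[, 2]
          ),
          survival_time = surv$time[i],
          event = surv$event[i],
          latent_risk = latent[i]
        ),
        class = "cine_study"
      )
      studies[[paste0(ids[i], "_", v)]] <- study
      poses[[length(poses) + 1]] <- data.frame(
        subject_id = ids[i], view = v, angle = ang, tx = tf$t[1], ty = tf$t[2]
      )
    }
  }

  structure(
    list(
      studies = studies,
      clinical = clinical,
      truth = data.frame(subject_id = ids, latent_risk = latent),
      poses = if (length(poses)) do.call(rbind, poses) else NULL,
      canonical_landmarks = lapply(
        stats::setNames(config$views, config$views),
        function(v) template_geometry(v, S)$landmarks
      ),
      signal_region = config$signal_region,
      config = config
    ),
    class = "cine_cohort"
  )
}

#' Studies of one view, in cohort order
#'
#' @param cohort a `cine_cohort`.
#' @param view `"SA"` or `"4Ch"`.
#' @param subject_ids optional subset, in the requested order.
#' @return list of `cine_study` objects.
#' @export
cohort_view <- function(cohort, view, subject_ids = NULL) {
  stopifnot(inherits(cohort, "cine_cohort"))
  if (is.null(subject_ids)) subject_ids <- cohort$clinical$subject_id
  keys <- paste0(subject_ids, "_", view)
  missing <- setdiff(keys, names(cohort$studies))
  if (length(missing)) stop("missing studies: ", paste(missing, collapse = ", "))
  cohort$studies[keys]
}

#' Map a canonical-template mask into a fitted reference pose
#'
#' Warps an in-plane mask defined on the canonical template through the
#' rigid transform aligning the canonical landmarks to a reference frame,
#' then downsamples to the analysis grid.
#'
#' @param mask logical matrix on the canonical template grid.
#' @param canonical_landmarks 3 x 2 canonical landmark matrix.
#' @param reference a `reference_frame`.
#' @param target_size analysis image side.
#' @return logical target x target matrix.
#' @export
mask_in_reference <- function(mask, canonical_landmarks, reference, target_size) {
  stopifnot(inherits(reference, "reference_frame"))
  tf <- fit_rigid_transform(canonical_landmarks, reference$reference_landmarks)
  m <- array(as.numeric(mask), c(dim(mask), 1))
  warped <- warp_tensor(m, tf)
  downsample_tensor(warped, target_size)[, , 1] >= 0.5
}

#' Planted signal mask mapped into a reference pose
#'
#' Ground-truth counterpart of the saliency localisation check: the
#' canonical signal mask expressed on the registered analysis grid.
#'
#' @param cohort a `cine_cohort` with planted signal.
#' @param view the view.
#' @param reference the `reference_frame` the cohort was registered to.
#' @param target_size analysis image side.
#' @return list with `mask` (logical target x target matrix) and `frames`.
#' @export
signal_mask_in_reference <- function(cohort, view, reference, target_size) {
  stopifnot(inherits(cohort, "cine_cohort"))
  reg <- cohort$signal_region[[view]]
  if (is.null(reg)) stop("cohort has no signal region for view ", view)
  list(
    mask = mask_in_reference(
      reg$mask, cohort$canonical_landmarks[[view]], reference, target_size
    ),
    frames = reg$frames
  )
}

#' Write a synthetic cohort to disk
#'
#' Per-study NIfTI images (`<id>_<view>.nii.gz`), a landmarks CSV
#' (subject_id, view, label, x, y), a clinical CSV and a JSON sidecar with
#' the generating configuration.
#'
#' @param cohort a `cine_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cine_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lm_rows <- list()
  for (key in names(cohort$studies)) {
    s <- cohort$studies[[key]]
    RNifti::writeNifti(RNifti::asNifti(s$tensor), file.path(dir, paste0(key, ".nii.gz")))
    lm_rows[[key]] <- data.frame(
      subject_id = s$subject_id, view = s$view,
      label = s$landmarks$label, x = s$landmarks$x, y = s$landmarks$y
    )
  }
  if (length(lm_rows)) {
    utils::write.csv(do.call(rbind, lm_rows), file.path(dir, "landmarks.csv"),
      row.names = FALSE
    )
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  cfg <- unclass(cohort$config)
  cfg$signal_region <- lapply(cfg$signal_region, function(r) {
    r$mask <- NULL
    r
  })
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
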