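# Cine preprocessing: z-score standardisation, landmark-based rigid
# registration to a cohort reference pose, elliptical masking of the heart,
# and local-mean downsampling. The pipeline order is fixed:
# standardise -> register -> mask -> downsample.

LANDMARK_LABELS <- list(
  SA = c(
    "superior_insertion_point",
    "rv_free_wall_inflexion",
    "mid_lv_lateral_wall"
  ),
  `4Ch` = c(
    "lv_apex",
    "lateral_mitral_annulus",
    "lateral_tricuspid_annulus"
  )
)

#' Z-score standardise a cine tensor
#'
#' Standardises voxel intensities over the subject's whole H x W x T array
#' so intensity scale is comparable between subjects. Applied before
#' registration and masking.
#'
#' @param tensor numeric array.
#' @return array of the same shape with overall mean 0 and SD 1.
#' @export
zscore_standardize <- function(tensor) {
  stopifnot(is.numeric(tensor), all(is.finite(tensor)))
  s <- stats::sd(tensor)
  if (s == 0) stop("constant tensor: z-score standardisation is undefined")
  (tensor - mean(tensor)) / s
}

check_landmarks <- function(landmarks, view) {
  expected <- LANDMARK_LABELS[[view]]
  if (is.null(expected)) stop("unknown view: ", view)
  if (!is.data.frame(landmarks) || !all(c("label", "x", "y") %in% names(landmarks))) {
    stop("landmarks must be a data.frame with columns label, x, y")
  }
  if (!setequal(landmarks$label, expected) || nrow(landmarks) != 3) {
    stop(
      "landmark labels for view ", view, " must be exactly {",
      paste(expected, collapse = ", "), "}"
    )
  }
  m <- as.matrix(landmarks[match(expected, landmarks$label), c("x", "y")])
  rownames(m) <- expected
  m
}

collinear_points <- function(p, tol = 1e-6) {
  # twice the triangle area
  a <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
    (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]))
  a < tol * max(1, max(abs(p)))
}

#' Build a reference pose from a cohort's landmark sets
#'
#' Generalised Procrustes mean of the landmark configurations: every set is
#' rigidly aligned to the current mean, the aligned sets are averaged, and
#' the loop repeats until the mean moves by less than `tol` (or `max_iter`).
#' The orientation gauge is anchored by rigidly aligning the converged mean
#' back onto the first subject's configuration. An axis-aligned elliptical
#' heart mask is derived from the reference configuration: centre at the
#' landmark centroid, semi-axes `k_ellipse` times the per-axis landmark
#' spread (SD).
#'
#' @param landmark_sets list of landmark data.frames (columns label, x, y),
#'   all of the same view.
#' @param view `"SA"` or `"4Ch"`.
#' @param k_ellipse semi-axis multiplier for the mask ellipse.
#' @param tol,max_iter Procrustes convergence controls.
#' @return object of class `reference_frame` with `reference_landmarks`
#'   (3 x 2 matrix) and `mask_params` (centre, semi-axes, orientation).
#' @export
fit_reference <- function(landmark_sets, view = "SA", k_ellipse = 2.5,
                          tol = 1e-8, max_iter = 100) {
  stopifnot(length(landmark_sets) >= 2)
  pts <- vector("list", length(landmark_sets))
  for (i in seq_along(landmark_sets)) {
    p <- check_landmarks(landmark_sets[[i]], view)
    if (collinear_points(p)) {
      stop("collinear landmarks in subject ", i, ": cannot define a pose")
    }
    pts[[i]] <- p
  }
  ref <- pts[[1]]
  for (iter in seq_len(max_iter)) {
    aligned <- lapply(pts, function(p) transform_points(p, fit_rigid_transform(p, ref)))
    new_ref <- Reduce(`+`, aligned) / length(aligned)
    shift <- max(abs(new_ref - ref))
    ref <- new_ref
    if (shift < tol) break
  }
  # anchor orientation/position to the first subject
  ref <- transform_points(ref, fit_rigid_transform(ref, pts[[1]]))
  rownames(ref) <- LANDMARK_LABELS[[view]]
  ctr <- colMeans(ref)
  spread <- apply(ref, 2, stats::sd)
  structure(
    list(
      view = view,
      reference_landmarks = ref,
      mask_params = list(
        center = ctr,
        semi_axes = k_ellipse * spread,
        orientation = 0
      ),
      k_ellipse = k_ellipse
    ),
    class = "reference_frame"
  )
}

#' Rigidly register a cine study to the reference pose
#'
#' Fits the least-squares rigid transform (rotation + translation; isotropic
#' scale only if `allow_scale`) mapping the study's three landmarks onto the
#' reference landmarks, and applies the identical in-plane transform to
#' every frame with bilinear interpolation (out-of-field voxels are 0).
#'
#' @param tensor H x W x T array (already z-scored).
#' @param landmarks data.frame with columns label, x, y.
#' @param ref a `reference_frame` of the same view.
#' @param allow_scale fit a similarity transform instead of a rigid one.
#' @return list with `tensor` (registered), `transform` (angle, tx, ty,
#'   scale) and `residual` (landmark RMSD after alignment).
#' @export
register_to_reference <- function(tensor, landmarks, ref, allow_scale = FALSE) {
  stopifnot(inherits(ref, "reference_frame"))
  p <- check_landmarks(landmarks, ref$view)
  tf <- fit_rigid_transform(p, ref$reference_landmarks, allow_scale = allow_scale)
  list(
    tensor = warp_tensor(tensor, tf),
    transform = c(angle = tf$angle, tx = tf$t[1], ty = tf$t[2], scale = tf$s),
    residual = tf$rmsd
  )
}

# logical in-plane ellipse mask for an H x W grid
ellipse_mask <- function(h, w, center, semi_axes, orientation = 0) {
  xs <- rep(0:(w - 1), each = h) - center[1]
  ys <- rep(0:(h - 1), times = w) - center[2]
  if (orientation != 0) {
    co <- cos(-orientation)
    si <- sin(-orientation)
    xr <- co * xs - si * ys
    yr <- si * xs + co * ys
    xs <- xr
    ys <- yr
  }
  matrix((xs / semi_axes[1])^2 + (ys / semi_axes[2])^2 <= 1, h, w)
}

#' Mask a registered tensor with the reference ellipse
#'
#' Voxels outside the in-plane ellipse are set to exactly 0 in every frame;
#' voxels inside are unchanged.
#'
#' @param tensor registered H x W x T array.
#' @param ref a `reference_frame` (its `mask_params` define the ellipse).
#' @return array with attribute `mask_fraction` (fraction of retained
#'   in-plane pixels).
#' @export
apply_elliptical_mask <- function(tensor, ref) {
  stopifnot(inherits(ref, "reference_frame"))
  d <- dim(tensor)
  mp <- ref$mask_params
  m <- ellipse_mask(d[1], d[2], mp$center, mp$semi_axes, mp$orientation)
  if (!any(m)) stop("mask ellipse covers no voxels")
  out <- tensor * as.vector(m) # recycles over frames
  attr(out, "mask_fraction") <- mean(m)
  out
}

#' Downsample a cine tensor by local-mean resampling
#'
#' Each frame is resized independently: source rows/columns are binned onto
#' the target grid and averaged, which anti-aliases and preserves constant
#' images exactly. The temporal dimension is unchanged.
#'
#' @param tensor H x W x T array.
#' @param target_size one of 32, 64, 128, 256 (not exceeding the source size).
#' @return target_size x target_size x T array.
#' @export
downsample_tensor <- function(tensor, target_size) {
  if (!target_size %in% c(32, 64, 128, 256)) {
    stop("target_size must be one of 32, 64, 128, 256")
  }
  d <- dim(tensor)
  if (target_size > d[1] || target_size > d[2]) {
    stop("target_size exceeds the source size")
  }
  shrink_rows <- function(m, from, to) {
    grp <- floor((seq_len(from) - 1) * to / from) + 1
    rowsum(m, grp) / as.vector(table(grp))
  }
  # rows
  x <- tensor
  dim(x) <- c(d[1], d[2] * d[3])
  x <- shrink_rows(x, d[1], target_size)
  dim(x) <- c(target_size, d[2], d[3])
  # columns
  x <- aperm(x, c(2, 1, 3))
  dim(x) <- c(d[2], target_size * d[3])
  x <- shrink_rows(x, d[2], target_size)
  dim(x) <- c(target_size, target_size, d[3])
  aperm(x, c(2, 1, 3))
}

#' Run the full preprocessing chain on a set of cine studies
#'
#' Applies, in order: z-score standardisation, rigid registration to a
#' reference pose, elliptical masking, and local-mean downsampling. When no
#' reference is supplied one is fitted by generalised Procrustes analysis of
#' the supplied studies' landmarks (use the training cohort only, then pass
#' the frozen reference for validation subjects).
#'
#' @param studies list of `cine_study` objects (see [generate_cohort()]) or
#'   lists with elements `tensor`, `landmarks`, `view`, `subject_id`.
#' @param target_size output image side (32, 64, 128 or 256).
#' @param reference optional frozen `reference_frame`.
#' @param allow_scale allow similarity registration.
#' @param k_ellipse mask semi-axis multiplier (when fitting the reference).
#' @return list with `tensors` (named list of arrays), `reference`,
#'   `transforms` (data.frame: subject_id, view, angle, tx, ty, scale,
#'   residual) and `mask_fraction`.
#' @export
preprocess_studies <- function(studies, target_size = 64, reference = NULL,
                               allow_scale = FALSE, k_ellipse = 2.5) {
  stopifnot(length(studies) >= 1)
  view <- studies[[1]]$view
  if (is.null(reference)) {
    reference <- fit_reference(
      lapply(studies, `[[`, "landmarks"),
      view = view, k_ellipse = k_ellipse
    )
  }
  tensors <- vector("list", length(studies))
  rows <- vector("list", length(studies))
  mask_fraction <- NA_real_
  for (i in seq_along(studies)) {
    s <- studies[[i]]
    if (!identical(s$view, reference$view)) {
      stop("study ", s$subject_id, " has view ", s$view, ", reference is ", reference$view)
    }
    z <- zscore_standardize(s$tensor)
    reg <- register_to_reference(z, s$landmarks, reference, allow_scale = allow_scale)
    masked <- apply_elliptical_mask(reg$tensor, reference)
    mask_fraction <- attr(masked, "mask_fraction")
    tensors[[i]] <- downsample_tensor(masked, target_size)
    rows[[i]] <- data.frame(
      subject_id = s$subject_id, view = view,
      angle = reg$transform[["angle"]], tx = reg$transform[["tx"]],
      ty = reg$transform[["ty"]], scale = reg$transform[["scale"]],
      residual = reg$residual
    )
  }
  names(tensors) <- vapply(studies, `[[`, character(1), "subject_id")
  list(
    tensors = tensors,
    reference = reference,
    transforms = do.call(rbind, rows),
    mask_fraction = mask_fraction,
    target_size = target_size
  )
}
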