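# Saliency: back-projection of linear classifier weights through the MPCA
# bases into voxel space, thresholding and morphological cleanup of the
# resulting weight map, and per-frame regional summaries.
#
# Because both the SVM and MPCA are linear, embedding the weight vector in
# an otherwise-zero core and reconstructing (without the mean) yields a
# signed H x W x T map whose inner product with a centred study equals the
# SVM decision value: positive voxels are mortality evidence, negative
# voxels survival evidence.

#' Voxel-space weight map of a linear prognostic model
#'
#' @param model a `prognostic_model` with a `selected` feature set whose
#'   indices address the MPCA feature order.
#' @param mpca the `mpca_model` the features came from.
#' @return object of class `saliency_map` with the signed `weights` array.
#' @export
feature_weight_map <- function(model, mpca) {
  stopifnot(inherits(model, "prognostic_model"), inherits(mpca, "mpca_model"))
  if (is.null(model$selected)) {
    stop("model carries no selected feature set; cannot back-project")
  }
  idx <- model$selected$indices
  stopifnot(length(idx) == length(model$w), max(idx) <= prod(mpca$core_dims))
  features <- numeric(prod(mpca$core_dims))
  features[idx] <- model$w
  structure(
    list(
      view = model$view,
      weights = mpca_reconstruct(mpca, features, add_mean = FALSE),
      threshold = NULL,
      clusters = NULL,
      labels = NULL
    ),
    class = "saliency_map"
  )
}

#' Discrete spherical structuring element
#'
#' All integer offsets (dx, dy, dt) with `dx^2 + dy^2 + dt^2 <= r^2`
#' (33 lattice points for r = 2).
#'
#' @param r radius in voxels.
#' @return integer matrix of offsets, one row per lattice point.
#' @export
sphere_element <- function(r = 2) {
  g <- expand.grid(dx = -r:r, dy = -r:r, dt = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 + g$dt^2 <= r^2, , drop = FALSE])
}

# shift a logical array by (dy rows, dx cols, dt frames), padding with
# `fill` outside the field of view
shift_mask <- function(mask, dx, dy, dt, fill = FALSE) {
  d <- dim(mask)
  out <- array(fill, d)
  src_r <- max(1, 1 - dy):min(d[1], d[1] - dy)
  src_c <- max(1, 1 - dx):min(d[2], d[2] - dx)
  src_t <- max(1, 1 - dt):min(d[3], d[3] - dt)
  if (length(src_r) < 1 || length(src_c) < 1 || length(src_t) < 1) {
    return(out)
  }
  out[src_r + dy, src_c + dx, src_t + dt] <- mask[src_r, src_c, src_t]
  out
}

# binary dilation / erosion with an offset-matrix structuring element
binary_morph <- function(mask, offsets, op = c("dilate", "erode")) {
  op <- match.arg(op)
  out <- if (op == "dilate") array(FALSE, dim(mask)) else array(TRUE, dim(mask))
  for (i in seq_len(nrow(offsets))) {
    s <- shift_mask(mask, offsets[i, "dx"], offsets[i, "dy"], offsets[i, "dt"])
    out <- if (op == "dilate") out | s else out & s
  }
  out
}

binary_closing <- function(mask, offsets) {
  binary_morph(binary_morph(mask, offsets, "dilate"), offsets, "erode")
}

# label 26-connected components of a logical 3-D mask; returns an integer
# array (0 = background)
label_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  vox <- which(mask)
  if (length(vox) == 0) {
    return(lab)
  }
  coords <- arrayInd(vox, d)
  id_of <- integer(prod(d))
  id_of[vox] <- seq_along(vox)
  offs <- expand.grid(dr = -1:1, dc = -1:1, dt = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0 & offs$dt == 0), ]
  # half the offsets suffice for an undirected edge list
  offs <- offs[seq_len(nrow(offs) / 2), ]
  edges <- list()
  for (i in seq_len(nrow(offs))) {
    nb <- coords
    nb[, 1] <- nb[, 1] + offs$dr[i]
    nb[, 2] <- nb[, 2] + offs$dc[i]
    nb[, 3] <- nb[, 3] + offs$dt[i]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    hit <- id_of[lin] > 0
    if (!any(hit)) next
    edges[[length(edges) + 1]] <- cbind(which(ok)[hit], id_of[lin[hit]])
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)$membership
  lab[vox] <- as.integer(comp)
  lab
}

#' Threshold a saliency map and extract morphologically cleaned clusters
#'
#' Voxels whose weight magnitude reaches the per-sign `percentile` cutoff
#' are binarised (positively and negatively weighted voxels separately),
#' closed (dilation then erosion) with a discrete sphere of radius
#' `radius` over the (x, y, t) lattice, and labelled as 26-connected
#' components; components smaller than `min_size` voxel-frames are
#' dropped.
#'
#' @param smap a `saliency_map`.
#' @param percentile magnitude quantile defining the cutoff per sign
#'   (default 0.95 = top 5%).
#' @param radius structuring-element radius.
#' @param min_size minimum cluster size in voxel-frames.
#' @return the `saliency_map` with `clusters` (data.frame: id, sign, size,
#'   centroid, frame span) and `labels` (signed integer label array:
#'   positive ids for high-risk, negative for low-risk clusters).
#' @export
threshold_and_cluster <- function(smap, percentile = 0.95, radius = 2, min_size = 20) {
  stopifnot(inherits(smap, "saliency_map"))
  w <- smap$weights
  if (max(w) == min(w)) stop("constant saliency map cannot be thresholded")
  se <- sphere_element(radius)
  labels <- array(0L, dim(w))
  rows <- list()
  next_id <- 1L
  for (sgn in c(1, -1)) {
    vals <- if (sgn > 0) w[w > 0] else -w[w < 0]
    if (length(vals) == 0) next
    cutoff <- stats::quantile(vals, percentile, names = FALSE)
    mask <- if (sgn > 0) w >= cutoff & w > 0 else (-w) >= cutoff & w < 0
    if (!any(mask)) next
    mask <- binary_closing(mask, se)
    # closing can spill onto opposite-signed voxels; a voxel contested by
    # both signs belongs to the sign of its own weight
    mask <- mask & (sgn * w > 0)
    lab <- label_components_26(mask)
    for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
      vox <- which(lab == id)
      if (length(vox) < min_size) next
      co <- arrayInd(vox, dim(w))
      labels[vox] <- sgn * next_id
      rows[[length(rows) + 1]] <- data.frame(
        id = next_id,
        sign = sgn,
        size = length(vox),
        centroid_x = mean(co[, 2] - 1),
        centroid_y = mean(co[, 1] - 1),
        centroid_t = mean(co[, 3]),
        frame_min = min(co[, 3]),
        frame_max = max(co[, 3])
      )
      next_id <- next_id + 1L
    }
  }
  smap$threshold <- percentile
  smap$clusters <- if (length(rows)) do.call(rbind, rows) else NULL
  smap$labels <- labels
  smap
}

#' Per-frame regional aggregates of a saliency map
#'
#' Mean signed weight per anatomical region per frame.
#'
#' @param smap a `saliency_map`.
#' @param region_masks named list of logical in-plane masks (e.g. RV, LV,
#'   septum), all within the map's spatial grid and pairwise disjoint.
#' @param frame_annotations optional named integer vector (e.g.
#'   `c(end_diastole = 1, end_systole = 8)`), carried through to the
#'   output attributes.
#' @return data.frame with columns region, frame, weight.
#' @export
temporal_regional_profile <- function(smap, region_masks, frame_annotations = NULL) {
  stopifnot(inherits(smap, "saliency_map"), is.list(region_masks))
  d <- dim(smap$weights)
  masks <- lapply(region_masks, function(m) {
    m <- as.logical(m)
    stopifnot(length(m) == d[1] * d[2])
    if (!any(m)) stop("empty region mask")
    m
  })
  flat <- vapply(masks, identity, logical(d[1] * d[2]))
  if (any(rowSums(flat) > 1)) stop("region masks must be disjoint")
  rows <- list()
  for (r in names(masks)) {
    for (t in seq_len(d[3])) {
      fr <- smap$weights[, , t]
      rows[[length(rows) + 1]] <- data.frame(
        region = r, frame = t, weight = mean(fr[matrix(masks[[r]], d[1], d[2])])
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "frame_annotations") <- frame_annotations
  out
}

#' Overlay saliency clusters on cine frames
#'
#' Writes one PNG per requested frame: the grayscale anatomy with
#' high-risk (positive) cluster voxels in red and low-risk (negative)
#' cluster voxels in blue. Rendering is deterministic and pixel-exact:
#' a pixel is coloured if and only if it belongs to a cluster in that
#' frame.
#'
#' @param tensor registered/downsampled H x W x T anatomy (same space as
#'   the map).
#' @param smap a clustered `saliency_map` (see [threshold_and_cluster()]).
#' @param frames frame indices to render.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of file paths, invisibly; the rendered RGB
#'   arrays as attribute `"images"`.
#' @export
overlay_saliency <- function(tensor, smap, frames, dir, prefix = "overlay") {
  stopifnot(inherits(smap, "saliency_map"))
  if (!identical(dim(tensor), dim(smap$weights))) {
    stop("tensor and saliency map are not in the same space")
  }
  if (is.null(smap$labels)) stop("saliency map has no clusters; run threshold_and_cluster first")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- range(tensor)
  gray <- if (diff(rng) > 0) (tensor - rng[1]) / diff(rng) else tensor * 0
  paths <- character(0)
  images <- list()
  for (t in frames) {
    g <- gray[, , t]
    rgb <- array(g, c(dim(g), 3))
    pos <- smap$labels[, , t] > 0
    neg <- smap$labels[, , t] < 0
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[pos] <- if (ch == 1) 1 else 0
      plane[neg] <- if (ch == 3) 1 else 0
      rgb[, , ch] <- plane
    }
    path <- file.path(dir, sprintf("%s_frame%02d.png", prefix, t))
    png::writePNG(rgb, path)
    paths <- c(paths, path)
    images[[length(images) + 1]] <- rgb
  }
  attr(paths, "images") <- images
  invisible(paths)
}

#' Score saliency localisation against a known target region
#'
#' Thresholds the weight map at a support-matched cutoff -- the top
#' positive voxel-frames, as many as the target region contains -- extracts
#' clusters, and reports the Dice overlap between the in-plane footprint
#' of the largest positive cluster and the target mask. Matching the
#' thresholded support to the target size makes the score a pure measure
#' of localisation: it is high only when the strongest mortality evidence
#' sits where the signal actually is.
#'
#' @param smap an unthresholded `saliency_map`.
#' @param target_mask logical in-plane mask of the true signal region.
#' @param target_frames frame indices of the true signal.
#' @param radius,min_size morphology settings (min_size is capped at the
#'   target support).
#' @return list with `dice`, `cluster_frames` (span of the largest
#'   positive cluster) and the clustered map.
#' @export
localize_saliency <- function(smap, target_mask, target_frames,
                              radius = 2, min_size = 20) {
  stopifnot(inherits(smap, "saliency_map"))
  n_target <- sum(target_mask) * length(target_frames)
  n_pos <- sum(smap$weights > 0)
  stopifnot(n_target >= 1, n_pos >= 1)
  pct <- max(0, 1 - n_target / n_pos)
  clustered <- threshold_and_cluster(
    smap,
    percentile = pct, radius = radius,
    min_size = min(min_size, n_target)
  )
  pos <- clustered$clusters[clustered$clusters$sign > 0, , drop = FALSE]
  if (is.null(clustered$clusters) || nrow(pos) == 0) {
    return(list(dice = 0, cluster_frames = integer(0), map = clustered))
  }
  big <- pos$id[which.max(pos$size)]
  footprint <- apply(clustered$labels == big, c(1, 2), any)
  list(
    dice = dice_coefficient(footprint, target_mask),
    cluster_frames = seq(
      pos$frame_min[which.max(pos$size)],
      pos$frame_max[which.max(pos$size)]
    ),
    map = clustered
  )
}

#' Synthetic anatomical region masks (RV, LV, septum)
#'
#' In-plane masks matching the synthetic template geometry of a view,
#' downsampled to the analysis grid; used to drive
#' [temporal_regional_profile()] on synthetic cohorts.
#'
#' @param view `"SA"` or `"4Ch"`.
#' @param image_size canonical template size the cohort was generated at.
#' @param target_size analysis grid side.
#' @return named list of logical target x target masks (pairwise disjoint).
#' @export
synthetic_region_masks <- function(view, image_size, target_size = image_size) {
  g <- template_geometry(view, image_size)
  S <- image_size
  if (view == "SA") {
    lv <- disc_mask(S, g$lv_center, g$lv_outer)
    rv <- ellipse_mask2(S, g$rv_center, g$rv_ax)
    sep <- disc_mask(S, g$septum_center, 0.075 * S)
  } else {
    lv <- ellipse_mask2(S, g$lv_center, g$lv_ax)
    rv <- ellipse_mask2(S, g$rv_center, g$rv_ax)
    sep <- disc_mask(S, g$septum_center, 0.075 * S)
  }
  lv <- lv & !sep
  rv <- rv & !sep & !lv
  shrink <- function(m) {
    downsample_tensor(array(as.numeric(m), c(S, S, 1)), target_size)[, , 1] >= 0.5
  }
  out <- list(RV = shrink(rv), LV = shrink(lv), septum = shrink(sep))
  out$LV <- out$LV & !out$septum
  out$RV <- out$RV & !out$septum & !out$LV
  out
}
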