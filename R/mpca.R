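# Multilinear principal component analysis (MPCA) for 3rd-order tensors.
#
# A cine study is an H x W x T array: two spatial modes and one temporal
# mode. MPCA learns one orthonormal basis per mode and represents each
# (centred) tensor by its core, the contraction with the transposed bases.
# Unlike PCA on the vectorised image, the projection respects the
# spatial-by-temporal structure, and its linearity is what later allows
# classifier weights to be back-projected into voxel space.

# mode-n unfolding of a 3rd-order array: rows index mode n.
unfold_tensor <- function(x, mode) {
  d <- dim(x)
  if (mode == 1) {
    dim(x) <- c(d[1], d[2] * d[3])
    x
  } else if (mode == 2) {
    x <- aperm(x, c(2, 1, 3))
    dim(x) <- c(d[2], d[1] * d[3])
    x
  } else {
    x <- aperm(x, c(3, 1, 2))
    dim(x) <- c(d[3], d[1] * d[2])
    x
  }
}

# mode-n product: Y_(n) = M %*% X_(n); the mode-n dimension becomes nrow(M).
mode_multiply <- function(x, M, mode) {
  d <- dim(x)
  xu <- M %*% unfold_tensor(x, mode)
  d[mode] <- nrow(M)
  if (mode == 1) {
    dim(xu) <- d
    xu
  } else if (mode == 2) {
    dim(xu) <- d[c(2, 1, 3)]
    aperm(xu, c(2, 1, 3))
  } else {
    dim(xu) <- d[c(3, 1, 2)]
    aperm(xu, c(2, 3, 1))
  }
}

# Deterministic sign convention: the largest-magnitude component of every
# basis vector is made positive.
fix_basis_sign <- function(B) {
  for (j in seq_len(ncol(B))) {
    i <- which.max(abs(B[, j]))
    if (B[i, j] < 0) B[, j] <- -B[, j]
  }
  B
}

#' Fit a multilinear PCA model to a set of 3rd-order tensors
#'
#' Centres the tensors by their sample mean, then per mode retains the
#' smallest number of leading eigenvectors of the mode-n total scatter
#' matrix whose cumulative eigenvalue fraction reaches `variance_kept`.
#' With `iters = 1` (the default) the bases come from this single
#' full-projection eigen-pass, which makes the retained subspaces nested
#' across `variance_kept` levels; `iters >= 2` adds alternating
#' partial-projection refinements (each mode's scatter recomputed with the
#' other modes projected onto their current bases).
#'
#' @param tensors list of numeric arrays, all of identical dimension
#'   `c(H, W, T)`.
#' @param variance_kept per-mode cumulative eigenvalue fraction to retain,
#'   in (0, 1].
#' @param iters number of eigen-passes (see Details).
#' @return an object of class `mpca_model`: mean tensor, per-mode orthonormal
#'   bases, per-feature training variances and the variance-descending
#'   feature order used by [mpca_project()].
#' @export
fit_mpca <- function(tensors, variance_kept = 0.97, iters = 1) {
  if (!is.list(tensors) || length(tensors) < 2) {
    stop("need at least two tensors")
  }
  d <- dim(tensors[[1]])
  if (length(d) != 3) stop("tensors must be 3rd-order arrays")
  for (x in tensors) {
    if (!identical(dim(x), d)) stop("all tensors must share the same shape")
    if (!all(is.finite(x))) stop("tensors must be finite")
  }
  if (!is.numeric(variance_kept) || variance_kept <= 0 || variance_kept > 1) {
    stop("variance_kept must lie in (0, 1]")
  }
  n <- length(tensors)
  mean_tensor <- Reduce(`+`, tensors) / n
  centered <- lapply(tensors, function(x) x - mean_tensor)

  bases <- vector("list", 3)
  for (m in 1:3) {
    S <- matrix(0, d[m], d[m])
    for (x in centered) {
      S <- S + tcrossprod(unfold_tensor(x, m))
    }
    ev <- eigen(S, symmetric = TRUE)
    vals <- pmax(ev$values, 0)
    tot <- sum(vals)
    P <- if (tot <= 0) 1L else which(cumsum(vals) / tot >= variance_kept - 1e-12)[1]
    bases[[m]] <- fix_basis_sign(ev$vectors[, seq_len(P), drop = FALSE])
  }

  if (iters >= 2) {
    for (it in 2:iters) {
      for (m in 1:3) {
        others <- setdiff(1:3, m)
        S <- matrix(0, d[m], d[m])
        for (x in centered) {
          y <- x
          for (o in others) y <- mode_multiply(y, t(bases[[o]]), o)
          S <- S + tcrossprod(unfold_tensor(y, m))
        }
        ev <- eigen(S, symmetric = TRUE)
        P <- ncol(bases[[m]])
        bases[[m]] <- fix_basis_sign(ev$vectors[, seq_len(P), drop = FALSE])
      }
    }
  }

  model <- structure(
    list(
      mean_tensor = mean_tensor,
      mode_bases = bases,
      dims = d,
      core_dims = vapply(bases, ncol, integer(1)),
      variance_kept = variance_kept,
      iters = iters,
      n_train = n
    ),
    class = "mpca_model"
  )

  # training projections in natural core order -> per-feature variances
  scores <- vapply(
    centered,
    function(x) as.vector(project_core(model, x)),
    numeric(prod(model$core_dims))
  )
  scores <- if (is.null(dim(scores))) matrix(scores, nrow = 1) else scores
  v <- apply(scores, 1, stats::var)
  model$feature_variance <- v
  model$feature_order <- order(v, decreasing = TRUE)
  model$total_variance <- sum(vapply(centered, function(x) sum(x^2), numeric(1))) / (n - 1)
  model
}

# core of a centred tensor (natural order, not yet permuted)
project_core <- function(model, centered) {
  y <- centered
  for (m in 1:3) y <- mode_multiply(y, t(model$mode_bases[[m]]), m)
  y
}

#' Project a tensor onto a fitted MPCA model
#'
#' @param model an `mpca_model`.
#' @param tensor array matching the model's training dimensions.
#' @return numeric feature vector of length `prod(core_dims)`, ordered by
#'   decreasing training variance.
#' @export
mpca_project <- function(model, tensor) {
  stopifnot(inherits(model, "mpca_model"))
  if (!identical(dim(tensor), model$dims)) {
    stop("tensor shape does not match the fitted model")
  }
  core <- project_core(model, tensor - model$mean_tensor)
  as.vector(core)[model$feature_order]
}

#' Reconstruct a tensor from MPCA features
#'
#' Inverse of [mpca_project()]: the features are placed back into the core,
#' back-contracted with the (transposed) mode bases and, by default, the
#' mean tensor is added. With square bases this is an exact inverse; with
#' truncated bases it is the best multilinear approximation.
#'
#' @param model an `mpca_model`.
#' @param features numeric vector of length `prod(core_dims)` in the order
#'   produced by [mpca_project()].
#' @param add_mean add the training mean tensor (set `FALSE` to back-project
#'   classifier weights).
#' @return array of the model's training dimensions.
#' @export
mpca_reconstruct <- function(model, features, add_mean = TRUE) {
  stopifnot(inherits(model, "mpca_model"))
  p <- prod(model$core_dims)
  if (length(features) != p) {
    stop("feature vector length ", length(features), " does not match core size ", p)
  }
  core_vec <- numeric(p)
  core_vec[model$feature_order] <- features
  y <- array(core_vec, model$core_dims)
  for (m in 1:3) y <- mode_multiply(y, model$mode_bases[[m]], m)
  if (add_mean) y <- y + model$mean_tensor
  y
}

#' @export
print.mpca_model <- function(x, ...) {
  cat(
    "MPCA model:", paste(x$dims, collapse = " x "), "->",
    paste(x$core_dims, collapse = " x "),
    sprintf(
      "(%d features, variance_kept = %.2f, n = %d)\n",
      prod(x$core_dims), x$variance_kept, x$n_train
    )
  )
  invisible(x)
}
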