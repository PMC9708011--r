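# Internal helpers shared across modules.
#
# Image coordinate convention (used everywhere): points are (x, y) with
# x = column - 1, y = row - 1, i.e. 0-based pixel centres. A tensor is an
# array [row, col, frame].

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' Ties in the scores count one half. Returns `NA` if either class is absent.
#'
#' @param scores numeric vector of risk scores (higher = more positive).
#' @param labels logical vector, `TRUE` for the positive class.
#' @return AUC in \[0, 1\].
#' @keywords internal
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  npos <- as.numeric(sum(labels))
  nneg <- as.numeric(sum(!labels))
  if (npos == 0L || nneg == 0L) {
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Dice overlap between two binary masks
#'
#' @param a,b logical arrays or vectors of equal length.
#' @return 2|A∩B| / (|A| + |B|).
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    return(NA_real_)
  }
  2 * sum(a & b) / denom
}

# Deterministic per-stage seed derived from one master seed; stays < 2^31.
derive_seed <- function(master, stage) {
  ((as.numeric(master) %% 100000) * 10007 + as.numeric(stage) * 101) %% 2147483647
}

# Stratified fold assignment: within each class, fold labels 1..folds are
# recycled and permuted. Uses the current RNG state.
stratified_folds <- function(labels, folds) {
  labels <- as.logical(labels)
  out <- integer(length(labels))
  for (cl in c(FALSE, TRUE)) {
    members <- which(labels == cl)
    if (length(members) > 0L) {
      out[members] <- sample(rep_len(seq_len(folds), length(members)))
    }
  }
  out
}

# Stratified subsample of size `size` (approximately preserving the class
# ratio, at least one case per class). Returns indices.
stratified_sample <- function(labels, size) {
  labels <- as.logical(labels)
  n <- length(labels)
  size <- min(size, n - 2L)
  npos <- max(1L, round(size * mean(labels)))
  # leave at least two cases per class outside the sample
  npos <- min(npos, max(1L, sum(labels) - 2L))
  nneg <- min(size - npos, max(1L, sum(!labels) - 2L))
  c(
    sample(which(labels), npos),
    sample(which(!labels), nneg)
  )
}

## ---- rigid 2-D geometry -------------------------------------------------

#' Least-squares rigid (or similarity) alignment of 2-D point sets
#'
#' Solves the orthogonal Procrustes problem mapping `src` onto `dst`:
#' `dst ~ s * src %*% t(R) + t` with `R` a proper rotation (no reflection),
#' `s = 1` unless `allow_scale`.
#'
#' @param src,dst n x 2 matrices of (x, y) points.
#' @param allow_scale fit an isotropic scale as well (similarity transform).
#' @return list with `R` (2 x 2 rotation), `s` (scale), `t` (length-2
#'   translation), `angle` (radians) and `rmsd` (residual after alignment).
#' @export
fit_rigid_transform <- function(src, dst, allow_scale = FALSE) {
  src <- as.matrix(src)
  dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, ncol(dst) == 2, nrow(src) == nrow(dst), nrow(src) >= 2)
  cs <- colMeans(src)
  cd <- colMeans(dst)
  A <- sweep(src, 2, cs)
  B <- sweep(dst, 2, cd)
  H <- crossprod(A, B) # 2 x 2
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (allow_scale) sum(diag(D) %*% diag(sv$d, 2)) / sum(A^2) else 1
  tvec <- cd - s * as.vector(R %*% cs)
  fitted <- s * src %*% t(R) + matrix(tvec, nrow(src), 2, byrow = TRUE)
  list(
    R = R, s = s, t = tvec,
    angle = atan2(R[2, 1], R[1, 1]),
    rmsd = sqrt(mean(rowSums((fitted - dst)^2)))
  )
}

# Apply a rigid/similarity transform to an n x 2 point matrix.
transform_points <- function(p, tf) {
  p <- as.matrix(p)
  tf$s * p %*% t(tf$R) + matrix(tf$t, nrow(p), 2, byrow = TRUE)
}

# Invert a rigid/similarity transform.
invert_transform <- function(tf) {
  Rinv <- t(tf$R)
  sinv <- 1 / tf$s
  list(R = Rinv, s = sinv, t = -sinv * as.vector(Rinv %*% tf$t), angle = -tf$angle)
}

# Bilinear sample of a single frame at fractional (x, y) source coordinates.
# Out-of-field contributions are zero.
bilinear_sample <- function(frame, sx, sy) {
  h <- nrow(frame)
  w <- ncol(frame)
  x0 <- floor(sx)
  y0 <- floor(sy)
  fx <- sx - x0
  fy <- sy - y0
  out <- numeric(length(sx))
  fetch <- function(xi, yi) {
    ok <- xi >= 0 & xi <= (w - 1) & yi >= 0 & yi <= (h - 1)
    v <- numeric(length(xi))
    v[ok] <- frame[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  out <- (1 - fx) * (1 - fy) * fetch(x0, y0) +
    fx * (1 - fy) * fetch(x0 + 1, y0) +
    (1 - fx) * fy * fetch(x0, y0 + 1) +
    fx * fy * fetch(x0 + 1, y0 + 1)
  out
}

# Resample an H x W x T tensor under a forward transform `tf` (source -> target
# coordinates): every output pixel pulls from the source via the inverse map.
# The identical in-plane transform is applied to every frame.
warp_tensor <- function(tensor, tf) {
  d <- dim(tensor)
  inv <- invert_transform(tf)
  # output grid in (x, y), column-major like the array
  xs <- rep(0:(d[2] - 1), each = d[1])
  ys <- rep(0:(d[1] - 1), times = d[2])
  src <- transform_points(cbind(xs, ys), inv)
  out <- array(0, d)
  for (t in seq_len(d[3])) {
    out[, , t] <- bilinear_sample(tensor[, , t], src[, 1], src[, 2])
  }
  out
}
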