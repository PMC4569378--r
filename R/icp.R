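#' Optimal rigid alignment of corresponded point sets (Kabsch)
#'
#' Closed-form weighted least-squares rotation and translation mapping
#' `source` onto `target` over all proper rigid transforms. The SVD sign
#' correction guarantees a rotation with determinant +1 even when the best
#' orthogonal map would be a reflection; no scaling is estimated.
#'
#' @param source,target n x 3 matrices of corresponded points (n >= 3).
#' @param weights optional non-negative per-point weights.
#' @return a [rigid_transform] minimizing
#'   `sum(w_i * ||R s_i + t - t_i||^2)`.
#' @export
kabsch <- function(source, target, weights = NULL) {
  source <- as.matrix(source); target <- as.matrix(target)
  n <- nrow(source)
  if (n != nrow(target)) stop("source and target must have equal point counts")
  if (n < 3L) stop("at least 3 corresponded points are required")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stop("weights must be non-negative, one per point")
  wsum <- sum(weights)
  if (wsum <= 0) stop("weights must not all be zero")
  w <- weights / wsum
  cs <- colSums(source * w)
  ct <- colSums(target * w)
  S <- sweep(source, 2, cs)
  T_ <- sweep(target, 2, ct)
  H <- t(S * w) %*% T_
  # degenerate (collinear) configurations leave the rotation about the line
  # undetermined
  if (sum(svd(crossprod(S))$d > 1e-12 * max(1, sum(S^2))) < 2L)
    stop("degenerate point configuration: points are (near) collinear")
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  rigid_transform(R, as.numeric(ct - R %*% cs))
}

#' Nearest correspondences from points to a target
#'
#' For each query point, the closest entity of the target: the closest vertex
#' when the target is a point set, or the exact closest surface point
#' (triangle interior, edge or vertex) when the target is a mesh. The
#' accelerated mesh query uses a uniform spatial grid whose ring-expansion
#' bound guarantees results identical to the brute-force minimum.
#'
#' @param points n x 3 matrix (or [landmark_set]) of query points.
#' @param target a [hand_mesh] or m x 3 point matrix.
#' @param method `"grid"` (accelerated) or `"brute"`; mesh targets only.
#' @return list with `distance` (mm, per query), and either `index` (point
#'   targets) or `point` (closest surface points) plus `face`.
#' @export
nearest_correspondences <- function(points, target, method = c("grid", "brute")) {
  method <- match.arg(method)
  if (inherits(points, "landmark_set")) points <- points$points
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("no query points")
  if (inherits(target, "hand_mesh")) {
    if (method == "grid")
      cpp_closest_on_mesh_grid(points, target$vertices, target$faces - 1L)
    else
      cpp_closest_on_mesh_brute(points, target$vertices, target$faces - 1L)
  } else {
    target <- as.matrix(target)
    if (nrow(target) < 1L) stop("empty target")
    cpp_closest_points(points, target)
  }
}

#' Iterative closest point rigid registration
#'
#' Classic ICP: alternate nearest-correspondence search (source vertices to
#' the target surface, or to target points) with a closed-form Kabsch update,
#' until the root-mean-square correspondence distance changes by less than
#' `tol` (or itself falls below `tol`) or `max_iter` is reached. With `trim_fraction > 0` the largest
#' correspondence distances are discarded each iteration before the update,
#' which robustifies against unmatched regions. No scaling is applied. The
#' default initializer translates the source centroid onto the target
#' centroid; pass `init` (e.g. a landmark-based [kabsch] fit) for cold starts.
#'
#' @param source a [hand_mesh] or n x 3 point matrix (moved).
#' @param target a [hand_mesh] or m x 3 point matrix (fixed).
#' @param init optional initial [rigid_transform]; default centroid alignment.
#' @param max_iter maximum iterations (default 100).
#' @param tol stop when `|rms_k - rms_{k-1}| < tol` mm (default 1e-4).
#' @param trim_fraction fraction in `[0, 1)` of worst correspondences dropped
#'   per iteration (default 0, classic ICP).
#' @return an `icp_result`: `transform` ([rigid_transform] mapping source
#'   into the target frame), `rms` (mm, over the correspondences used at
#'   convergence), `iterations`, `converged`, and `rms_history`.
#' @export
icp_register <- function(source, target, init = NULL, max_iter = 100L,
                         tol = 1e-4, trim_fraction = 0) {
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (trim_fraction < 0 || trim_fraction >= 1)
    stop("trim_fraction must be in [0, 1)")
  src_pts <- if (inherits(source, "hand_mesh")) source$vertices else as.matrix(source)
  tgt_pts <- if (inherits(target, "hand_mesh")) target$vertices else as.matrix(target)
  if (is.null(init)) {
    init <- rigid_transform(diag(3), colMeans(tgt_pts) - colMeans(src_pts))
  }
  trans <- init
  rms_hist <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  it <- 0L
  n <- nrow(src_pts)
  keep_n <- max(3L, ceiling((1 - trim_fraction) * n))
  for (it in seq_len(max_iter)) {
    moved <- apply_transform(trans, src_pts)
    nc <- nearest_correspondences(moved, target)
    tgt_match <- if (!is.null(nc$point)) nc$point else tgt_pts[nc$index, , drop = FALSE]
    ord <- seq_len(n)
    if (trim_fraction > 0) {
      ord <- order(nc$distance)[seq_len(keep_n)]
      if (length(ord) < 3L) stop("fewer than 3 correspondences left after trimming")
    }
    rms <- sqrt(mean(nc$distance[ord]^2))
    rms_hist <- c(rms_hist, rms)
    if (rms < tol || abs(prev_rms - rms) < tol) { converged <- TRUE; break }
    prev_rms <- rms
    upd <- kabsch(moved[ord, , drop = FALSE], tgt_match[ord, , drop = FALSE])
    trans <- compose_transform(upd, trans)
  }
  structure(list(transform = trans, rms = rms_hist[length(rms_hist)],
                 iterations = it, converged = converged,
                 rms_history = rms_hist),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("ICP registration: rms %.4f mm after %d iteration%s (%s)\n",
              x$rms, x$iterations, if (x$iterations == 1) "" else "s",
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}
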