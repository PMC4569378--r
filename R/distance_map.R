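#' Exact point-to-triangle distance
#'
#' Minimum Euclidean distance from a point to a closed triangle, handling the
#' interior, edge and vertex regions exactly.
#'
#' @param p length-3 point.
#' @param tri 3 x 3 matrix, one triangle vertex per row.
#' @return distance in mm.
#' @export
point_to_triangle_distance <- function(p, tri) {
  tri <- as.matrix(tri)
  stopifnot(length(p) == 3L, all(dim(tri) == c(3L, 3L)))
  ab <- tri[2, ] - tri[1, ]
  ac <- tri[3, ] - tri[1, ]
  if (sqrt(sum(pracma_cross(ab, ac)^2)) / 2 <= 0)
    stop("zero-area triangle")
  cpp_point_tri_closest(as.numeric(p), tri)[1]
}

#' Surface-to-surface distance map
#'
#' Per-point unsigned Euclidean distance from each source vertex to the
#' target surface (exact closest point over all target triangles). The meshes
#' must already be registered: no transform is applied here. Optionally the
#' map is restricted to the source vertices of one anatomical region, e.g.
#' the palm, to probe how rigid that region is compared to the freely moving
#' fingers.
#'
#' @param source,target registered [hand_mesh] objects; one sample per
#'   source vertex.
#' @param regions optional [region_map] for `source`.
#' @param region optional region name (one of palm, thumb, index, middle,
#'   ring, little); requires `regions`.
#' @param method `"grid"` (accelerated; identical results) or `"brute"`.
#' @return a `distance_map`: `sample_points`, `distances` (mm, >= 0),
#'   `signed` (FALSE), `region` label used (or `"full"`), `index` of the
#'   source vertices sampled.
#' @export
surface_distance_map <- function(source, target, regions = NULL, region = NULL,
                                 method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(source, "hand_mesh"), inherits(target, "hand_mesh"))
  idx <- seq_len(nrow(source$vertices))
  reg_label <- "full"
  if (!is.null(region)) {
    if (is.null(regions)) stop("a region map is required to restrict to a region")
    if (length(regions) != nrow(source$vertices))
      stop("region map is not bound to the source mesh")
    if (!region %in% HAND_REGIONS)
      stop("unknown region ", sQuote(region), "; valid regions are: ",
           paste(HAND_REGIONS, collapse = ", "))
    idx <- which(as.character(regions) == region)
    if (!length(idx)) stop("no source vertices in region ", sQuote(region))
    reg_label <- region
  }
  pts <- source$vertices[idx, , drop = FALSE]
  nc <- nearest_correspondences(pts, target, method = method)
  structure(list(sample_points = pts, distances = nc$distance,
                 closest_points = nc$point, closest_face = nc$face,
                 signed = FALSE, region = reg_label, index = idx),
            class = "distance_map")
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

check_orientation <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  edges <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
                 cbind(f[, 3], f[, 1]))
  key <- (edges[, 1] - 1) * as.numeric(nv) + edges[, 2]
  if (anyDuplicated(key))
    stop("inconsistently oriented mesh: a directed edge is shared by two faces")
  invisible(TRUE)
}

#' Signed surface-to-surface distance map
#'
#' Same magnitudes as [surface_distance_map()], with a sign per sample:
#' positive when the source point lies on the outward-normal side of its
#' closest target point (i.e. outside the target surface), negative
#' otherwise. The target's faces must be consistently oriented; adjacent
#' faces that disagree are an error.
#'
#' @inheritParams surface_distance_map
#' @return a `distance_map` with `signed = TRUE` and an extra `sign` field;
#'   `distances` keeps the unsigned magnitudes.
#' @export
signed_surface_distance_map <- function(source, target,
                                        method = c("grid", "brute")) {
  method <- match.arg(method)
  check_orientation(target)
  dm <- surface_distance_map(source, target, method = method)
  nrm <- face_normals(target)
  d <- dm$sample_points - dm$closest_points
  sgn <- sign(rowSums(d * nrm[dm$closest_face, , drop = FALSE]))
  sgn[sgn == 0] <- 1
  dm$signed <- TRUE
  dm$sign <- sgn
  dm
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("%s distance map (%s region): %d samples, mean %.3f mm, max %.3f mm\n",
              if (isTRUE(x$signed)) "Signed" else "Unsigned",
              x$region, length(x$distances),
              mean(x$distances), max(x$distances)))
  invisible(x)
}

#' Reproducibility summary of a distance map
#'
#' The absolute mean, 50th and 90th percentile of the per-point registration
#' error, in millimetres. Percentiles use linear interpolation between order
#' statistics (R's default quantile type 7).
#'
#' @param object a `distance_map`.
#' @param ... unused.
#' @return a `repro_summary`: `abs_mean`, `p50`, `p90` (mm), `n_points`,
#'   `region`.
#' @export
summary.distance_map <- function(object, ...) {
  d <- abs(object$distances)
  if (!length(d)) stop("empty distance map")
  q <- unname(quantile(d, c(0.5, 0.9), type = 7))
  structure(list(abs_mean = mean(d), p50 = q[1], p90 = q[2],
                 n_points = length(d), region = object$region),
            class = "repro_summary")
}

#' @export
print.repro_summary <- function(x, ...) {
  cat(sprintf("Registration error (%s, n = %d): abs mean %.2f mm, p50 %.2f mm, p90 %.2f mm\n",
              x$region, x$n_points, x$abs_mean, x$p50, x$p90))
  invisible(x)
}
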