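#' @useDynLib handmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile cov sd pt rlnorm median dist t.test
#'   coef predict residuals simulate
#' @importFrom utils read.csv write.csv head
NULL

HAND_REGIONS <- c("palm", "thumb", "index", "middle", "ring", "little")
DIGITS <- c("thumb", "index", "middle", "ring", "little")

#' Triangle surface mesh
#'
#' Construct a triangle mesh from a vertex matrix and a face index matrix.
#' Coordinates are millimetres in a right-handed frame. All invariants are
#' validated: faces must reference valid vertices with three distinct indices,
#' coordinates must be finite, and at least one face must be present.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @return an object of class `hand_mesh` with elements `vertices` and `faces`.
#' @export
hand_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) < 1L) stop("mesh must have at least one face")
  if (!all(is.finite(vertices))) stop("vertex coordinates must all be finite")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range: faces must reference vertices 1..",
         nrow(vertices))
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
          faces[, 2] == faces[, 3]))
    stop("degenerate face: each face needs three distinct vertex indices")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "hand_mesh")
}

#' @export
print.hand_mesh <- function(x, ...) {
  rng <- apply(x$vertices, 2, range)
  cat("Triangle mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces\n")
  cat(sprintf("  extent (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Named anatomical landmark set
#'
#' An ordered, labelled set of 3D anatomical points on one hand. Two landmark
#' sets are comparable only when their schema and label order match; readers
#' and constructors normalise point order to the schema order.
#'
#' @param points numeric matrix, L x 3, with rownames giving landmark labels.
#' @param schema character vector of labels defining the schema order, or a
#'   schema name resolvable by [landmark_schema()]. Defaults to the labels of
#'   `points` in their given order.
#' @param schema_id name of the schema.
#' @param side `"left"` or `"right"`.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, schema = rownames(points),
                         schema_id = "custom", side = c("right", "left")) {
  side <- match.arg(side)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an L x 3 matrix")
  labs <- rownames(points)
  if (is.null(labs)) stop("points must have rownames giving landmark labels")
  if (anyDuplicated(labs)) stop("duplicate landmark label: ",
                                labs[duplicated(labs)][1])
  if (is.character(schema) && length(schema) == 1L && !is.null(names(schema)))
    schema <- unname(schema)
  if (length(schema) == 1L && !schema %in% labs)
    schema <- landmark_schema(schema)$labels
  missing_lab <- setdiff(schema, labs)
  if (length(missing_lab))
    stop("landmark(s) missing from schema: ", paste(missing_lab, collapse = ", "))
  extra <- setdiff(labs, schema)
  if (length(extra))
    stop("label(s) outside schema: ", paste(extra, collapse = ", "))
  points <- points[schema, , drop = FALSE]
  colnames(points) <- NULL
  if (!all(is.finite(points))) stop("landmark coordinates must all be finite")
  structure(list(points = points, schema_id = schema_id, side = side),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Landmark set:", nrow(x$points), "landmarks, schema", sQuote(x$schema_id),
      paste0("(", x$side, " hand)\n"))
  invisible(x)
}

#' Per-vertex anatomical region labels
#'
#' Assigns every vertex of a mesh to one of six anatomical subregions: palm,
#' thumb, index, middle, ring, little.
#'
#' @param labels character vector of region names, one per mesh vertex.
#' @param mesh the `hand_mesh` the labels belong to (for length validation).
#' @return an object of class `region_map` (a factor over the six regions).
#' @export
region_map <- function(labels, mesh = NULL) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), HAND_REGIONS)
  if (length(bad))
    stop("unknown region name(s) ", paste(sQuote(bad), collapse = ", "),
         "; valid regions are: ", paste(HAND_REGIONS, collapse = ", "))
  if (!is.null(mesh) && length(labels) != nrow(mesh$vertices))
    stop("region label count (", length(labels),
         ") does not match vertex count (", nrow(mesh$vertices), ")")
  structure(factor(labels, levels = HAND_REGIONS), class = c("region_map", "factor"))
}

#' @export
print.region_map <- function(x, ...) {
  cat("Region map over", length(x), "vertices:\n")
  print(table(factor(x, levels = HAND_REGIONS)))
  invisible(x)
}

#' Rigid transform (rotation + translation)
#'
#' A proper rigid-body transform: an orthonormal rotation with determinant +1
#' and a translation in mm. No scaling: size differences between hands are a
#' finding, so every registration in this package is strictly rigid.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (length(translation) != 3L) stop("translation must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal (tolerance 1e-8)")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper (det +1); reflections are not rigid")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("Rigid transform: rotation %.4f rad, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `t1` first, then `t2`.
#'
#' @param t2,t1 `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transform <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a rigid transform
#'
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.numeric(t(t$rotation) %*% t$translation))
}

#' Rotation angle of a rotation matrix
#'
#' Angle (radians) of the axis-angle representation; 0 for the identity.
#' Useful as a scalar measure of how far a recovered transform is from the
#' one that was applied.
#'
#' @param R 3 x 3 rotation matrix.
#' @return angle in radians in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  # atan2 on the skew part is well conditioned near the identity, where
  # acos((tr - 1) / 2) loses half the significant digits
  s <- sqrt(sum((R - t(R))^2)) / (2 * sqrt(2))
  c <- (sum(diag(R)) - 1) / 2
  atan2(min(1, s), max(-1, min(1, c)))
}

#' Apply a rigid transform
#'
#' Maps every point to `R p + t`. Faces, labels and region assignments are
#' untouched.
#'
#' @param t a `rigid_transform`.
#' @param x a `hand_mesh`, `landmark_set`, or n x 3 point matrix.
#' @return an object of the same type as `x`.
#' @export
apply_transform <- function(t, x) UseMethod("apply_transform", x)

#' @export
apply_transform.matrix <- function(t, x) {
  sweep(x %*% t(t$rotation), 2, -t$translation)
}

#' @export
apply_transform.hand_mesh <- function(t, x) {
  x$vertices <- apply_transform(t, x$vertices)
  x
}

#' @export
apply_transform.landmark_set <- function(t, x) {
  pts <- apply_transform(t, x$points)
  rownames(pts) <- rownames(x$points)
  x$points <- pts
  x
}

#' @export
apply_transform.default <- function(t, x) {
  apply_transform(t, as.matrix(x))
}

#' Random rigid rotation helpers
#'
#' Draw a rotation matrix about a uniformly random axis with a Gaussian angle.
#' @param sd_deg angle standard deviation in degrees.
#' @return 3 x 3 rotation matrix.
#' @keywords internal
random_rotation <- function(sd_deg) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- rnorm(1, 0, sd_deg * pi / 180)
  axis_angle_rotation(ax, ang)
}

#' Rotation about an axis by an angle (Rodrigues)
#' @param axis unit 3-vector.
#' @param angle radians.
#' @return 3 x 3 rotation matrix.
#' @keywords internal
axis_angle_rotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
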