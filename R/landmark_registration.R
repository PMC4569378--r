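check_same_schema <- function(a, b) {
  if (!identical(a$schema_id, b$schema_id) ||
      !identical(rownames(a$points), rownames(b$points)))
    stop("landmark sets are not comparable: schema or label order differ")
  invisible(TRUE)
}

#' Rigid Procrustes alignment of one landmark set onto a reference
#'
#' Label-matched rigid (no scaling) least-squares superposition via
#' [kabsch()]. Scale is deliberately preserved: size differences between
#' hands are a finding, not a nuisance parameter.
#'
#' @param moving,reference [landmark_set] objects with identical schema and
#'   label order.
#' @return list with `transform` (the [rigid_transform]), `rms` (mm,
#'   root-mean-square residual after alignment) and `aligned` (the moved
#'   landmark set).
#' @export
procrustes_align <- function(moving, reference) {
  stopifnot(inherits(moving, "landmark_set"), inherits(reference, "landmark_set"))
  check_same_schema(moving, reference)
  tr <- kabsch(moving$points, reference$points)
  aligned <- apply_transform(tr, moving)
  rms <- sqrt(mean(rowSums((aligned$points - reference$points)^2)))
  list(transform = tr, rms = rms, aligned = aligned)
}

landmark_array <- function(sets) {
  L <- nrow(sets[[1]]$points)
  arr <- array(NA_real_, c(L, 3, length(sets)),
               dimnames = list(rownames(sets[[1]]$points), NULL, NULL))
  for (i in seq_along(sets)) arr[, , i] <- sets[[i]]$points
  arr
}

mean_landmark_set <- function(sets) {
  arr <- landmark_array(sets)
  m <- apply(arr, c(1, 2), mean)
  rownames(m) <- rownames(sets[[1]]$points)
  landmark_set(m, schema = rownames(m), schema_id = sets[[1]]$schema_id,
               side = sets[[1]]$side)
}

pooled_rms <- function(sets, mean_lm) {
  sq <- vapply(sets, function(s) rowSums((s$points - mean_lm$points)^2),
               numeric(nrow(mean_lm$points)))
  list(per_specimen = sqrt(colMeans(as.matrix(sq))),
       overall = sqrt(mean(sq)))
}

#' Average landmark configuration with variation ellipsoids
#'
#' Landmark-wise arithmetic mean over aligned sets, per-landmark 3 x 3 sample
#' covariance (denominator n - 1), and variation ellipsoids whose semi-axes
#' are two standard deviations: 2 * sqrt(eigenvalues), with axes the
#' covariance eigenvectors, sorted by decreasing semi-axis.
#'
#' @param aligned list of >= 2 [landmark_set] objects in a common frame.
#' @return an `average_hand_model`: `mean_landmarks`, `covariances` (list of
#'   3 x 3, mm^2), `ellipsoid_semi_axes` (L x 3, mm, descending),
#'   `ellipsoid_axes` (list of 3 x 3 eigenvector matrices), `n_specimens`.
#' @export
compute_average <- function(aligned) {
  if (length(aligned) < 2L)
    stop("at least 2 aligned sets are required (covariance undefined for n < 2)")
  for (s in aligned[-1]) check_same_schema(aligned[[1]], s)
  arr <- landmark_array(aligned)
  mean_lm <- mean_landmark_set(aligned)
  L <- dim(arr)[1]
  covs <- vector("list", L)
  semi <- matrix(0, L, 3, dimnames = list(rownames(mean_lm$points), NULL))
  axes <- vector("list", L)
  for (l in seq_len(L)) {
    X <- t(arr[l, , ])           # n x 3
    C <- cov(X)
    e <- eigen(C, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    covs[[l]] <- C
    semi[l, ] <- 2 * sqrt(ev)    # eigen() sorts decreasing
    axes[[l]] <- e$vectors
  }
  names(covs) <- names(axes) <- rownames(mean_lm$points)
  structure(list(mean_landmarks = mean_lm, covariances = covs,
                 ellipsoid_semi_axes = semi, ellipsoid_axes = axes,
                 n_specimens = length(aligned)),
            class = "average_hand_model")
}

#' @export
print.average_hand_model <- function(x, ...) {
  cat("Average hand model:", nrow(x$mean_landmarks$points), "landmarks over",
      x$n_specimens, "specimens\n")
  cat(sprintf("  mean largest ellipsoid semi-axis (2 sd): %.3f mm\n",
              mean(x$ellipsoid_semi_axes[, 1])))
  invisible(x)
}

#' Pooled RMS error of a registration run
#'
#' Root of the mean, over all specimens and all landmarks, of squared
#' landmark-to-mean distances: the precision measure of the computed average
#' model. Invariant to a common rigid transform of all aligned sets and the
#' mean.
#'
#' @param aligned list of aligned [landmark_set]s (or a registration run
#'   containing `$aligned_sets`).
#' @param model an `average_hand_model` sharing the schema.
#' @return RMS in mm.
#' @export
rms_error <- function(aligned, model) {
  if (!is.null(aligned$aligned_sets)) aligned <- aligned$aligned_sets
  for (s in aligned) check_same_schema(s, model$mean_landmarks)
  pooled_rms(aligned, model$mean_landmarks)$overall
}

validate_cohort_sets <- function(sets) {
  if (length(sets) < 2L) stop("at least 2 landmark sets are required")
  side <- unique(vapply(sets, function(s) s$side, character(1)))
  if (length(side) > 1L)
    stop("mixed sides: left and right hands are never pooled in one registration")
  for (s in sets[-1]) check_same_schema(sets[[1]], s)
  invisible(TRUE)
}

#' Groupwise registration, method 1: whole-hand rigid Procrustes
#'
#' Generalized (groupwise) rigid Procrustes over complete landmark sets.
#' Pass 1 aligns every set to a randomly selected reference set and averages;
#' each further pass re-aligns every original set to the current average and
#' re-averages. The canonical procedure uses two passes (random reference,
#' then the average as reference); `n_passes` can be raised to iterate
#' further.
#'
#' @param sets list of >= 2 [landmark_set]s, one schema, one side.
#' @param seed integer seed (reference selection).
#' @param n_passes number of passes, >= 2.
#' @return list with `run` (`registration_run`: `method`, `aligned_sets`,
#'   `per_specimen_rms`, `overall_rms`, `reference_history`) and `model`
#'   (`average_hand_model`).
#' @export
register_method1 <- function(sets, seed = 1L, n_passes = 2L) {
  validate_cohort_sets(sets)
  if (n_passes < 2L) stop("n_passes must be >= 2")
  with_seed(seed, {
    ref_id <- sample.int(length(sets), 1L)
    reference <- sets[[ref_id]]
    ref_hist <- as.character(ref_id)
    aligned <- sets
    for (pass in seq_len(n_passes)) {
      aligned <- lapply(sets, function(s) procrustes_align(s, reference)$aligned)
      reference <- mean_landmark_set(aligned)
      if (pass < n_passes) ref_hist <- c(ref_hist, "average")
    }
    model <- compute_average(aligned)
    r <- pooled_rms(aligned, model$mean_landmarks)
    run <- structure(list(method = "method1", aligned_sets = aligned,
                          per_specimen_rms = r$per_specimen,
                          overall_rms = r$overall,
                          reference_history = ref_hist),
                     class = "registration_run")
    list(run = run, model = model)
  })
}

#' @export
print.registration_run <- function(x, ...) {
  cat(sprintf("Groupwise registration (%s): %d specimens, overall RMS %.4f mm\n",
              x$method, length(x$aligned_sets), x$overall_rms))
  invisible(x)
}

region_landmark_labels <- function(region) {
  if (region == "palm")
    c("palm_base_radial", "palm_base_ulnar", "palm_top_radial", "palm_top_ulnar",
      paste0(DIGITS, "_base"))
  else paste0(region, c("_tip", "_distal", "_proximal", "_base"))
}

region_submesh <- function(mesh, regions, region) {
  sel <- which(as.character(regions) == region)
  if (length(sel) < 3L) return(NULL)
  keep <- matrix(mesh$faces %in% sel, ncol = 3)
  fi <- which(rowSums(keep) == 3L)
  if (!length(fi)) return(NULL)
  remap <- integer(nrow(mesh$vertices))
  remap[sel] <- seq_along(sel)
  hand_mesh(mesh$vertices[sel, , drop = FALSE],
            matrix(remap[mesh$faces[fi, ]], ncol = 3))
}

align_subregions <- function(specimen, ref_landmarks, ref_mesh, ref_regions,
                             use_surface, icp_max_iter, icp_tol,
                             landmark_labels_of) {
  lm <- specimen$landmarks
  out <- lm$points
  for (reg in HAND_REGIONS) {
    labs <- landmark_labels_of(reg)
    labs <- labs[labs %in% rownames(lm$points)]
    if (length(labs) < 3L)
      stop("subregion ", sQuote(reg), " has fewer than 3 landmarks")
    tr <- kabsch(lm$points[labs, , drop = FALSE],
                 ref_landmarks$points[labs, , drop = FALSE])
    if (use_surface && !is.null(specimen$mesh) && !is.null(ref_mesh)) {
      src <- specimen$mesh$vertices[as.character(specimen$regions) == reg, ,
                                    drop = FALSE]
      tgt <- region_submesh(ref_mesh, ref_regions, reg)
      if (!is.null(tgt) && nrow(src) >= 3L) {
        res <- icp_register(src, tgt, init = tr, max_iter = icp_max_iter,
                            tol = icp_tol)
        tr <- res$transform
      }
    }
    out[labs, ] <- apply_transform(tr, lm$points[labs, , drop = FALSE])
  }
  landmark_set(out, schema = rownames(lm$points), schema_id = lm$schema_id,
               side = lm$side)
}

#' Groupwise registration, method 2: per-subregion adapted ICP
#'
#' An adapted iterative-closest-point registration in which each hand is
#' divided into six anatomical subregions (palm, thumb, index, middle, ring,
#' little) that are registered independently: the subregion's landmarks are
#' rigidly matched to the reference subregion (Kabsch) and, when meshes are
#' supplied, refined by rigid surface ICP of the subregion's vertices against
#' the reference subregion surface. The aligned landmark set is re-assembled
#' from the per-region alignments. As in method 1, pass 1 uses a randomly
#' selected reference specimen and later passes use the current average as
#' reference; the average surface targeted by the ICP in later passes is the
#' pass-1 reference mesh warped onto the current mean landmarks by a
#' thin-plate spline.
#'
#' Because a digit's articulation between captures is (to good approximation)
#' a rigid motion of that digit, per-subregion registration absorbs it, which
#' whole-hand Procrustes cannot.
#'
#' @param specimens list of specimen lists, each with `landmarks`
#'   ([landmark_set]) and optionally `mesh` ([hand_mesh]) and `regions`
#'   ([region_map]).
#' @param seed integer seed (reference selection).
#' @param n_passes number of passes, >= 2.
#' @param use_surface refine per-region transforms with surface ICP when
#'   meshes are present (default TRUE).
#' @param icp_max_iter,icp_tol ICP refinement controls.
#' @param region_labels function mapping a region name to its landmark
#'   labels; the default follows the `hand24` schema (digit base landmarks
#'   count towards both their digit and the palm).
#' @return list with `run` (`registration_run`) and `model`
#'   (`average_hand_model`, including `average_surface` when meshes are
#'   given).
#' @export
register_method2 <- function(specimens, seed = 1L, n_passes = 2L,
                             use_surface = TRUE, icp_max_iter = 30L,
                             icp_tol = 1e-3,
                             region_labels = region_landmark_labels) {
  if (length(specimens) < 2L) stop("at least 2 specimens are required")
  sets <- lapply(specimens, `[[`, "landmarks")
  validate_cohort_sets(sets)
  have_meshes <- all(vapply(specimens, function(s)
    !is.null(s$mesh) && !is.null(s$regions), logical(1)))
  with_seed(seed, {
    ref_id <- sample.int(length(specimens), 1L)
    ref <- specimens[[ref_id]]
    ref_hist <- as.character(ref_id)
    ref_landmarks <- ref$landmarks
    ref_mesh <- if (have_meshes) ref$mesh else NULL
    ref_regions <- if (have_meshes) ref$regions else NULL
    aligned <- NULL
    model <- NULL
    for (pass in seq_len(n_passes)) {
      aligned <- lapply(specimens, align_subregions,
                        ref_landmarks = ref_landmarks, ref_mesh = ref_mesh,
                        ref_regions = ref_regions,
                        use_surface = use_surface && have_meshes,
                        icp_max_iter = icp_max_iter, icp_tol = icp_tol,
                        landmark_labels_of = region_labels)
      model <- compute_average(aligned)
      if (pass < n_passes) {
        ref_landmarks <- model$mean_landmarks
        if (have_meshes) {
          ref_mesh <- build_average_surface(specimens[[ref_id]]$mesh,
                                            specimens[[ref_id]]$landmarks,
                                            model)
          ref_regions <- specimens[[ref_id]]$regions
        }
        ref_hist <- c(ref_hist, "average")
      }
    }
    if (have_meshes)
      model$average_surface <- build_average_surface(specimens[[ref_id]]$mesh,
                                                     specimens[[ref_id]]$landmarks,
                                                     model)
    r <- pooled_rms(aligned, model$mean_landmarks)
    run <- structure(list(method = "method2", aligned_sets = aligned,
                          per_specimen_rms = r$per_specimen,
                          overall_rms = r$overall,
                          reference_history = ref_hist),
                     class = "registration_run")
    list(run = run, model = model)
  })
}

# thin-plate spline interpolant in 3D (kernel U(r) = r), exact at the
# control points; reproduces affine (hence rigid) maps exactly
tps_fit <- function(src, dst) {
  n <- nrow(src)
  D <- as.matrix(dist(src))
  if (any(D[upper.tri(D)] < 1e-9))
    stop("coincident source landmarks: thin-plate spline undefined")
  P <- cbind(1, src)
  A <- rbind(cbind(D, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(dst, matrix(0, 4, 3))
  sol <- solve(A, rhs)
  list(w = sol[seq_len(n), , drop = FALSE],
       a = sol[n + 1:4, , drop = FALSE], src = src)
}

tps_eval <- function(fit, x) {
  D2 <- outer(rowSums(x^2), rep(1, nrow(fit$src))) +
        outer(rep(1, nrow(x)), rowSums(fit$src^2)) -
        2 * x %*% t(fit$src)
  K <- sqrt(pmax(D2, 0))
  K %*% fit$w + cbind(1, x) %*% fit$a
}

#' Average hand surface by thin-plate-spline warping
#'
#' The groupwise registration averages landmarks, not surfaces; to obtain an
#' average surface, a reference specimen's mesh is warped by the thin-plate
#' spline interpolant that carries the reference landmarks exactly onto the
#' model's mean landmarks. Topology (faces) is unchanged. When the mean
#' landmarks are a rigid transform of the reference landmarks, the spline
#' reduces to that rigid map.
#'
#' @param reference_mesh a [hand_mesh] whose landmarks are known.
#' @param reference_landmarks [landmark_set] on the reference mesh.
#' @param model an `average_hand_model` with the same schema.
#' @return the warped [hand_mesh].
#' @export
build_average_surface <- function(reference_mesh, reference_landmarks, model) {
  check_same_schema(reference_landmarks, model$mean_landmarks)
  fit <- tps_fit(reference_landmarks$points, model$mean_landmarks$points)
  hand_mesh(tps_eval(fit, reference_mesh$vertices), reference_mesh$faces)
}

#' Mirror a hand across the x = 0 plane
#'
#' Utility for optionally pooling left and right hands: reflects a mesh or
#' landmark set and (for meshes) reverses face winding so the surface
#' orientation stays consistent. Pooling is off by default everywhere;
#' registrations never mix sides.
#'
#' @param x a [hand_mesh] or [landmark_set].
#' @return the mirrored object (landmark sets get the opposite `side`).
#' @export
mirror_hand <- function(x) {
  if (inherits(x, "hand_mesh")) {
    v <- x$vertices; v[, 1] <- -v[, 1]
    hand_mesh(v, x$faces[, c(1, 3, 2)])
  } else if (inherits(x, "landmark_set")) {
    p <- x$points; p[, 1] <- -p[, 1]
    landmark_set(p, schema = rownames(p), schema_id = x$schema_id,
                 side = if (x$side == "left") "right" else "left")
  } else stop("cannot mirror object of class ", class(x)[1])
}
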