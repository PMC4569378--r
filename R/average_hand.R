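#' Fit an average hand model to a cohort
#'
#' The central estimator of the package: given repeated landmark sets (and
#' optionally their surfaces), groupwise rigid registration brings all
#' specimens into a common frame and the landmark-wise mean configuration,
#' per-landmark covariances and 2-standard-deviation variation ellipsoids are
#' estimated. Two registration methods are available: `"procrustes"`
#' (method 1, whole-hand generalized rigid Procrustes) and `"subregion"`
#' (method 2, per-subregion adapted ICP, which absorbs finger articulation).
#' Neither method scales: hand size is preserved as signal.
#'
#' @param specimens either a list of [landmark_set]s, or a list of specimen
#'   lists with `landmarks` and optionally `mesh` + `regions` (e.g. the
#'   subjects of [generate_cohort()]).
#' @param method `"procrustes"` (method 1) or `"subregion"` (method 2).
#' @param seed integer seed used for random reference selection.
#' @param n_passes registration passes (>= 2; pass 1 registers to a random
#'   reference specimen, later passes to the running average).
#' @param ... further arguments passed to [register_method2()]
#'   (`use_surface`, `icp_max_iter`, `icp_tol`).
#' @return an object of class `average_hand` combining the fitted
#'   `average_hand_model` and the `registration_run`; supports `print()`,
#'   `summary()`, `coef()` (mean landmark matrix), `residuals()`,
#'   `predict()`, `simulate()` and `plot()`.
#' @examples
#' cohort <- generate_cohort(3, seed = 1)
#' fit <- average_hand(cohort, method = "subregion", seed = 1)
#' fit
#' head(coef(fit))
#' @export
average_hand <- function(specimens, method = c("procrustes", "subregion"),
                         seed = 1L, n_passes = 2L, ...) {
  method <- match.arg(method)
  is_lmset <- vapply(specimens, inherits, logical(1), "landmark_set")
  if (method == "procrustes") {
    sets <- if (all(is_lmset)) specimens else lapply(specimens, `[[`, "landmarks")
    res <- register_method1(sets, seed = seed, n_passes = n_passes)
  } else {
    specs <- if (all(is_lmset))
      lapply(specimens, function(s) list(landmarks = s)) else specimens
    res <- register_method2(specs, seed = seed, n_passes = n_passes, ...)
  }
  structure(c(res$model,
              list(run = res$run, method = method, seed = seed,
                   n_passes = n_passes, call = match.call())),
            class = c("average_hand", "average_hand_model"))
}

#' @export
print.average_hand <- function(x, ...) {
  cat("Average hand model (", x$method, " registration, ",
      x$n_specimens, " specimens, ", x$n_passes, " passes)\n", sep = "")
  cat(sprintf("  overall RMS error: %.4f mm\n", x$run$overall_rms))
  cat(sprintf("  mean largest ellipsoid semi-axis (2 sd): %.3f mm\n",
              mean(x$ellipsoid_semi_axes[, 1])))
  if (!is.null(x$average_surface))
    cat("  average surface:", nrow(x$average_surface$vertices), "vertices\n")
  invisible(x)
}

#' @export
summary.average_hand <- function(object, ...) {
  tab <- data.frame(
    landmark = rownames(object$mean_landmarks$points),
    semi_a = object$ellipsoid_semi_axes[, 1],
    semi_b = object$ellipsoid_semi_axes[, 2],
    semi_c = object$ellipsoid_semi_axes[, 3],
    row.names = NULL
  )
  structure(list(method = object$method,
                 n_specimens = object$n_specimens,
                 overall_rms = object$run$overall_rms,
                 per_specimen_rms = object$run$per_specimen_rms,
                 ellipsoids = tab),
            class = "summary.average_hand")
}

#' @export
print.summary.average_hand <- function(x, ...) {
  cat("Average hand model —", x$method, "registration\n")
  cat(sprintf("  specimens: %d   overall RMS: %.4f mm\n",
              x$n_specimens, x$overall_rms))
  cat(sprintf("  per-specimen RMS (mm): min %.4f, median %.4f, max %.4f\n",
              min(x$per_specimen_rms), median(x$per_specimen_rms),
              max(x$per_specimen_rms)))
  cat("  variation ellipsoid semi-axes (2 sd, mm), largest landmarks:\n")
  o <- order(-x$ellipsoids$semi_a)
  print(head(x$ellipsoids[o, ], 5), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.average_hand <- function(object, ...) object$mean_landmarks$points

#' @export
residuals.average_hand <- function(object, ...) {
  m <- object$mean_landmarks$points
  res <- lapply(object$run$aligned_sets, function(s) s$points - m)
  arr <- array(unlist(res), c(nrow(m), 3, length(res)),
               dimnames = list(rownames(m), c("x", "y", "z"), NULL))
  arr
}

#' Align a new landmark set into a fitted model's frame
#'
#' Rigidly superimposes `newdata` on the model's mean configuration and
#' returns the aligned set plus its RMS distance to the mean: how well a new
#' hand conforms to the average.
#'
#' @param object an `average_hand` fit.
#' @param newdata a [landmark_set] with the model's schema.
#' @param ... unused.
#' @return list with `aligned` ([landmark_set]) and `rms` (mm).
#' @export
predict.average_hand <- function(object, newdata, ...) {
  pa <- procrustes_align(newdata, object$mean_landmarks)
  list(aligned = pa$aligned, rms = pa$rms)
}

#' Simulate landmark sets from a fitted average hand model
#'
#' Draws each landmark independently from its fitted trivariate normal
#' distribution (mean position, per-landmark covariance).
#'
#' @param object an `average_hand` fit.
#' @param nsim number of landmark sets to draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` [landmark_set]s.
#' @export
simulate.average_hand <- function(object, nsim = 1, seed = 1L, ...) {
  m <- object$mean_landmarks$points
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      pts <- m
      for (l in seq_len(nrow(m))) {
        C <- object$covariances[[l]]
        e <- eigen(C, symmetric = TRUE)
        A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 3)
        pts[l, ] <- m[l, ] + as.numeric(A %*% rnorm(3))
      }
      landmark_set(pts, schema = rownames(m),
                   schema_id = object$mean_landmarks$schema_id,
                   side = object$mean_landmarks$side)
    })
  })
}

#' Plot an average hand model
#'
#' Projects the aligned landmark clouds, the mean configuration and the
#' 2-standard-deviation variation ellipses (the ellipsoids' projection onto
#' the chosen plane) onto a coordinate plane.
#'
#' @param x an `average_hand` fit.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.average_hand <- function(x, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  ij <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  m <- x$mean_landmarks$points[, ij, drop = FALSE]
  pts <- do.call(rbind, lapply(x$run$aligned_sets,
                               function(s) s$points[, ij, drop = FALSE]))
  graphics::plot(pts, pch = 16, cex = 0.4, col = "grey60",
                 xlab = paste0(substr(plane, 1, 1), " (mm)"),
                 ylab = paste0(substr(plane, 2, 2), " (mm)"),
                 main = sprintf("Average hand (%s), 2 sd ellipses", x$method),
                 asp = 1, ...)
  graphics::points(m, pch = 3, col = "red")
  th <- seq(0, 2 * pi, length.out = 60)
  for (l in seq_len(nrow(m))) {
    C2 <- x$covariances[[l]][ij, ij]
    e <- eigen(C2, symmetric = TRUE)
    A <- e$vectors %*% diag(2 * sqrt(pmax(e$values, 0)), 2)
    ell <- t(A %*% rbind(cos(th), sin(th))) + matrix(m[l, ], 60, 2, byrow = TRUE)
    graphics::lines(ell, col = "steelblue")
  }
  invisible(x)
}
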