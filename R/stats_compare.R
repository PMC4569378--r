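#' Paired t-test between two methods' per-specimen errors
#'
#' Two-sided paired t-test on differences `a - b`, pairing by specimen:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom. The
#' significance level follows the study convention of 5%. The standard case
#' delegates to [stats::t.test()]; the degenerate zero-variance case (all
#' paired differences identical) is handled explicitly: p = 1 when the common
#' difference is zero, otherwise p = 0 with a warning, since the t statistic
#' is not defined there.
#'
#' @param errors_a,errors_b numeric vectors of per-specimen errors (mm),
#'   equal length `n >= 2`, paired by position.
#' @return a `paired_t_result`: `t_statistic`, `degrees_of_freedom`,
#'   `p_value`, `mean_difference` (mm, a - b), `significant_at_5pct`.
#' @export
paired_t_test <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b))
    stop("errors_a and errors_b must pair up: unequal lengths")
  n <- length(errors_a)
  if (n < 2L) stop("paired t-test needs at least 2 pairs")
  d <- errors_a - errors_b
  md <- mean(d)
  if (sd(d) == 0) {
    if (md == 0) {
      res <- list(t_statistic = 0, degrees_of_freedom = n - 1L, p_value = 1,
                  mean_difference = 0)
    } else {
      warning("zero variance of paired differences with nonzero mean; p reported as 0")
      res <- list(t_statistic = sign(md) * Inf, degrees_of_freedom = n - 1L,
                  p_value = 0, mean_difference = md)
    }
  } else {
    tt <- stats::t.test(errors_a, errors_b, paired = TRUE)
    res <- list(t_statistic = unname(tt$statistic),
                degrees_of_freedom = unname(tt$parameter),
                p_value = tt$p.value, mean_difference = md)
  }
  res$significant_at_5pct <- res$p_value < 0.05
  class(res) <- "paired_t_result"
  res
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4f, df = %d, p = %.4g, mean difference %.4f mm (%ssignificant at 5%%)\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              x$mean_difference, if (x$significant_at_5pct) "" else "not "))
  invisible(x)
}

#' Compare male and female average hands
#'
#' Rigidly registers (no scaling, so the size difference survives as signal)
#' the female average surface onto the male average surface via landmark
#' Procrustes refined by surface ICP, then computes the signed distance map
#' with the male surface as source — positive distances mean the male surface
#' lies outside the female one — and per-landmark 3D deltas (male mean minus
#' female mean) in the common frame.
#'
#' @param male_model,female_model `average_hand_model` / `average_hand`
#'   objects sharing one schema, each carrying an `average_surface`.
#' @param refine_icp refine the rigid alignment by surface ICP (default
#'   TRUE).
#' @return a `group_contrast`: `signed_map` (a `distance_map`),
#'   `landmark_deltas` (L x 3 mm), `mean_signed_distance` (mm),
#'   `fraction_male_outside`.
#' @export
compare_sex_averages <- function(male_model, female_model, refine_icp = TRUE) {
  check_same_schema(male_model$mean_landmarks, female_model$mean_landmarks)
  if (is.null(male_model$average_surface) || is.null(female_model$average_surface))
    stop("both models must carry an average surface")
  # bring the female average into the male frame (rigid only)
  pa <- procrustes_align(female_model$mean_landmarks, male_model$mean_landmarks)
  tr <- pa$transform
  f_surf <- apply_transform(tr, female_model$average_surface)
  if (refine_icp) {
    res <- icp_register(f_surf, male_model$average_surface, max_iter = 50L)
    f_surf <- apply_transform(res$transform, f_surf)
    tr <- compose_transform(res$transform, tr)
  }
  f_lm <- apply_transform(tr, female_model$mean_landmarks)
  dmap <- signed_surface_distance_map(male_model$average_surface, f_surf)
  signed <- dmap$sign * dmap$distances
  deltas <- male_model$mean_landmarks$points - f_lm$points
  structure(list(signed_map = dmap,
                 landmark_deltas = deltas,
                 mean_signed_distance = mean(signed),
                 fraction_male_outside = mean(signed > 0),
                 male_landmarks = male_model$mean_landmarks,
                 female_landmarks_aligned = f_lm,
                 female_to_male_transform = tr),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("Male vs female average hands: mean signed distance %.3f mm (male %s female)\n",
              x$mean_signed_distance,
              if (x$mean_signed_distance > 0) "outside" else "inside"))
  cat(sprintf("  fraction of male surface outside female: %.2f\n",
              x$fraction_male_outside))
  tips <- grep("_tip$", rownames(x$landmark_deltas))
  cat(sprintf("  mean fingertip delta magnitude: %.2f mm\n",
              mean(sqrt(rowSums(x$landmark_deltas[tips, , drop = FALSE]^2)))))
  invisible(x)
}
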