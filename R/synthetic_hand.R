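# Parametric articulated hand: a palm slab joined to five capsule-like digits
# in fully spread pose, with ground-truth landmarks and per-vertex region
# labels. Geometry is schematic on purpose: the registration and distance-map
# machinery only needs a surface with a palm/digit decomposition and
# repeatable landmarks.

.schemas <- new.env(parent = emptyenv())

#' Landmark schemas
#'
#' A schema is a named, ordered list of landmark labels. The default
#' `"hand24"` schema has four landmarks per digit (tip, distal joint,
#' proximal joint, base) and four palm-boundary landmarks, 24 in total.
#' Schemas are configurable: register a custom one with
#' `register_landmark_schema()`.
#'
#' @param id schema name.
#' @return a list with `id` and `labels`.
#' @export
landmark_schema <- function(id = "hand24") {
  if (!exists(id, envir = .schemas))
    stop("unknown landmark schema ", sQuote(id),
         "; known: ", paste(ls(.schemas), collapse = ", "))
  get(id, envir = .schemas)
}

#' @rdname landmark_schema
#' @param labels character vector of unique landmark labels in schema order.
#' @export
register_landmark_schema <- function(id, labels) {
  stopifnot(is.character(labels), !anyDuplicated(labels))
  assign(id, list(id = id, labels = labels), envir = .schemas)
  invisible(id)
}

hand24_labels <- function() {
  c(as.vector(t(outer(DIGITS, c("tip", "distal", "proximal", "base"),
                      paste, sep = "_"))),
    "palm_base_radial", "palm_base_ulnar", "palm_top_radial", "palm_top_ulnar")
}

.onLoad <- function(libname, pkgname) {
  register_landmark_schema("hand24", hand24_labels())
}

#' Synthetic hand parameters
#'
#' Defaults approximate an adult female hand (mm). `sex_scale` is a
#' dimensionless similarity multiplier applied to every length, emulating the
#' overall size difference between sexes (broader base and longer fingers).
#'
#' @param palm_width,palm_length,palm_thickness palm slab dimensions in mm.
#' @param finger_lengths five lengths in mm (thumb, index, middle, ring,
#'   little), measured from the knuckle to the fingertip.
#' @param finger_radii five capsule radii in mm, same order.
#' @param side `"right"` or `"left"`.
#' @param sex_scale multiplier > 0 applied to all lengths and radii.
#' @param resolution target mesh edge length in mm; smaller is denser.
#' @return a `hand_params` list.
#' @export
hand_params <- function(palm_width = 80, palm_length = 95, palm_thickness = 24,
                        finger_lengths = c(58, 72, 80, 74, 58),
                        finger_radii = c(10.5, 8.5, 8.5, 8, 7),
                        side = c("right", "left"), sex_scale = 1,
                        resolution = 6) {
  side <- match.arg(side)
  p <- list(palm_width = palm_width, palm_length = palm_length,
            palm_thickness = palm_thickness,
            finger_lengths = as.numeric(finger_lengths),
            finger_radii = as.numeric(finger_radii),
            side = side, sex_scale = sex_scale, resolution = resolution)
  lens <- c(p$palm_width, p$palm_length, p$palm_thickness,
            p$finger_lengths, p$finger_radii)
  if (length(p$finger_lengths) != 5L || length(p$finger_radii) != 5L)
    stop("finger_lengths and finger_radii must each have five values")
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths and radii must be strictly positive")
  if (!is.finite(p$sex_scale) || p$sex_scale <= 0)
    stop("sex_scale must be > 0")
  class(p) <- "hand_params"
  p
}

#' Acquisition jitter parameters
#'
#' Describes how a repeat capture of the same hand differs from the first:
#' independent per-finger articulation about the knuckle (subjects cannot keep
#' their fingers perfectly still between captures), one global rigid pose
#' change, and isotropic sensor noise on every vertex. Defaults are set so
#' the palm stays rigid while fingers move a few millimetres at the tip.
#'
#' @param global_rotation_sd sd of the global pose rotation angle, degrees.
#' @param global_translation_sd sd of each translation component, mm.
#' @param finger_articulation_sd sd of each digit's flexion angle about its
#'   base landmark, degrees.
#' @param sensor_noise_sd sd of isotropic per-vertex Gaussian noise, mm.
#' @return an `acquisition_jitter` list.
#' @export
acquisition_jitter <- function(global_rotation_sd = 5,
                               global_translation_sd = 10,
                               finger_articulation_sd = 3,
                               sensor_noise_sd = 0.1) {
  j <- list(global_rotation_sd = global_rotation_sd,
            global_translation_sd = global_translation_sd,
            finger_articulation_sd = finger_articulation_sd,
            sensor_noise_sd = sensor_noise_sd)
  if (any(!vapply(j, function(v) is.finite(v) && v >= 0, logical(1))))
    stop("all jitter sd values must be finite and >= 0")
  class(j) <- "acquisition_jitter"
  j
}

# digit layout on the distal palm edge: base x position as fraction of palm
# width, and spread direction (degrees from +y toward +x) for a right hand
digit_layout <- function(p) {
  W <- p$palm_width
  L <- p$palm_length
  data.frame(
    digit = DIGITS,
    bx = c(0.58 * W, 0.30 * W, 0.10 * W, -0.10 * W, -0.30 * W),
    by = c(0.40 * L, L, L, L, L),
    angle = c(55, 16, 4, -8, -22),
    stringsAsFactors = FALSE
  )
}

# open grid mesh for one rectangular panel spanned by origin + s*e1 + t*e2,
# s,t in [0,1]; winding chosen so normals point along e1 x e2
panel_mesh <- function(origin, e1, e2, n1, n2) {
  s <- seq(0, 1, length.out = n1 + 1L)
  t <- seq(0, 1, length.out = n2 + 1L)
  verts <- matrix(0, (n1 + 1L) * (n2 + 1L), 3)
  k <- 1L
  for (j in seq_along(t)) for (i in seq_along(s)) {
    verts[k, ] <- origin + s[i] * e1 + t[j] * e2
    k <- k + 1L
  }
  idx <- function(i, j) (j - 1L) * (n1 + 1L) + i
  faces <- matrix(0L, 2L * n1 * n2, 3)
  k <- 1L
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    faces[k, ] <- c(a, b, c); faces[k + 1L, ] <- c(a, c, d)
    k <- k + 2L
  }
  list(vertices = verts, faces = faces)
}

# capsule along unit axis u from base point, total length len (base to apex),
# radius r; dorsal reference direction gives the phi=0 meridian
capsule_mesh <- function(base, u, r, len, resolution) {
  u <- u / sqrt(sum(u^2))
  ref <- c(0, 0, 1)
  if (abs(sum(ref * u)) > 0.99) ref <- c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(u, e1)
  ncirc <- max(8L, ceiling(2 * pi * r / resolution))
  shaft <- max(2L, ceiling((len - r) / resolution))
  ncap <- max(2L, ceiling((pi / 2 * r) / resolution))
  phi <- seq(0, 2 * pi, length.out = ncirc + 1L)[-(ncirc + 1L)]
  ring <- function(center, rad) {
    t(vapply(phi, function(a) center + rad * (cos(a) * e1 + sin(a) * e2),
             numeric(3)))
  }
  verts <- NULL
  for (i in 0:shaft)
    verts <- rbind(verts, ring(base + (i / shaft) * (len - r) * u, r))
  # spherical cap rings
  for (j in seq_len(ncap - 1L)) {
    th <- (j / ncap) * (pi / 2)
    verts <- rbind(verts,
                   ring(base + ((len - r) + r * sin(th)) * u, r * cos(th)))
  }
  apex <- base + len * u
  verts <- rbind(verts, matrix(apex, 1, 3))
  nring <- shaft + ncap            # number of full rings
  faces <- NULL
  for (i in seq_len(nring - 1L)) {
    a0 <- (i - 1L) * ncirc
    b0 <- i * ncirc
    for (k in seq_len(ncirc)) {
      k2 <- if (k == ncirc) 1L else k + 1L
      faces <- rbind(faces,
                     c(a0 + k, b0 + k, b0 + k2),
                     c(a0 + k, b0 + k2, a0 + k2))
    }
  }
  top0 <- (nring - 1L) * ncirc
  apex_i <- nring * ncirc + 1L
  for (k in seq_len(ncirc)) {
    k2 <- if (k == ncirc) 1L else k + 1L
    faces <- rbind(faces, c(top0 + k, apex_i, top0 + k2))
  }
  faces <- faces[, c(1, 3, 2)]   # outward orientation
  list(vertices = verts, faces = faces, apex = apex)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a synthetic hand
#'
#' Builds the triangle mesh (palm slab + five capsule digits, fully spread,
#' digits in the palm plane), the 24-landmark ground-truth set, and the
#' per-vertex region map. Output is a deterministic, purely geometric
#' function of the parameters: no randomness is involved, so the same
#' parameters always give bit-identical output. The hand is built in a
#' right-handed frame with the palm base at the origin, +y towards the
#' fingers and +z dorsal; a left hand is the mirror image across the x = 0
#' plane.
#'
#' @param params a [hand_params] object.
#' @return list with elements `mesh` ([hand_mesh]), `landmarks`
#'   ([landmark_set]), `regions` ([region_map]).
#' @export
generate_hand <- function(params = hand_params()) {
  stopifnot(inherits(params, "hand_params"))
  s <- params$sex_scale
  W <- params$palm_width * s
  L <- params$palm_length * s
  T <- params$palm_thickness * s
  flen <- params$finger_lengths * s
  frad <- params$finger_radii * s
  # resolution and embed depth scale with the hand so that scaling the
  # parameters scales the generated vertex array exactly (same connectivity)
  res <- params$resolution * s
  embed <- 2 * s

  p_scaled <- params
  p_scaled$palm_width <- W; p_scaled$palm_length <- L
  lay <- digit_layout(list(palm_width = W, palm_length = L))

  nx <- max(2L, ceiling(W / res))
  ny <- max(2L, ceiling(L / res))
  nz <- max(1L, ceiling(T / res))
  x0 <- -W / 2
  panels <- list(
    panel_mesh(c(x0, 0, T / 2), c(W, 0, 0), c(0, L, 0), nx, ny),       # dorsal (+z)
    panel_mesh(c(x0, 0, -T / 2), c(0, L, 0), c(W, 0, 0), ny, nx),      # palmar (-z)
    panel_mesh(c(x0, 0, -T / 2), c(W, 0, 0), c(0, 0, T), nx, nz),      # proximal edge (y=0)... normal -y
    panel_mesh(c(x0, L, -T / 2), c(0, 0, T), c(W, 0, 0), nz, nx),      # distal edge (y=L)
    panel_mesh(c(x0, 0, -T / 2), c(0, 0, T), c(0, L, 0), nz, ny),      # ulnar side (x=-W/2)
    panel_mesh(c(W / 2, 0, -T / 2), c(0, L, 0), c(0, 0, T), ny, nz)    # radial side (x=+W/2)
  )
  verts <- NULL; faces <- NULL; region <- character()
  add_part <- function(part, label) {
    off <- if (is.null(verts)) 0L else nrow(verts)
    verts <<- rbind(verts, part$vertices)
    faces <<- rbind(faces, part$faces + off)
    region <<- c(region, rep(label, nrow(part$vertices)))
  }
  for (p in panels) add_part(p, "palm")

  lm <- matrix(NA_real_, 24, 3)
  rownames(lm) <- hand24_labels()
  for (d in seq_along(DIGITS)) {
    ang <- lay$angle[d] * pi / 180
    u <- c(sin(ang), cos(ang), 0)
    base <- c(lay$bx[d], lay$by[d], 0)
    # embed the capsule root slightly inside the palm so surfaces join
    root <- base - embed * u
    cap <- capsule_mesh(root, u, frad[d], flen[d] + embed, res)
    add_part(cap[c("vertices", "faces")], DIGITS[d])
    dorsal <- c(0, 0, 1)
    lm[paste0(DIGITS[d], "_tip"), ] <- cap$apex
    lm[paste0(DIGITS[d], "_distal"), ] <- base + 0.75 * flen[d] * u + frad[d] * dorsal
    lm[paste0(DIGITS[d], "_proximal"), ] <- base + 0.45 * flen[d] * u + frad[d] * dorsal
    lm[paste0(DIGITS[d], "_base"), ] <- base + frad[d] * dorsal
  }
  lm["palm_base_radial", ] <- c(W / 2, 0, T / 2)
  lm["palm_base_ulnar", ] <- c(-W / 2, 0, T / 2)
  lm["palm_top_radial", ] <- c(W / 2, L, T / 2)
  lm["palm_top_ulnar", ] <- c(-W / 2, L, T / 2)

  if (params$side == "left") {
    verts[, 1] <- -verts[, 1]
    lm[, 1] <- -lm[, 1]
    faces <- faces[, c(1, 3, 2)]   # keep outward orientation after mirroring
  }
  mesh <- hand_mesh(verts, faces)
  list(mesh = mesh,
       landmarks = landmark_set(lm, schema = hand24_labels(),
                                schema_id = "hand24", side = params$side),
       regions = region_map(region, mesh))
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

digit_frame <- function(lm, digit) {
  base <- lm$points[paste0(digit, "_base"), ]
  tip <- lm$points[paste0(digit, "_tip"), ]
  prox <- lm$points[paste0(digit, "_proximal"), ]
  u <- tip - base
  u <- u / sqrt(sum(u^2))
  w <- prox - base
  dorsal <- w - sum(w * u) * u
  nd <- sqrt(sum(dorsal^2))
  if (nd < 1e-9) {   # degenerate: pick any perpendicular
    dorsal <- pracma_cross(u, c(1, 0, 0))
    if (sqrt(sum(dorsal^2)) < 1e-9) dorsal <- pracma_cross(u, c(0, 1, 0))
    nd <- sqrt(sum(dorsal^2))
  }
  dorsal <- dorsal / nd
  list(base = base, u = u, dorsal = dorsal,
       flex_axis = pracma_cross(u, dorsal))
}

#' Simulate a repeat acquisition of the same hand
#'
#' Emulates capturing the same hand a second time: each digit articulates by
#' a small random flexion about its base landmark (affecting only vertices of
#' that digit's region, with a short linear blend near the knuckle so the
#' surface does not tear), then one global rigid pose change is applied, then
#' isotropic sensor noise displaces every vertex. Landmarks are transported
#' by the articulation and pose maps; palm vertices see only the global
#' transform plus noise.
#'
#' @param hand list with `mesh`, `landmarks`, `regions`, as returned by
#'   [generate_hand()].
#' @param jitter an [acquisition_jitter] object.
#' @param seed integer seed; the simulation is deterministic given
#'   `hand`, `jitter` and `seed`.
#' @param blend_radius mm over which digit motion ramps in near the knuckle.
#' @return list with `mesh`, `landmarks`, `regions` (labels unchanged), and
#'   `applied_global` (the [rigid_transform] of the pose change).
#' @export
simulate_repeat_acquisition <- function(hand, jitter = acquisition_jitter(),
                                        seed = 1L, blend_radius = 3) {
  stopifnot(inherits(jitter, "acquisition_jitter"))
  mesh <- hand$mesh; lm <- hand$landmarks; regions <- hand$regions
  if (length(regions) != nrow(mesh$vertices))
    stop("region map is not bound to this mesh")
  with_seed(seed, {
    V <- mesh$vertices
    P <- lm$points
    for (d in DIGITS) {
      ang <- rnorm(1, 0, jitter$finger_articulation_sd * pi / 180)
      fr <- digit_frame(lm, d)
      R <- axis_angle_rotation(fr$flex_axis, ang)
      sel <- which(as.character(regions) == d)
      if (length(sel)) {
        rel <- sweep(V[sel, , drop = FALSE], 2, fr$base)
        along <- as.numeric(rel %*% fr$u)
        wgt <- pmin(1, pmax(0, along / blend_radius))
        full <- rel %*% t(R)
        Vnew <- rel + wgt * (full - rel)   # small-angle blend toward rotated
        V[sel, ] <- sweep(Vnew, 2, -fr$base)
      }
      li <- paste0(d, c("_tip", "_distal", "_proximal", "_base"))
      relL <- sweep(P[li, , drop = FALSE], 2, fr$base)
      P[li, ] <- sweep(relL %*% t(R), 2, -fr$base)
    }
    Rg <- random_rotation(jitter$global_rotation_sd)
    centroid <- colMeans(V)
    tg <- rnorm(3, 0, jitter$global_translation_sd)
    # rotate about the centroid, then translate
    trans_g <- rigid_transform(Rg, as.numeric(centroid - Rg %*% centroid) + tg)
    V <- apply_transform(trans_g, V)
    P2 <- apply_transform(trans_g, P)
    rownames(P2) <- rownames(P)
    if (jitter$sensor_noise_sd > 0)
      V <- V + matrix(rnorm(length(V), 0, jitter$sensor_noise_sd), nrow(V), 3)
    mesh2 <- hand_mesh(V, mesh$faces)
    list(mesh = mesh2,
         landmarks = landmark_set(P2, schema = rownames(P2),
                                  schema_id = lm$schema_id, side = lm$side),
         regions = regions,
         applied_global = trans_g)
  })
}

#' Generate a synthetic cohort of hands
#'
#' Draws `n_per_sex` female and `n_per_sex` male subjects. Each subject's
#' length parameters (palm dimensions, finger lengths and radii) are drawn
#' log-normally around sex-specific medians: the female median is
#' `base_params`, the male median is `base_params` scaled by `male_scale`.
#'
#' @param n_per_sex subjects per sex (>= 1).
#' @param base_params [hand_params] giving the female median hand.
#' @param male_scale multiplicative male/female size ratio (default 1.1).
#' @param between_subject_sd log-scale sd of the per-subject, per-parameter
#'   size multipliers (a fraction; default 0.04).
#' @param seed integer seed.
#' @return list of subjects, each a list with `id`, `sex`, `mesh`,
#'   `landmarks`, `regions`, `params`.
#' @export
generate_cohort <- function(n_per_sex, base_params = hand_params(),
                            male_scale = 1.1, between_subject_sd = 0.04,
                            seed = 1L) {
  stopifnot(n_per_sex >= 1)
  with_seed(seed, {
    subjects <- list()
    k <- 1L
    for (sex in c("female", "male")) {
      sc <- if (sex == "male") male_scale else 1
      for (i in seq_len(n_per_sex)) {
        p <- base_params
        draw <- function(x) x * sc * exp(rnorm(length(x), 0, between_subject_sd))
        p$palm_width <- draw(p$palm_width)
        p$palm_length <- draw(p$palm_length)
        p$palm_thickness <- draw(p$palm_thickness)
        p$finger_lengths <- draw(p$finger_lengths)
        p$finger_radii <- draw(p$finger_radii)
        h <- generate_hand(p)
        subjects[[k]] <- list(id = sprintf("%s%02d", substr(sex, 1, 1), i),
                              sex = sex, mesh = h$mesh,
                              landmarks = h$landmarks, regions = h$regions,
                              params = p)
        k <- k + 1L
      }
    }
    subjects
  })
}
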