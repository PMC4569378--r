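# Independent oracles and small fixtures used across the suite. These stay
# deliberately naive (exhaustive scans, dense sampling, random-restart
# optimization) so they never share code with the implementation they check.

# exhaustive nearest-neighbour scan in plain R
brute_nn <- function(Q, P) {
  idx <- integer(nrow(Q))
  d <- numeric(nrow(Q))
  for (i in seq_len(nrow(Q))) {
    dd <- sqrt(rowSums(sweep(P, 2, Q[i, ])^2))
    idx[i] <- which.min(dd)
    d[i] <- dd[idx[i]]
  }
  list(index = idx, distance = d)
}

# barycentric sampling upper bound on point-to-triangle distance; one fixed
# dense sample layout (interior + edges + vertices) shared across calls
.tri_samples <- local({
  set.seed(424242)
  n <- 1e5
  u <- runif(n); v <- runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  te <- seq(0, 1, length.out = 400)
  cbind(c(1 - u - v, 1 - te, te, rep(0, 400), 1, 0, 0),
        c(u, te, rep(0, 400), 1 - te, 0, 1, 0),
        c(v, rep(0, 400), 1 - te, te, 0, 0, 1))
})

sampling_tri_dist <- function(p, tri) {
  pts <- .tri_samples %*% tri
  min(sqrt(rowSums(sweep(pts, 2, p)^2)))
}

# best rigid fit by random-restart Nelder-Mead over axis-angle rotation with
# the translation solved in closed form per rotation; independent of the SVD
# route used by kabsch()
rigid_residual <- function(R, source, target, weights) {
  w <- weights / sum(weights)
  tr <- colSums(target * w) - as.numeric(R %*% colSums(source * w))
  moved <- sweep(source %*% t(R), 2, -tr)
  sum(weights * rowSums((moved - target)^2))
}

rot_from_vec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  a <- v / th
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

oracle_best_rigid <- function(source, target, weights = rep(1, nrow(source)),
                              n_restarts = 40) {
  obj <- function(v) rigid_residual(rot_from_vec(v), source, target, weights)
  best <- Inf
  for (r in seq_len(n_restarts)) {
    v0 <- if (r == 1) c(0, 0, 0) else runif(3, -pi, pi)
    fit <- optim(v0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  best
}

# fixtures ------------------------------------------------------------------

unit_tetra <- function() {
  hand_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
            rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

# closed UV sphere with shared vertices and consistent outward winding
uv_sphere <- function(radius = 10, nlat = 12, nlon = 18) {
  th <- seq(0, pi, length.out = nlat + 2)[2:(nlat + 1)]
  ph <- seq(0, 2 * pi, length.out = nlon + 1)[-(nlon + 1)]
  verts <- rbind(c(0, 0, radius))
  for (t in th)
    verts <- rbind(verts, cbind(radius * sin(t) * cos(ph),
                                radius * sin(t) * sin(ph),
                                radius * cos(t)))
  verts <- rbind(verts, c(0, 0, -radius))
  south <- nrow(verts)
  vid <- function(i, j) 1L + (i - 1L) * nlon + ((j - 1L) %% nlon) + 1L
  faces <- NULL
  for (j in seq_len(nlon))
    faces <- rbind(faces, c(1L, vid(1, j), vid(1, j + 1)))
  for (i in seq_len(nlat - 1)) for (j in seq_len(nlon))
    faces <- rbind(faces,
                   c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1)),
                   c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1)))
  for (j in seq_len(nlon))
    faces <- rbind(faces, c(south, vid(nlat, j + 1), vid(nlat, j)))
  hand_mesh(verts, faces)
}

random_mesh <- function(n_tri = 60, seed = 1, spread = 50) {
  set.seed(seed)
  v <- matrix(runif(n_tri * 9, -spread, spread), ncol = 3)
  hand_mesh(v, matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE))
}

random_rigid_transform <- function(seed, max_deg = 20, max_trans = 30) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, -max_deg, max_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  rigid_transform(R, runif(3, -max_trans, max_trans))
}

small_hand <- function(...) generate_hand(hand_params(resolution = 10, ...))

as_specimens <- function(hands) {
  lapply(hands, function(h) list(landmarks = h$landmarks, mesh = h$mesh,
                                 regions = h$regions))
}
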