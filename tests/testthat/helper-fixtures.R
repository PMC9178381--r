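# Shared fixtures and independent oracles, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Points sampled on a sphere surface (full or capped), optionally noisy.
sphere_points <- function(n, centre, radius, noise_sd = 0) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- radius * u + matrix(centre, n, 3, byrow = TRUE)
  if (noise_sd > 0) pts <- pts + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
  pts
}

# Points on a cylinder band: unit axis through `centre`, given radius,
# angular arc (deg) and axial length.
cylinder_points <- function(n, centre, axis, radius, arc_deg = 180,
                            len = 10, noise_sd = 0) {
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * a) * a; u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  th <- stats::runif(n, -arc_deg / 2, arc_deg / 2) * pi / 180
  z <- stats::runif(n, -len / 2, len / 2)
  pts <- matrix(centre, n, 3, byrow = TRUE) + outer(z, a) +
    radius * (outer(cos(th), u) + outer(sin(th), v))
  if (noise_sd > 0) pts <- pts + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
  pts
}

random_rigid <- function() {
  jointpose:::rigid_transform(jointpose:::random_rotation(),
                              stats::runif(3, -50, 50))
}

# Independent sphere oracle: coarse grid of centre candidates followed by
# Nelder-Mead polish of the summed squared radial residuals.
oracle_sphere <- function(pts, grid_half_width = 2, grid_n = 5) {
  ssr <- function(par) {
    d <- sqrt(rowSums(sweep(pts, 2, par[1:3])^2))
    sum((d - par[4])^2)
  }
  ctr0 <- colMeans(pts)
  offs <- seq(-grid_half_width, grid_half_width, length.out = grid_n)
  best <- NULL
  for (dx in offs) for (dy in offs) for (dz in offs) {
    c0 <- ctr0 + c(dx, dy, dz)
    r0 <- mean(sqrt(rowSums(sweep(pts, 2, c0)^2)))
    v <- ssr(c(c0, r0))
    if (is.null(best) || v < best$v) best <- list(par = c(c0, r0), v = v)
  }
  fit <- stats::optim(best$par, ssr, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(centroid = fit$par[1:3], radius = fit$par[4])
}

# Independent cylinder-axis oracle: exhaustive search over axis orientations
# on a spherical grid (step_deg spacing), each scored by an algebraic circle
# fit of the points projected perpendicular to the trial axis.
oracle_cylinder_axis <- function(pts, step_deg = 2) {
  ctr <- colMeans(pts)
  d0 <- sweep(pts, 2, ctr)
  best <- NULL
  for (el in seq(0, 90, by = step_deg)) {
    azs <- if (el == 90) 0 else seq(0, 180 - step_deg, by = step_deg)
    for (az in azs) {
      a <- c(cos(el * pi / 180) * cos(az * pi / 180),
             cos(el * pi / 180) * sin(az * pi / 180),
             sin(el * pi / 180))
      ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * a) * a; u <- u / sqrt(sum(u^2))
      v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
             a[1] * u[2] - a[2] * u[1])
      uv <- cbind(d0 %*% u, d0 %*% v)
      A <- cbind(2 * uv, 1)
      beta <- tryCatch(qr.solve(A, rowSums(uv^2)),
                       error = function(e) NULL)
      if (is.null(beta)) next
      r <- sqrt(max(beta[3] + beta[1]^2 + beta[2]^2, 0))
      res <- sqrt(rowSums(sweep(uv, 2, beta[1:2])^2)) - r
      v_ssr <- sum(res^2)
      if (is.null(best) || v_ssr < best$ssr) best <- list(axis = a, ssr = v_ssr)
    }
  }
  best
}

angle_between_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, max(-1, abs(sum(a * b))))) * 180 / pi
}

# Small standard limbs reused across tests.
test_limb <- function(sides = "right", fused = TRUE, noise_sd = 0, seed = 11,
                      resolution = 12) {
  generate_limb(limb_blueprint(sides = sides, fused = fused,
                               noise_sd = noise_sd, seed = seed,
                               resolution = resolution))
}

max_abs_dof <- function(tab) {
  max(abs(as.matrix(tab[, c("FE_deg", "ABAD_deg", "LAR_deg",
                            "t_x_mm", "t_y_mm", "t_z_mm")])))
}
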