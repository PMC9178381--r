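# Least-squares fitting of geometric primitives (sphere, cylinder, plane) to
# articular surface patches. Fitted axes and normals are sign-ambiguous;
# anatomical signs ("axis positive laterally", "normal positive proximally")
# are resolved with per-patch reference directions and never influence the
# geometry of the fit itself.

FIT_MAXITER <- 200L
FIT_RELTOL <- 1e-10

# Resolve (points, reference_direction) from either a bare point matrix or a
# surface_patch + mesh pair.
resolve_patch_input <- function(x, mesh, reference_direction) {
  if (inherits(x, "surface_patch")) {
    if (is.null(mesh)) stop("a mesh is required when fitting a surface_patch",
                            call. = FALSE)
    if (is.null(reference_direction))
      reference_direction <- x$reference_direction
    list(points = patch_vertices(x, mesh), patch = x,
         reference_direction = reference_direction)
  } else {
    list(points = as.matrix(x), patch = NULL,
         reference_direction = reference_direction)
  }
}

# Singular values of the centered point cloud; basis for degeneracy checks
# and principal-direction initialization.
point_svd <- function(pts) {
  ctr <- colMeans(pts)
  svd(sweep(pts, 2, ctr))
}

flip_to_reference <- function(v, reference_direction) {
  if (is.null(reference_direction)) return(v)
  if (sum(v * reference_direction) < 0) -v else v
}

#' Fit a sphere to a point cloud by least squares
#'
#' Initializes with the algebraic (linear) solve and refines centre and
#' radius by Levenberg-Marquardt on the geometric radial residuals
#' `|p_i - c| - r`, to relative tolerance 1e-10.
#'
#' @param x n x 3 matrix of points (mm), or a [surface_patch()].
#' @param mesh required when `x` is a patch.
#' @return object of class `sphere_fit`: `centroid`, `radius`,
#'   `rms_residual` (all mm).
#' @export
#' @examples
#' u <- matrix(rnorm(300), ncol = 3)
#' pts <- 5 * u / sqrt(rowSums(u^2)) + rep(c(1, 2, 3), each = 100)
#' fit_sphere(pts)
fit_sphere <- function(x, mesh = NULL) {
  inp <- resolve_patch_input(x, mesh, NULL)
  pts <- inp$points
  if (nrow(pts) < 4L)
    stop("sphere fitting needs at least 4 points", call. = FALSE)
  sv <- point_svd(pts)
  if (sv$d[3] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate geometry: points are coplanar, cannot fit a sphere",
         call. = FALSE)
  # algebraic initialization: |p|^2 = 2 c.p + (r^2 - |c|^2)
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  beta <- qr.solve(A, b)
  centre <- beta[1:3]
  r <- sqrt(max(beta[4] + sum(centre^2), .Machine$double.eps))
  # geometric refinement
  resfun <- function(par) {
    sqrt(rowSums(sweep(pts, 2, par[1:3])^2)) - par[4]
  }
  fit <- minpack.lm::nls.lm(
    par = c(centre, r), fn = resfun,
    control = minpack.lm::nls.lm.control(
      maxiter = FIT_MAXITER, ftol = FIT_RELTOL, ptol = FIT_RELTOL))
  par <- fit$par
  res <- resfun(par)
  structure(list(centroid = as.numeric(par[1:3]), radius = as.numeric(par[4]),
                 rms_residual = sqrt(mean(res^2))),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("sphere_fit: centre (%.3f, %.3f, %.3f) mm, r = %.3f mm, rms = %.2e mm\n",
              x$centroid[1], x$centroid[2], x$centroid[3], x$radius,
              x$rms_residual))
  invisible(x)
}

# Sum of squared point-to-cylinder-surface distances for a given axis
# parameterization; used by both the fitter and its tests.
cylinder_residuals <- function(par, pts) {
  a <- c(cos(par[1]) * cos(par[2]), cos(par[1]) * sin(par[2]), sin(par[1]))
  basis <- axis_plane_basis(a)
  c0 <- attr(pts, "ctr") + par[3] * basis$u + par[4] * basis$v
  d <- sweep(pts, 2, c0)
  along <- d %*% a
  perp2 <- rowSums(d^2) - along^2
  sqrt(pmax(perp2, 0)) - par[5]
}

# Orthonormal basis of the plane perpendicular to unit axis a.
axis_plane_basis <- function(a) {
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(cross3(a, ref))
  v <- cross3(a, u)
  list(u = u, v = v)
}

#' Fit a cylinder to a point cloud by least squares
#'
#' Minimizes the sum of squared distances from the points to the cylinder
#' surface. The axis is initialized from the principal directions of the
#' point cloud (each principal direction is tried; the converged fit with the
#' lowest residual wins, deterministically) and refined by
#' Levenberg-Marquardt over axis orientation, axis position and radius.
#'
#' The reported `centroid` is the midpoint of the extremal projections of the
#' points onto the fitted axis line, so it reflects the extent of the patch
#' along the axis. If `reference_direction` is available the axis is flipped
#' so that `dot(axis, reference_direction) > 0`.
#'
#' A warning is raised when the points cover less than 30 degrees of arc
#' about the fitted axis, below which the fit is poorly identifiable.
#'
#' @param x n x 3 matrix of points (mm), or a [surface_patch()].
#' @param mesh required when `x` is a patch.
#' @param reference_direction optional 3-vector resolving the axis sign;
#'   defaults to the patch's own reference direction when `x` is a patch.
#' @return object of class `cylinder_fit`: `centroid`, unit `axis`, `radius`,
#'   `rms_residual`, `arc_deg` (angular coverage about the axis).
#' @export
fit_cylinder <- function(x, mesh = NULL, reference_direction = NULL) {
  inp <- resolve_patch_input(x, mesh, reference_direction)
  pts <- inp$points
  reference_direction <- inp$reference_direction
  if (nrow(pts) < 6L)
    stop("cylinder fitting needs at least 6 points", call. = FALSE)
  sv <- point_svd(pts)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate geometry: points are collinear, cannot fit a cylinder",
         call. = FALSE)
  if (sv$d[3] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate geometry: points are coplanar, cannot fit a cylinder",
         call. = FALSE)
  ctr <- colMeans(pts)
  attr(pts, "ctr") <- ctr
  best <- NULL
  for (k in 1:3) {
    a0 <- sv$v[, k]
    # initialize axis position and radius by an algebraic (Kasa) circle fit
    # of the points projected onto the plane perpendicular to the trial axis
    basis0 <- axis_plane_basis(a0)
    d0 <- sweep(pts, 2, ctr)
    uv <- cbind(d0 %*% basis0$u, d0 %*% basis0$v)
    A <- cbind(2 * uv, 1)
    beta <- tryCatch(qr.solve(A, rowSums(uv^2)), error = function(e) c(0, 0, 1))
    r0 <- sqrt(max(beta[3] + beta[1]^2 + beta[2]^2, .Machine$double.eps))
    par0 <- c(asin(clamp1(a0[3])), atan2(a0[2], a0[1]), beta[1], beta[2], r0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, fn = cylinder_residuals, pts = pts,
        control = minpack.lm::nls.lm.control(
          maxiter = FIT_MAXITER, ftol = FIT_RELTOL, ptol = FIT_RELTOL)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(cylinder_residuals(fit$par, pts)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    stop("cylinder fit failed to converge in ", FIT_MAXITER, " iterations",
         call. = FALSE)
  par <- best$fit$par
  a <- c(cos(par[1]) * cos(par[2]), cos(par[1]) * sin(par[2]), sin(par[1]))
  basis <- axis_plane_basis(a)
  c0 <- ctr + par[3] * basis$u + par[4] * basis$v
  r <- abs(par[5])
  a <- flip_to_reference(a, reference_direction)
  # canonical centroid: midpoint of extremal axial projections
  along <- as.vector(sweep(pts, 2, c0) %*% a)
  centroid <- c0 + (max(along) + min(along)) / 2 * a
  res <- cylinder_residuals(par, pts)
  # angular coverage about the axis
  d <- sweep(pts, 2, c0)
  ang <- sort(atan2(d %*% basis$v, d %*% basis$u))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  arc_deg <- (2 * pi - max(gaps)) * RAD2DEG
  if (arc_deg < 30)
    warning("cylinder patch covers only ", round(arc_deg, 1),
            " degrees of arc; axis is poorly identifiable", call. = FALSE)
  structure(list(centroid = as.numeric(centroid), axis = as.numeric(a),
                 radius = r, rms_residual = sqrt(mean(res^2)),
                 arc_deg = arc_deg),
            class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf(
    "cylinder_fit: centroid (%.3f, %.3f, %.3f) mm, axis (%.3f, %.3f, %.3f), r = %.3f mm, rms = %.2e mm\n",
    x$centroid[1], x$centroid[2], x$centroid[3],
    x$axis[1], x$axis[2], x$axis[3], x$radius, x$rms_residual))
  invisible(x)
}

#' Fit a plane to a patch by total least squares
#'
#' The normal is the direction of least variance of the patch vertices
#' (smallest right singular vector of the centered cloud). The reported
#' centroid is the area-weighted centroid of the patch faces projected onto
#' the fitted plane (so sliver triangulation does not bias the origin); when
#' only bare points are supplied the vertex mean is used instead.
#'
#' @param x n x 3 matrix of points (mm), or a [surface_patch()].
#' @param mesh required when `x` is a patch (supplies the faces for the
#'   area-weighted centroid).
#' @param reference_direction optional 3-vector resolving the normal sign;
#'   defaults to the patch's own reference direction when `x` is a patch.
#' @return object of class `plane_fit`: `centroid`, unit `normal`,
#'   `rms_residual`.
#' @export
fit_plane <- function(x, mesh = NULL, reference_direction = NULL) {
  inp <- resolve_patch_input(x, mesh, reference_direction)
  pts <- inp$points
  reference_direction <- inp$reference_direction
  if (nrow(pts) < 3L)
    stop("plane fitting needs at least 3 points", call. = FALSE)
  sv <- point_svd(pts)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate geometry: points are collinear, cannot fit a plane",
         call. = FALSE)
  ctr <- colMeans(pts)
  normal <- flip_to_reference(sv$v[, 3], reference_direction)
  if (!is.null(inp$patch)) {
    areas <- face_areas(mesh, inp$patch$face_indices)
    fcent <- face_centroids(mesh, inp$patch$face_indices)
    raw_centroid <- colSums(fcent * areas) / sum(areas)
  } else {
    raw_centroid <- ctr
  }
  # project onto the fitted plane (through ctr with the fitted normal)
  centroid <- raw_centroid - sum((raw_centroid - ctr) * normal) * normal
  res <- as.vector(sweep(pts, 2, ctr) %*% normal)
  structure(list(centroid = as.numeric(centroid),
                 normal = as.numeric(normal),
                 rms_residual = sqrt(mean(res^2))),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf(
    "plane_fit: centroid (%.3f, %.3f, %.3f) mm, normal (%.3f, %.3f, %.3f), rms = %.2e mm\n",
    x$centroid[1], x$centroid[2], x$centroid[3],
    x$normal[1], x$normal[2], x$normal[3], x$rms_residual))
  invisible(x)
}
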