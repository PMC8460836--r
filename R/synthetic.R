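# Synthetic phantoms with machine-checkable ground truth: voxelized closed
# surfaces with analytic mean curvature, planar contours with known curvature
# and convexity, annulus cross-sections, and Boltzmann-distributed per-cell
# measurements. Phantom scales mirror the biology (lumen radii ~2-15 um,
# voxel spacing 0.1-0.5 um) so the stated tolerances are meaningful at a
# realistic discretization.

# mean curvature of the zero level set of F at points (rows), outward-positive
# for a convex body enclosing F < 0; invariant to monotone rescaling of F
implicit_mean_curvature <- function(F, pts, h = 1e-4) {
  vapply(seq_len(nrow(pts)), function(i) {
    x <- pts[i, ]
    g <- numeric(3)
    He <- matrix(0, 3, 3)
    f0 <- F(rbind(x))
    for (a in 1:3) {
      ea <- c(0, 0, 0); ea[a] <- h
      fp <- F(rbind(x + ea)); fm <- F(rbind(x - ea))
      g[a] <- (fp - fm) / (2 * h)
      He[a, a] <- (fp - 2 * f0 + fm) / h^2
    }
    for (a in 1:2) for (b in (a + 1):3) {
      ea <- c(0, 0, 0); ea[a] <- h
      eb <- c(0, 0, 0); eb[b] <- h
      He[a, b] <- He[b, a] <-
        (F(rbind(x + ea + eb)) - F(rbind(x + ea - eb)) -
         F(rbind(x - ea + eb)) + F(rbind(x - ea - eb))) / (4 * h^2)
    }
    ng <- sqrt(sum(g^2))
    n <- g / ng
    (sum(diag(He)) - drop(t(n) %*% He %*% n)) / (2 * ng)
  }, numeric(1))
}

#' Voxelized 3D phantom surface with analytic ground truth
#'
#' @param kind `"sphere"`, `"ellipsoid"`, or `"bumpy_sphere"` (a sphere with
#'   one inward Gaussian dimple centered on the +y axis,
#'   `r(theta) = R (1 - amplitude * exp(-(theta/width)^2))` with `theta` the
#'   polar angle from +y).
#' @param radius sphere / bumpy-sphere radius (um).
#' @param semi_axes ellipsoid semi-axes `c(a, b, c)` (um).
#' @param bump_amplitude,bump_width dimple depth (fraction of `radius`, < 1 so
#'   the radial map stays single-valued) and angular width (radians).
#' @param spacing voxel size, scalar or `c(x, y, z)` (um).
#' @param margin empty border margin (um).
#' @param noise boundary-voxel flip rate in \[0, 1\].
#' @param seed seed for the noise flips.
#' @return list with `surface` (a [voxel_surface()]) and `truth`: analytic
#'   `V`, `A`, `fraction_concave`, and `H_fun(points)` returning the exact
#'   mean curvature at physical points on the surface.
#' @export
make_phantom_surface <- function(kind = c("sphere", "ellipsoid", "bumpy_sphere"),
                                 radius = 10, semi_axes = c(15, 8, 8),
                                 bump_amplitude = 0.3, bump_width = 0.6,
                                 spacing = 0.5, margin = 2, noise = 0,
                                 seed = NULL) {
  kind <- match.arg(kind)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  extent <- switch(kind, sphere = radius, bumpy_sphere = radius,
                   ellipsoid = max(semi_axes)) + margin
  min_span <- switch(kind, sphere = 2 * radius,
                     bumpy_sphere = 2 * radius * (1 - bump_amplitude),
                     ellipsoid = 2 * min(semi_axes))
  if (min_span / max(spacing) < 8) stop("spacing too coarse: < 8 voxels across")
  axes <- lapply(1:3, function(a) {
    n <- 2L * ceiling(extent / spacing[a]) + 1L
    (seq_len(n) - 1L - (n - 1L) / 2L) * spacing[a]
  })
  Fimp <- switch(kind,
    sphere = function(P) sqrt(rowSums(P^2)) - radius,
    ellipsoid = function(P) {
      sqrt((P[, 1L] / semi_axes[1L])^2 + (P[, 2L] / semi_axes[2L])^2 +
           (P[, 3L] / semi_axes[3L])^2) - 1
    },
    bumpy_sphere = function(P) {
      # dimple axis along +y: in-plane for both the XY and YZ section
      # families, so the concave crater is visible to slice boundaries
      rr <- sqrt(rowSums(P^2))
      th <- acos(pmin(pmax(P[, 2L] / pmax(rr, 1e-12), -1), 1))
      rr - radius * (1 - bump_amplitude * exp(-(th / bump_width)^2))
    })
  grid <- as.matrix(expand.grid(x = axes[[1L]], y = axes[[2L]], z = axes[[3L]]))
  mask <- array(Fimp(grid) < 0, dim = vapply(axes, length, integer(1)))
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    sh <- function(m, a, dir) {
      out <- array(FALSE, dim(m))
      d <- dim(m)
      idx <- lapply(d, seq_len)
      src <- idx
      src[[a]] <- if (dir > 0) c(1L, seq_len(d[a] - 1L)) else c(seq_len(d[a] - 1L) + 1L, d[a])
      do.call(`[`, c(list(m), src))
    }
    nb <- sh(mask, 1, 1) | sh(mask, 1, -1) | sh(mask, 2, 1) |
      sh(mask, 2, -1) | sh(mask, 3, 1) | sh(mask, 3, -1)
    inner <- mask & !(sh(mask, 1, 1) & sh(mask, 1, -1) & sh(mask, 2, 1) &
                      sh(mask, 2, -1) & sh(mask, 3, 1) & sh(mask, 3, -1))
    outer <- !mask & nb
    cand <- which(inner | outer)
    flip <- cand[runif(length(cand)) < noise]
    mask[flip] <- !mask[flip]
    # simultaneous on/off flips can strand single voxels; keep the largest
    # component so the phantom remains one closed surface
    lab <- label3d_cpp(as.logical(mask), dim(mask))
    if (max(lab) > 1L) {
      keep <- which.max(tabulate(lab[lab > 0L], nbins = max(lab)))
      mask <- array(lab == keep, dim = dim(mask))
    }
  }
  truth <- switch(kind,
    sphere = list(V = 4 / 3 * pi * radius^3, A = 4 * pi * radius^2,
                  fraction_concave = 0,
                  H_fun = function(pts) rep(1 / radius, nrow(pts))),
    ellipsoid = {
      a <- semi_axes[1L]; b <- semi_axes[2L]; cc <- semi_axes[3L]
      th <- seq(0, pi, length.out = 201L)[-c(1L, 201L)]
      ph <- seq(0, 2 * pi, length.out = 201L)[-201L]
      dth <- diff(seq(0, pi, length.out = 201L))[1L]
      dph <- diff(seq(0, 2 * pi, length.out = 201L))[1L]
      g <- expand.grid(th = th, ph = ph)
      # |r_th x r_ph| for the standard parameterization
      st <- sin(g$th); ct <- cos(g$th); sp <- sin(g$ph); cp <- cos(g$ph)
      E1 <- cbind(a * ct * cp, b * ct * sp, -cc * st)
      E2 <- cbind(-a * st * sp, b * st * cp, 0)
      cr <- cbind(E1[, 2L] * E2[, 3L] - E1[, 3L] * E2[, 2L],
                  E1[, 3L] * E2[, 1L] - E1[, 1L] * E2[, 3L],
                  E1[, 1L] * E2[, 2L] - E1[, 2L] * E2[, 1L])
      list(V = 4 / 3 * pi * a * b * cc,
           A = sum(sqrt(rowSums(cr^2))) * dth * dph,
           fraction_concave = 0,
           H_fun = function(pts) implicit_mean_curvature(Fimp, pts))
    },
    bumpy_sphere = {
      rfun <- function(th) radius * (1 - bump_amplitude * exp(-(th / bump_width)^2))
      drfun <- function(th) radius * bump_amplitude * 2 * th / bump_width^2 *
        exp(-(th / bump_width)^2)
      V <- 2 * pi / 3 * integrate(function(th) rfun(th)^3 * sin(th), 0, pi,
                                  rel.tol = 1e-10)$value
      A <- 2 * pi * integrate(function(th) {
        rfun(th) * sin(th) * sqrt(rfun(th)^2 + drfun(th)^2)
      }, 0, pi, rel.tol = 1e-10)$value
      th <- seq(1e-4, pi - 1e-4, length.out = 2000L)
      pts <- cbind(rfun(th) * sin(th), rfun(th) * cos(th), 0)
      Hs <- implicit_mean_curvature(Fimp, pts)
      w <- rfun(th) * sin(th) * sqrt(rfun(th)^2 + drfun(th)^2)
      list(V = V, A = A, fraction_concave = sum(w[Hs < 0]) / sum(w),
           H_fun = function(p) implicit_mean_curvature(Fimp, p))
    })
  truth$kind <- kind
  list(surface = voxel_surface(mask, spacing, label = "apical"), truth = truth)
}

#' Planar phantom contour with ground truth
#'
#' @param kind `"circle"`, `"ellipse"`, `"star"` (polar curve
#'   `R (1 + amplitude * cos(lobes * phi))`), `"plus"` (plus-sign polygon
#'   of 5 unit squares), or `"square"`.
#' @param radius circle / star base radius; square side length.
#' @param semi_axes ellipse semi-axes `c(a, b)`.
#' @param lobes,amplitude star lobe count and relative amplitude.
#' @param n number of sampled boundary points (polygonal kinds use their
#'   corners when `n` is NULL).
#' @param noise sd of i.i.d. Gaussian jitter added to the points.
#' @param seed seed for the jitter.
#' @return list with `contour` (a [planar_contour()]) and `truth`: `area`,
#'   `perimeter`, `solidity`, `ipq`, and (for smooth kinds) `k_fun(s_param)`
#'   giving the signed curvature at the sampling parameter.
#' @export
make_phantom_contour <- function(kind = c("circle", "ellipse", "star", "plus", "square"),
                                 radius = 5, semi_axes = c(2, 1), lobes = 5L,
                                 amplitude = 0.3, n = 512L, noise = 0,
                                 seed = NULL) {
  kind <- match.arg(kind)
  tt <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  if (kind == "circle") {
    pts <- radius * cbind(cos(tt), sin(tt))
    truth <- list(area = pi * radius^2, perimeter = 2 * pi * radius,
                  solidity = 1, ipq = 1,
                  k_fun = function(t) rep(1 / radius, length(t)))
  } else if (kind == "ellipse") {
    a <- semi_axes[1L]; b <- semi_axes[2L]
    pts <- cbind(a * cos(tt), b * sin(tt))
    per <- integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                     0, 2 * pi, rel.tol = 1e-12)$value
    truth <- list(area = pi * a * b, perimeter = per, solidity = 1,
                  ipq = 4 * pi * pi * a * b / per^2,
                  k_fun = function(t) a * b / (a^2 * sin(t)^2 + b^2 * cos(t)^2)^1.5)
  } else if (kind == "star") {
    r <- radius * (1 + amplitude * cos(lobes * tt))
    pts <- cbind(r * cos(tt), r * sin(tt))
    rf <- function(t) radius * (1 + amplitude * cos(lobes * t))
    drf <- function(t) -radius * amplitude * lobes * sin(lobes * t)
    ddrf <- function(t) -radius * amplitude * lobes^2 * cos(lobes * t)
    per <- integrate(function(t) sqrt(rf(t)^2 + drf(t)^2), 0, 2 * pi,
                     rel.tol = 1e-12)$value
    area <- pi * radius^2 * (1 + amplitude^2 / 2)
    h <- chull(pts)
    sol <- area / abs(polygon_area_signed(pts[h, , drop = FALSE]))
    truth <- list(area = area, perimeter = per, solidity = sol,
                  ipq = 4 * pi * area / per^2,
                  k_fun = function(t) {
                    (rf(t)^2 + 2 * drf(t)^2 - rf(t) * ddrf(t)) /
                      (rf(t)^2 + drf(t)^2)^1.5
                  })
  } else if (kind == "plus") {
    pts <- cbind(c(1, 2, 2, 3, 3, 2, 2, 1, 1, 0, 0, 1),
                 c(0, 0, 1, 1, 2, 2, 3, 3, 2, 2, 1, 1))
    truth <- list(area = 5, perimeter = 12, solidity = 5 / 7,
                  ipq = 4 * pi * 5 / 144)
  } else { # square
    side <- radius
    m <- max(4L, n %/% 4L)
    e <- seq(0, side, length.out = m + 1L)[-(m + 1L)]
    pts <- rbind(cbind(e, 0), cbind(side, e), cbind(side - e, side), cbind(0, side - e))
    truth <- list(area = side^2, perimeter = 4 * side, solidity = 1, ipq = pi / 4)
  }
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    pts <- pts + matrix(rnorm(length(pts), sd = noise), ncol = 2L)
  }
  truth$kind <- kind
  list(contour = planar_contour(pts), truth = truth)
}

#' Boltzmann-distributed per-cell measurements
#'
#' Under thermal-like fluctuations at energy scale `kBT`, per-cell areas and
#' apical lengths are independent Gaussians with variances `kBT / (2 k_A)`
#' and `kBT / (2 k_l)` about their preferred values. These samples feed the
#' stringency estimator `k = var(A) / (var(l_a) A0)`, whose ground truth here
#' is `k_l / (k_A A0)`.
#'
#' @param n number of cells (>= 3).
#' @param k_A,k_l area and length spring constants (> 0).
#' @param A_0 preferred cell area.
#' @param l_a preferred apical length.
#' @param kBT effective thermal energy (> 0).
#' @param seed RNG seed.
#' @return list with `areas`, `apical_lengths`, and `k_true`.
#' @export
sample_boltzmann_cells <- function(n, k_A = 1, k_l = 2, A_0 = 1, l_a = 0.6,
                                   kBT = 0.05, seed = NULL) {
  if (n < 3L) stop("n must be >= 3")
  if (min(k_A, k_l, kBT) <= 0) stop("k_A, k_l and kBT must be positive")
  if (!is.null(seed)) set.seed(seed)
  sd_A <- sqrt(kBT / (2 * k_A))
  sd_l <- sqrt(kBT / (2 * k_l))
  if (pnorm(0, l_a, sd_l) > 0.01) {
    warning("more than 1% of apical-length mass is negative at these parameters")
  }
  list(areas = rnorm(n, A_0, sd_A), apical_lengths = rnorm(n, l_a, sd_l),
       k_true = k_l / (k_A * A_0))
}

#' Annulus cross-section fixture
#'
#' Concentric (or offset) circles as a lumen/basal polygon pair, with the
#' exact mean-thickness (R - r) and normalized-radius (r / (R - r))
#' ground truths.
#'
#' @param R basal (outer) radius.
#' @param r lumen (inner) radius, `0 < r < R`.
#' @param offset lumen center displacement along x; must keep the lumen
#'   strictly inside.
#' @param n polygon vertices per circle.
#' @param n_cells cell count recorded on the cross-section.
#' @return list with `cross_section` (a [spheroid_cross_section()]) and
#'   `truth` (`thickness`, `r_norm`).
#' @export
make_annulus_cross_section <- function(R, r, offset = 0, n = 720L, n_cells = 8L) {
  if (!(R > r && r > 0)) stop("need R > r > 0")
  if (abs(offset) + r >= R) stop("lumen escapes basal circle")
  tt <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  lumen <- cbind(offset + r * cos(tt), r * sin(tt))
  basal <- cbind(R * cos(tt), R * sin(tt))
  list(cross_section = spheroid_cross_section(lumen, basal, n_cells, check = FALSE),
       truth = list(thickness = R - r, r_norm = r / (R - r)))
}
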