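# Independent oracles used across tests, deliberately sharing no code with
# the implementation paths they check.

# central-finite-difference curvature of a fourier_contour at parameter s
fd_curvature <- function(fc, s, h = 1e-4) {
  p0 <- fourier_eval(fc, s)
  pp <- fourier_eval(fc, s + h)
  pm <- fourier_eval(fc, s - h)
  d1 <- (pp - pm) / (2 * h)
  d2 <- (pp - 2 * p0 + pm) / h^2
  (d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) / (d1[, 1]^2 + d1[, 2]^2)^1.5
}

# shoelace area of a dense polygonalization of one cell (4 boundaries, arcs
# sampled at n points each) -- oracle for the closed-form cell area
cell_area_oracle <- function(state, i, n = 512) {
  N <- state$n_cells
  j <- if (i == N) 1 else i + 1
  arc_pts <- function(p1, p2, kappa) {
    d <- sqrt(sum((p2 - p1)^2))
    tt <- seq(0, 1, length.out = n + 1)[-(n + 1)]
    a <- abs(kappa) * d / 2
    if (a < 1e-9) {
      return(cbind(p1[1] + tt * (p2[1] - p1[1]), p1[2] + tt * (p2[2] - p1[2])))
    }
    R <- 1 / abs(kappa)
    u <- (p2 - p1) / d
    n_out <- c(u[2], -u[1])
    ctr <- (p1 + p2) / 2 - sign(kappa) * sqrt(max(R^2 - (d / 2)^2, 0)) * n_out
    th <- 2 * asin(min(a, 1))
    phi1 <- atan2(p1[2] - ctr[2], p1[1] - ctr[1])
    phi <- phi1 + sign(kappa) * th * tt
    cbind(ctr[1] + R * cos(phi), ctr[2] + R * sin(phi))
  }
  bi <- c(state$bx[i], state$by[i]); bj <- c(state$bx[j], state$by[j])
  ai <- c(state$ax[i], state$ay[i]); aj <- c(state$ax[j], state$ay[j])
  poly <- rbind(arc_pts(bi, bj, state$kb[i]),      # basal arc forward
                arc_pts(bj, aj, 0),                # lateral up
                arc_pts(aj, ai, -state$ka[i]),     # apical arc reversed
                arc_pts(ai, bi, 0))                # lateral down
  m <- nrow(poly)
  k <- c(2:m, 1)
  0.5 * sum(poly[, 1] * poly[k, 2] - poly[k, 1] * poly[, 2])
}

lumen_area_oracle <- function(state, n = 512) {
  poly <- lumenmorph:::loop_polygon(state, "apical", n)
  m <- nrow(poly)
  k <- c(2:m, 1)
  0.5 * sum(poly[, 1] * poly[k, 2] - poly[k, 1] * poly[, 2])
}

# a random feasible (arcs well under the semicircle limit) spheroid state
random_feasible_state <- function(N = 5, seed = 1) {
  set.seed(seed)
  th_b <- sort(runif(N, 0, 2 * pi))
  th_a <- sort(runif(N, 0, 2 * pi))
  rb <- 2 + runif(N, -0.1, 0.1)
  ra <- 1 + runif(N, -0.1, 0.1)
  st <- lumenmorph:::new_spheroid_state(
    ra * cos(th_a), ra * sin(th_a), rb * cos(th_b), rb * sin(th_b),
    runif(N, -0.3, 0.3), runif(N, -0.3, 0.3))
  st
}

# brute-force convex hull area from dense boundary samples
hull_area_oracle <- function(pts) {
  h <- grDevices::chull(pts)
  p <- pts[h, , drop = FALSE]
  m <- nrow(p)
  k <- c(2:m, 1)
  abs(0.5 * sum(p[, 1] * p[k, 2] - p[k, 1] * p[, 2]))
}

# random simple star-shaped polygon about the origin
random_star_polygon <- function(n = 24, seed = 1, rmin = 0.5, rmax = 1.5) {
  set.seed(seed)
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, rmin, rmax)
  cbind(r * cos(th), r * sin(th))
}
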