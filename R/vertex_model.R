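# Dimensionless 2D vertex model of a growing spheroid. A state holds, for N
# cells, the apical and basal vertex positions plus one signed apical and one
# signed basal arc curvature per cell (6N coordinates). Cell i is bounded by
# the basal arc b_i -> b_{i+1}, two straight laterals, and the apical arc
# a_i -> a_{i+1}; positive curvature bulges away from the enclosed interior.
# All lengths are in units of sqrt(A0), areas in units of A0, energies in
# units of k_A A0^2.

#' Vertex-model parameters
#'
#' @param p dimensionless luminal pressure (pressure over the area-elasticity
#'   scale `k_A A0`); may be zero or negative.
#' @param k dimensionless stringency of membrane-domain size regulation
#'   (`k_l / (k_A A0)`), > 0.
#' @param la,lb dimensionless preferred apical and basal lengths
#'   (`l / sqrt(A0)`), >= 0. Laterals have rest length zero.
#' @param n_target final cell count of a growth run (default 10).
#' @param seed RNG seed controlling initialization and descent noise.
#' @param step optimizer step size (dimensionless units).
#' @param noise initial scale of the Gaussian direction noise (decays as
#'   `1/sqrt(iter)`).
#' @param tol convergence tolerance: size of the single-coordinate probe move
#'   that must not lower the energy (default 0.01 dimensionless units).
#' @param tol_disp max-norm displacement of a full descent pass below which
#'   the probe certificate is attempted.
#' @param maxit iteration cap per minimization.
#' @return object of class `vm_params`.
#' @export
vm_params <- function(p = 1, k = 2, la = 0.6, lb = 1, n_target = 10L,
                      seed = 1L, step = 1e-3, noise = 0.05, tol = 0.01,
                      tol_disp = 1e-3, maxit = 5000L) {
  if (k <= 0) stop("k must be > 0")
  if (la < 0 || lb < 0) stop("preferred lengths must be >= 0")
  if (tol <= 0) stop("tol must be > 0")
  if (n_target < 3L) stop("n_target must be >= 3")
  structure(list(p = p, k = k, la = la, lb = lb, n_target = as.integer(n_target),
                 seed = as.integer(seed), step = step, noise = noise, tol = tol,
                 tol_disp = tol_disp, maxit = as.integer(maxit)),
            class = "vm_params")
}

#' Named parameter presets for the three experimental conditions
#'
#' `"WT"` uses the data-estimated la = 0.6 and k = 2.0; `"Rab11aOE"` raises
#' la to 0.8; `"CldnqKO"` raises la to 1.0 and divides the pressure tenfold
#' (leaky tight junctions). Pressure and lb are free parameters of the model,
#' calibrated once so that the leaky-junction condition reproduces the
#' observed ordering (larger lumen cross-section and basal length than wild
#' type at matched cell number, with only a moderate solidity change):
#' p = 0.2, lb = 1.0.
#'
#' @param name preset name.
#' @param ... overrides passed to [vm_params()].
#' @export
vm_preset <- function(name = c("WT", "Rab11aOE", "CldnqKO"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    WT = list(p = 0.2, k = 2, la = 0.6, lb = 1),
    Rab11aOE = list(p = 0.2, k = 2, la = 0.8, lb = 1),
    CldnqKO = list(p = 0.02, k = 2, la = 1.0, lb = 1))
  do.call(vm_params, utils::modifyList(base, list(...)))
}

new_spheroid_state <- function(ax, ay, bx, by, ka, kb) {
  structure(list(n_cells = length(ax), ax = ax, ay = ay, bx = bx, by = by,
                 ka = ka, kb = kb),
            class = "spheroid_state")
}

pack_state <- function(state) {
  c(state$ax, state$ay, state$bx, state$by, state$ka, state$kb)
}

unpack_state <- function(x, N) {
  new_spheroid_state(x[1:N], x[N + 1:N], x[2 * N + 1:N], x[3 * N + 1:N],
                     x[4 * N + 1:N], x[5 * N + 1:N])
}

#' Initialize a 3-cell spheroid
#'
#' Basal vertices evenly spaced on a circle of radius 2; apical vertices drawn
#' independently and uniformly from the interior of the unit disk, then
#' relabelled in counterclockwise angular order about their centroid (a
#' relabelling of an exchangeable draw, needed so cell adjacency is well
#' defined); apical curvatures uniform on \[1, 2\]; basal curvatures start at
#' 1/2, the curvature of the radius-2 basal circle.
#'
#' The draw is rejection-sampled: configurations whose apical arcs
#' self-intersect (possible for strongly bowed arcs between nearby vertices)
#' are redrawn, conditioning the stated distribution on a physically valid
#' spheroid. This keeps the self-intersection constraint active from the
#' first descent step.
#'
#' @param params a [vm_params()]; its `seed` is applied before drawing.
#' @return a `spheroid_state` with 3 cells.
#' @export
init_spheroid <- function(params) {
  stopifnot(inherits(params, "vm_params"))
  set.seed(params$seed)
  th <- 2 * pi * (0:2) / 3
  for (try in 1:1000) {
    r <- sqrt(runif(3))
    phi <- 2 * pi * runif(3)
    ax <- r * cos(phi); ay <- r * sin(phi)
    ctr <- c(mean(ax), mean(ay))
    o <- order(atan2(ay - ctr[2L], ax - ctr[1L]))
    st <- new_spheroid_state(ax[o], ay[o], 2 * cos(th), 2 * sin(th),
                             runif(3, 1, 2), rep(0.5, 3))
    if (vm_simple_cpp(pack_state(st), 3L)) return(st)
  }
  stop("could not draw a non-self-intersecting initial state")
}

#' Per-cell geometry of a state
#'
#' Arc lengths from chord `d` and curvature `kappa` via
#' `l = (2/|kappa|) asin(|kappa| d / 2)` (reducing to `d` as `kappa -> 0`),
#' cell areas as the vertex-quad shoelace area plus/minus the circular-segment
#' areas of the basal and apical arcs, and straight lateral lengths.
#'
#' @param state a `spheroid_state`.
#' @param i optional single cell index (1-based); if given, a list for that
#'   cell with `A_i`, `l_a`, `l_b`, `l_l_left`, `l_l_right`.
#' @return data.frame over cells (or a list for one cell).
#' @export
geometry_terms <- function(state, i = NULL) {
  stopifnot(inherits(state, "spheroid_state"))
  N <- state$n_cells
  g <- vm_geometry_cpp(pack_state(state), N)
  if (!g$feasible) stop("infeasible arc: chord longer than arc diameter")
  nxt <- c(2:N, 1L)
  df <- data.frame(cell = seq_len(N), area = g$area, l_a = g$l_a, l_b = g$l_b,
                   l_l_left = g$l_l, l_l_right = g$l_l[nxt])
  if (is.null(i)) return(df)
  as.list(df[i, -1L])
}

#' Lumen area of a state
#'
#' Shoelace area of the apical-vertex polygon plus the signed segment areas of
#' the apical arcs (arcs bulging away from the lumen add area).
#'
#' @param state a `spheroid_state`.
#' @export
lumen_area <- function(state) {
  stopifnot(inherits(state, "spheroid_state"))
  # validity is judged on the sampled arc boundary (same sampler the
  # optimizer's physicality check uses): chords of strongly bulging arcs may
  # cross even when the lumen outline is a perfectly simple curve
  if (!vm_loop_simple_cpp(state$ax, state$ay, state$ka)) {
    stop("invalid lumen: apical loop self-intersects")
  }
  g <- vm_geometry_cpp(pack_state(state), state$n_cells)
  if (!g$feasible) stop("infeasible arc: chord longer than arc diameter")
  g$lumen_area
}

#' Dimensionless vertex-model energy
#'
#' `H = -p A_L + sum_i [(A_i - 1)^2 + k ((l_a,i - la)^2 + (l_b,i - lb)^2 +
#' l_l,i^2)]`, with one lateral term per cell (each lateral belongs to exactly
#' one summand). The pressure term is attributed to no cell.
#'
#' @param state a `spheroid_state`.
#' @param params a [vm_params()].
#' @return list with `energy`, `per_cell` (the bracketed summand of each
#'   cell), and `lumen_area`.
#' @export
vm_energy <- function(state, params) {
  stopifnot(inherits(state, "spheroid_state"), inherits(params, "vm_params"))
  g <- vm_geometry_cpp(pack_state(state), state$n_cells)
  if (!g$feasible) stop("infeasible arc: chord longer than arc diameter")
  e <- vm_energy_cpp(pack_state(state), state$n_cells,
                     params$p, params$k, params$la, params$lb)
  list(energy = e$energy, per_cell = e$per_cell, lumen_area = e$lumen_area)
}

#' Dimensional vertex-model energy
#'
#' The dimensional Hamiltonian `-P_L A_L + sum_i [k_A (A_i - A0)^2 +
#' k_l ((l_a,i - l_a)^2 + (l_b,i - l_b)^2 + l_l,i^2)]`, evaluated directly on
#' a state expressed in physical units. Dividing by `k_A A0^2` and mapping the
#' parameters through [nondimensionalize_params()] recovers the dimensionless
#' energy; tests assert this correspondence.
#'
#' @param state a `spheroid_state` in physical units.
#' @param P_L,k_A,A_0,k_l,l_a,l_b dimensional model constants.
#' @export
vm_energy_dimensional <- function(state, P_L, k_A, A_0, k_l, l_a, l_b) {
  stopifnot(inherits(state, "spheroid_state"))
  g <- vm_geometry_cpp(pack_state(state), state$n_cells)
  if (!g$feasible) stop("infeasible arc")
  -P_L * g$lumen_area + sum(k_A * (g$area - A_0)^2 +
    k_l * ((g$l_a - l_a)^2 + (g$l_b - l_b)^2 + g$l_l^2))
}

#' Map dimensional constants to the dimensionless parameters
#'
#' `p = P_L / (k_A A0)`, `k = k_l / (k_A A0)`, `la = l_a / sqrt(A0)`,
#' `lb = l_b / sqrt(A0)`.
#'
#' @inheritParams vm_energy_dimensional
#' @param ... further arguments passed to [vm_params()].
#' @export
nondimensionalize_params <- function(P_L, k_A, A_0, k_l, l_a, l_b, ...) {
  vm_params(p = P_L / (k_A * A_0), k = k_l / (k_A * A_0),
            la = l_a / sqrt(A_0), lb = l_b / sqrt(A_0), ...)
}

#' Rescale a state between dimensional and dimensionless units
#'
#' Positions scale with `sqrt(A0)`, curvatures with `1/sqrt(A0)`.
#'
#' @param state a `spheroid_state`.
#' @param length_scale multiplicative factor applied to positions.
#' @export
scale_state <- function(state, length_scale) {
  new_spheroid_state(state$ax * length_scale, state$ay * length_scale,
                     state$bx * length_scale, state$by * length_scale,
                     state$ka / length_scale, state$kb / length_scale)
}

#' Minimize the energy of a state
#'
#' Stochastic gradient descent on the 6N coordinates (finite-difference
#' gradient, seeded Gaussian direction noise decaying as `1/sqrt(iter)`,
#' backtracking so the energy never increases and self-intersecting proposals
#' are rejected). Terminates when a full pass moves every coordinate by less
#' than `tol_disp` and no single-coordinate move of size `tol` lowers the
#' energy — an operational certificate that the state is within `tol` of a
#' local minimum.
#'
#' @param state a `spheroid_state`.
#' @param params a [vm_params()].
#' @param seed optional seed applied before the run; by default the current
#'   RNG stream continues (so [grow_spheroid()] controls one stream).
#' @return the minimized `spheroid_state`, with attributes `energy`,
#'   `energy0`, `converged`, `iterations`.
#' @export
vm_minimize <- function(state, params, seed = NULL) {
  stopifnot(inherits(state, "spheroid_state"), inherits(params, "vm_params"))
  if (!is.null(seed)) set.seed(seed)
  res <- vm_minimize_cpp(pack_state(state), state$n_cells,
                         params$p, params$k, params$la, params$lb,
                         step0 = params$step, noise0 = params$noise,
                         tol_disp = params$tol_disp, probe = params$tol,
                         maxit = params$maxit)
  out <- unpack_state(res$state, state$n_cells)
  attr(out, "energy") <- res$energy
  attr(out, "energy0") <- res$energy0
  attr(out, "converged") <- res$converged
  attr(out, "iterations") <- res$iterations
  if (!res$converged) warning("minimization did not converge; best state returned")
  out
}

# point halfway along a circular arc from p1 to p2 with signed curvature kappa
arc_midpoint <- function(p1, p2, kappa) {
  d <- sqrt(sum((p2 - p1)^2))
  mid <- (p1 + p2) / 2
  a <- abs(kappa) * d / 2
  if (a < 1e-9) return(mid)
  if (a > 1) stop("infeasible arc")
  R <- 1 / abs(kappa)
  h <- R - sqrt(max(R^2 - (d / 2)^2, 0))
  u <- (p2 - p1) / d
  n_out <- c(u[2L], -u[1L]) # right of the traversal direction
  mid + sign(kappa) * h * n_out
}

#' Divide the highest-energy cell
#'
#' The cell with the largest per-cell energy summand (pressure excluded; ties
#' broken toward the lowest index) is split by inserting a new apical and a
#' new basal vertex at the midpoints of its apical and basal arcs. Daughters
#' inherit the parent's arc curvatures, so the union of boundaries — and with
#' it the lumen area, every cell area, and every boundary length — is
#' unchanged at the instant of division.
#'
#' @param state a `spheroid_state` with at least 3 cells.
#' @param params a [vm_params()] (needed to evaluate per-cell energies).
#' @return a `spheroid_state` with one more cell.
#' @export
divide_highest_energy_cell <- function(state, params) {
  stopifnot(inherits(state, "spheroid_state"), inherits(params, "vm_params"))
  N <- state$n_cells
  if (N < 3L) stop("need at least 3 cells")
  e <- vm_energy_cpp(pack_state(state), N, params$p, params$k, params$la, params$lb)
  i <- which.max(e$per_cell) # first index wins ties
  j <- if (i == N) 1L else i + 1L
  am <- arc_midpoint(c(state$ax[i], state$ay[i]), c(state$ax[j], state$ay[j]),
                     state$ka[i])
  bm <- arc_midpoint(c(state$bx[i], state$by[i]), c(state$bx[j], state$by[j]),
                     state$kb[i])
  ins <- function(v, val) append(v, val, after = i)
  new_spheroid_state(ins(state$ax, am[1L]), ins(state$ay, am[2L]),
                     ins(state$bx, bm[1L]), ins(state$by, bm[2L]),
                     ins(state$ka, state$ka[i]), ins(state$kb, state$kb[i]))
}

#' Grow a spheroid from 3 cells to the target size
#'
#' Alternates energy minimization and division of the highest-energy cell,
#' starting from [init_spheroid()] (which applies the seed), and returns every
#' minimized state from N = 3 up to `n_target`.
#'
#' @param params a [vm_params()].
#' @return object of class `spheroid_trajectory`: list with `states` (one
#'   minimized `spheroid_state` per N), `params`, and a `summary` data.frame
#'   (`n_cells`, `energy`, `converged`).
#' @export
grow_spheroid <- function(params) {
  stopifnot(inherits(params, "vm_params"))
  state <- init_spheroid(params)
  states <- list()
  repeat {
    state <- suppressWarnings(vm_minimize(state, params))
    states[[length(states) + 1L]] <- state
    if (state$n_cells >= params$n_target) break
    if (!attr(state, "converged")) break # truncate, flagged in summary
    state <- divide_highest_energy_cell(state, params)
  }
  summary <- data.frame(
    n_cells = vapply(states, function(s) s$n_cells, integer(1)),
    energy = vapply(states, function(s) attr(s, "energy"), numeric(1)),
    converged = vapply(states, function(s) attr(s, "converged"), logical(1)))
  structure(list(states = states, params = params, summary = summary),
            class = "spheroid_trajectory")
}

# polygonalize the apical (or basal) loop: n points per arc
loop_polygon <- function(state, which = c("apical", "basal"), n = 512L) {
  which <- match.arg(which)
  N <- state$n_cells
  if (which == "apical") {
    px <- state$ax; py <- state$ay; kk <- state$ka
  } else {
    px <- state$bx; py <- state$by; kk <- state$kb
  }
  out <- vector("list", N)
  for (i in seq_len(N)) {
    j <- if (i == N) 1L else i + 1L
    p1 <- c(px[i], py[i]); p2 <- c(px[j], py[j])
    d <- sqrt(sum((p2 - p1)^2))
    a <- abs(kk[i]) * d / 2
    tt <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    if (a < 1e-9) {
      seg <- cbind(p1[1L] + tt * (p2[1L] - p1[1L]), p1[2L] + tt * (p2[2L] - p1[2L]))
    } else {
      R <- 1 / abs(kk[i])
      u <- (p2 - p1) / d
      n_out <- c(u[2L], -u[1L])
      ctr <- (p1 + p2) / 2 - sign(kk[i]) * sqrt(max(R^2 - (d / 2)^2, 0)) * n_out
      th <- 2 * asin(min(a, 1))
      phi1 <- atan2(p1[2L] - ctr[2L], p1[1L] - ctr[1L])
      phi <- phi1 + sign(kk[i]) * th * tt
      seg <- cbind(ctr[1L] + R * cos(phi), ctr[2L] + R * sin(phi))
    }
    out[[i]] <- seg
  }
  do.call(rbind, out)
}

#' Shape measurements of a state
#'
#' Polygonalizes the apical and basal loops (`n_arc` points per arc) and hands
#' them to the cross-section metric functions, so a state is measured exactly
#' as a traced cross-section would be.
#'
#' @param state a `spheroid_state`.
#' @param params optional [vm_params()]; when given, total and per-cell
#'   energies are included.
#' @param n_arc points per arc for polygonalization.
#' @return one-row data.frame: `n_cells`, `lumen_area_norm`, `lumen_solidity`,
#'   `normalized_lumen_radius`, `mean_basal_length_norm`, `mean_apical_length`,
#'   and `energy` when `params` is given.
#' @export
measure_state <- function(state, params = NULL, n_arc = 512L) {
  stopifnot(inherits(state, "spheroid_state"))
  lp <- loop_polygon(state, "apical", n_arc)
  bp <- loop_polygon(state, "basal", n_arc)
  g <- geometry_terms(state)
  cs <- spheroid_cross_section(lp, bp, n_cells = state$n_cells, check = FALSE)
  out <- data.frame(n_cells = state$n_cells,
                    lumen_area_norm = lumen_area(state),
                    lumen_solidity = solidity(lp, check = FALSE),
                    normalized_lumen_radius = normalized_lumen_radius(cs)$r_norm,
                    mean_basal_length_norm = mean(g$l_b),
                    mean_apical_length = mean(g$l_a))
  if (!is.null(params)) out$energy <- vm_energy(state, params)$energy
  out
}

#' Estimate model parameters from per-cell measurements
#'
#' `A0` is the mean cell cross-sectional area; `la` the mean apical length
#' over `sqrt(A0)`; and the stringency `k` is the variance ratio
#' `var(areas) / (var(apical lengths) * A0)` — the Boltzmann-fluctuation
#' estimator, since thermal-like fluctuations give `var(A) = kBT / (2 k_A)`
#' and `var(l_a) = kBT / (2 k_l)`.
#'
#' @param areas per-cell cross-sectional areas (>= 3 values).
#' @param apical_lengths per-cell apical lengths (>= 3 values).
#' @return list with `A_0`, `la_tilde`, `k`.
#' @export
estimate_params <- function(areas, apical_lengths) {
  if (length(areas) < 3L || length(apical_lengths) < 3L) {
    stop("need at least 3 samples of each")
  }
  if (var(apical_lengths) == 0) stop("zero variance in apical lengths")
  A0 <- mean(areas)
  list(A_0 = A0, la_tilde = mean(apical_lengths) / sqrt(A0),
       k = var(areas) / (var(apical_lengths) * A0))
}

#' Run growth simulations over a parameter grid
#'
#' @param grid data.frame with columns among `p`, `k`, `la`, `lb` (one row per
#'   condition); missing columns take the [vm_params()] defaults.
#' @param seeds integer vector of seeds (one replicate per seed).
#' @param n_target final cell count.
#' @param ... further arguments to [vm_params()].
#' @return tidy data.frame: one row per (condition, seed, N) with the
#'   parameters, shape measurements, energy and convergence flag.
#' @export
vm_sweep <- function(grid, seeds = 1:25, n_target = 10L, ...) {
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cond <- as.list(grid[g, , drop = FALSE])
    for (s in seeds) {
      par <- do.call(vm_params,
                     c(cond, list(seed = s, n_target = n_target), ...))
      traj <- grow_spheroid(par)
      for (st in traj$states) {
        m <- tryCatch(measure_state(st, par), error = function(e) {
          data.frame(n_cells = st$n_cells, lumen_area_norm = NA_real_,
                     lumen_solidity = NA_real_,
                     normalized_lumen_radius = NA_real_,
                     mean_basal_length_norm = NA_real_,
                     mean_apical_length = NA_real_, energy = NA_real_)
        })
        m$valid <- !anyNA(m)
        m$seed <- s
        m$p <- par$p; m$k <- par$k; m$la <- par$la; m$lb <- par$lb
        m$converged <- attr(st, "converged")
        rows[[length(rows) + 1L]] <- m
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.spheroid_state <- function(x, ...) {
  cat(sprintf("spheroid_state: %d cells\n", x$n_cells))
  invisible(x)
}

#' @export
print.spheroid_trajectory <- function(x, ...) {
  cat(sprintf("spheroid_trajectory: N = %d..%d, final energy %.4f\n",
              x$summary$n_cells[1L], tail(x$summary$n_cells, 1L),
              tail(x$summary$energy, 1L)))
  invisible(x)
}
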