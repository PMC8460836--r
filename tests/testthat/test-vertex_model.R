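test_that("initialization matches the stated construction and is reproducible", {
  par <- vm_params(seed = 42)
  st <- init_spheroid(par)
  expect_equal(st$n_cells, 3L)
  expect_equal(sqrt(st$bx^2 + st$by^2), rep(2, 3))
  expect_true(all(sqrt(st$ax^2 + st$ay^2) < 1))
  expect_true(all(st$ka >= 1 & st$ka <= 2))
  expect_equal(st$kb, rep(0.5, 3))
  st2 <- init_spheroid(par)
  expect_identical(st, st2)
  st3 <- init_spheroid(vm_params(seed = 43))
  expect_false(identical(st$ax, st3$ax))
})

test_that("arc geometry matches closed forms and a polygonalization oracle", {
  # a semicircular apical arc: chord 2r, curvature 1/r -> length pi r,
  # and the arc contributes a half-disk of area to the lumen
  r <- 0.8
  st <- lumenmorph:::new_spheroid_state(
    ax = c(r, -r, 0), ay = c(0, 0, -0.6),
    bx = 2 * cos(2 * pi * (0:2) / 3 + pi / 2),
    by = 2 * sin(2 * pi * (0:2) / 3 + pi / 2),
    ka = c(1 / r, 0, 0), kb = rep(0, 3))
  g <- geometry_terms(st)
  expect_equal(g$l_a[1], pi * r, tolerance = 1e-12)
  chord_poly <- abs(lumenmorph:::polygon_area_signed(cbind(st$ax, st$ay)))
  expect_equal(lumen_area(st), chord_poly + pi * r^2 / 2, tolerance = 1e-12)

  # straight boundaries: lengths are chords, areas are polygon areas
  g0 <- geometry_terms(lumenmorph:::new_spheroid_state(
    st$ax, st$ay, st$bx, st$by, rep(0, 3), rep(0, 3)))
  expect_equal(g0$l_a[1], 2 * r, tolerance = 1e-12)

  # random feasible states against the dense polygonalization oracle
  for (seed in 1:6) {
    stR <- random_feasible_state(N = 5, seed = seed)
    gR <- geometry_terms(stR)
    for (i in 1:5) {
      expect_equal(gR$area[i], cell_area_oracle(stR, i, n = 2048),
                   tolerance = 1e-6)
    }
    expect_equal(lumen_area(stR), lumen_area_oracle(stR, n = 4096),
                 tolerance = 1e-6)
  }

  # infeasible arc: chord longer than the arc diameter
  bad <- random_feasible_state(N = 4, seed = 1)
  bad$ka[1] <- 50
  expect_error(geometry_terms(bad), "infeasible arc")
})

test_that("the energy is the stated sum of pressure, area, and spring terms", {
  par <- vm_params(p = 0.7, k = 2, la = 0.6, lb = 1)
  st <- random_feasible_state(N = 6, seed = 2)
  g <- geometry_terms(st)
  e <- vm_energy(st, par)
  manual_cells <- (g$area - 1)^2 +
    par$k * ((g$l_a - par$la)^2 + (g$l_b - par$lb)^2 + g$l_l_left^2)
  expect_equal(e$per_cell, manual_cells, tolerance = 1e-12)
  expect_equal(e$energy, -par$p * lumen_area(st) + sum(manual_cells),
               tolerance = 1e-12)

  # the pressure term is linear in lumen area and belongs to no cell
  e0 <- vm_energy(st, vm_params(p = 0, k = 2, la = 0.6, lb = 1))
  expect_equal(e0$energy - e$energy, 0.7 * e$lumen_area, tolerance = 1e-12)
  expect_equal(e0$per_cell, e$per_cell)
})

test_that("dimensional and dimensionless Hamiltonians agree under the map", {
  for (seed in 1:5) {
    st <- random_feasible_state(N = 5, seed = seed)
    P_L <- 0.8; k_A <- 2.5; A_0 <- 3.2; k_l <- 4.1
    l_a <- 0.6 * sqrt(A_0); l_b <- 1.0 * sqrt(A_0)
    par <- nondimensionalize_params(P_L, k_A, A_0, k_l, l_a, l_b)
    st_dim <- scale_state(st, sqrt(A_0))
    E_dim <- vm_energy_dimensional(st_dim, P_L, k_A, A_0, k_l, l_a, l_b)
    E_nd <- vm_energy(st, par)$energy
    expect_equal(E_dim, k_A * A_0^2 * E_nd, tolerance = 1e-8)
  }
})

test_that("minimization descends and certifies near-stationarity", {
  par <- vm_params(p = 1, seed = 7, n_target = 3, maxit = 4000)
  st <- init_spheroid(par)
  e0 <- vm_energy(st, par)$energy
  mn <- vm_minimize(st, par, seed = 7)
  expect_true(attr(mn, "converged"))
  expect_lte(attr(mn, "energy"), e0)
  expect_equal(attr(mn, "energy0"), e0, tolerance = 1e-10)

  # finite-difference gradient certificate: no coordinate gradient exceeds
  # what the 0.01-probe acceptance bound allows given the local curvature
  x <- lumenmorph:::pack_state(mn)
  g <- lumenmorph:::vm_grad_cpp(x, mn$n_cells, par$p, par$k, par$la, par$lb)
  hdiag <- vapply(seq_along(x), function(i) {
    h <- 1e-4
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    ep <- lumenmorph:::vm_energy_cpp(xp, mn$n_cells, par$p, par$k, par$la, par$lb)$energy
    em <- lumenmorph:::vm_energy_cpp(xm, mn$n_cells, par$p, par$k, par$la, par$lb)$energy
    e0 <- lumenmorph:::vm_energy_cpp(x, mn$n_cells, par$p, par$k, par$la, par$lb)$energy
    (ep - 2 * e0 + em) / h^2
  }, numeric(1))
  bound <- 0.5 * max(abs(hdiag)) * par$tol * 1.5
  expect_lt(max(abs(g)), bound)

  # an already-minimal state is left essentially unchanged
  mn2 <- vm_minimize(mn, par, seed = 8)
  expect_lt(max(abs(lumenmorph:::pack_state(mn2) - x)), par$tol)
})

test_that("division splits the highest-energy cell and conserves geometry", {
  par <- vm_params(p = 1, seed = 5)
  st <- vm_minimize(init_spheroid(par), par, seed = 5)
  e <- vm_energy(st, par)
  target <- which.max(e$per_cell)
  child <- divide_highest_energy_cell(st, par)
  expect_equal(child$n_cells, st$n_cells + 1L)

  # inserted apical vertex is the parent arc's midpoint
  i <- target
  j <- if (i == st$n_cells) 1L else i + 1L
  am <- lumenmorph:::arc_midpoint(c(st$ax[i], st$ay[i]),
                                  c(st$ax[j], st$ay[j]), st$ka[i])
  expect_equal(c(child$ax[i + 1], child$ay[i + 1]), am, tolerance = 1e-12)
  expect_equal(child$ka[i], st$ka[i])
  expect_equal(child$ka[i + 1], st$ka[i])

  # conservation at the instant of division
  expect_equal(lumen_area(child), lumen_area(st), tolerance = 1e-9)
  g0 <- geometry_terms(st); g1 <- geometry_terms(child)
  expect_equal(sum(g1$area), sum(g0$area), tolerance = 1e-9)
  expect_equal(sum(g1$l_a), sum(g0$l_a), tolerance = 1e-9)
  expect_equal(sum(g1$l_b), sum(g0$l_b), tolerance = 1e-9)
  # daughters split the parent boundary in half
  expect_equal(g1$l_a[i], g0$l_a[i] / 2, tolerance = 1e-12)

  # exact tie: a square state with exact +-1/0 coordinates has bitwise-equal
  # per-cell energies; the lowest index wins
  sym <- lumenmorph:::new_spheroid_state(
    c(1, 0, -1, 0), c(0, 1, 0, -1),
    c(2, 0, -2, 0), c(0, 2, 0, -2),
    rep(0.5, 4), rep(0.5, 4))
  esym <- vm_energy(sym, par)$per_cell
  expect_true(all(esym == esym[1])) # the tie is exact
  div <- divide_highest_energy_cell(sym, par)
  expect_equal(c(div$ax[2], div$ay[2]), lumenmorph:::arc_midpoint(
    c(sym$ax[1], sym$ay[1]), c(sym$ax[2], sym$ay[2]), 0.5),
    tolerance = 1e-12)
})

test_that("growth runs 3 to n_target with non-increasing energy per stage", {
  par <- vm_params(p = 1, la = 0.6, k = 2, lb = 1, seed = 11, n_target = 10)
  traj <- grow_spheroid(par)
  expect_equal(traj$summary$n_cells, 3:10)
  expect_true(all(traj$summary$converged))
  # every minimize call ended at or below its starting energy
  for (s in traj$states) {
    expect_lte(attr(s, "energy"), attr(s, "energy0") + 1e-12)
  }
  # determinism under the seed
  traj2 <- grow_spheroid(par)
  expect_identical(traj$summary, traj2$summary)
})

test_that("state measurements agree bitwise with the 2D metric functions", {
  par <- vm_params(p = 1, seed = 13, n_target = 4)
  traj <- grow_spheroid(par)
  st <- traj$states[[2]]
  m <- measure_state(st, par)
  lp <- lumenmorph:::loop_polygon(st, "apical", 512)
  bp <- lumenmorph:::loop_polygon(st, "basal", 512)
  expect_identical(m$lumen_solidity, solidity(lp, check = FALSE))
  cs <- spheroid_cross_section(lp, bp, st$n_cells, check = FALSE)
  expect_identical(m$normalized_lumen_radius, normalized_lumen_radius(cs)$r_norm)

  # near-circular lumen measures as fully convex
  circ <- lumenmorph:::new_spheroid_state(
    cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6),
    2 * cos(2 * pi * (0:5) / 6), 2 * sin(2 * pi * (0:5) / 6),
    rep(1, 6), rep(0.5, 6))
  expect_equal(measure_state(circ)$lumen_solidity, 1, tolerance = 1e-9)
  expect_equal(measure_state(circ)$lumen_area_norm, pi, tolerance = 1e-9)

  # one deeply re-entrant apical arc drops solidity below 1
  dent <- circ
  dent$ka[1] <- -1.9
  expect_lt(measure_state(dent)$lumen_solidity, 1)
})

test_that("pressure raises final solidity (scaled two-condition check)", {
  sw <- vm_sweep(data.frame(p = c(0, 2), la = 0.6, k = 2, lb = 1),
                 seeds = 1:8, n_target = 8)
  fin <- sw[sw$n_cells == 8, ]
  m <- tapply(fin$lumen_solidity, fin$p, mean)
  expect_gt(m[["2"]], m[["0"]])
})

test_that("the Boltzmann estimator recovers the stringency parameter", {
  cells <- sample_boltzmann_cells(1e4, k_A = 1, k_l = 2, A_0 = 1, l_a = 0.6,
                                  kBT = 0.05, seed = 99)
  est <- estimate_params(cells$areas, cells$apical_lengths)
  expect_lt(abs(est$k - 2) / 2, 0.10)
  expect_equal(est$A_0, 1, tolerance = 0.02)
  expect_equal(est$la_tilde, 0.6, tolerance = 0.02)

  # identical variances and unit area give k = 1 exactly
  x <- c(0.9, 1.0, 1.1, 1.05, 0.95)
  shifted <- x - mean(x) + 0.6
  est1 <- estimate_params(x - mean(x) + 1, shifted)
  expect_equal(est1$k, 1, tolerance = 1e-12)
  expect_error(estimate_params(x, rep(0.6, 5)), "zero variance")
  expect_error(estimate_params(x[1:2], x[1:2]), "at least 3")
})
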