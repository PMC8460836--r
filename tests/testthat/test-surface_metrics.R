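# Shared phantoms are built once per test run (lazily) to keep the suite fast.
phantom_cache <- new.env(parent = emptyenv())
get_phantom <- function(name) {
  if (!is.null(phantom_cache[[name]])) return(phantom_cache[[name]])
  ph <- switch(name,
    sphere = make_phantom_surface("sphere", radius = 10, spacing = 0.5),
    sphere_aniso = make_phantom_surface("sphere", radius = 8,
                                        spacing = c(0.25, 0.25, 0.5)),
    ellipsoid = make_phantom_surface("ellipsoid", semi_axes = c(15, 8, 8),
                                     spacing = 0.5),
    bumpy = make_phantom_surface("bumpy_sphere", radius = 10,
                                 bump_amplitude = 0.6, bump_width = 0.8,
                                 spacing = 0.4))
  sm <- suppressWarnings(smooth_stack(ph$surface))
  res <- list(ph = ph, sm = sm)
  phantom_cache[[name]] <- res
  res
}
phys_center <- function(surface) (dim(surface$mask) - 1) / 2 * surface$spacing

test_that("sphere slices smooth to near-perfect circles", {
  p <- get_phantom("sphere")
  ipqs <- vapply(p$sm$xy, function(e) {
    cm <- contour_measures(e$fc)
    4 * pi * cm$area / cm$perimeter^2
  }, numeric(1))
  expect_true(all(ipqs > 0.99))

  # single-slice object cannot support the construction
  thin <- array(FALSE, c(12, 12, 7))
  thin[4:9, 4:9, 4] <- TRUE
  expect_error(suppressWarnings(smooth_stack(voxel_surface(thin))),
               "surface too thin")
})

test_that("anisotropic spacing is honoured in physical units", {
  p <- get_phantom("sphere_aniso")
  ctr <- phys_center(p$ph$surface)
  for (e in p$sm$yz[c(5, 15, 25)]) {
    x0 <- e$fixed - ctr[1]
    rho <- sqrt(8^2 - x0^2)
    cm <- contour_measures(e$fc)
    expect_lt(abs(sqrt(cm$area / pi) - rho) / rho, 0.05)
  }
  va <- volume_and_area(p$ph$surface, p$sm)
  expect_lt(abs(va$V / p$ph$truth$V - 1), 0.02)
})

test_that("volume and area converge on the sphere and scale dimensionally", {
  p <- get_phantom("sphere")
  va <- volume_and_area(p$ph$surface, p$sm)
  expect_lt(abs(va$V - 4188.79) / 4188.79, 0.02)
  expect_lt(abs(va$A - 1256.64) / 1256.64, 0.03)

  # doubling the spacing scales V by 8 and A by 4 (same mask)
  s2 <- voxel_surface(p$ph$surface$mask, spacing = p$ph$surface$spacing * 2)
  va2 <- volume_and_area(s2)
  expect_equal(va2$V / va$V, 8, tolerance = 1e-6)
  expect_equal(va2$A / va$A, 4, tolerance = 1e-6)

  # slab box: V equals slice area x thickness
  m <- array(FALSE, c(30, 40, 12))
  m[6:25, 6:35, 4:9] <- TRUE
  vb <- suppressWarnings(volume_and_area(voxel_surface(m)))
  expect_lt(abs(vb$V - 20 * 30 * 6) / (20 * 30 * 6), 0.02)
})

test_that("mean curvature field matches analytic curvature", {
  p <- get_phantom("sphere")
  fr <- mean_curvature_field(p$ph$surface, p$sm)
  expect_lt(abs(median(fr$H) - 0.1) / 0.1, 0.05)
  expect_lte(fraction_concave(fr), 0.02)

  # two orthogonal normal curvatures agree on an umbilic surface
  ratio <- fr$kn_xy / fr$kn_yz
  expect_lt(median(abs(ratio - 1)), 0.10)
  expect_gt(mean(abs(ratio - 1) < 0.10), 0.9)

  # ellipsoid against the implicit-surface oracle, away from the poles
  pe <- get_phantom("ellipsoid")
  fre <- mean_curvature_field(pe$ph$surface, pe$sm)
  ctr <- phys_center(pe$ph$surface)
  pts <- cbind(fre$x - ctr[1], fre$y - ctr[2], fre$z - ctr[3])
  keep <- abs(pts[, 1]) < 11
  Ht <- pe$ph$truth$H_fun(pts[keep, ])
  expect_lt(median(abs(fre$H[keep] - Ht) / abs(Ht)), 0.10)
  expect_lte(fraction_concave(fre), 0.02)

  # locally flat: on a near-flat surface patch (sphere of radius 120 um)
  # the estimated |H| stays below 0.01 per um
  big <- make_phantom_surface("sphere", radius = 120, spacing = 2)
  frb <- suppressWarnings(mean_curvature_field(big$surface))
  expect_lt(median(abs(frb$H)), 0.01)
})

test_that("fraction concave matches analytic truth on a dimpled sphere", {
  p <- get_phantom("bumpy")
  fr <- mean_curvature_field(p$ph$surface, p$sm)
  expect_lt(abs(fraction_concave(fr) - p$ph$truth$fraction_concave), 0.05)
  expect_gt(fraction_concave(fr), 0) # the crater is actually seen
  expect_error(fraction_concave(fr[0, ]), "empty")
  # degenerate all-concave input
  fake <- data.frame(H = c(-1, -2, -0.5))
  expect_equal(fraction_concave(fake), 1)
})

test_that("sphericity anchors: sphere = 1, cube = 0.81, and sphere maximality", {
  r <- 3.2
  sph <- sphericity_and_radius(4 / 3 * pi * r^3, 4 * pi * r^2)
  expect_equal(sph$sphericity, 1, tolerance = 1e-12)
  expect_equal(sph$r, r, tolerance = 1e-12)

  cube <- sphericity_and_radius(1, 6)
  expect_equal(round(cube$sphericity, 2), 0.81)
  expect_equal(cube$sphericity, pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-12)

  expect_equal(sphericity_and_radius(4 * pi / 3, 1)$r, 1, tolerance = 1e-12)
  expect_error(sphericity_and_radius(-1, 6), "positive")

  # sphere attains the maximum over measured phantoms, and none exceed 1 + 2%
  psis <- vapply(c("sphere", "ellipsoid", "bumpy"), function(nm) {
    p <- get_phantom(nm)
    va <- volume_and_area(p$ph$surface, p$sm)
    sphericity_and_radius(va$V, va$A)$sphericity_raw
  }, numeric(1))
  expect_true(all(psis <= 1 + 0.02))
  expect_equal(which.max(psis), c(sphere = 1L))
})

test_that("surface_metrics assembles one tidy row per surface", {
  p <- get_phantom("sphere")
  row <- surface_metrics(p$ph$surface)
  expect_equal(nrow(row), 1L)
  expect_equal(row$label, "apical")
  expect_lt(abs(row$sphericity - 1), 0.02)
  expect_lt(abs(row$r - 10) / 10, 0.01)
  expect_equal(row$fraction_concave, 0)
  expect_gt(row$n_frames, 500)
})
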