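# Closed planar contours and their Fourier smoothing.
#
# A contour is parameterized by cumulative polygon arc length, normalized to
# [0, 2*pi) so the Fourier frequencies are integers. Each coordinate is fit
# separately as a truncated Fourier series; a single order is selected for
# both coordinates by BIC.

#' Construct a closed planar contour
#'
#' Stores an ordered list of 2D points (physical units) on a closed loop. The
#' endpoint is not duplicated: the segment from the last point back to the
#' first closes the loop. Points are re-oriented counterclockwise on ingest so
#' the curvature sign convention is global.
#'
#' @param points numeric matrix with two columns (x, y), at least 4 rows.
#' @param plane which orthogonal section the contour lies in, `"xy"` (fixed z)
#'   or `"yz"` (fixed x).
#' @param fixed the fixed third coordinate of the section plane.
#' @return an object of class `planar_contour`.
#' @export
planar_contour <- function(points, plane = c("xy", "yz"), fixed = 0) {
  plane <- match.arg(plane)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("points must have two columns")
  if (anyNA(points)) stop("points must be finite")
  # drop a duplicated closing point if the caller stored one
  n <- nrow(points)
  if (n > 1L && all(points[1L, ] == points[n, ])) points <- points[-n, , drop = FALSE]
  if (nrow(points) < 4L) stop("contour needs at least 4 points")
  if (polygon_area_signed(points) < 0) points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  structure(list(points = points, plane = plane, fixed = fixed, closed = TRUE),
            class = "planar_contour")
}

#' Extract the outer boundary of a binary mask slice
#'
#' Finds the ordered outer boundary (8-connectivity) of the foreground
#' component of a 2D binary image and returns it in physical units,
#' counterclockwise, with coordinates at pixel centers (0-based voxel index
#' times pixel spacing).
#'
#' @param mask_slice 2D matrix; nonzero entries are foreground.
#' @param spacing length-2 pixel size (same units for both axes).
#' @param select what to do when the slice holds several components:
#'   `"error"` (default) or `"largest"`.
#' @param plane,fixed passed through to [planar_contour()].
#' @return a [planar_contour()].
#' @export
extract_contour <- function(mask_slice, spacing = c(1, 1), select = c("error", "largest"),
                            plane = "xy", fixed = 0) {
  select <- match.arg(select)
  m <- (as.matrix(mask_slice) > 0) * 1L
  if (!any(m > 0)) stop("no object in slice")
  lab <- EBImage::bwlabel(m)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    if (select == "error") {
      stop(sprintf("ambiguous object: %d components of sizes %s",
                   ncomp, paste(sizes, collapse = ", ")))
    }
    keep <- which.max(sizes)
    m <- (lab == keep) * 1L
  }
  oc <- EBImage::ocontour(m)[[1L]]
  pts <- cbind(oc[, 1L] * spacing[1L], oc[, 2L] * spacing[2L])
  planar_contour(pts, plane = plane, fixed = fixed)
}

#' Fit a closed contour with a Fourier series of fixed order
#'
#' Each coordinate is fit by least squares as a function of the normalized
#' contour-length parameter `s` in `[0, 2*pi)`:
#' `x(s) = a0 + sum_m a_m cos(m s) + b_m sin(m s)`, `m = 1..order`. The two
#' coordinates share the parameterization but are fit independently.
#'
#' @param contour a [planar_contour()].
#' @param order integer Fourier order `M >= 1`.
#' @return an object of class `fourier_contour` with elements `order`,
#'   `coefficients` ((2M+1) x 2 matrix), `period` (total contour length, used
#'   to map the parameter back to physical arc length), `residual` (summed
#'   squared error over both coordinates), `rss` (per-coordinate), and
#'   `n_points`.
#' @export
fit_fourier <- function(contour, order) {
  stopifnot(inherits(contour, "planar_contour"))
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  pts <- contour$points
  n <- nrow(pts)
  if (n <= 2L * (2L * order + 1L)) stop("order too high for number of points")
  # The parameter is cumulative arc length of a lightly pre-smoothed copy of
  # the polygon (5-point circular moving average; the fitted points are NOT
  # smoothed). Point noise otherwise random-walks into the cumulative sum and
  # masquerades as low-order harmonics, biasing BIC toward spurious orders.
  sm <- pts
  if (n >= 20L) {
    w <- 2L
    idx <- outer(seq_len(n), -w:w, function(i, d) ((i + d - 1L) %% n) + 1L)
    sm <- cbind(rowMeans(matrix(pts[idx, 1L], n)), rowMeans(matrix(pts[idx, 2L], n)))
  }
  seg <- sqrt(rowSums((sm[c(2:n, 1L), ] - sm)^2))
  segL <- sqrt(rowSums((pts[c(2:n, 1L), ] - pts)^2))
  L <- sum(segL) # physical length of the raw polygon
  s <- 2 * pi * c(0, cumsum(seg[-n])) / sum(seg)
  X <- fourier_basis(s, order, deriv = 0L)
  qrX <- qr(X)
  coef <- qr.coef(qrX, pts)
  res <- pts - X %*% coef
  rss <- colSums(res^2)
  structure(list(order = order, coefficients = coef, period = L,
                 residual = sum(rss), rss = rss, n_points = n,
                 plane = contour$plane, fixed = contour$fixed),
            class = "fourier_contour")
}

fourier_basis <- function(s, order, deriv = 0L) {
  m <- seq_len(order)
  sm <- outer(s, m)
  if (deriv == 0L) {
    cbind(1, cos(sm), sin(sm))
  } else if (deriv == 1L) {
    cbind(0, -sweep(sin(sm), 2L, m, `*`), sweep(cos(sm), 2L, m, `*`))
  } else if (deriv == 2L) {
    cbind(0, -sweep(cos(sm), 2L, m^2, `*`), -sweep(sin(sm), 2L, m^2, `*`))
  } else stop("deriv must be 0, 1 or 2")
}

#' Evaluate a Fourier contour (or its derivatives)
#'
#' @param fc a `fourier_contour`.
#' @param s parameter values in `[0, 2*pi)` (values outside wrap).
#' @param deriv derivative order with respect to `s` (0, 1, or 2).
#' @return numeric matrix, one row per value of `s`, columns = coordinates.
#' @export
fourier_eval <- function(fc, s, deriv = 0L) {
  fourier_basis(s, fc$order, deriv) %*% fc$coefficients
}

#' Select the Fourier order by BIC
#'
#' Fits all orders from 1 to `max_order` (capped so the fit stays
#' overdetermined) and returns the fit minimizing the Gaussian BIC,
#' `sum over coordinates of [n log(RSS/n) + (2M+1) log n]`. Ties within 1e-9
#' are broken toward the lower order. A single order is selected for both
#' coordinates, keeping the curve representation coherent.
#'
#' @param contour a [planar_contour()].
#' @param max_order maximum order considered (default 15).
#' @return the selected `fourier_contour`, with the BIC table in
#'   `attr(, "bic")`.
#' @export
select_order_bic <- function(contour, max_order = 15L) {
  stopifnot(inherits(contour, "planar_contour"))
  if (max_order < 1L) stop("max_order must be >= 1")
  n <- nrow(contour$points)
  feas <- floor((n - 3L) / 4L) # largest M with n > 2(2M+1)
  if (feas < 1L) stop("order too high: too few points for any Fourier fit")
  orders <- seq_len(min(max_order, feas))
  fits <- lapply(orders, function(M) fit_fourier(contour, M))
  bic <- vapply(fits, function(f) {
    rss <- pmax(f$rss, 1e-300)
    sum(n * log(rss / n) + (2 * f$order + 1) * log(n))
  }, numeric(1))
  best <- min(bic)
  pick <- which(bic - best < 1e-9)[1L]
  out <- fits[[pick]]
  attr(out, "bic") <- data.frame(order = orders, bic = bic)
  out
}

#' Signed curvature of a smoothed contour
#'
#' `k(s) = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)` from the analytic
#' derivatives of the Fourier series. The formula is invariant to the speed of
#' the parameterization, so the result is the geometric curvature in inverse
#' coordinate units. Counterclockwise contours give positive curvature where
#' the curve bends toward the enclosed interior.
#'
#' @param fc a `fourier_contour`.
#' @param s parameter value(s) in `[0, 2*pi)`.
#' @param tol tangent-speed tolerance below which the parameterization is
#'   declared degenerate.
#' @return numeric vector of signed curvatures.
#' @export
planar_curvature <- function(fc, s, tol = 1e-10) {
  d1 <- fourier_eval(fc, s, 1L)
  d2 <- fourier_eval(fc, s, 2L)
  sp2 <- d1[, 1L]^2 + d1[, 2L]^2
  if (any(sp2 < tol)) stop("degenerate parameterization: vanishing tangent")
  (d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]) / sp2^1.5
}

#' Area and perimeter of a smoothed contour
#'
#' Area by the Green's-theorem line integral `0.5 * integral(x y' - y x') ds`
#' and perimeter by arc-length quadrature, both on a dense periodic grid
#' (trapezoid rule, which is spectrally accurate for periodic smooth
#' integrands). The area is returned positive. A self-intersecting smoothed
#' curve triggers a warning and the result is flagged unreliable.
#'
#' @param fc a `fourier_contour`.
#' @param n_grid quadrature grid size.
#' @return list with `area`, `perimeter`, and logical `unreliable`.
#' @export
contour_measures <- function(fc, n_grid = 2048L) {
  s <- seq(0, 2 * pi, length.out = n_grid + 1L)[-(n_grid + 1L)]
  p <- fourier_eval(fc, s, 0L)
  d1 <- fourier_eval(fc, s, 1L)
  area <- 0.5 * mean(p[, 1L] * d1[, 2L] - p[, 2L] * d1[, 1L]) * 2 * pi
  per <- mean(sqrt(d1[, 1L]^2 + d1[, 2L]^2)) * 2 * pi
  idx <- seq(1L, n_grid, by = max(1L, n_grid %/% 256L))
  unreliable <- !is_simple_polygon(p[idx, , drop = FALSE])
  if (unreliable) warning("smoothed contour self-intersects; area/perimeter unreliable")
  list(area = abs(area), perimeter = per, unreliable = unreliable)
}

# signed shoelace area (positive for counterclockwise)
polygon_area_signed <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  0.5 * sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L])
}

polygon_perimeter <- function(p) {
  n <- nrow(p)
  sum(sqrt(rowSums((p[c(2:n, 1L), , drop = FALSE] - p)^2)))
}

# O(n^2) proper-crossing test on polygon edges (adjacent edges excluded)
is_simple_polygon <- function(p) {
  n <- nrow(p)
  if (n < 4L) return(TRUE)
  j <- c(2:n, 1L)
  ax <- p[, 1L]; ay <- p[, 2L]
  bx <- p[j, 1L]; by <- p[j, 2L]
  for (i in seq_len(n - 2L)) {
    ks <- (i + 2L):n
    if (i == 1L) ks <- ks[ks != n]
    if (length(ks) == 0L) next
    o1 <- sign((bx[i] - ax[i]) * (ay[ks] - ay[i]) - (by[i] - ay[i]) * (ax[ks] - ax[i]))
    o2 <- sign((bx[i] - ax[i]) * (by[ks] - ay[i]) - (by[i] - ay[i]) * (bx[ks] - ax[i]))
    o3 <- sign((bx[ks] - ax[ks]) * (ay[i] - ay[ks]) - (by[ks] - ay[ks]) * (ax[i] - ax[ks]))
    o4 <- sign((bx[ks] - ax[ks]) * (by[i] - ay[ks]) - (by[ks] - ay[ks]) * (bx[i] - ax[ks]))
    if (any(o1 * o2 < 0 & o3 * o4 < 0)) return(FALSE)
  }
  TRUE
}
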