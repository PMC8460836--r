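# 2D cross-section shape metrics: solidity, isoperimetric quotient, mean cell
# thickness, estimated radii and the normalized lumen radius.

# coerce a polygon matrix / planar_contour / fourier_contour to polygon points;
# smoothed contours are sampled densely so hulls and areas converge
as_polygon <- function(x, n = 512L) {
  if (inherits(x, "fourier_contour")) {
    s <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    return(fourier_eval(x, s))
  }
  if (inherits(x, "planar_contour")) return(x$points)
  p <- as.matrix(x)
  if (ncol(p) != 2L) stop("polygon must have two columns")
  np <- nrow(p)
  if (np > 1L && all(p[1L, ] == p[np, ])) p <- p[-np, , drop = FALSE]
  p
}

#' Solidity of a closed shape
#'
#' Ratio of the shape area to the area of its convex hull. A value of 1
#' describes completely convex shapes (an ellipse, a regular polygon); lower
#' values reflect surface concavity.
#'
#' @param polygon closed 2D point list (matrix), [planar_contour()], or
#'   `fourier_contour` (sampled at `n` points).
#' @param check verify the polygon is simple (O(n^2); disable for dense
#'   contours known to be simple).
#' @param n sampling density used for smoothed contours.
#' @return solidity in (0, 1].
#' @export
solidity <- function(polygon, check = TRUE, n = 512L) {
  p <- as_polygon(polygon, n)
  if (check && !is_simple_polygon(p)) stop("self-intersecting polygon")
  a <- abs(polygon_area_signed(p))
  if (a <= 0) stop("polygon area must be positive")
  h <- chull(p)
  a / abs(polygon_area_signed(p[h, , drop = FALSE]))
}

#' Isoperimetric quotient
#'
#' `IPQ = 4 pi a / p^2` for area `a` and perimeter `p`; 1 for a perfect
#' circle.
#'
#' @inheritParams solidity
#' @export
ipq <- function(polygon, check = TRUE, n = 512L) {
  p <- as_polygon(polygon, n)
  if (check && !is_simple_polygon(p)) stop("self-intersecting polygon")
  per <- polygon_perimeter(p)
  if (per <= 0) stop("zero perimeter")
  4 * pi * abs(polygon_area_signed(p)) / per^2
}

#' Construct a spheroid cross-section
#'
#' Holds the traced apical (lumen) and basal polygons of one mid cross-section
#' together with the cell count, and caches enclosed areas and perimeters.
#'
#' @param lumen_polygon,basal_polygon closed 2D point lists (physical units).
#' @param n_cells number of cells in the cross-section (>= 2).
#' @param check verify that the basal polygon strictly contains the lumen
#'   polygon (vertex-wise point-in-polygon test).
#' @return object of class `spheroid_cross_section` with fields
#'   `lumen_polygon`, `basal_polygon`, `n_cells`, `A_a`, `A_b`, `P_a`, `P_b`.
#' @export
spheroid_cross_section <- function(lumen_polygon, basal_polygon, n_cells,
                                   check = TRUE) {
  lp <- as_polygon(lumen_polygon)
  bp <- as_polygon(basal_polygon)
  n_cells <- as.integer(n_cells)
  if (n_cells < 2L) stop("n_cells must be >= 2")
  if (check && !all(points_in_polygon(lp, bp))) {
    stop("basal polygon must contain the lumen polygon")
  }
  structure(list(lumen_polygon = lp, basal_polygon = bp, n_cells = n_cells,
                 A_a = abs(polygon_area_signed(lp)),
                 A_b = abs(polygon_area_signed(bp)),
                 P_a = polygon_perimeter(lp),
                 P_b = polygon_perimeter(bp)),
            class = "spheroid_cross_section")
}

#' Mean cell thickness of a cross-section
#'
#' `2 (A_b - A_a) / (P_b + P_a)` for apical/basal areas and perimeters; for a
#' concentric annulus this collapses to the ring width `R - r` exactly.
#'
#' @param cs a [spheroid_cross_section()].
#' @export
mean_cell_thickness <- function(cs) {
  stopifnot(inherits(cs, "spheroid_cross_section"))
  if (cs$A_b <= cs$A_a) stop("lumen not inside: basal area must exceed lumen area")
  2 * (cs$A_b - cs$A_a) / (cs$P_b + cs$P_a)
}

#' Normalized lumen radius
#'
#' Estimated radii from the enclosed areas, `r(A) = sqrt(A / pi)`, and the
#' normalized lumen radius `r_norm = r_l / (r_s - r_l)` — the lumen radius in
#' units of the mean cell width.
#'
#' @param cs a [spheroid_cross_section()].
#' @return list with `r_l`, `r_s`, `r_norm`.
#' @export
normalized_lumen_radius <- function(cs) {
  stopifnot(inherits(cs, "spheroid_cross_section"))
  if (cs$A_a <= 0 || cs$A_b <= 0) stop("areas must be positive")
  r_l <- sqrt(cs$A_a / pi)
  r_s <- sqrt(cs$A_b / pi)
  if (r_s <= r_l) stop("spheroid radius must exceed lumen radius")
  list(r_l = r_l, r_s = r_s, r_norm = r_l / (r_s - r_l))
}

#' Mean luminal surface area per cell
#'
#' @param lumen_surface_area lumen surface area.
#' @param n_cells number of cells in the spheroid (>= 1).
#' @export
luminal_area_per_cell <- function(lumen_surface_area, n_cells) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  lumen_surface_area / n_cells
}

#' All 2D metrics for one cross-section
#'
#' @param cs a [spheroid_cross_section()].
#' @return one-row data.frame: `a`, `p`, `A_c` (convex-hull area), `solidity`,
#'   `ipq`, `r_l`, `r_s`, `r_norm`, `thickness`, `n_cells`.
#' @export
cross_section_metrics <- function(cs) {
  stopifnot(inherits(cs, "spheroid_cross_section"))
  lp <- cs$lumen_polygon
  h <- chull(lp)
  rad <- normalized_lumen_radius(cs)
  data.frame(a = cs$A_a, p = cs$P_a,
             A_c = abs(polygon_area_signed(lp[h, , drop = FALSE])),
             solidity = solidity(lp, check = FALSE),
             ipq = ipq(lp, check = FALSE),
             r_l = rad$r_l, r_s = rad$r_s, r_norm = rad$r_norm,
             thickness = mean_cell_thickness(cs),
             n_cells = cs$n_cells)
}

# vectorized ray-casting point-in-polygon (TRUE for strictly/boundary inside)
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  j <- c(2:n, 1L)
  x <- pts[, 1L]; y <- pts[, 2L]
  inside <- rep(FALSE, length(x))
  for (e in seq_len(n)) {
    x1 <- poly[e, 1L]; y1 <- poly[e, 2L]
    x2 <- poly[j[e], 1L]; y2 <- poly[j[e], 2L]
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}
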