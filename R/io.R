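# Readers/writers and the end-to-end metrics pipeline. Masks travel as
# multi-page TIFF stacks (pages = z, page rows = x, page columns = y) with a
# JSON sidecar {"spacing": [z, y, x], "label": ...}; voxel indices are
# 0-based with physical coordinates at voxel centers.

#' Read a binary mask stack with its spacing sidecar
#'
#' @param path multi-page TIFF of a binary mask.
#' @param sidecar path to the JSON sidecar; defaults to `<path>.json`.
#' @param spacing optional `c(x, y, z)` spacing overriding the sidecar.
#' @param label optional label overriding the sidecar.
#' @param check passed to [voxel_surface()] (single component, closed).
#' @return a [voxel_surface()].
#' @export
read_mask_stack <- function(path, sidecar = NULL, spacing = NULL, label = NULL,
                            check = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mask <- array(0, dim = c(dim(pages[[1L]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
    mask[, , k] <- pg
  }
  if (is.null(spacing) || is.null(label)) {
    if (is.null(sidecar)) sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) stop("missing spacing: no sidecar at ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(spacing)) {
      if (is.null(meta$spacing)) stop("missing spacing in sidecar")
      spacing <- rev(as.numeric(meta$spacing)) # sidecar stores (z, y, x)
    }
    if (is.null(label)) label <- if (is.null(meta$label)) "apical" else meta$label
  }
  voxel_surface(mask > 0.5, spacing = spacing, label = label, check = check)
}

#' Write a mask stack and its sidecar
#'
#' @param surface a [voxel_surface()].
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @export
write_mask_stack <- function(surface, path) {
  stopifnot(inherits(surface, "voxel_surface"))
  pages <- lapply(seq_len(dim(surface$mask)[3L]),
                  function(k) (surface$mask[, , k]) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(spacing = rev(surface$spacing), label = surface$label),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the 3D metrics pipeline over a set of surfaces
#'
#' Computes all [surface_metrics()] per input. Per-input failures are caught,
#' logged, and reported as a row with `failed = TRUE`; the pipeline always
#' processes every input.
#'
#' @param inputs either a character vector of TIFF paths (sidecars looked up
#'   as `<path>.json`) or a list of [voxel_surface()] objects.
#' @param output_csv optional path; when given the table is also written as
#'   CSV.
#' @param max_order maximum Fourier order for slice smoothing.
#' @return data.frame with one row per input (`input`, metrics columns,
#'   `failed`, `error`); the number of failures in `attr(, "n_failed")`.
#' @export
run_pipeline <- function(inputs, output_csv = NULL, max_order = 15L) {
  get_surface <- function(i) {
    if (is.character(inputs)) read_mask_stack(inputs[[i]]) else inputs[[i]]
  }
  nm <- if (is.character(inputs)) inputs else
    paste0("surface_", seq_along(inputs))
  rows <- lapply(seq_along(inputs), function(i) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      m <- surface_metrics(get_surface(i), max_order = max_order)
      cbind(data.frame(input = nm[[i]]), m,
            data.frame(failed = FALSE, error = NA_character_))
    }, error = function(e) {
      data.frame(input = nm[[i]], label = NA_character_, V = NA_real_,
                 A = NA_real_, sphericity = NA_real_, r = NA_real_,
                 fraction_concave = NA_real_, n_frames = NA_integer_,
                 failed = TRUE, error = conditionMessage(e))
    })
    res$seconds <- proc.time()[["elapsed"]] - t0
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- sum(out$failed)
  if (!is.null(output_csv)) write.csv(out, output_csv, row.names = FALSE)
  out
}

#' Column dictionary for the pipeline output table
#'
#' @return data.frame with one row per output column of [run_pipeline()].
#' @export
pipeline_data_dictionary <- function() {
  data.frame(
    column = c("input", "label", "V", "A", "sphericity", "r",
               "fraction_concave", "n_frames", "failed", "error", "seconds"),
    unit = c("-", "-", "um^3", "um^2", "-", "um", "-", "count", "-", "-", "s"),
    description = c(
      "input path or surface name",
      "apical (lumen) or basal",
      "enclosed volume from smoothed slice areas",
      "surface area from banded quadrature over smoothed contours",
      "pi^(1/3) (6V)^(2/3) / A, clamped to [0, 1]",
      "volume-equivalent radius (3V / 4 pi)^(1/3)",
      "fraction of curvature frames with negative mean curvature",
      "number of curvature frames sampled",
      "TRUE if this input raised an error",
      "error message for failed inputs",
      "wall-clock seconds spent on this input"))
}

#' Serialize a vertex-model state to JSON
#'
#' @param state a `spheroid_state`.
#' @param path output path.
#' @param params optional [vm_params()] stored alongside.
#' @export
write_state_json <- function(state, path, params = NULL) {
  stopifnot(inherits(state, "spheroid_state"))
  obj <- list(n_cells = state$n_cells,
              apical_vertices = cbind(state$ax, state$ay),
              basal_vertices = cbind(state$bx, state$by),
              apical_curvatures = state$ka, basal_curvatures = state$kb)
  if (!is.null(params)) obj$params <- unclass(params)
  if (!is.null(attr(state, "energy"))) obj$energy <- attr(state, "energy")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vertex-model state from JSON
#'
#' @param path path written by [write_state_json()].
#' @return a `spheroid_state` (with `$params` attribute when stored).
#' @export
read_state_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- new_spheroid_state(obj$apical_vertices[, 1L], obj$apical_vertices[, 2L],
                           obj$basal_vertices[, 1L], obj$basal_vertices[, 2L],
                           obj$apical_curvatures, obj$basal_curvatures)
  if (!is.null(obj$params)) attr(st, "params") <- obj$params
  st
}

#' Write a smoothed contour as CSV (s, x, y, k)
#'
#' @param fc a `fourier_contour`.
#' @param path output CSV path.
#' @param n number of sampled parameter values.
#' @export
write_contour_csv <- function(fc, path, n = 256L) {
  s <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  p <- fourier_eval(fc, s)
  write.csv(data.frame(s = s, x = p[, 1L], y = p[, 2L],
                       k = planar_curvature(fc, s)),
            path, row.names = FALSE)
  invisible(path)
}

#' Write Fourier coefficients as JSON
#'
#' @param fc a `fourier_contour`.
#' @param path output JSON path.
#' @export
write_fourier_json <- function(fc, path) {
  jsonlite::write_json(list(order = fc$order, period = fc$period,
                            coefficients = fc$coefficients,
                            residual = fc$residual, n_points = fc$n_points),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
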