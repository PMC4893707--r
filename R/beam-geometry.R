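#' Interlaced microbeam transection geometry
#'
#' Tools for computing the geometry of an interlaced-microbeam radiosurgical
#' transection: several thin planar beams ("slabs") delivered through ports at
#' different in-plane angles, each shifted laterally by a fixed step along the
#' stacking axis, so that only their common overlap receives the full dose.
#'
#' @name beam-geometry
NULL

#' Irradiation plan for one interlaced transection
#'
#' @param port_angles_deg in-plane port angles (degrees); a strip at angle
#'   `a` equals one at `a + 180`.
#' @param beam_width_um beam thickness along the stacking (step) axis, in
#'   micrometres.
#' @param beam_height_mm in-plane beam extent (the width of each strip), mm.
#' @param step_um lateral shift between successive ports along the stacking
#'   axis, micrometres.
#' @param ap_coords_mm anteroposterior coordinates of the transection planes
#'   (mm from bregma).
#' @param ml_mm mediolateral position of the transection column (mm).
#' @param entrance_dose_Gy,target_dose_Gy informational dose metadata; carried
#'   through untouched (no transport is computed).
#' @return An object of class `transection_plan`.
#' @export
transection_plan <- function(port_angles_deg = c(0, 45, 90, -45),
                             beam_width_um = 50,
                             beam_height_mm = 2,
                             step_um = 50,
                             ap_coords_mm = c(2, 0, -2, -4),
                             ml_mm = -4.5,
                             entrance_dose_Gy = 800,
                             target_dose_Gy = 820) {
  if (length(port_angles_deg) < 1L)
    stop("a transection plan needs at least one port", call. = FALSE)
  if (beam_width_um <= 0) stop("beam_width_um must be > 0", call. = FALSE)
  if (beam_height_mm <= 0) stop("beam_height_mm must be > 0", call. = FALSE)
  if (step_um < 0) stop("step_um must be >= 0", call. = FALSE)
  structure(list(port_angles_deg = port_angles_deg,
                 beam_width_um = beam_width_um,
                 beam_height_mm = beam_height_mm,
                 step_um = step_um,
                 ap_coords_mm = ap_coords_mm,
                 ml_mm = ml_mm,
                 entrance_dose_Gy = entrance_dose_Gy,
                 target_dose_Gy = target_dose_Gy),
            class = "transection_plan")
}

#' Stacked thickness of interlaced beam slabs
#'
#' With `n_ports` slabs of thickness `beam_width_um` each shifted by `step_um`
#' along the stacking axis, the irradiated extent along that axis is
#' `beam_width + (n_ports - 1) * step`. A step larger than the beam width
#' leaves unirradiated gaps between slabs and triggers a warning.
#'
#' @param n_ports number of ports (>= 1).
#' @param beam_width_um beam thickness, micrometres (> 0).
#' @param step_um lateral step between ports, micrometres (>= 0).
#' @return Stacked extent in micrometres.
#' @examples
#' interlaced_thickness(4, 50, 50)  # 200
#' @export
interlaced_thickness <- function(n_ports, beam_width_um, step_um) {
  if (n_ports < 1L) stop("n_ports must be >= 1", call. = FALSE)
  if (beam_width_um <= 0) stop("beam_width_um must be > 0", call. = FALSE)
  if (step_um < 0) stop("step_um must be >= 0", call. = FALSE)
  if (n_ports > 1L && step_um > beam_width_um)
    warning("step exceeds beam width: stacked slabs leave gaps", call. = FALSE)
  beam_width_um + (n_ports - 1) * step_um
}

## Clip a convex polygon (matrix of vertices, counter-clockwise) against the
## half-plane a.x + b.y <= c (Sutherland-Hodgman, one edge at a time).
clip_halfplane <- function(poly, a, b, cc, tol = 1e-12) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  out <- matrix(numeric(0), ncol = 2)
  d <- a * poly[, 1] + b * poly[, 2] - cc
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    din <- d[i] <= tol
    djn <- d[j] <= tol
    if (din) out <- rbind(out, poly[i, ])
    if (din != djn) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

## Drop consecutive duplicate vertices.
dedupe_vertices <- function(poly, tol = 1e-9) {
  if (nrow(poly) < 2L) return(poly)
  keep <- logical(nrow(poly))
  keep[1] <- TRUE
  for (i in 2:nrow(poly)) {
    keep[i] <- sqrt(sum((poly[i, ] - poly[which(keep)[sum(keep)], ])^2)) > tol
  }
  if (sum(keep) > 1L &&
      sqrt(sum((poly[which(keep)[sum(keep)], ] - poly[1, ])^2)) <= tol)
    keep[which(keep)[sum(keep)]] <- FALSE
  poly[keep, , drop = FALSE]
}

#' In-plane intersection footprint of angled strips
#'
#' Each port contributes a strip of width `strip_width_mm` centred on the
#' common axis, oriented at its in-plane angle. Their intersection is a convex
#' polygon (for the standard four ports at 45 degree spacing, a regular
#' octagon). The minimum width over all directions ("across-flats" diameter)
#' is computed by rotating calipers; the across-vertices value (circumscribed
#' diameter) is also reported because "diameter" is ambiguous for a polygon.
#'
#' @param angles_deg port angles in degrees; at least 2 distinct strip
#'   orientations are required (a single strip is unbounded).
#' @param strip_width_mm strip width (mm, > 0).
#' @return A `footprint_result` list: `vertices` (n x 2 matrix, mm, ordered
#'   counter-clockwise), `n_vertices`, `min_caliper_width_mm`,
#'   `max_diameter_mm`, `area_mm2`.
#' @examples
#' fp <- intersection_footprint(c(0, 45, 90, 135), 2)
#' fp$min_caliper_width_mm  # 2
#' @export
intersection_footprint <- function(angles_deg, strip_width_mm) {
  if (strip_width_mm <= 0) stop("strip_width_mm must be > 0", call. = FALSE)
  ang <- sort(unique(angles_deg %% 180))
  if (length(ang) < 2L)
    stop("need >= 2 distinct strip orientations (intersection unbounded)",
         call. = FALSE)
  w <- strip_width_mm
  ## start from a generous bounding square, clip by both edges of each strip
  big <- 10 * w
  poly <- matrix(c(-big, -big, big, -big, big, big, -big, big),
                 ncol = 2, byrow = TRUE)
  for (a in ang * pi / 180) {
    ## strip along direction (cos a, sin a): |x sin a - y cos a| <= w/2
    nx <- sin(a); ny <- -cos(a)
    poly <- clip_halfplane(poly, nx, ny, w / 2)
    poly <- clip_halfplane(poly, -nx, -ny, w / 2)
  }
  poly <- dedupe_vertices(poly)
  structure(list(vertices = poly,
                 n_vertices = nrow(poly),
                 min_caliper_width_mm = min_caliper_width(poly),
                 max_diameter_mm = max_diameter(poly),
                 area_mm2 = polygon_area(poly)),
            class = "footprint_result")
}

#' @export
print.footprint_result <- function(x, ...) {
  cat("Interlaced beam footprint\n")
  cat(sprintf("  vertices           : %d\n", x$n_vertices))
  cat(sprintf("  min caliper width  : %.4f mm (across flats)\n",
              x$min_caliper_width_mm))
  cat(sprintf("  max diameter       : %.4f mm (across vertices)\n",
              x$max_diameter_mm))
  cat(sprintf("  area               : %.4f mm^2\n", x$area_mm2))
  invisible(x)
}

## Shoelace area of a polygon.
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

## Minimum width over all directions of a convex polygon: for each edge,
## the maximum distance of any vertex from that edge's line (rotating
## calipers; the minimizing direction is always normal to an edge).
min_caliper_width <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    d <- (poly[, 1] - poly[i, 1]) * nrm[1] + (poly[, 2] - poly[i, 2]) * nrm[2]
    max(abs(d))
  }, numeric(1))
  min(widths)
}

## Largest vertex-to-vertex distance.
max_diameter <- function(poly) {
  n <- nrow(poly)
  if (n < 2L) return(0)
  d2 <- as.matrix(stats::dist(poly))
  max(d2)
}

#' Rasterized dose-print of an interlaced plan
#'
#' Renders, in the plane spanned by the in-plane beam axis (u) and the
#' stacking axis (y), the number of beams traversing each pixel. Each port's
#' beam occupies a slab `beam_width_um` thick along y, offset by successive
#' multiples of `step_um`, across the full in-plane extent `beam_height_mm`.
#' With a step equal to the beam width the slabs tile a contiguous band whose
#' extent equals [interlaced_thickness()].
#'
#' @param plan a [transection_plan()].
#' @param pixel_um raster pixel size, micrometres (> 0).
#' @param max_pixels cap on total raster size.
#' @return A list with `counts` (matrix, rows = y pixels, cols = u pixels),
#'   `u_mm`, `y_um` (pixel-centre axes) of class `doseprint`.
#' @export
render_doseprint <- function(plan, pixel_um = 5, max_pixels = 4e6) {
  if (!inherits(plan, "transection_plan"))
    stop("plan must be a transection_plan", call. = FALSE)
  if (pixel_um <= 0) stop("pixel_um must be > 0", call. = FALSE)
  n_ports <- length(plan$port_angles_deg)
  w <- plan$beam_width_um
  s <- plan$step_um
  y_max <- w + (n_ports - 1) * s
  margin <- max(w, 25)
  y_um <- seq(-margin + pixel_um / 2, y_max + margin, by = pixel_um)
  u_half_um <- plan$beam_height_mm * 1000 / 2
  u_um <- seq(-u_half_um + pixel_um / 2, u_half_um, by = pixel_um)
  if (as.numeric(length(y_um)) * as.numeric(length(u_um)) > max_pixels)
    stop("raster exceeds size cap; increase pixel_um", call. = FALSE)
  counts <- matrix(0L, nrow = length(y_um), ncol = length(u_um))
  for (k in seq_len(n_ports) - 1L) {
    inside <- y_um >= k * s & y_um <= k * s + w
    counts[inside, ] <- counts[inside, ] + 1L
  }
  structure(list(counts = counts, u_mm = u_um / 1000, y_um = y_um,
                 pixel_um = pixel_um),
            class = "doseprint")
}
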