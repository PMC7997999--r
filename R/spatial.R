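#' Outline primitives for cell geometry
#'
#' Outlines are either analytic circles or simple closed polygons (vertices
#' in order, implicitly closed). Circles admit exact area arithmetic; mixed
#' or polygonal geometries fall back to grid integration.
#'
#' @param center Numeric `c(x, y)`, microns.
#' @param radius Positive radius, microns.
#' @return An object of class `outline`.
#' @export
circle_outline <- function(center, radius) {
  center <- as.numeric(center)
  if (length(center) != 2 || !all(is.finite(center))) {
    stop("`center` must be a finite (x, y) pair", call. = FALSE)
  }
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) || radius <= 0) {
    stop("`radius` must be a single positive number", call. = FALSE)
  }
  structure(list(type = "circle", center = center, radius = as.numeric(radius)),
            class = "outline")
}

#' @rdname circle_outline
#' @param vertices Two-column numeric matrix of polygon vertices, microns,
#'   in boundary order (not repeated at the end); at least 3 rows, nonzero
#'   enclosed area.
#' @export
polygon_outline <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3 || !all(is.finite(vertices))) {
    stop("`vertices` must be a finite n x 2 matrix with n >= 3", call. = FALSE)
  }
  # drop a duplicated closing vertex if present
  n <- nrow(vertices)
  if (all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  if (abs(shoelace_area(vertices)) <= 0) {
    stop("polygon must enclose a nonzero area", call. = FALSE)
  }
  structure(list(type = "polygon", vertices = vertices), class = "outline")
}

shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

#' Area enclosed by an outline
#' @param outline An [circle_outline()] or [polygon_outline()].
#' @return Area, square microns.
#' @export
outline_area <- function(outline) {
  stopifnot(inherits(outline, "outline"))
  if (outline$type == "circle") pi * outline$radius^2
  else abs(shoelace_area(outline$vertices))
}

# Membership test, vectorized over points (n x 2 matrix). Boundary treated
# as inside for circles; even-odd crossing rule for polygons.
outline_contains <- function(outline, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (outline$type == "circle") {
    d2 <- (pts[, 1] - outline$center[1])^2 + (pts[, 2] - outline$center[2])^2
    return(d2 <= outline$radius^2 * (1 + 1e-12) + 1e-300)
  }
  v <- outline$vertices
  n <- nrow(v)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Distance from points to the outline considered as a SET (zero inside),
# vectorized over points.
outline_set_distance <- function(outline, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (outline$type == "circle") {
    d <- sqrt((pts[, 1] - outline$center[1])^2 + (pts[, 2] - outline$center[2])^2)
    return(pmax(d - outline$radius, 0))
  }
  v <- outline$vertices
  n <- nrow(v)
  best <- rep(Inf, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    ax <- v[j, 1]; ay <- v[j, 2]
    bx <- v[i, 1]; by <- v[i, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, nrow(pts)) else
      pmin(pmax(((pts[, 1] - ax) * dx + (pts[, 2] - ay) * dy) / L2, 0), 1)
    ex <- ax + t * dx - pts[, 1]
    ey <- ay + t * dy - pts[, 2]
    best <- pmin(best, ex * ex + ey * ey)
    j <- i
  }
  d <- sqrt(best)
  d[outline_contains(outline, pts)] <- 0
  d
}

outline_bbox <- function(outline) {
  if (outline$type == "circle") {
    c(outline$center[1] - outline$radius, outline$center[1] + outline$radius,
      outline$center[2] - outline$radius, outline$center[2] + outline$radius)
  } else {
    c(range(outline$vertices[, 1]), range(outline$vertices[, 2]))[c(1, 2, 3, 4)]
  }
}

#' Cell geometry for perinuclear quantification
#'
#' Bundles the nucleus outline, the cell outline and the perinuclear band
#' width (the distance the band extends outward from the nucleus border).
#'
#' @param nucleus,cell [circle_outline()] or [polygon_outline()] objects.
#' @param band_width Band width, microns (>= 0, default 2).
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(nucleus, cell, band_width = 2) {
  stopifnot(inherits(nucleus, "outline"), inherits(cell, "outline"))
  if (!is.numeric(band_width) || length(band_width) != 1 || band_width < 0) {
    stop("`band_width` must be a single number >= 0", call. = FALSE)
  }
  structure(list(nucleus = nucleus, cell = cell, band_width = as.numeric(band_width)),
            class = "cell_geometry")
}

# Area of intersection of two discs (closed-form lens area).
circle_intersection_area <- function(c1, r1, c2, r2) {
  d <- sqrt(sum((c1 - c2)^2))
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  tri <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - tri
}

#' Membership test for the perinuclear band
#'
#' A point lies in the band iff it is outside the nucleus, within
#' `band_width` of the nucleus (i.e. inside the dilated nucleus), and inside
#' the cell. Boundaries are inclusive.
#'
#' @param pts Two-column matrix (or length-2 vector) of points, microns.
#' @param geom A [cell_geometry()].
#' @return Logical vector.
#' @export
in_perinuclear_band <- function(pts, geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (geom$band_width <= 0) return(rep(FALSE, nrow(pts)))
  dn <- outline_set_distance(geom$nucleus, pts)
  dn > 0 & dn <= geom$band_width & outline_contains(geom$cell, pts)
}

#' Perinuclear band region and area
#'
#' The band is the region extending `band_width` microns outward from the
#' nucleus border, clipped to the cell outline: `(dilate(nucleus, w) \
#' nucleus) intersect cell`. Any part of the dilated ring falling outside
#' the cell is thereby subtracted from the quantification area. For
#' circle/circle geometries the area is computed in closed form from
#' circle-lens areas; otherwise by midpoint grid integration over the band's
#' bounding box.
#'
#' @param geom A [cell_geometry()].
#' @param method `"auto"` (closed form when both outlines are circles, else
#'   grid), `"analytic"`, or `"grid"`.
#' @param grid_resolution Grid pitch for numeric integration, microns.
#' @return A list of class `perinuclear_band`: `area` (square microns),
#'   `band_width`, `method`, and the input `geom`.
#' @export
perinuclear_band <- function(geom, method = c("auto", "analytic", "grid"),
                             grid_resolution = 0.02) {
  stopifnot(inherits(geom, "cell_geometry"))
  method <- match.arg(method)
  w <- geom$band_width
  if (w == 0) {
    return(structure(list(area = 0, band_width = 0, method = "degenerate",
                          geom = geom), class = "perinuclear_band"))
  }
  both_circles <- geom$nucleus$type == "circle" && geom$cell$type == "circle"
  if (method == "analytic" && !both_circles) {
    stop("analytic band area requires circular nucleus and cell outlines", call. = FALSE)
  }
  use_analytic <- method == "analytic" || (method == "auto" && both_circles)
  if (use_analytic) {
    # nucleus subset of its dilation, so band area is a difference of lenses
    area <- circle_intersection_area(geom$nucleus$center, geom$nucleus$radius + w,
                                     geom$cell$center, geom$cell$radius) -
      circle_intersection_area(geom$nucleus$center, geom$nucleus$radius,
                               geom$cell$center, geom$cell$radius)
    meth <- "analytic"
  } else {
    bbn <- outline_bbox(geom$nucleus)
    bbc <- outline_bbox(geom$cell)
    x0 <- max(bbn[1] - w, bbc[1]); x1 <- min(bbn[2] + w, bbc[2])
    y0 <- max(bbn[3] - w, bbc[3]); y1 <- min(bbn[4] + w, bbc[4])
    if (x1 <= x0 || y1 <= y0) {
      area <- 0
    } else {
      h <- grid_resolution
      # cap the grid at ~4e6 cells to bound memory/time
      n_cells <- ((x1 - x0) / h) * ((y1 - y0) / h)
      if (n_cells > 4e6) h <- sqrt((x1 - x0) * (y1 - y0) / 4e6)
      gx <- seq(x0 + h / 2, x1, by = h)
      gy <- seq(y0 + h / 2, y1, by = h)
      count <- 0
      for (yy in gy) {
        pts <- cbind(gx, yy)
        count <- count + sum(in_perinuclear_band(pts, geom))
      }
      area <- count * h * h
    }
    meth <- "grid"
  }
  structure(list(area = area, band_width = w, method = meth, geom = geom),
            class = "perinuclear_band")
}

#' Filter detected particles by size
#'
#' Retains particles whose size is greater than or equal to `min_size`
#' (inclusive boundary), preserving order. Used to select pigmented
#' melanosome-scale structures before counting.
#'
#' @param particles Data frame with columns `x`, `y` (microns) and `size`
#'   (nanometres).
#' @param min_size Minimum size, nanometres (default 150).
#' @return The filtered data frame.
#' @export
filter_particles <- function(particles, min_size = 150) {
  if (!is.data.frame(particles) || !all(c("x", "y", "size") %in% names(particles))) {
    stop("`particles` must be a data frame with columns x, y, size", call. = FALSE)
  }
  if (!is.numeric(min_size) || length(min_size) != 1 || min_size <= 0) {
    stop("`min_size` must be a single positive number (nm)", call. = FALSE)
  }
  if (any(particles$size <= 0, na.rm = TRUE)) {
    stop("particle sizes must be positive", call. = FALSE)
  }
  particles[particles$size >= min_size, , drop = FALSE]
}

#' Perinuclear particle count and density
#'
#' Counts particles whose centroid lies in the perinuclear band
#' (boundary-inclusive) and normalizes by the band area. Size-filter the
#' particles first with [filter_particles()] (enforced unless
#' `filtered = TRUE` is asserted and sizes are absent).
#'
#' @param particles Data frame with columns `x`, `y` (microns), optionally
#'   `size` (nm).
#' @param geom A [cell_geometry()].
#' @param band Optional precomputed [perinuclear_band()] (avoids
#'   recomputing the area).
#' @param min_size Size filter applied when a `size` column is present, nm.
#' @return A list: `count`, `density` (per square micron), `area`.
#' @export
perinuclear_density <- function(particles, geom, band = NULL, min_size = 150) {
  stopifnot(inherits(geom, "cell_geometry"))
  if (!is.data.frame(particles) || !all(c("x", "y") %in% names(particles))) {
    stop("`particles` must be a data frame with columns x, y", call. = FALSE)
  }
  if ("size" %in% names(particles)) {
    particles <- filter_particles(particles, min_size)
  }
  if (is.null(band)) band <- perinuclear_band(geom)
  inb <- if (nrow(particles)) {
    in_perinuclear_band(cbind(particles$x, particles$y), geom)
  } else logical(0)
  count <- sum(inb)
  if (band$area == 0) {
    if (count > 0) stop("zero band area with particles counted inside it", call. = FALSE)
    return(list(count = 0L, density = 0, area = 0))
  }
  list(count = as.integer(count), density = count / band$area, area = band$area)
}

#' Melanosome cross-section area from electron-microscopy axes
#'
#' Reproduces the reported convention `area = length * width * pi` verbatim.
#' Note this convention omits the 1/4 factor of a true ellipse area; the
#' geometrically correct value `pi * (length/2) * (width/2)` is available
#' with `corrected = TRUE`.
#'
#' @param length,width Particle axes (any consistent unit); positive,
#'   vectorized.
#' @param corrected Use the true ellipse area instead of the reported
#'   convention.
#' @return Areas on the squared unit scale of the inputs.
#' @export
em_area <- function(length, width, corrected = FALSE) {
  if (!is.numeric(length) || !is.numeric(width) ||
      any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0)) {
    stop("`length` and `width` must be positive and finite", call. = FALSE)
  }
  if (corrected) pi * (length / 2) * (width / 2) else length * width * pi
}
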