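#' Read a study-area boundary polygon from GeoJSON
#'
#' Accepts a GeoJSON `Polygon` or `MultiPolygon`, optionally wrapped in a
#' `Feature` or `FeatureCollection` (the first feature is used). Coordinates
#' are taken as planar (same units as the grid, typically meters); no
#' reprojection is performed here — project occurrence data and boundary to a
#' common planar CRS before use.
#'
#' Ring orientation is normalized internally: outer rings counter-clockwise,
#' holes clockwise, so that signed areas compose correctly.
#'
#' @param path Path to a GeoJSON file.
#' @return An object of class `ps_boundary`: a list of polygons, each a list
#'   of rings (first outer, rest holes), each ring an n x 2 coordinate matrix.
#' @export
read_boundary <- function(path) {
  if (!file.exists(path)) stop("boundary file not found: ", path)
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$type)) stop("invalid GeoJSON: no 'type' member")
  geom <- g
  if (g$type == "FeatureCollection") {
    if (length(g$features) == 0L) stop("boundary GeoJSON has no features")
    geom <- g$features[[1L]]$geometry
  } else if (g$type == "Feature") {
    geom <- g$geometry
  }
  polys <- switch(geom$type,
    Polygon = list(geom$coordinates),
    MultiPolygon = geom$coordinates,
    stop("boundary must be a Polygon or MultiPolygon, got: ", geom$type)
  )
  polys <- lapply(polys, function(poly) {
    lapply(poly, function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt) as.numeric(pt[seq_len(2L)])))
      .validate_ring(m)
    })
  })
  boundary(polys)
}

#' Construct a boundary object from coordinate rings
#'
#' Programmatic alternative to [read_boundary()]. Useful for synthetic
#' study areas.
#'
#' @param polygons A list of polygons; each polygon a list of rings (outer
#'   first); each ring an n x 2 numeric matrix of planar coordinates. A single
#'   matrix is accepted as shorthand for one polygon with one ring.
#' @return A `ps_boundary` object.
#' @export
boundary <- function(polygons) {
  if (is.matrix(polygons)) polygons <- list(list(polygons))
  if (is.list(polygons) && is.matrix(polygons[[1L]])) polygons <- list(polygons)
  polys <- lapply(polygons, function(poly) {
    poly <- lapply(poly, .validate_ring)
    # normalize: outer ring CCW (positive area), holes CW (negative)
    for (k in seq_along(poly)) {
      a <- .ring_area(poly[[k]])
      flip <- if (k == 1L) a < 0 else a > 0
      if (flip) poly[[k]] <- poly[[k]][rev(seq_len(nrow(poly[[k]]))), , drop = FALSE]
    }
    poly
  })
  structure(list(polygons = polys), class = "ps_boundary")
}

.validate_ring <- function(m) {
  if (!is.matrix(m) || ncol(m) != 2L || !is.numeric(m)) {
    stop("boundary ring must be an n x 2 numeric matrix")
  }
  if (any(!is.finite(m))) stop("boundary ring contains non-finite coordinates")
  # drop explicit closing vertex; algorithms treat rings as implicitly closed
  if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("boundary ring has fewer than 3 distinct vertices")
  if (abs(.ring_area(m)) == 0) stop("boundary ring has zero area")
  m
}

# shoelace signed area (CCW positive); ring implicitly closed
.ring_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# even-odd crossing test, vectorized over query points; ring implicitly closed
.ring_crossings <- function(x, y, ring) {
  inside <- rep(FALSE, length(x))
  n <- nrow(ring)
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    if (yi != yj) {
      hit <- ((yi > y) != (yj > y)) & (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
      inside <- xor(inside, hit)
    }
    j <- i
  }
  inside
}

#' Test whether planar points fall inside a boundary
#'
#' Even-odd rule across all rings, so holes are excluded automatically.
#'
#' @param x,y Numeric vectors of planar coordinates.
#' @param bnd A `ps_boundary` object.
#' @return Logical vector, one element per point.
#' @export
point_in_boundary <- function(x, y, bnd) {
  stopifnot(inherits(bnd, "ps_boundary"), length(x) == length(y))
  inside <- rep(FALSE, length(x))
  for (poly in bnd$polygons) {
    for (ring in poly) inside <- xor(inside, .ring_crossings(x, y, ring))
  }
  inside
}

# Sutherland-Hodgman clip of one ring against the rectangle
# [xmin,xmax] x [ymin,ymax]; returns a matrix (possibly < 3 rows) or NULL
.clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  pts <- ring
  clip_half <- function(pts, inside_fun, intersect_fun) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), 0L, 2L)
    prev <- pts[n, ]
    prev_in <- inside_fun(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside_fun(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect_fun(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect_fun(prev, cur))
      }
      prev <- cur; prev_in <- cur_in
    }
    out
  }
  ix <- function(p, q, xv) { t <- (xv - p[1L]) / (q[1L] - p[1L]); c(xv, p[2L] + t * (q[2L] - p[2L])) }
  iy <- function(p, q, yv) { t <- (yv - p[2L]) / (q[2L] - p[2L]); c(p[1L] + t * (q[1L] - p[1L]), yv) }
  pts <- clip_half(pts, function(p) p[1L] >= xmin, function(p, q) ix(p, q, xmin))
  pts <- clip_half(pts, function(p) p[1L] <= xmax, function(p, q) ix(p, q, xmax))
  pts <- clip_half(pts, function(p) p[2L] >= ymin, function(p, q) iy(p, q, ymin))
  pts <- clip_half(pts, function(p) p[2L] <= ymax, function(p, q) iy(p, q, ymax))
  pts
}

# area of boundary ∩ rectangle; holes subtract via orientation normalization
.boundary_rect_area <- function(bnd, xmin, xmax, ymin, ymax) {
  total <- 0
  for (poly in bnd$polygons) {
    for (ring in poly) {
      cl <- .clip_ring_rect(ring, xmin, xmax, ymin, ymax)
      if (nrow(cl) >= 3L) total <- total + .ring_area(cl)
    }
  }
  total
}

#' @export
print.ps_boundary <- function(x, ...) {
  np <- length(x$polygons)
  nr <- sum(vapply(x$polygons, length, 1L))
  cat(sprintf("<ps_boundary> %d polygon(s), %d ring(s)\n", np, nr))
  invisible(x)
}
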