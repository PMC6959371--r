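#' Build a Lagrangian boundary for a circle or ellipse
#'
#' Discretizes the particle perimeter into linear elements of roughly one
#' grid spacing, ordered counter-clockwise so the element normals point
#' outward.  Marker coordinates are in the body frame, relative to the
#' centroid; [place_boundary()] maps them into the channel.
#'
#' @param axes full axis lengths `c(ax, ay)` in lattice units (`ax = ay`
#'   for a circle).  At orientation zero the y-axis is the wall-normal
#'   direction, so an ellipse built with `ay > ax` starts with its major
#'   axis orthogonal to the wall.
#' @param h target element length (lattice units, default one spacing).
#' @return an object of class `lbad_boundary`: markers (`n x 2`), element
#'   centroids, outward unit normals, element lengths, polygon `area`,
#'   `perimeter`, and second moment of area `inertia_area` about the
#'   centroid.
#' @export
#' @examples
#' b <- build_boundary(c(36, 36))   # circle d = 0.18H at H = 200
#' abs(b$area - pi * 18^2) / (pi * 18^2)   # < 0.5%
build_boundary <- function(axes, h = 1) {
  if (length(axes) != 2L || any(!is.finite(axes)) || any(axes <= 0))
    stop("invalid shape: both axis lengths must be positive")
  a <- axes[1] / 2
  b <- axes[2] / 2
  # equal-arc-length parameterization of the ellipse (CCW)
  tfine <- seq(0, 2 * pi, length.out = 20001)
  xf <- a * cos(tfine)
  yf <- b * sin(tfine)
  ds <- sqrt(diff(xf)^2 + diff(yf)^2)
  s <- c(0, cumsum(ds))
  perim <- s[length(s)]
  n <- max(8L, as.integer(ceiling(perim / h)))
  s_target <- seq(0, perim, length.out = n + 1)[-(n + 1)]
  tpar <- approx(s, tfine, xout = s_target)$y
  markers <- cbind(a * cos(tpar), b * sin(tpar))
  geo <- element_geometry(markers)
  structure(
    c(list(markers = markers, n = n), geo),
    class = "lbad_boundary"
  )
}

#' Element geometry of a closed marker polygon
#'
#' Centroids, outward unit normals (counter-clockwise ordering assumed),
#' element lengths, enclosed area, perimeter and area moment of inertia
#' about the polygon centroid.
#'
#' @param markers `n x 2` matrix of marker positions (closed polygon,
#'   last element connects back to the first marker).
#' @return list with `centroids`, `normals`, `lengths`, `area`,
#'   `perimeter`, `centroid`, `inertia_area`.
#' @export
element_geometry <- function(markers) {
  n <- nrow(markers)
  nxt <- c(2:n, 1L)
  dx <- markers[nxt, 1] - markers[, 1]
  dy <- markers[nxt, 2] - markers[, 2]
  len <- sqrt(dx^2 + dy^2)
  cr <- markers[, 1] * markers[nxt, 2] - markers[nxt, 1] * markers[, 2]
  area <- 0.5 * sum(cr)
  cx <- sum((markers[, 1] + markers[nxt, 1]) * cr) / (6 * area)
  cy <- sum((markers[, 2] + markers[nxt, 2]) * cr) / (6 * area)
  # second polar moment of area about the centroid (uniform density)
  x0 <- markers[, 1] - cx
  y0 <- markers[, 2] - cy
  x1 <- markers[nxt, 1] - cx
  y1 <- markers[nxt, 2] - cy
  cr0 <- x0 * y1 - x1 * y0
  ixx <- sum(cr0 * (y0^2 + y0 * y1 + y1^2)) / 12
  iyy <- sum(cr0 * (x0^2 + x0 * x1 + x1^2)) / 12
  list(
    centroids = cbind(markers[, 1] + dx / 2, markers[, 2] + dy / 2),
    normals = cbind(dy / len, -dx / len),
    lengths = len,
    area = area,
    perimeter = sum(len),
    centroid = c(cx, cy),
    inertia_area = ixx + iyy
  )
}

#' Place a body-frame boundary into the channel
#'
#' Rigidly rotates and translates the markers, recomputing element
#' centroids, normals and probe positions in world coordinates.
#'
#' @param boundary an `lbad_boundary`.
#' @param x_c centroid position `c(x, y)` in lattice units.
#' @param theta orientation angle (radians).
#' @param probe_len probe distance along the outward normal (lattice units).
#' @return list with world-frame `markers`, `centroids`, `normals`,
#'   `lengths`, `probes`.
#' @export
place_boundary <- function(boundary, x_c, theta = 0, probe_len = 1.2) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  m <- boundary$markers %*% t(R)
  m[, 1] <- m[, 1] + x_c[1]
  m[, 2] <- m[, 2] + x_c[2]
  geo <- element_geometry(m)
  list(
    markers = m,
    centroids = geo$centroids,
    normals = geo$normals,
    lengths = geo$lengths,
    probes = geo$centroids + probe_len * geo$normals
  )
}
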