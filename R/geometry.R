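# Planar geometry in a local metric projection. All polygon clipping assumes a
# convex clip polygon; subject geometry may be arbitrary.

EARTH_RADIUS_KM <- 6371.0088  # IUGG mean radius

#' Local equirectangular projection
#'
#' Builds a projection of lon/lat (WGS84 degrees) onto a local plane in km,
#' centred on a reference point. Within the extent of a study region a few
#' hundred km across this is accurate to well under a percent, which is the
#' regime all grid construction and geometry clipping operate in.
#'
#' @param ref_lon,ref_lat reference point (degrees).
#' @return a list with functions `fwd(lon, lat)` and `inv(x, y)`, each
#'   returning a two-column matrix (x/y in km, or lon/lat in degrees).
#' @keywords internal
local_projection <- function(ref_lon, ref_lat) {
  kx <- pi / 180 * EARTH_RADIUS_KM * cos(ref_lat * pi / 180)
  ky <- pi / 180 * EARTH_RADIUS_KM
  list(
    ref_lon = ref_lon, ref_lat = ref_lat,
    fwd = function(lon, lat) {
      cbind(x = (lon - ref_lon) * kx, y = (lat - ref_lat) * ky)
    },
    inv = function(x, y) {
      cbind(lon = x / kx + ref_lon, lat = y / ky + ref_lat)
    }
  )
}

# Signed area of a polygon ring (shoelace). Positive for counter-clockwise.
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_area <- function(xy) abs(polygon_signed_area(xy))

# Drop a repeated closing vertex if present.
open_ring <- function(xy) {
  n <- nrow(xy)
  if (n > 1 && all(xy[1, ] == xy[n, ])) xy[-n, , drop = FALSE] else xy
}

# Orient a ring counter-clockwise.
ccw_ring <- function(xy) {
  xy <- open_ring(xy)
  if (polygon_signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

is_convex_ring <- function(xy, tol = 1e-9) {
  xy <- ccw_ring(xy)
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  cross <- (xy[nxt, 1] - xy[, 1]) * (xy[prv, 2] - xy[, 2]) -
    (xy[nxt, 2] - xy[, 2]) * (xy[prv, 1] - xy[, 1])
  # CCW convex ring: every (next - cur) x (prev - cur) is nonnegative
  all(cross >= -tol * max(1, max(abs(xy))))
}

# Ray-casting point-in-polygon; boundary points count as inside.
point_in_polygon <- function(px, py, xy) {
  xy <- open_ring(xy)
  n <- nrow(xy)
  xs <- xy[, 1]; ys <- xy[, 2]
  m <- length(px)
  inside <- logical(m)
  for (k in seq_len(m)) {
    x <- px[k]; y <- py[k]
    inn <- FALSE
    j <- n
    on_edge <- FALSE
    for (i in seq_len(n)) {
      xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
      # boundary check: point on segment (i, j)
      cr <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
      if (abs(cr) < 1e-12 * max(1, abs(xj - xi), abs(yj - yi)) &&
          x >= min(xi, xj) - 1e-12 && x <= max(xi, xj) + 1e-12 &&
          y >= min(yi, yj) - 1e-12 && y <= max(yi, yj) + 1e-12) {
        on_edge <- TRUE
        break
      }
      if ((yi > y) != (yj > y)) {
        xint <- xi + (y - yi) / (yj - yi) * (xj - xi)
        if (x < xint) inn <- !inn
      }
      j <- i
    }
    inside[k] <- if (on_edge) TRUE else inn
  }
  inside
}

# Half-plane representation of a convex ring: rows (a, b, c) with
# a*x + b*y <= c for interior points.
convex_halfplanes <- function(xy) {
  xy <- ccw_ring(xy)
  n <- nrow(xy)
  nxt <- c(2:n, 1L)
  dx <- xy[nxt, 1] - xy[, 1]
  dy <- xy[nxt, 2] - xy[, 2]
  # interior is to the left of each directed edge: -dy*x + dx*y <= -dy*x0 + dx*y0... sign
  a <- dy
  b <- -dx
  c <- a * xy[, 1] + b * xy[, 2]
  cbind(a = a, b = b, c = c)
}

# Clip segment p0->p1 to a convex polygon; returns clipped length (km units of
# the input coordinates), 0 if fully outside.
clip_segment_length <- function(p0, p1, halfplanes) {
  t0 <- 0; t1 <- 1
  d <- p1 - p0
  for (i in seq_len(nrow(halfplanes))) {
    a <- halfplanes[i, 1]; b <- halfplanes[i, 2]; cc <- halfplanes[i, 3]
    denom <- a * d[1] + b * d[2]
    num <- cc - (a * p0[1] + b * p0[2])
    if (abs(denom) < 1e-15) {
      if (num < 0) return(0)  # parallel and outside
    } else {
      t <- num / denom
      if (denom > 0) t1 <- min(t1, t) else t0 <- max(t0, t)
      if (t0 > t1) return(0)
    }
  }
  (t1 - t0) * sqrt(sum(d^2))
}

# Length of a polyline clipped to a convex polygon.
clip_polyline_length <- function(xy, halfplanes) {
  n <- nrow(xy)
  if (n < 2) return(0)
  total <- 0
  for (i in seq_len(n - 1L)) {
    total <- total + clip_segment_length(xy[i, ], xy[i + 1L, ], halfplanes)
  }
  total
}

# Sutherland-Hodgman: clip an arbitrary subject polygon against a convex clip
# polygon; returns the clipped area.
clip_polygon_area <- function(subject, clip) {
  clip <- ccw_ring(clip)
  out <- open_ring(subject)
  n <- nrow(clip)
  nxt <- c(2:n, 1L)
  for (e in seq_len(n)) {
    if (nrow(out) == 0) return(0)
    a <- clip[e, ]; b <- clip[nxt[e], ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- function(p) ex * (p[2] - a[2]) - ey * (p[1] - a[1])  # >=0 inside (left)
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    m <- nrow(inp)
    prev <- inp[m, ]
    sprev <- side(prev)
    for (i in seq_len(m)) {
      cur <- inp[i, ]
      scur <- side(cur)
      if (scur >= 0) {
        if (sprev < 0) {
          t <- sprev / (sprev - scur)
          out <- rbind(out, prev + t * (cur - prev))
        }
        out <- rbind(out, cur)
      } else if (sprev >= 0) {
        t <- sprev / (sprev - scur)
        out <- rbind(out, prev + t * (cur - prev))
      }
      prev <- cur
      sprev <- scur
    }
  }
  if (nrow(out) < 3) 0 else polygon_area(out)
}
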