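#' Albers equal-area conic projection parameters
#'
#' Parameter set for the ellipsoidal Albers equal-area conic projection.
#' The default is the standard continental-Australia configuration
#' (GDA94 / Australian Albers): central meridian 132 E, latitude of origin
#' 0, standard parallels 18 S and 36 S, GRS80 ellipsoid, zero false
#' easting/northing.
#'
#' @param lon0 central meridian (decimal degrees).
#' @param lat0 latitude of origin.
#' @param lat1,lat2 standard parallels.
#' @param falseEasting,falseNorthing offsets in meters.
#' @param a semi-major axis (m).
#' @param invFlattening inverse flattening of the ellipsoid.
#' @return named list of projection parameters.
#' @examples
#' p <- albersParams()
#' albersForward(132, 0, p)   # the projection origin maps to (0, 0)
#' @export
albersParams <- function(lon0 = 132, lat0 = 0, lat1 = -18, lat2 = -36,
                         falseEasting = 0, falseNorthing = 0,
                         a = 6378137, invFlattening = 298.257222101) {
  list(lon0 = lon0, lat0 = lat0, lat1 = lat1, lat2 = lat2,
       falseEasting = falseEasting, falseNorthing = falseNorthing,
       a = a, invFlattening = invFlattening)
}

# authalic q function (Snyder 1987, eq. 3-12)
.albersQ <- function(phi, e) {
  s <- sin(phi)
  (1 - e^2) * (s / (1 - e^2 * s^2) -
               (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
}

.albersConstants <- function(p) {
  f <- 1 / p$invFlattening
  e2 <- f * (2 - f)
  e <- sqrt(e2)
  d2r <- pi / 180
  phi0 <- p$lat0 * d2r; phi1 <- p$lat1 * d2r; phi2 <- p$lat2 * d2r
  m <- function(phi) cos(phi) / sqrt(1 - e2 * sin(phi)^2)
  m1 <- m(phi1); m2 <- m(phi2)
  q0 <- .albersQ(phi0, e); q1 <- .albersQ(phi1, e); q2 <- .albersQ(phi2, e)
  n <- (m1^2 - m2^2) / (q2 - q1)
  C <- m1^2 + n * q1
  rho0 <- p$a * sqrt(C - n * q0) / n
  list(a = p$a, e = e, e2 = e2, n = n, C = C, rho0 = rho0,
       lam0 = p$lon0 * d2r, FE = p$falseEasting, FN = p$falseNorthing)
}

#' Forward and inverse Albers equal-area conic projection
#'
#' Ellipsoidal forward/inverse mapping between geographic coordinates
#' (decimal degrees) and the planar Albers coordinates (meters). The inverse
#' recovers latitude by Newton iteration on the authalic-latitude relation;
#' a forward-inverse round trip reproduces coordinates to well under 1 m.
#'
#' @param lon,lat geographic coordinates (vectors, decimal degrees).
#' @param x,y planar coordinates (meters).
#' @param params projection parameters from [albersParams()].
#' @return \code{albersForward}: data.frame with columns \code{x}, \code{y};
#'   \code{albersInverse}: data.frame with columns \code{lon}, \code{lat}.
#' @examples
#' xy <- albersForward(135, -25)
#' albersInverse(xy$x, xy$y)
#' @export
albersForward <- function(lon, lat, params = albersParams()) {
  if (any(!is.finite(lon) | !is.finite(lat))) {
    stop("non-finite coordinates cannot be projected")
  }
  if (any(abs(lat) > 90) || any(abs(lon) > 360)) {
    bad <- which(abs(lat) > 90 | abs(lon) > 360)
    stop("coordinates out of range at record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  k <- .albersConstants(params)
  d2r <- pi / 180
  q <- .albersQ(lat * d2r, k$e)
  rho <- k$a * sqrt(k$C - k$n * q) / k$n
  theta <- k$n * (lon * d2r - k$lam0)
  data.frame(x = k$FE + rho * sin(theta),
             y = k$FN + k$rho0 - rho * cos(theta))
}

#' @rdname albersForward
#' @export
albersInverse <- function(x, y, params = albersParams()) {
  k <- .albersConstants(params)
  xp <- x - k$FE
  yp <- k$rho0 - (y - k$FN)
  sgn <- sign(k$n)
  rho <- sgn * sqrt(xp^2 + yp^2)
  theta <- atan2(sgn * xp, sgn * yp)
  q <- (k$C - (rho * k$n / k$a)^2) / k$n
  e <- k$e; e2 <- k$e2
  # Newton iteration for latitude (Snyder 1987, eq. 3-16)
  phi <- asin(pmin(1, pmax(-1, q / 2)))
  for (i in 1:25) {
    s <- sin(phi)
    delta <- (1 - e2 * s^2)^2 / (2 * cos(phi)) *
      (q / (1 - e2) - s / (1 - e2 * s^2) +
       (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
    phi <- phi + delta
    if (all(abs(delta) < 1e-13)) break
  }
  r2d <- 180 / pi
  data.frame(lon = (k$lam0 + theta / k$n) * r2d, lat = phi * r2d)
}
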