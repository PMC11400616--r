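## internal geometry + small helpers

deg2rad <- function(d) d * pi / 180

#' Great-circle (haversine) distance in kilometres
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorised).
#' @param radius_km sphere radius; default mean Earth radius 6371 km.
#' @return numeric vector of distances in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2, radius_km = 6371) {
  phi1 <- deg2rad(lat1)
  phi2 <- deg2rad(lat2)
  dphi <- deg2rad(lat2 - lat1)
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

## full pairwise distance matrix (n small: city networks)
gc_dist_matrix <- function(lon, lat, radius_km = 6371) {
  n <- length(lon)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- great_circle_km(lon[i], lat[i], lon, lat, radius_km)
  }
  diag(m) <- 0
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## z-score with population (1/n) variance, as conventional for Moran's I
standardize_n <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) {
    stop("cannot standardize a zero-variance vector", call. = FALSE)
  }
  (x - mu) / s
}

## weighted Pearson correlation; weights need not sum to 1
weighted_pearson <- function(x, y, w) {
  keep <- is.finite(x) & is.finite(y) & is.finite(w) & w > 0
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (length(x) < 3) return(NA_real_)
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}
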