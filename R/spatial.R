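## spatial weights, bivariate Moran's I, geographically weighted correlation

#' k-nearest-neighbour spatial weights over cities
#'
#' Neighbours by great-circle distance, row-standardized weights `1/k`.
#' Ties (including duplicate coordinates) break deterministically by
#' (distance, city id).
#'
#' @param metadata table with `city_id`, `longitude`, `latitude`.
#' @param k neighbours per city (>= 1; needs at least k+1 cities).
#' @return object of class `spatial_weights`: `ids`, `nb` (list of
#'   neighbour index vectors), `w` (list of weights, each row summing
#'   to 1), `k`, `dist` (full great-circle distance matrix, km).
#' @export
knn_weights <- function(metadata, k = 5L) {
  md <- data.table::as.data.table(metadata)
  n <- nrow(md)
  if (n < k + 1) stop("need at least k+1 cities", call. = FALSE)
  stopifnot(all(is.finite(md$longitude)), all(is.finite(md$latitude)))
  d <- gc_dist_matrix(md$longitude, md$latitude)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], md$city_id)      # deterministic tie-break
    ord <- ord[ord != i]
    nb[[i]] <- sort(ord[seq_len(k)])
  }
  structure(list(ids = md$city_id, nb = nb,
                 w = replicate(n, rep(1 / k, k), simplify = FALSE),
                 k = as.integer(k), dist = d),
            class = "spatial_weights")
}

## dense row-standardized weight matrix (for oracles and linear algebra)
#' Dense matrix form of spatial weights
#' @param W a `spatial_weights` object.
#' @return n x n row-standardized matrix with zero diagonal.
#' @export
weights_matrix <- function(W) {
  n <- length(W$ids)
  m <- matrix(0, n, n, dimnames = list(W$ids, W$ids))
  for (i in seq_len(n)) m[i, W$nb[[i]]] <- W$w[[i]]
  m
}

## spatial lag under list weights
spatial_lag <- function(z, W) {
  vapply(seq_along(z), function(i) sum(W$w[[i]] * z[W$nb[[i]]]), numeric(1))
}

#' Bivariate local and global Moran's I with conditional permutation
#'
#' Both variables are standardized to zero mean and unit (1/n) variance;
#' the local statistic at city i is `I_i = c * x_i * sum_j w_ij y_j`
#' (default proportionality constant `c = 1`) and the global statistic is
#' the mean of the local values.  Pseudo p-values come from conditional
#' permutation: `x_i` is held fixed while the neighbour values of y are
#' drawn from y at the other locations; the global p permutes y wholesale.
#'
#' @param x,y numeric city vectors aligned with `W$ids`; each must have
#'   nonzero variance.
#' @param W a `spatial_weights` object.
#' @param n_perm permutation draws (default 999).
#' @param seed RNG seed for the permutations.
#' @param c_const proportionality constant in the local statistic.
#' @param alternative `"observed_sign"` (one-sided on the sign of the
#'   observed statistic, the GeoDa convention), `"greater"`, `"less"` or
#'   `"two.sided"`.
#' @param local_inference compute per-city conditional-permutation
#'   pseudo p-values (default TRUE; disable for speed when only the
#'   global statistic is needed).
#' @return list of class `bimoran`: `global_I`, `global_p`, `local`
#'   (`data.table` with `local_I`, `quadrant` in HH/LL/LH/HL from the signs
#'   of standardized x and the lag of standardized y, `pseudo_p`),
#'   `n_perm`, `seed`.
#' @export
bimoran <- function(x, y, W, n_perm = 999L, seed = 1L, c_const = 1,
                    alternative = c("observed_sign", "greater", "less",
                                    "two.sided"),
                    local_inference = TRUE) {
  alternative <- match.arg(alternative)
  n <- length(W$ids)
  stopifnot(length(x) == n, length(y) == n)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  zx <- standardize_n(x)
  zy <- standardize_n(y)
  lag <- spatial_lag(zy, W)
  local_I <- c_const * zx * lag
  global_I <- mean(local_I)
  quadrant <- ifelse(zx >= 0 & lag >= 0, "HH",
                     ifelse(zx < 0 & lag < 0, "LL",
                            ifelse(zx < 0, "LH", "HL")))
  set.seed(seed)
  ptail <- function(sim, obs) {
    ge <- sum(sim >= obs)
    le <- sum(sim <= obs)
    switch(alternative,
           observed_sign = if (obs >= 0) ge else le,
           greater = ge,
           less = le,
           two.sided = min(ge, le) * 2L)
  }
  pseudo_p <- rep(NA_real_, n)
  k <- W$k
  if (local_inference) for (i in seq_len(n)) {
    pool <- zy[-i]
    sims <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      sims[p] <- c_const * zx[i] *
        sum(W$w[[i]] * pool[sample.int(n - 1L, k)])
    }
    pseudo_p[i] <- (ptail(sims, local_I[i]) + 1) / (n_perm + 1)
  }
  gsims <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    zp <- zy[sample.int(n)]
    gsims[p] <- mean(c_const * zx * spatial_lag(zp, W))
  }
  global_p <- (ptail(gsims, global_I) + 1) / (n_perm + 1)
  pseudo_p <- pmin(pseudo_p, 1)
  global_p <- min(global_p, 1)
  structure(list(
    global_I = global_I, global_p = global_p,
    local = data.table::data.table(city_id = W$ids, local_I = local_I,
                                   quadrant = quadrant, pseudo_p = pseudo_p),
    n_perm = as.integer(n_perm), seed = as.integer(seed),
    alternative = alternative
  ), class = "bimoran")
}

#' @export
print.bimoran <- function(x, ...) {
  cat(sprintf("Bivariate Moran's I = %.4f (pseudo p = %.4g, %d permutations)\n",
              x$global_I, x$global_p, x$n_perm))
  print(table(x$local$quadrant))
  invisible(x)
}

## bisquare kernel on distance d with bandwidth dmax
bisquare <- function(d, dmax) {
  w <- (1 - (d / dmax)^2)^2
  w[d >= dmax] <- 0
  w
}

#' Geographically weighted local PM2.5-O3 correlation
#'
#' For each city, the weighted Pearson correlation of the paired
#' (PM2.5, O3) annual means pooled over the city and its kernel-weighted
#' neighbours.  The adaptive bandwidth is the distance to the
#' `bandwidth`-th nearest city; kernels: bisquare (default) or uniform.
#' With a uniform kernel and bandwidth covering all cities every local
#' value equals the global pooled Pearson r.
#'
#' @param annual_pairs `data.table` (`city_id`, `year`, `pm`, `o3`) of
#'   valid annual means.
#' @param metadata city metadata with coordinates.
#' @param bandwidth adaptive bandwidth: number of nearest cities included.
#' @param kernel `"bisquare"` or `"uniform"`.
#' @return `data.table` (`city_id`, `local_r`, `n_eff` pairs with positive
#'   weight); `local_r` is NA when fewer than 3 effective pairs exist.
#' @export
local_correlation <- function(annual_pairs, metadata, bandwidth = 20L,
                              kernel = c("bisquare", "uniform")) {
  kernel <- match.arg(kernel)
  md <- data.table::as.data.table(metadata)
  ap <- data.table::as.data.table(annual_pairs)
  ap <- ap[is.finite(pm) & is.finite(o3)]
  n <- nrow(md)
  bandwidth <- min(bandwidth, n)
  d <- gc_dist_matrix(md$longitude, md$latitude)
  out <- data.table::data.table(city_id = md$city_id, local_r = NA_real_,
                                n_eff = 0L)
  for (i in seq_len(n)) {
    di <- d[i, ]
    ord <- order(di, md$city_id)
    sel <- ord[seq_len(bandwidth)]
    wcity <- if (kernel == "uniform") {
      rep(1, length(sel))
    } else {
      dmax <- max(di[sel])
      if (dmax == 0) rep(1, length(sel)) else bisquare(di[sel], dmax)
    }
    wmap <- data.table::data.table(city_id = md$city_id[sel], w = wcity)
    pairs <- ap[wmap, on = "city_id", nomatch = NULL]
    pairs <- pairs[w > 0]
    out$n_eff[i] <- nrow(pairs)
    if (nrow(pairs) >= 3) {
      out$local_r[i] <- weighted_pearson(pairs$pm, pairs$o3, pairs$w)
    }
  }
  out[]
}

#' Per-city temporal PM2.5-O3 correlation
#'
#' The temporal reading of the co-pollutant correlation: for each city,
#' the Pearson correlation of its paired valid daily PM2.5 and O3 values.
#' Complements the geographically weighted spatial reading of
#' [local_correlation()].
#'
#' @param series a QC-filtered `city_series`.
#' @param min_pairs minimum paired days (default 3); below it `local_r`
#'   is NA.
#' @return `data.table` (`city_id`, `local_r`, `n_pairs`).
#' @export
temporal_correlation <- function(series, min_pairs = 3L) {
  dd <- data.table::as.data.table(series)[valid == TRUE]
  dw <- data.table::dcast(dd, city_id + date ~ pollutant,
                          value.var = "value")
  if (!all(c("PM25", "O3") %in% names(dw))) {
    stop("series must contain both PM25 and O3", call. = FALSE)
  }
  dw <- dw[!is.na(PM25) & !is.na(O3)]
  dw[, .(local_r = if (.N >= min_pairs && sd(PM25) > 0 && sd(O3) > 0) {
    cor(PM25, O3)
  } else NA_real_, n_pairs = .N), by = city_id]
}

#' Quadratic fit of local correlation against PM2.5 level
#'
#' Ordinary least squares of `local_r` on `(pm, pm^2)`; reports the fitted
#' peak location `-b/(2a)` (and peak value) when the curvature is negative,
#' otherwise the peak is NA.
#'
#' @param local_r per-city local correlations.
#' @param pm_means per-city PM2.5 period means, µg/m³.
#' @return list: `coefficients` (intercept, pm, pm2), `r_squared`,
#'   `peak_pm`, `peak_r`, `n`.
#' @export
correlation_curvature <- function(local_r, pm_means) {
  keep <- is.finite(local_r) & is.finite(pm_means)
  r <- local_r[keep]
  pm <- pm_means[keep]
  if (length(r) < 4) stop("need at least 4 cities with defined local_r",
                          call. = FALSE)
  if (var(pm) == 0) stop("singular design: all PM2.5 means equal",
                         call. = FALSE)
  fit <- lm(r ~ pm + I(pm^2))
  cf <- coef(fit)
  ss_tot <- sum((r - mean(r))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  a <- cf[[3]]
  b <- cf[[2]]
  ## curvature must be negative beyond numeric noise for a peak to exist
  if (is.finite(a) && a < -sqrt(.Machine$double.eps)) {
    peak_pm <- -b / (2 * a)
    peak_r <- cf[[1]] + b * peak_pm + a * peak_pm^2
  } else {
    peak_pm <- NA_real_
    peak_r <- NA_real_
  }
  list(coefficients = c(intercept = cf[[1]], pm = b, pm2 = a),
       r_squared = r2, peak_pm = peak_pm, peak_r = peak_r, n = length(r))
}

#' Spatial association of precursor emissions with concentrations
#'
#' Delegates to [bimoran()] with x = emissions and y = concentration means,
#' and adds the plain Pearson correlation.
#'
#' @param emissions per-city emission totals (tons/yr), aligned to `W$ids`.
#' @param conc_means per-city concentration means, µg/m³.
#' @param W a `spatial_weights` object.
#' @param ... passed to [bimoran()].
#' @return list: `moran` (a `bimoran`), `pearson_r`.
#' @export
precursor_association <- function(emissions, conc_means, W, ...) {
  list(moran = bimoran(emissions, conc_means, W, ...),
       pearson_r = cor(emissions, conc_means))
}
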