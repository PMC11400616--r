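toy_meta <- function(n, seed = 2) {
  set.seed(seed)
  data.table::data.table(
    city_id = sprintf("T%02d", seq_len(n)),
    longitude = runif(n, -30, 30),
    latitude = runif(n, -30, 30))
}

test_that("kNN weights: row sums, no self, deterministic ties", {
  md <- toy_meta(12)
  W <- knn_weights(md, k = 4)
  m <- weights_matrix(W)
  expect_equal(unname(rowSums(m)), rep(1, 12))
  expect_true(all(diag(m) == 0))
  # two cities, k = 1: mutual neighbours with weight 1
  W2 <- knn_weights(toy_meta(2), k = 1)
  expect_equal(W2$nb, list(2L, 1L))
  expect_equal(unlist(W2$w), c(1, 1))
  # equilateral-ish triangle, k = 2: all weights 0.5
  tri <- data.table::data.table(city_id = c("a", "b", "c"),
                                longitude = c(0, 1, 0.5),
                                latitude = c(0, 0, sqrt(3) / 2))
  m3 <- weights_matrix(knn_weights(tri, k = 2))
  expect_true(all(m3[m3 > 0] == 0.5))
  # duplicate coordinates resolved by id order, reproducibly
  dup <- data.table::data.table(city_id = c("a", "b", "c", "d"),
                                longitude = c(0, 0, 0, 10),
                                latitude = c(0, 0, 0, 0))
  Wd1 <- knn_weights(dup, k = 1)
  Wd2 <- knn_weights(dup, k = 1)
  expect_identical(Wd1$nb, Wd2$nb)
  expect_error(knn_weights(toy_meta(3), k = 5), "k\\+1")
})

test_that("bivariate Moran: two-city anti-aligned case gives exactly -1", {
  md <- toy_meta(2)
  W <- knn_weights(md, k = 1)
  bm <- bimoran(c(10, 2), c(8, 1), W, n_perm = 19, seed = 1)
  expect_equal(bm$global_I, -1)
  expect_error(bimoran(c(1, 2), c(5, 5), W), "zero-variance")
})

test_that("global and local Moran match the double-sum oracle", {
  set.seed(5)
  for (rep_i in 1:10) {
    n <- sample(10:40, 1)
    md <- toy_meta(n, seed = rep_i)
    W <- knn_weights(md, k = sample(2:5, 1))
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    bm <- bimoran(x, y, W, n_perm = 9, seed = 1, local_inference = FALSE)
    m <- weights_matrix(W)
    expect_equal(bm$global_I, bimoran_oracle(x, y, m), tolerance = 1e-12)
    # local values average to the global and quadrants are conserved
    expect_equal(mean(bm$local$local_I), bm$global_I)
    expect_equal(sum(table(bm$local$quadrant)), n)
  }
})

test_that("conditional permutation flags a planted spatial signal", {
  cfg <- synth_config(n_cities = 60, seed = 4)
  meta <- generate_city_metadata(cfg)
  truth <- synth_truth(generate_daily_series(cfg, meta))
  truth <- truth[match(meta$city_id, city_id)]
  W <- knn_weights(meta, k = 5)
  bm <- bimoran(truth$true_mean_pm, truth$true_mean_o3, W,
                n_perm = 199, seed = 8)
  expect_gt(bm$global_I, 0)
  expect_lt(bm$global_p, 0.05)
  expect_true(all(bm$local$pseudo_p > 0 & bm$local$pseudo_p <= 1))
  expect_true(all(bm$local$quadrant %in% c("HH", "LL", "LH", "HL")))
})

test_that("local correlation limits: global-r limit and collinearity", {
  cfg <- tiny_synth(n_cities = 15, seed = 6)
  meta <- generate_city_metadata(cfg)
  set.seed(6)
  ap <- data.table::CJ(city_id = meta$city_id, year = 2019:2022)
  ap[, pm := rnorm(.N, 50, 15)]
  ap[, o3 := 0.6 * pm + rnorm(.N, 0, 10)]
  # uniform kernel covering every city: local r == pooled Pearson r
  lc <- local_correlation(ap, meta, bandwidth = 15, kernel = "uniform")
  expect_equal(lc$local_r, rep(cor(ap$pm, ap$o3), 15), tolerance = 1e-12)
  # perfect collinearity: local r = 1 everywhere
  ap2 <- data.table::copy(ap)[, o3 := pm]
  lc2 <- local_correlation(ap2, meta, bandwidth = 8, kernel = "bisquare")
  expect_equal(lc2$local_r, rep(1, 15))
  # affine invariance of either pollutant
  ap3 <- data.table::copy(ap)[, `:=`(pm = 2 * pm + 3, o3 = 0.1 * o3 - 7)]
  lc3 <- local_correlation(ap3, meta, bandwidth = 8, kernel = "bisquare")
  lc0 <- local_correlation(ap, meta, bandwidth = 8, kernel = "bisquare")
  expect_equal(lc3$local_r, lc0$local_r, tolerance = 1e-10)
})

test_that("local correlation matches a hand-rolled weighted Pearson", {
  # 5 cities on a line; bisquare weights recomputed by hand
  md <- data.table::data.table(city_id = sprintf("L%d", 1:5),
                               longitude = c(0, 1, 2, 3, 4) * 2,
                               latitude = rep(0, 5))
  set.seed(12)
  ap <- data.table::CJ(city_id = md$city_id, year = 2019:2021)
  ap[, pm := runif(.N, 20, 80)]
  ap[, o3 := runif(.N, 60, 140)]
  lc <- local_correlation(ap, md, bandwidth = 3, kernel = "bisquare")
  d <- sapply(seq_len(5), function(j)
    great_circle_km(md$longitude[1], md$latitude[1],
                    md$longitude[j], md$latitude[j]))
  sel <- order(d)[1:3]
  dmax <- max(d[sel])
  wc <- (1 - (d[sel] / dmax)^2)^2
  wc[d[sel] >= dmax] <- 0
  keep <- sel[wc > 0]
  x <- ap[city_id %in% md$city_id[keep]]
  wv <- wc[match(x$city_id, md$city_id[sel])]
  expect_equal(lc$local_r[1], weighted_pearson_oracle(x$pm, x$o3, wv))
})

test_that("temporal correlation: bounds, collinearity, pairing", {
  days <- seq(as.Date("2019-01-01"), by = "day", length.out = 40)
  set.seed(14)
  v <- runif(40, 10, 90)
  raw <- rbind(
    data.frame(city_id = "A", date = as.character(days), pollutant = "PM25",
               value = v),
    data.frame(city_id = "A", date = as.character(days), pollutant = "O3",
               value = v),                    # collinear
    data.frame(city_id = "B", date = as.character(days), pollutant = "PM25",
               value = runif(40, 10, 90)),
    data.frame(city_id = "B", date = as.character(days[1:2]),
               pollutant = "O3", value = c(50, 60)))  # too few pairs
  tc <- temporal_correlation(qc_filter(raw))
  expect_equal(tc[city_id == "A", local_r], 1)
  expect_equal(tc[city_id == "A", n_pairs], 40)
  expect_true(is.na(tc[city_id == "B", local_r]))
  expect_equal(tc[city_id == "B", n_pairs], 2)
})

test_that("correlation_curvature recovers an exact parabola and rejects flats", {
  pm <- c(20, 60, 100, 140, 180)
  r <- -0.0001 * (pm - 110)^2 + 0.62
  fit <- correlation_curvature(r, pm)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$peak_pm, 110)
  expect_equal(fit$peak_r, 0.62)
  # zero curvature: peak undefined
  flat <- correlation_curvature(0.001 * pm + 0.2, pm)
  expect_true(is.na(flat$peak_pm))
  expect_error(correlation_curvature(c(0.1, 0.2, 0.3), c(1, 2, 3)),
               "at least 4")
  expect_error(correlation_curvature(c(0.1, 0.2, 0.3, 0.4), rep(5, 4)),
               "singular")
})

test_that("precursor_association delegates to bimoran", {
  md <- toy_meta(20, seed = 9)
  W <- knn_weights(md, k = 4)
  set.seed(9)
  x <- rnorm(20)
  y <- rnorm(20)
  pa <- precursor_association(x, y, W, n_perm = 49, seed = 3)
  bm <- bimoran(x, y, W, n_perm = 49, seed = 3)
  expect_equal(pa$moran$global_I, bm$global_I)
  expect_equal(pa$moran$local$pseudo_p, bm$local$pseudo_p)
  expect_equal(pa$pearson_r, cor(x, y))
})
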