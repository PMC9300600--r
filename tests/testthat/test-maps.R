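test_that("grid cells are half a standard deviation wide, anchored at the mean", {
  set.seed(1)
  vec <- as_biomarker(rnorm(5000, 100, 10))
  g <- make_grid(vec)
  expect_equal(unique(round(diff(g$edges), 9)), round(vec$sigma / 2, 9))
  # the mean sits exactly on a cell boundary
  expect_true(any(abs(g$edges - vec$mu) < 1e-9))
  # edges cover the data range
  expect_lte(g$edges[1], min(vec$values))
  expect_gte(g$edges[length(g$edges)], max(vec$values))
})

test_that("a large standard normal sample spans the expected bin range", {
  set.seed(3)
  vec <- as_biomarker(rnorm(1e5))
  g <- make_grid(vec)
  dm <- build_dmap(vec, list(g), suppress = FALSE)
  # oracle: bins spanned by the simulated range at width 1/2 (tail bins
  # inside the span may be empty at this n)
  span <- floor(max(vec$zscores) / 0.5) - floor(min(vec$zscores) / 0.5) + 1
  expect_equal(g$nbins, span)
  populated <- sum(dm$n_cell > 0)
  expect_gte(populated, 13)
  expect_lte(populated, span)
  # the bulk (middle ~14 bins, ±3.5 SD) is fully populated
  mid <- abs(g$z_centers) < 3.5
  expect_true(all(dm$n_cell[mid] > 0))
})

test_that("grids are affine-equivariant and degenerate input errors", {
  set.seed(2)
  x <- rnorm(1000, 50, 5)
  g1 <- make_grid(as_biomarker(x))
  g2 <- make_grid(as_biomarker(2 * x + 30))
  expect_equal(g2$edges, 2 * g1$edges + 30, tolerance = 1e-9)
  expect_equal(g2$nbins, g1$nbins)
  expect_error(make_grid(structure(list(name = "c", values = rep(1, 5),
                                        mu = 1, sigma = 0,
                                        zscores = rep(NA_real_, 5), n = 5),
                                   class = "biomarker_vector")),
               class = "norse_degenerate_error")
})

test_that("d-map counts conserve the analysis population", {
  set.seed(4)
  v <- c(rnorm(3000, 80, 8), NA, NA, NA)
  vec <- as_biomarker(v)
  dm <- build_dmap(vec, suppress = FALSE)
  expect_equal(sum(dm$n_cell), 3000)   # missing values excluded from n_tot
  expect_equal(dm$n_tot, 3000)
  expect_equal(sum(dm$fraction), 1)
  expect_true(all(dm$fraction >= 0 & dm$fraction <= 1))
})

test_that("d-map counts match a brute-force per-participant assignment", {
  set.seed(5)
  v <- round(runif(200, 60, 140), 1)
  vec <- as_biomarker(v)
  g <- make_grid(vec)
  dm <- build_dmap(vec, list(g), suppress = FALSE)
  # oracle: assign each participant by scanning edges
  brute <- integer(g$nbins)
  for (x in v) {
    z <- (x - vec$mu) / vec$sigma
    k <- max(which(g$z_edges <= z + 1e-12))
    brute[k] <- brute[k] + 1
  }
  expect_equal(as.vector(dm$n_cell), brute)
})

test_that("d-map counts agree with a histogram over the same breaks", {
  set.seed(6)
  v <- runif(4000, 0, 4)
  vec <- as_biomarker(v)
  g <- make_grid(vec)
  dm <- build_dmap(vec, list(g), suppress = FALSE)
  h <- hist(vec$zscores, breaks = g$z_edges, right = FALSE, plot = FALSE)
  expect_equal(as.vector(dm$n_cell), h$counts)
})

test_that("2D d-maps conserve counts and match 1D margins", {
  set.seed(7)
  x <- rnorm(4000, 0, 1)
  y <- 0.8 * x + rnorm(4000, 0, 0.6)
  dm <- build_dmap(list(as_biomarker(x), as_biomarker(y)), suppress = FALSE)
  expect_equal(sum(dm$n_cell), 4000)
  dx <- build_dmap(as_biomarker(x), suppress = FALSE)
  expect_equal(rowSums(dm$n_cell), as.vector(dx$n_cell))
})

test_that("p-map prevalence and suppression follow the stated rules exactly", {
  # three values -> three cells with controlled counts 39, 40, 500
  v <- c(rep(10, 39), rep(20, 40), rep(30, 500))
  flags <- c(rep(0, 39), rep(1, 10), rep(0, 30), rep(1, 250), rep(0, 250))
  vec <- as_biomarker(v)
  pm <- build_pmap(vec, flags, min_cell = 40, min_frac = 0)
  populated <- which(pm$n_cell > 0)
  counts <- pm$n_cell[populated]
  expect_equal(sort(counts), c(39, 40, 500))
  # n_cell = 39 suppressed regardless of prevalence; 40 is not
  expect_true(pm$suppressed[populated][counts == 39])
  expect_false(pm$suppressed[populated][counts == 40])
  expect_equal(pm$prevalence[populated][counts == 40], 25)
  expect_equal(pm$prevalence[populated][counts == 500], 50)
  expect_true(all(pm$n_cond <= pm$n_cell))
})

test_that("the cell-fraction rule suppresses cells below 0.2% of the map", {
  # a 500-strong cell in a 300000-strong map: fraction 0.167% < 0.2%
  v <- c(rep(10, 299500), rep(30, 500))
  flags <- rep(0, length(v))
  pm <- build_pmap(as_biomarker(v), flags, min_cell = 40, min_frac = 0.002)
  populated <- which(pm$n_cell > 0)
  small <- populated[pm$n_cell[populated] == 500]
  expect_true(pm$suppressed[small])
  # same cell passes when it is 0.2% exactly
  v2 <- c(rep(10, 249500), rep(30, 500))
  pm2 <- build_pmap(as_biomarker(v2), rep(0, length(v2)),
                    min_cell = 40, min_frac = 0.002)
  small2 <- which(pm2$n_cell == 500)
  expect_false(pm2$suppressed[small2])
})

test_that("suppression is monotone in the count threshold", {
  set.seed(8)
  v <- rnorm(5000, 0, 1)
  flags <- rbinom(5000, 1, 0.3)
  vec <- as_biomarker(v)
  thresholds <- c(10, 40, 100, 400)
  masks <- lapply(thresholds, function(mc)
    build_pmap(vec, flags, min_cell = mc)$suppressed)
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i + 1]][masks[[i]]]))  # never un-suppresses
  }
})

test_that("rows with missing flags are excluded and n_tot matches the d-map", {
  set.seed(9)
  v <- rnorm(2000, 0, 1)
  flags <- rbinom(2000, 1, 0.2)
  flags[sample(2000, 100)] <- NA
  vec <- as_biomarker(v)
  pm <- build_pmap(vec, flags)
  expect_equal(pm$n_tot, 1900)
  expect_equal(sum(pm$n_cell), 1900)
  expect_error(build_pmap(vec, ifelse(flags == 1, 2, 0)),
               class = "norse_map_error")
})

test_that("maps export one row per cell and round-trip through CSV", {
  set.seed(10)
  vec <- as_biomarker(rnorm(500))
  flags <- rbinom(500, 1, 0.4)
  pm <- build_pmap(vec, flags, min_cell = 10)
  df <- as.data.frame(pm)
  expect_equal(nrow(df), pm$grids[[1]]$nbins)
  expect_named(df, c("x_lo", "x_hi", "n_cell", "n_cond", "prevalence",
                     "suppressed"))
  path <- tempfile(fileext = ".csv")
  write_map(pm, path)
  back <- read.csv(path)
  expect_equal(back$n_cell, df$n_cell)
  expect_equal(back$prevalence, df$prevalence)
})
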