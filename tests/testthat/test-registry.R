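test_that("built-in registry holds the 23 biomarkers in their three groups", {
  reg <- biomarker_registry()
  expect_length(reg, 23)
  groups <- vapply(reg, `[[`, "", "group")
  expect_equal(sum(groups == "regional"), 10)
  expect_equal(sum(groups == "global"), 7)
  expect_equal(sum(groups == "non_composition"), 6)
  expect_setequal(list_biomarkers(reg, "global"),
                  c("pbf", "ftl", "fmi", "pi", "bmi", "weight", "ffmi"))
})

test_that("ratio formulas give the published worked values", {
  tbl <- make_participants(2, waist_circ = c(85, 87.5),
                           hip_circ = c(100, 97.5),
                           weight = c(80, 80), height = c(200, 200))
  whr <- derive_biomarker(tbl, "whr")$values
  expect_equal(whr[1], 0.85)
  expect_equal(round(whr[2], 1), 0.9)        # mis-measured tape example
  expect_equal(round(whr[2] - whr[1], 2), 0.05)
  expect_equal(derive_biomarker(tbl, "bmi")$values, c(20, 20))
})

test_that("derivation propagates missingness and flags bad measurements", {
  tbl <- make_participants(3, waist_circ = c(80, NA, 90),
                           hip_circ = c(100, 100, -5))
  expect_warning(v <- derive_biomarker(tbl, "whr", standardize = FALSE),
                 "non-positive")
  expect_equal(is.na(v$values), c(FALSE, TRUE, TRUE))
  expect_error(derive_biomarker(tbl, "nope"), class = "norse_registry_error")
})

test_that("derivation is row-wise and scale-free for ratios", {
  set.seed(7)
  tbl <- make_participants(50, waist_circ = runif(50, 70, 110),
                           hip_circ = runif(50, 90, 120))
  v <- derive_biomarker(tbl, "whr", standardize = FALSE)$values
  perm <- sample(50)
  vp <- derive_biomarker(tbl[perm, ], "whr", standardize = FALSE)$values
  expect_equal(vp, v[perm])
  tbl2 <- tbl
  tbl2$waist_circ <- tbl2$waist_circ * 2.54
  tbl2$hip_circ <- tbl2$hip_circ * 2.54
  expect_equal(derive_biomarker(tbl2, "whr", standardize = FALSE)$values, v)
})

test_that("rfm adds the female offset", {
  tbl <- make_participants(2, sex = c("male", "female"),
                           waist_circ = 100, height = 170)
  v <- derive_biomarker(tbl, "rfm", standardize = FALSE)$values
  expect_equal(v[2] - v[1], 12)
  expect_equal(v[1], 64 - 20 * 170 / 100)
})

test_that("registry formulas can be overridden", {
  reg <- register_biomarker(biomarker_registry(), "whr", "regional",
                            c("waist_circ", "hip_circ"),
                            function(d) 2 * d$waist_circ / d$hip_circ)
  tbl <- make_participants(1, waist_circ = 85, hip_circ = 100)
  expect_equal(derive_biomarker(tbl, "whr", reg)$values, 1.7)
  # the alternative trunk-fat denominator
  reg2 <- biomarker_registry(ptf_denominator = "total_fat_mass")
  tbl2 <- make_participants(1, trunk_fat_mass = 10, total_fat_mass = 20,
                            weight = 80)
  expect_equal(derive_biomarker(tbl2, "ptf", reg2)$values, 50)
  expect_equal(derive_biomarker(tbl2, "ptf")$values, 12.5)
})

test_that("zscore standardizes with the population SD convention", {
  v <- zscore(as_biomarker(c(-1, 0, 1)))
  expect_equal(v$mu, 0)
  expect_equal(v$sigma, sqrt(2 / 3))  # divide-by-n convention
  expect_equal(v$zscores[2], 0)
  expect_equal(mean(v$zscores), 0)
  expect_equal(norse:::sd_pop(v$zscores), 1)
  # sample convention switchable
  vs <- zscore(as_biomarker(c(-1, 0, 1)), sd_type = "sample")
  expect_equal(vs$sigma, 1)
})

test_that("zscore recovers generating parameters on a large normal sample", {
  set.seed(42)
  v <- zscore(as_biomarker(rnorm(1e5, 100, 10)))
  expect_lt(abs(v$mu - 100), 0.1)
  expect_lt(abs(v$sigma - 10), 0.1)
})

test_that("zscore is equivariant under positive affine maps and idempotent", {
  set.seed(9)
  x <- rnorm(200, 50, 5)
  z1 <- zscore(as_biomarker(x))$zscores
  z2 <- zscore(as_biomarker(3.7 * x + 11))$zscores
  expect_equal(z2, z1, tolerance = 1e-12)
  expect_equal(zscore(as_biomarker(z1))$zscores, z1, tolerance = 1e-12)
})

test_that("degenerate vectors are rejected", {
  expect_error(zscore(as_biomarker(rep(5, 10))),
               class = "norse_degenerate_error")
  expect_error(zscore(as_biomarker(c(1, NA))),
               class = "norse_degenerate_error")
})

test_that("pair enumeration is complete, unordered and deterministic", {
  p23 <- list_pairs(list_biomarkers())
  expect_equal(nrow(p23), 253)
  expect_false(any(p23$x == p23$y))
  expect_equal(anyDuplicated(paste(pmin(p23$x, p23$y),
                                   pmax(p23$x, p23$y))), 0)
  expect_equal(nrow(list_pairs(c("a", "b"))), 1)
  expect_equal(nrow(list_pairs("a")), 0)
  expect_error(list_pairs(c("a", "a")), class = "norse_registry_error")
  expect_identical(list_pairs(c("a", "b", "c")),
                   list_pairs(c("a", "b", "c")))
})
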