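test_that("the packaged phenolic profile loads with full structure", {
  tbl <- read_compound_table(fixture_table_path())
  expect_s3_class(tbl, "compound_table")
  expect_equal(nrow(tbl$mean), 17)
  expect_equal(ncol(tbl$mean), 6)
  expect_setequal(tbl$conditions$temperature_C, c(40, 50))
  # rutin is undetected in all three 40 C conditions, quantified at 50 C
  rutin <- tbl$mean["Rutin", ]
  expect_true(all(is.na(rutin[tbl$conditions$temperature_C == 40])))
  expect_true(all(!is.na(rutin[tbl$conditions$temperature_C == 50])))
})

test_that("single-compound tables are valid and malformed ones are not", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,category,rt_min,mean_40C_NE,sd_40C_NE,mean_50C_NE,sd_50C_NE",
               "Catechin,flavanol,20.03,309.10,5.72,44.08,3.45"), path)
  tbl <- read_compound_table(path)
  expect_equal(nrow(tbl$mean), 1)
  expect_equal(ncol(tbl$mean), 2)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,category,rt_min,mean_40C_NE,sd_40C_NE",
               "A,flavanol,1,10,1", "A,flavanol,2,11,1"), bad)
  expect_error(read_compound_table(bad), "duplicate")
  writeLines(c("compound,category,rt_min,mean_40C_NE,sd_40C_NE",
               "A,mystery,1,10,1"), bad)
  expect_error(read_compound_table(bad), "unknown categories")
  writeLines(c("compound,category,rt_min,mean_40C_NE,sd_40C_NE",
               "A,flavanol,1,-3,1"), bad)
  expect_error(read_compound_table(bad), "negative")
})

test_that("category summary counts and proportions behave", {
  tbl <- read_compound_table(fixture_table_path())
  cs <- category_summary(tbl)
  expect_equal(sum(cs$counts), 17)
  expect_equal(unname(cs$counts["phenolic acid"]), 9)
  expect_equal(colSums(cs$proportions), rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  # toy arithmetic: 10 and 30 ug/g in one category
  toy <- toy_compound_table()
  ts <- category_summary(toy)
  expect_equal(unname(ts$proportions["flavanol", 1]), 1)
  expect_equal(unname(toy$mean[, 1] / sum(toy$mean[, 1])), c(0.25, 0.75))
})

test_that("condition queries return printed extrema with their conditions", {
  tbl <- read_compound_table(fixture_table_path())
  mx <- condition_query(tbl, "Catechin", "max")
  expect_equal(mx$value, 855.66)
  expect_equal(mx$temperature_C, 50)
  expect_equal(mx$enzyme, "1")
  mn <- condition_query(tbl, "Catechin", "min")
  expect_equal(mn$value, 44.08)
  expect_equal(mn$temperature_C, 50)
  expect_equal(mn$enzyme, "NE")
  # a single-condition compound has max = min
  toy <- toy_compound_table()
  expect_equal(condition_query(toy, "A", "max")$value,
               condition_query(toy, "A", "min")$value)
  expect_error(condition_query(tbl, "nonexistent"), "unknown compound")
})

test_that("replicate expansion has the right shape, limits and determinism", {
  tbl <- read_compound_table(fixture_table_path())
  X <- expand_replicates(tbl, 3, seed = 1)
  expect_equal(dim(X), c(18, 17))
  expect_equal(length(attr(X, "condition")), 18)
  expect_true(all(X >= 0))
  expect_identical(X, expand_replicates(tbl, 3, seed = 1))
  expect_false(identical(X, expand_replicates(tbl, 3, seed = 2)))
  # sd = 0 collapses replicates onto the means (missing -> 0)
  tbl0 <- tbl
  tbl0$sd[] <- 0
  tbl0$sd[is.na(tbl0$mean)] <- NA
  X0 <- expand_replicates(tbl0, 3, seed = 5)
  m0 <- tbl$mean
  m0[is.na(m0)] <- 0
  expect_equal(unname(X0), unname(m0[, rep(1:6, each = 3)] |> t()),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(expand_replicates(tbl, 0, seed = 1), "n_reps")
  expect_error(expand_replicates(tbl, 3), "seed")
})

test_that("autoscaled PCA satisfies its algebraic invariants", {
  set.seed(31)
  X <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  p <- pca_autoscaled(X)
  expect_equal(sum(p$explained_pct), 100, tolerance = 1e-6)
  expect_true(all(diff(p$explained_pct) <= 1e-12))
  expect_equal(crossprod(p$loadings), diag(ncol(X)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # scores * loadings' reconstructs the preprocessed matrix
  Z <- scale(X, center = p$center, scale = p$scale)
  expect_equal(p$scores %*% t(p$loadings), Z, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCA shares match a closed-form correlation eigendecomposition", {
  # two autoscaled variables with sample correlation r have correlation
  # matrix eigenvalues 1 +/- r: shares (1+r)/2 and (1-r)/2
  set.seed(8)
  n <- 40
  a <- rnorm(n)
  b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n)
  X <- cbind(a = a, b = b)
  r <- cor(a, b)
  p <- pca_autoscaled(X)
  expect_equal(p$explained_pct[1], 100 * (1 + abs(r)) / 2, tolerance = 1e-8)
  expect_equal(p$explained_pct[2], 100 * (1 - abs(r)) / 2, tolerance = 1e-8)
  # perfectly collinear 2-D data put 100% on PC1
  Y <- cbind(x = 1:6, y = 2 * (1:6) + 3)
  expect_equal(pca_autoscaled(Y)$explained_pct[1], 100, tolerance = 1e-9)
})

test_that("zero-sd expansion reproduces the PCA of the repeated means", {
  tbl <- read_compound_table(fixture_table_path())
  tbl0 <- tbl
  tbl0$sd[!is.na(tbl0$sd)] <- 0
  X0 <- expand_replicates(tbl0, 3, seed = 1)
  m0 <- t(tbl$mean)
  m0[is.na(m0)] <- 0
  Xm <- m0[rep(1:6, each = 3), ]
  p1 <- pca_autoscaled(X0)
  p2 <- pca_autoscaled(Xm)
  expect_equal(p1$explained_pct, p2$explained_pct, tolerance = 1e-9)
})

test_that("replicate-expanded PC1 share is stable across seeds", {
  tbl <- read_compound_table(fixture_table_path())
  shares <- vapply(1:50, function(s) {
    pca_autoscaled(expand_replicates(tbl, 3, seed = s))$explained_pct[1]
  }, numeric(1))
  expect_lt(max(shares) - min(shares), 6)           # +/- 3 points
  expect_lt(abs(mean(shares) - median(shares)), 1)  # no wild outliers
})

test_that("constant columns are dropped with a warning", {
  X <- cbind(a = rnorm(10), b = rep(2, 10), c = rnorm(10))
  expect_warning(p <- pca_autoscaled(X), "constant")
  expect_equal(nrow(p$loadings), 2)
  expect_equal(p$dropped, "b")
  expect_error(pca_autoscaled(X[1:2, ]), "at least 3")
})
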