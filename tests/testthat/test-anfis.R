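train48 <- function(seed, noise = 0.05, epochs = 30) {
  cfg <- generator_config(seed = seed, noise_sd_range = c(noise, noise))
  ds <- simulate_kinetics(cfg)
  us <- ds[ds$method == "US", , drop = FALSE]
  sp <- split_dataset(us, 0.6, seed = seed)
  m0 <- anfis_init(sp$train[anfis_features], sp$train$yield_mg_per_g)
  fit <- suppressWarnings(
    anfis_train(m0, sp$train[anfis_features], sp$train$yield_mg_per_g,
                sp$test[anfis_features], sp$test$yield_mg_per_g,
                epochs = epochs))
  list(fit = fit, split = sp)
}

test_that("membership functions are bounded and cross near one half", {
  x <- cbind(a = runif(20), b = runif(20), c = runif(20))
  y <- rnorm(20)
  m <- anfis_init(x, y, n_mf = 2)
  grid <- seq(0, 1, length.out = 101)
  for (j in 1:3) {
    for (k in 1:2) {
      v <- mf_eval(m$mfs[[j]][[k]], grid)
      expect_true(all(v >= 0 & v <= 1))
      expect_equal(mf_eval(m$mfs[[j]][[k]], 0.5), 0.5, tolerance = 0.1)
    }
  }
  # rule bases are full factorials of the memberships
  expect_equal(nrow(anfis_init(x, y, n_mf = 3)$rules), 27)
  expect_equal(nrow(anfis_init(x, y, n_mf = 1)$rules), 1)
  expect_error(anfis_init(cbind(a = rep(1, 20), b = runif(20)), y[1:20]),
               "constant")
})

test_that("normalization layer sums to one for random in-domain inputs", {
  set.seed(11)
  x <- cbind(runif(60, 40, 50), runif(60, 2.5, 40), runif(60, 0, 1))
  m <- anfis_init(x, rnorm(60))
  probe <- sapply(1:3, function(j) runif(1000, m$domain_lo[j], m$domain_hi[j]))
  pred <- anfis_predict(m, probe, trace = TRUE)
  wbar <- attr(pred, "trace")$normalized
  expect_equal(rowSums(wbar), rep(1, 1000), tolerance = 1e-12)
})

test_that("single-rule and hand-built models give hand-computed outputs", {
  x <- cbind(a = runif(12), b = runif(12), c = runif(12))
  m <- anfis_init(x, rnorm(12), n_mf = 1)
  m$consequents <- matrix(c(0, 0, 0, 7), 1)  # constant consequent
  expect_equal(unname(anfis_predict(m, c(0.3, 0.9, 0.1))), 7)
  expect_equal(unname(anfis_predict(m, c(0.5, 0.5, 0.5))), 7)

  # 1-input, 2-rule model checked against manual forward-pass arithmetic
  m1 <- anfis_init(matrix(seq(0, 1, length.out = 10), ncol = 1), rnorm(10),
                   n_mf = 2)
  m1$consequents <- matrix(c(1, 2,   # rule 1: f = x + 2
                             -1, 5), # rule 2: f = -x + 5
                           2, byrow = TRUE)
  xq <- 0.5
  mu1 <- mf_eval(m1$mfs[[1]][[1]], xq)
  mu2 <- mf_eval(m1$mfs[[1]][[2]], xq)
  manual <- (mu1 * (xq + 2) + mu2 * (-xq + 5)) / (mu1 + mu2)
  expect_equal(unname(anfis_predict(m1, xq)), manual, tolerance = 1e-12)
})

test_that("a linear target is solved exactly by the first LSE pass", {
  set.seed(2)
  x <- cbind(runif(30), runif(30), runif(30))
  y <- 2 * x[, 1] - 3 * x[, 2] + 0.5 * x[, 3] + 4
  m0 <- anfis_init(x, y, n_mf = 1)  # single rule = one linear regressor
  fit <- anfis_train(m0, x, y, epochs = 1)
  expect_lt(fit$report$train_rmse[1], 1e-8)
  expect_error(anfis_train(m0, x, y, epochs = 0), "epochs")
})

test_that("the premise gradient matches finite differences", {
  set.seed(4)
  x <- cbind(runif(15), runif(15))
  y <- sin(3 * x[, 1]) + x[, 2]
  m <- anfis_init(x, y, n_mf = 2)
  m$consequents <- matrix(rnorm(nrow(m$rules) * 3), nrow(m$rules))
  xs <- phenolflux:::anfis_scale(m, x)
  grads <- phenolflux:::premise_gradient(m, xs, y)
  sse <- function(model) sum((y - phenolflux:::predict_scaled(model, xs))^2)
  h <- 1e-6
  for (j in 1:2) {
    for (k in 1:2) {
      for (p in 1:4) {
        mp <- m; mp$mfs[[j]][[k]]$params[p] <- mp$mfs[[j]][[k]]$params[p] + h
        mm <- m; mm$mfs[[j]][[k]]$params[p] <- mm$mfs[[j]][[k]]$params[p] - h
        fd <- (sse(mp) - sse(mm)) / (2 * h)
        expect_equal(grads[[j]][[k]][p], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("the forward pass leaves consequents at a least-squares optimum", {
  out <- train48(3, epochs = 5)
  m <- out$fit$model
  xs <- phenolflux:::anfis_scale(m, as.matrix(out$split$train[anfis_features]))
  y <- out$split$train$yield_mg_per_g
  sse0 <- sum((y - phenolflux:::predict_scaled(m, xs))^2)
  set.seed(9)
  for (i in 1:20) {
    mp <- m
    r <- sample(nrow(m$consequents), 1); c <- sample(ncol(m$consequents), 1)
    mp$consequents[r, c] <- mp$consequents[r, c] + sample(c(-1e-3, 1e-3), 1)
    ssep <- sum((y - phenolflux:::predict_scaled(mp, xs))^2)
    expect_gte(ssep, sse0 - 1e-10)
  }
})

test_that("training is reproducible and can recover a same-architecture model", {
  a <- train48(7)
  b <- train48(7)
  expect_identical(a$fit$report, b$fit$report)
  expect_identical(a$fit$final_r2_test, b$fit$final_r2_test)

  # noiseless data generated by an ANFIS of the same architecture: the LSE
  # pass must recover its predictions (parameters are degenerate, outputs
  # are not)
  set.seed(12)
  x <- cbind(runif(40, 40, 50), runif(40, 2.5, 40), runif(40, 0, 1))
  gen <- anfis_init(x, rnorm(40))
  gen$consequents <- matrix(rnorm(32), 8)
  y <- anfis_predict(gen, x)
  fit <- anfis_train(anfis_init(x, y), x, y, epochs = 1)
  xnew <- sapply(1:3, function(j) runif(25, min(x[, j]), max(x[, j])))
  expect_lt(rmse(anfis_predict(fit$model, xnew), anfis_predict(gen, xnew)),
            1e-3)
})

test_that("stratified 6:4 split is disjoint, exhaustive and reproducible", {
  cfg <- generator_config(seed = 1)
  us <- simulate_kinetics(cfg)
  us <- us[us$method == "US", ]
  sp <- split_dataset(us, 0.6, seed = 4)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), seq_len(48))
  expect_true(nrow(sp$train) %in% c(28, 29))
  # every (temperature, enzyme) cell appears in both subsets
  cells <- function(d) unique(paste(d$temperature_C, d$enzyme_pct))
  expect_setequal(cells(sp$train), cells(us))
  expect_setequal(cells(sp$test), cells(us))
  sp2 <- split_dataset(us, 0.6, seed = 4)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_error(split_dataset(us, 1.0, seed = 1), "ratio")
  expect_error(split_dataset(us[1:5, ], 0.6, seed = 1), "at least 10")
})

test_that("evaluation reuses the shared metric implementations", {
  out <- train48(2, epochs = 3)
  m <- out$fit$model
  x <- as.matrix(out$split$test[anfis_features])
  y <- out$split$test$yield_mg_per_g
  ev <- anfis_evaluate(m, x, y)
  pred <- anfis_predict(m, x)
  expect_equal(ev$rmse, rmse(pred, y), tolerance = 1e-12)
  expect_equal(ev$r_squared, r_squared(pred, y), tolerance = 1e-12)
  # a constant model can legitimately return r^2 <= 0
  mc <- anfis_init(x, y, n_mf = 1)
  mc$consequents <- matrix(c(0, 0, 0, mean(y) + 2), 1)
  expect_lt(anfis_evaluate(mc, x, y)$r_squared, 0)
  # perfect self-prediction
  ev2 <- anfis_evaluate(m, x, pred)
  expect_equal(ev2$rmse, 0, tolerance = 1e-12)
  expect_equal(ev2$r_squared, 1, tolerance = 1e-12)
})

test_that("response surfaces agree with pointwise prediction", {
  out <- train48(6, epochs = 5)
  surf <- anfis_surface(out$fit, c("temperature_C", "enzyme_pct"),
                        fixed = c(time_min = 10), n = 12)
  i <- 4; j <- 9
  expect_equal(surf$z[i, j],
               unname(anfis_predict(out$fit$model,
                                    c(surf$x[i], 10, surf$y[j]))),
               tolerance = 1e-12)
  # constant model -> flat surface
  mc <- anfis_init(as.matrix(out$split$train[anfis_features]),
                   out$split$train$yield_mg_per_g, n_mf = 1)
  mc$consequents <- matrix(c(0, 0, 0, 3.3), 1)
  sc <- anfis_surface(mc, c("temperature_C", "time_min"),
                      fixed = c(enzyme_pct = 0.5), n = 10)
  expect_equal(max(sc$z) - min(sc$z), 0, tolerance = 1e-12)
  expect_error(anfis_surface(mc, c("time_min", "time_min"),
                             fixed = c(enzyme_pct = 0)), "distinct")
  expect_error(anfis_surface(mc, c("temperature_C", "time_min"),
                             fixed = c(enzyme_pct = 7)), "outside")
})

test_that("models survive a JSON round trip", {
  out <- train48(8, epochs = 3)
  path <- withr::local_tempfile(fileext = ".json")
  anfis_save(out$fit, path)
  back <- anfis_load(path)
  x <- as.matrix(out$split$test[anfis_features])
  expect_equal(anfis_predict(back, x), anfis_predict(out$fit$model, x),
               tolerance = 1e-12)
  expect_equal(attr(back, "training")$best_epoch, out$fit$best_epoch)
})
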