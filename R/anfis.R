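#' Evaluate a fuzzy membership function
#'
#' Two kinds are supported. `dsigmf` is the difference of two sigmoids,
#' `sig(a1 (x - c1)) - sig(a2 (x - c2))`, an interval-shaped set well suited
#' to "optimal within a range" behaviour; `gaussmf` is the Gaussian
#' `exp(-(x - c)^2 / (2 sigma^2))`.
#'
#' @param mf List with `kind` (`"dsigmf"` or `"gaussmf"`) and `params`
#'   (`c(a1, c1, a2, c2)` or `c(sigma, c)`).
#' @param x Numeric vector of (scaled) input values.
#' @return Membership degrees in \[0, 1\].
#' @export
mf_eval <- function(mf, x) {
  p <- mf$params
  switch(mf$kind,
    dsigmf = stats::plogis(p[1] * (x - p[2])) -
             stats::plogis(p[3] * (x - p[4])),
    gaussmf = exp(-(x - p[2])^2 / (2 * p[1]^2)),
    stop("unknown membership function kind: ", mf$kind, call. = FALSE)
  )
}

# partial derivatives of the membership value w.r.t. its parameters,
# needed by the backward (gradient) half of hybrid training
mf_grad <- function(mf, x) {
  p <- mf$params
  if (mf$kind == "dsigmf") {
    s1 <- stats::plogis(p[1] * (x - p[2])); d1 <- s1 * (1 - s1)
    s2 <- stats::plogis(p[3] * (x - p[4])); d2 <- s2 * (1 - s2)
    cbind(a1 = (x - p[2]) * d1, c1 = -p[1] * d1,
          a2 = -(x - p[4]) * d2, c2 = p[3] * d2)
  } else {
    v <- exp(-(x - p[2])^2 / (2 * p[1]^2))
    cbind(sigma = v * (x - p[2])^2 / p[1]^3,
          c = v * (x - p[2]) / p[1]^2)
  }
}

#' Initialise a Sugeno fuzzy model by grid partitioning
#'
#' Builds the standard five-layer Takagi-Sugeno structure: each input gets
#' `n_mf` membership functions with centres equally spaced over its observed
#' domain and widths chosen so adjacent sets cross near membership 0.5; the
#' rule base is the full factorial of memberships (so `n_mf^d` rules);
#' consequents are zero-initialised first-order polynomials
#' `p x1 + q x2 + r x3 + s` (or constants for `order = "zero"`). Inputs are
#' min-max scaled to \[0, 1\] internally; the stored domains descale at the
#' interface.
#'
#' @param x Data frame or matrix of input samples (columns = variables).
#' @param y Numeric target vector (same length as rows of `x`).
#' @param n_mf Membership functions per input (default 2).
#' @param mf_kind `"dsigmf"` (default) or `"gaussmf"`.
#' @param order `"first"` (default) or `"zero"` Sugeno consequents.
#' @return Object of class `anfis`.
#' @export
anfis_init <- function(x, y, n_mf = 2, mf_kind = c("dsigmf", "gaussmf"),
                       order = c("first", "zero")) {
  mf_kind <- match.arg(mf_kind)
  order <- match.arg(order)
  x <- as.matrix(x)
  if (!nrow(x) || nrow(x) != length(y)) {
    stop("`x` and `y` must be nonempty with matching rows", call. = FALSE)
  }
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  flat <- hi - lo <= 0
  if (any(flat)) {
    stop("constant input column(s): ",
         paste(colnames(x)[flat], collapse = ", "), call. = FALSE)
  }
  d <- ncol(x)
  centers <- if (n_mf == 1) 0.5 else seq(0, 1, length.out = n_mf)
  wd <- if (n_mf == 1) 1 else 1 / (2 * (n_mf - 1))  # half-spacing
  mfs <- lapply(seq_len(d), function(j) {
    lapply(centers, function(m) {
      if (mf_kind == "dsigmf") {
        # slope 3.5/wd: ~0.5 membership at the crossing with broad overlap,
        # which keeps the consequent system well conditioned
        list(kind = "dsigmf", params = c(3.5 / wd, m - wd, 3.5 / wd, m + wd))
      } else {
        list(kind = "gaussmf", params = c(2 * wd / 2.3548, m))
      }
    })
  })
  rules <- as.matrix(expand.grid(rep(list(seq_len(n_mf)), d)))
  dimnames(rules) <- NULL
  n_coef <- if (order == "first") d + 1L else 1L
  structure(
    list(var_names = colnames(x) %||% paste0("x", seq_len(d)),
         domain_lo = lo, domain_hi = hi,
         n_mf = n_mf, mf_kind = mf_kind, order = order,
         mfs = mfs, rules = rules,
         consequents = matrix(0, nrow(rules), n_coef)),
    class = "anfis"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

anfis_scale <- function(model, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, model$domain_lo, "-"), 2,
        model$domain_hi - model$domain_lo, "/")
}

# layer I + II: membership matrix (n x d x n_mf as list) and rule firings
anfis_firings <- function(model, xs) {
  n <- nrow(xs); d <- ncol(xs); R <- nrow(model$rules)
  mu <- lapply(seq_len(d), function(j) {
    matrix(sapply(seq_len(model$n_mf),
                  function(m) mf_eval(model$mfs[[j]][[m]], xs[, j])),
           nrow = n)
  })  # list of n x n_mf matrices
  w <- matrix(1, n, R)
  for (r in seq_len(R)) {
    for (j in seq_len(d)) {
      w[, r] <- w[, r] * mu[[j]][, model$rules[r, j], drop = TRUE]
    }
  }
  list(mu = mu, w = w)
}

#' Predict with a fuzzy model
#'
#' Runs the five-layer forward pass: fuzzification (layer I), product-rule
#' firing (II), normalization (III), weighted first-order consequents (IV)
#' and summation (V). Inputs outside the training domain are allowed (the
#' sigmoids extrapolate) but flagged with a warning.
#'
#' @param model An `anfis` object.
#' @param x Input matrix / data frame (columns in training-variable order)
#'   or a single numeric vector of length d.
#' @param trace If `TRUE`, attach the per-layer intermediates (memberships,
#'   firings, normalized weights, rule outputs) as attribute `"trace"`.
#' @return Numeric vector of predictions.
#' @export
anfis_predict <- function(model, x, trace = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$domain_lo)) {
    stop("wrong number of input columns", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("inputs must be finite", call. = FALSE)
  xs <- anfis_scale(model, x)
  if (any(xs < -1e-9) || any(xs > 1 + 1e-9)) {
    warning("input outside the training domain; extrapolating", call. = FALSE)
  }
  fir <- anfis_firings(model, xs)
  wsum <- rowSums(fir$w)
  if (any(wsum <= 0)) stop("input outside fuzzy support", call. = FALSE)
  wbar <- fir$w / wsum
  f <- rule_outputs(model, xs)
  y <- rowSums(wbar * f)
  if (trace) {
    attr(y, "trace") <- list(memberships = fir$mu, firing = fir$w,
                             normalized = wbar, rule_outputs = f)
  }
  y
}

# layer IV rule outputs f_r(x) for each sample (n x R)
rule_outputs <- function(model, xs) {
  R <- nrow(model$rules)
  if (model$order == "first") {
    cbind(xs, 1) %*% t(model$consequents)
  } else {
    matrix(rep(model$consequents[, 1], each = nrow(xs)), nrow(xs), R)
  }
}

# design matrix of the consequent least-squares problem:
# column block r holds wbar_r * [x, 1] (or wbar_r for zero order)
anfis_design <- function(model, xs) {
  fir <- anfis_firings(model, xs)
  wbar <- fir$w / rowSums(fir$w)
  R <- nrow(model$rules)
  basis <- if (model$order == "first") cbind(xs, 1) else matrix(1, nrow(xs), 1)
  do.call(cbind, lapply(seq_len(R), function(r) wbar[, r] * basis))
}

#' Split samples into stratified train and test subsets
#'
#' Draws `round(ratio * n)` training rows, allocated across
#' (temperature, enzyme) strata by largest remainder so every cell with at
#' least 2 samples contributes to both subsets; a singleton stratum goes to
#' the training set with a warning. Reproducible for a fixed seed.
#'
#' @param data Data frame of samples.
#' @param ratio Train fraction in (0, 1).
#' @param seed Integer seed.
#' @param strata_cols Columns defining the strata (default
#'   `c("temperature_C", "enzyme_pct")`; columns absent from `data` are
#'   ignored, and with no usable columns the split is simple random).
#' @return List with `train`, `test` (data frames) and `train_idx`,
#'   `test_idx` (integer row indices).
#' @export
split_dataset <- function(data, ratio = 0.6, seed = 1,
                          strata_cols = c("temperature_C", "enzyme_pct")) {
  n <- nrow(data)
  if (n < 10) stop("need at least 10 samples to split", call. = FALSE)
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop("`ratio` must be in (0, 1)", call. = FALSE)
  }
  n_train <- round(ratio * n)
  strata_cols <- intersect(strata_cols, names(data))
  key <- if (length(strata_cols)) {
    interaction(data[strata_cols], drop = TRUE, lex.order = TRUE)
  } else factor(rep(1, n))
  groups <- split(seq_len(n), key)

  with_seed(seed, {
    sizes <- vapply(groups, length, integer(1))
    singletons <- sizes == 1L
    if (any(singletons)) {
      warning("stratum with a single sample assigned to train: ",
              paste(names(groups)[singletons], collapse = ", "),
              call. = FALSE)
    }
    quota <- ratio * sizes
    take <- floor(quota)
    # keep both subsets nonempty per stratum where possible
    take <- pmin(pmax(take, ifelse(sizes >= 2, 1L, sizes)), sizes - ifelse(sizes >= 2, 1L, 0L))
    deficit <- n_train - sum(take)
    if (deficit != 0) {
      rem <- quota - floor(quota)
      ord <- order(if (deficit > 0) -rem else rem,
                   stats::runif(length(groups)))  # seeded tie-break
      i <- 1
      while (deficit != 0 && i <= 2 * length(groups)) {
        g <- ord[((i - 1) %% length(groups)) + 1]
        if (deficit > 0 && take[g] < sizes[g] - (sizes[g] >= 2)) {
          take[g] <- take[g] + 1L; deficit <- deficit - 1
        } else if (deficit < 0 && take[g] > min(1L, sizes[g])) {
          take[g] <- take[g] - 1L; deficit <- deficit + 1
        }
        i <- i + 1
      }
    }
    train_idx <- sort(unlist(lapply(seq_along(groups), function(g) {
      idx <- groups[[g]]
      if (length(idx) == 1L) idx else sample(idx, take[g])
    }), use.names = FALSE))
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = data[train_idx, , drop = FALSE],
       test = data[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Train a fuzzy model by hybrid learning
#'
#' Each epoch first solves the consequent coefficients exactly by linear
#' least squares on the normalized-firing design matrix (forward pass), then
#' updates the membership-function parameters by one batch gradient-descent
#' step on the squared error with the consequents held fixed (backward
#' pass). The premise update is steepest descent along the gradient
#' normalized to unit length, with an adaptive step: the step size (default
#' 0.05) is halved whenever the training RMSE increases and grown by 10%
#' after four consecutive decreases. The returned model is the
#' post-least-squares snapshot at the epoch with the lowest test RMSE
#' (training RMSE when no test set is given). A rank-deficient
#' least-squares system falls back to ridge regression (lambda = 1e-8) with
#' a one-time warning.
#'
#' @param model An initialised `anfis` model.
#' @param x,y Training inputs and targets.
#' @param x_test,y_test Optional held-out set monitored per epoch.
#' @param epochs Number of training cycles (>= 1, default 30).
#' @param lr Initial step size for the premise-parameter updates.
#' @return List of class `anfis_fit`: `model` (best snapshot), `report`
#'   (data.frame epoch / train_rmse / test_rmse), `best_epoch`,
#'   `final_r2_train`, `final_r2_test`, `algorithm`.
#' @export
anfis_train <- function(model, x, y, x_test = NULL, y_test = NULL,
                        epochs = 30, lr = 0.05) {
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  x <- as.matrix(x)
  if (!nrow(x)) stop("empty training set", call. = FALSE)
  xs <- anfis_scale(model, x)
  xst <- if (!is.null(x_test)) anfis_scale(model, as.matrix(x_test))
  ridge_warned <- FALSE
  report <- data.frame(epoch = integer(), train_rmse = numeric(),
                       test_rmse = numeric())
  best <- list(rmse = Inf, model = model, epoch = 0L)

  for (e in seq_len(epochs)) {
    ## forward pass: exact LSE for the consequents
    A <- anfis_design(model, xs)
    qrA <- qr(A)
    if (qrA$rank < ncol(A)) {
      if (!ridge_warned) {
        warning(sprintf(paste0("consequent least-squares system is rank ",
                               "deficient (rank %d of %d); using ridge ",
                               "fallback (lambda = 1e-8)"),
                        qrA$rank, ncol(A)), call. = FALSE)
        ridge_warned <- TRUE
      }
      theta <- solve(crossprod(A) + 1e-8 * diag(ncol(A)), crossprod(A, y))
    } else {
      theta <- qr.coef(qrA, y)
    }
    model$consequents <- matrix(theta, nrow(model$rules), byrow = TRUE)

    pred_tr <- predict_scaled(model, xs)
    tr_rmse <- rmse(pred_tr, y)
    te_rmse <- if (!is.null(xst)) rmse(predict_scaled(model, xst), y_test)
               else NA_real_
    report <- rbind(report, data.frame(epoch = e, train_rmse = tr_rmse,
                                       test_rmse = te_rmse))
    monitor <- if (!is.null(xst)) te_rmse else tr_rmse
    if (monitor < best$rmse) best <- list(rmse = monitor, model = model, epoch = e)

    if (e > 1 && tr_rmse > report$train_rmse[e - 1]) {
      lr <- lr / 2
    } else if (e > 4 && all(diff(report$train_rmse[(e - 4):e]) < 0)) {
      lr <- lr * 1.1
    }
    if (e == epochs) break

    ## backward pass: normalized-gradient step on the premise parameters
    model <- premise_gradient_step(model, xs, y, lr)
  }

  final <- best$model
  r2_tr <- tryCatch(r_squared(predict_scaled(final, xs), y),
                    error = function(e) NA_real_)
  r2_te <- if (!is.null(xst)) {
    tryCatch(r_squared(predict_scaled(final, xst), y_test),
             error = function(e) NA_real_)
  } else NA_real_
  structure(
    list(model = final, report = report, best_epoch = best$epoch,
         final_r2_train = r2_tr, final_r2_test = r2_te,
         algorithm = "hybrid", lr_final = lr),
    class = "anfis_fit"
  )
}

# forward pass on already-scaled inputs
predict_scaled <- function(model, xs) {
  fir <- anfis_firings(model, xs)
  wbar <- fir$w / rowSums(fir$w)
  rowSums(wbar * rule_outputs(model, xs))
}

# one steepest-descent update of every MF parameter, consequents fixed;
# dE/dp = -2 sum_i e_i sum_r (f_ir - yhat_i)/W_i * dw_ir/dp, with the full
# premise gradient normalized to unit length before applying the step `lr`
premise_gradient_step <- function(model, xs, y, lr) {
  grads <- premise_gradient(model, xs, y)
  gnorm <- sqrt(sum(unlist(grads)^2))
  if (gnorm == 0) return(model)
  for (j in seq_along(model$mfs)) {
    for (m in seq_len(model$n_mf)) {
      g <- grads[[j]][[m]]
      model$mfs[[j]][[m]]$params <-
        model$mfs[[j]][[m]]$params - lr * g / gnorm
    }
  }
  model
}

# raw gradient of the training SSE w.r.t. every MF parameter, as a nested
# list [[input]][[mf]] -> numeric(4 or 2); kept separate so tests can check
# it against finite differences
premise_gradient <- function(model, xs, y) {
  n <- nrow(xs); d <- ncol(xs)
  fir <- anfis_firings(model, xs)
  W <- rowSums(fir$w)
  wbar <- fir$w / W
  f <- rule_outputs(model, xs)
  yhat <- rowSums(wbar * f)
  err <- y - yhat
  lapply(seq_len(d), function(j) {
    lapply(seq_len(model$n_mf), function(m) {
      uses <- which(model$rules[, j] == m)
      if (!length(uses)) return(numeric(length(model$mfs[[j]][[m]]$params)))
      grad_mu <- numeric(n)  # sum over rules of dyhat/dw_r * dw_r/dmu_jm
      for (r in uses) {
        # firing without input j's factor (stable when mu ~ 0)
        w_excl <- rep(1, n)
        for (k in seq_len(d)) {
          if (k != j) w_excl <- w_excl * fir$mu[[k]][, model$rules[r, k]]
        }
        grad_mu <- grad_mu + (f[, r] - yhat) / W * w_excl
      }
      gmu <- mf_grad(model$mfs[[j]][[m]], xs[, j])
      as.numeric(crossprod(gmu, -2 * err * grad_mu))
    })
  })
}

#' Evaluate predictions of a fuzzy model on a dataset
#'
#' @param model An `anfis` object (or an `anfis_fit`, whose model is used).
#' @param x Inputs.
#' @param y Observed targets.
#' @return List with `rmse` and `r_squared` (the latter as computed by
#'   Eq.-style R^2, which has no lower floor).
#' @export
anfis_evaluate <- function(model, x, y) {
  if (inherits(model, "anfis_fit")) model <- model$model
  pred <- anfis_predict(model, x)
  list(rmse = rmse(pred, y), r_squared = r_squared(pred, y))
}

#' Response surface of a trained model over two inputs
#'
#' Evaluates the model on a regular grid over two input variables with the
#' remaining variable held fixed, for contour / 3-D surface rendering.
#'
#' @param model An `anfis` or `anfis_fit`.
#' @param vars Character vector of two distinct input names.
#' @param fixed Named scalar: value of the remaining input (must lie in its
#'   training domain).
#' @param n Grid resolution per axis (>= 10).
#' @return List with `x`, `y` (axis vectors), `z` (matrix, rows follow `x`),
#'   `vars`, `fixed`; also a long-format data frame under `df`.
#' @export
anfis_surface <- function(model, vars, fixed, n = 50) {
  if (inherits(model, "anfis_fit")) model <- model$model
  if (length(vars) != 2 || vars[1] == vars[2]) {
    stop("`vars` must name two distinct inputs", call. = FALSE)
  }
  if (n < 10) stop("grid resolution must be >= 10", call. = FALSE)
  all_vars <- model$var_names
  if (!all(vars %in% all_vars)) stop("unknown input variable", call. = FALSE)
  other <- setdiff(all_vars, vars)
  if (length(other) && (!length(names(fixed)) || !all(other %in% names(fixed)))) {
    stop("`fixed` must name the remaining input(s): ",
         paste(other, collapse = ", "), call. = FALSE)
  }
  i1 <- match(vars[1], all_vars); i2 <- match(vars[2], all_vars)
  ax1 <- seq(model$domain_lo[i1], model$domain_hi[i1], length.out = n)
  ax2 <- seq(model$domain_lo[i2], model$domain_hi[i2], length.out = n)
  grid <- expand.grid(ax1, ax2)
  X <- matrix(0, nrow(grid), length(all_vars))
  X[, i1] <- grid[[1]]; X[, i2] <- grid[[2]]
  for (v in other) {
    io <- match(v, all_vars)
    val <- fixed[[v]]
    if (val < model$domain_lo[io] || val > model$domain_hi[io]) {
      stop("fixed value for ", v, " is outside the training domain",
           call. = FALSE)
    }
    X[, io] <- val
  }
  z <- matrix(anfis_predict(model, X), n, n)
  list(x = ax1, y = ax2, z = z, vars = vars, fixed = fixed,
       df = data.frame(grid[[1]], grid[[2]], as.vector(z)) |>
         stats::setNames(c(vars, "yield_mg_per_g")))
}

#' Serialize a fuzzy model to JSON
#'
#' Writes a versioned JSON document holding the domains, membership-function
#' parameters, rule base, consequents and metadata, loadable with
#' [anfis_load()].
#'
#' @param model An `anfis` or `anfis_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
anfis_save <- function(model, path) {
  fit <- NULL
  if (inherits(model, "anfis_fit")) { fit <- model; model <- model$model }
  doc <- list(
    schema = "phenolflux-anfis/1",
    var_names = model$var_names,
    domain_lo = model$domain_lo, domain_hi = model$domain_hi,
    n_mf = model$n_mf, mf_kind = model$mf_kind, order = model$order,
    mfs = lapply(model$mfs, function(per_var) {
      lapply(per_var, function(mf) list(kind = mf$kind, params = mf$params))
    }),
    rules = model$rules,
    consequents = model$consequents,
    training = if (!is.null(fit)) {
      list(best_epoch = fit$best_epoch, algorithm = fit$algorithm,
           final_r2_train = fit$final_r2_train,
           final_r2_test = fit$final_r2_test,
           report = fit$report)
    }
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a fuzzy model saved by [anfis_save()]
#' @param path JSON path.
#' @return An `anfis` object (training metadata, if present, as attribute
#'   `"training"`).
#' @export
anfis_load <- function(path) {
  doc <- jsonlite::read_json(path)  # no simplification: rebuild explicitly
  if (!identical(doc$schema, "phenolflux-anfis/1")) {
    stop("unrecognised model schema", call. = FALSE)
  }
  var_names <- unlist(doc$var_names)
  model <- structure(
    list(var_names = var_names,
         domain_lo = stats::setNames(unlist(doc$domain_lo), var_names),
         domain_hi = stats::setNames(unlist(doc$domain_hi), var_names),
         n_mf = doc$n_mf, mf_kind = doc$mf_kind, order = doc$order,
         mfs = lapply(doc$mfs, function(per_var) {
           lapply(per_var, function(mf) {
             list(kind = mf$kind, params = as.numeric(unlist(mf$params)))
           })
         }),
         rules = do.call(rbind, lapply(doc$rules, function(r)
           as.integer(unlist(r)))),
         consequents = do.call(rbind, lapply(doc$consequents, function(r)
           as.numeric(unlist(r))))),
    class = "anfis"
  )
  attr(model, "training") <- doc$training
  model
}

#' @export
print.anfis <- function(x, ...) {
  cat(sprintf("anfis: %d inputs (%s), %d x %s MFs, %d rules, %s order\n",
              length(x$var_names), paste(x$var_names, collapse = ", "),
              x$n_mf, x$mf_kind, nrow(x$rules), x$order))
  invisible(x)
}

#' @export
print.anfis_fit <- function(x, ...) {
  cat(sprintf("anfis_fit: %d epochs, best epoch %d\n",
              nrow(x$report), x$best_epoch))
  cat(sprintf("  train RMSE %.4g (R^2 %.4f)", min(x$report$train_rmse),
              x$final_r2_train))
  if (!is.na(x$final_r2_test)) {
    cat(sprintf("; test RMSE %.4g (R^2 %.4f)",
                x$report$test_rmse[x$best_epoch], x$final_r2_test))
  }
  cat("\n")
  invisible(x)
}
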