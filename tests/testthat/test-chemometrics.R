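make_labels <- function(n1, n2) {
  factor(rep(c("control", "burn"), c(n1, n2)), levels = c("control", "burn"))
}

test_that("scaling methods produce the defined columns", {
  set.seed(1)
  X <- matrix(rnorm(40, sd = 4), 10, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  # center on zero-mean input is the identity
  X0 <- sweep(X, 2, colMeans(X))
  sc <- scale_matrix(X0, "center")
  expect_equal(sc$x, X0, ignore_attr = TRUE)
  # uv gives unit SDs
  uv <- scale_matrix(X, "uv")
  expect_equal(unname(apply(uv$x, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # pareto divisor is sqrt(SD)
  Xp <- X; Xp[, 2] <- Xp[, 2] / sd(Xp[, 2]) * 4   # SD exactly 4
  pa <- scale_matrix(Xp, "pareto")
  expect_equal(unname(pa$params$divisors[2]), 2)
  # constant feature under uv errors with the feature name
  Xc <- X; Xc[, 3] <- 7
  expect_error(scale_matrix(Xc, "uv"), "f3")
  # apply_scaling reproduces the training transform
  expect_equal(apply_scaling(X, uv$params), uv$x)
})

test_that("PCA reproduces variance structure and reconstructs the data", {
  # rank-1 data: first component explains everything
  set.seed(2)
  t1 <- rnorm(20); v <- c(1, -2, 0.5)
  X1 <- outer(t1, v) + 10
  colnames(X1) <- paste0("f", 1:3)
  m1 <- fit_pca(X1, k = 1, scaling = "center")
  expect_equal(m1$explained[1], 1, tolerance = 1e-10)

  # symmetric 2-feature toy: first loading is +/- (1,1)/sqrt(2)
  z <- rnorm(200)
  X2 <- cbind(f1 = z + rnorm(200, sd = 1e-6), f2 = z + rnorm(200, sd = 1e-6))
  m2 <- fit_pca(X2, k = 1, scaling = "center")
  expect_equal(abs(unname(m2$loadings[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 1e-3)

  # full-rank reconstruction at k = rank
  X <- matrix(rnorm(300), 30, 10, dimnames = list(NULL, paste0("f", 1:10)))
  m <- fit_pca(X, k = 10, scaling = "uv")
  Xs <- scale_matrix(X, "uv")$x
  expect_equal(m$scores %*% t(m$loadings), Xs, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(m$loadings), diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(m$explained) <= 1e-12))
  expect_lte(sum(m$explained), 1 + 1e-12)
  expect_error(fit_pca(X, k = 30), "k must be")
})

test_that("OPLS-DA recovers a planted discriminant axis", {
  set.seed(3)
  n <- 200
  y <- make_labels(100, 100)
  yc <- as.numeric(y) - 1
  X <- cbind(d = yc,
             matrix(rnorm(n * 9), n, 9,
                    dimnames = list(NULL, paste0("noise", 1:9))))
  fit <- opls_da(X, y, n_orth = 1)
  expect_gt(abs(fit$w["d"]), 0.95)
  co <- backscale_loadings(fit)
  expect_gt(co$correlation[co$feature == "d"], 0.95)
})

test_that("OPLS-DA structural invariants hold on random data", {
  set.seed(4)
  for (rep in 1:25) {
    n <- sample(12:40, 1)
    p <- sample(5:30, 1)
    n_orth <- sample(0:2, 1)
    y <- make_labels(ceiling(n / 2), floor(n / 2))
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    X[, 1] <- X[, 1] + (as.numeric(y) - 1)   # some class signal
    fit <- opls_da(X, y, n_orth = n_orth)
    expect_equal(sum(fit$w^2), 1, tolerance = 1e-10)
    yc <- (as.numeric(y) - 1) - fit$y_mean
    for (k in seq_len(fit$n_orth)) {
      expect_lt(abs(sum(fit$t_orth[, k] * yc)),
                1e-8 * sqrt(sum(fit$t_orth[, k]^2) * sum(yc^2)))
      expect_lt(abs(sum(fit$t_orth[, k] * fit$t_pred)),
                1e-8 * sqrt(sum(fit$t_orth[, k]^2) * sum(fit$t_pred^2)))
    }
    expect_gte(fit$r2x, 0); expect_lte(fit$r2x, 1)
    expect_gte(fit$r2y, 0); expect_lte(fit$r2y, 1)
  }
})

test_that("with n_orth = 0 the predictive component matches NIPALS PLS1", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 24; p <- 8
    y <- make_labels(12, 12)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    fit <- opls_da(X, y, n_orth = 0, scaling = "uv")
    sc <- scale_matrix(X, "uv")
    yc <- (as.numeric(y) - 1) - mean(as.numeric(y) - 1)
    ref <- nipals_pls1(sc$x, yc)
    sgn <- sign(sum(ref$w * fit$w))
    expect_equal(unname(fit$w), sgn * ref$w, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(unname(fit$t_pred), sgn * ref$t, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("swapping class codes negates t_pred and preserves fit statistics", {
  set.seed(6)
  y <- make_labels(10, 12)
  X <- matrix(rnorm(22 * 6), 22, 6, dimnames = list(NULL, paste0("f", 1:6)))
  a <- opls_da(X, y, n_orth = 1)
  y_sw <- factor(as.character(y), levels = rev(levels(y)))
  b <- opls_da(X, y_sw, n_orth = 1)
  expect_equal(unname(b$t_pred), -unname(a$t_pred), tolerance = 1e-10)
  expect_equal(b$r2x, a$r2x, tolerance = 1e-10)
  expect_equal(b$r2y, a$r2y, tolerance = 1e-10)
  expect_equal(abs(unname(b$p)), abs(unname(a$p)), tolerance = 1e-10)
})

test_that("model interface methods are coherent", {
  set.seed(7)
  cfg <- default_cfg()
  ds <- simulate_cohort(cfg, seed = 8)
  X <- combined_panel(ds)
  y <- ds$samples$group
  fit <- opls_da(X, y, n_orth = 1)
  # predictions on training data separate the classes reasonably
  cls <- predict(fit, X, type = "class")
  expect_gt(mean(cls == y), 0.85)
  expect_equal(fitted(fit) + residuals(fit),
               unname((as.numeric(y) - 1) - fit$y_mean), tolerance = 1e-10,
               ignore_attr = TRUE)
  sc <- predict(fit, X, type = "scores")
  expect_equal(sc$t_pred, unname(fit$t_pred), tolerance = 1e-10,
               ignore_attr = TRUE)
  co <- coef(fit)
  expect_identical(co$feature, colnames(X))
  # back-scaled loading = loading x divisor; centering-shift invariant
  expect_equal(co$backscaled_loading,
               as.numeric(fit$p) * as.numeric(fit$scaling$divisors),
               ignore_attr = TRUE)
  X2 <- X; X2[, 3] <- X2[, 3] + 100
  fit2 <- opls_da(X2, y, n_orth = 1)
  expect_equal(backscale_loadings(fit2)$backscaled,
               backscale_loadings(fit)$backscaled, tolerance = 1e-8)
  # formula interface agrees with the matrix interface
  df <- data.frame(group = y, X, check.names = FALSE)
  ff <- opls_da(group ~ ., data = df, n_orth = 1)
  expect_equal(unname(ff$t_pred), unname(fit$t_pred), tolerance = 1e-10)
  # plot method draws without error
  pdf(NULL); on.exit(dev.off())
  expect_no_error(plot(fit))
  # error contracts
  expect_error(opls_da(X[18:22, ], y[18:22]), "at least 6")
  expect_error(opls_da(X, y, n_orth = nrow(X)), "n_orth")
  expect_error(opls_da(X, factor(rep("burn", nrow(X)),
                                 levels = c("control", "burn"))),
               "two-level|both classes")
})

test_that("resubstitution R2Y bounds cross-validated Q2Y", {
  set.seed(8)
  cfg <- default_cfg()
  ok <- vapply(1:20, function(s) {
    ds <- simulate_cohort(cfg, n_burn = 20, n_control = 20, seed = s)
    X <- combined_panel(ds); y <- ds$samples$group
    fit <- opls_da(X, y, n_orth = 1)
    cv <- cross_validate(X, y, folds = 5, n_orth = 1, seed = s)
    fit$r2y >= cv$q2y
  }, logical(1))
  expect_true(all(ok))
})

test_that("cross-validation is stratified, deterministic and calibrated", {
  set.seed(9)
  y <- make_labels(20, 24)
  X <- matrix(rnorm(44 * 8), 44, 8, dimnames = list(NULL, paste0("f", 1:8)))
  cv <- cross_validate(X, y, folds = 7, n_orth = 1, seed = 3)
  # folds partition samples with both classes in every fold
  expect_equal(sort(unique(cv$assignment)), 1:7)
  for (f in 1:7)
    expect_equal(length(unique(y[cv$assignment == f])), 2L)
  expect_lte(cv$q2y, 1)
  # determinism, incl. leave-one-out
  expect_identical(cross_validate(X, y, folds = 7, seed = 3)$q2y, cv$q2y)
  loo1 <- cross_validate(X, y, folds = 44, n_orth = 1, seed = 1)
  loo2 <- cross_validate(X, y, folds = 44, n_orth = 1, seed = 99)
  expect_identical(loo1$q2y, loo2$q2y)   # LOO has no shuffle freedom
  expect_error(cross_validate(X, y, folds = 30), "class smaller")
  expect_error(cross_validate(X, y, folds = 1), "at least 2")

  # perfectly separable data (5-SD planted shift) predicts well
  sep <- tiny_cfg(burn_shift = c(5, 0, 0))
  ds <- simulate_cohort(sep, n_burn = 100, n_control = 100, seed = 10)
  cv2 <- cross_validate(combined_panel(ds), ds$samples$group, seed = 11)
  expect_gt(cv2$q2y, 0.8)
})

test_that("permutation test hits its boundaries and reproduces with a seed", {
  set.seed(10)
  cfg <- default_cfg()
  ds <- simulate_cohort(cfg, n_burn = 25, n_control = 25, seed = 12)
  X <- combined_panel(ds); y <- ds$samples$group
  pt <- permutation_test(X, y, n_perm = 39, folds = 5, seed = 13)
  # strong real effect: observed exceeds every permuted Q2Y
  expect_equal(pt$p, 1 / 40)
  expect_length(pt$null, 39L)
  pt2 <- permutation_test(X, y, n_perm = 39, folds = 5, seed = 13)
  expect_identical(pt$null, pt2$null)
  expect_error(permutation_test(X, y, n_perm = 5), "at least 20")
})
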