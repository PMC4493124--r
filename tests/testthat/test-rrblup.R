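test_that("one-way ANOVA variance components match textbook arithmetic", {
  # 3 lines x 2 reps: (10,12 | 20,22 | 30,32)
  plots <- tibble::tibble(line = rep(c("a", "b", "c"), each = 2),
                          replicate = rep(c("r1", "r2"), 3),
                          value = c(10, 12, 20, 22, 30, 32))
  vc <- estimate_variance_anova(plots)
  expect_equal(vc$ms_within, 2)
  expect_equal(vc$ms_between, 2 * var(c(11, 21, 31)))   # 200
  expect_equal(vc$Vg, (200 - 2) / 2)                    # 99
  expect_equal(vc$Ve, 2)
  expect_equal(vc$h2, 99 / (99 + 2 / 2))
  expect_true(vc$balanced)

  # zero within-line variance -> Ve = 0, h2 = 1
  vc0 <- estimate_variance_anova(
    tibble::tibble(line = rep(c("a", "b"), each = 2), value = c(1, 1, 5, 5)))
  expect_equal(vc0$Ve, 0)
  expect_equal(vc0$h2, 1)

  expect_error(estimate_variance_anova(
    tibble::tibble(line = c("a", "b"), value = c(1, 2))), "unidentifiable")
  # negative between-within contrast truncates Vg at zero
  set.seed(2)
  noise <- tibble::tibble(line = rep(letters[1:4], each = 10),
                          value = rnorm(40))
  expect_gte(estimate_variance_anova(noise)$Vg, 0)
})

test_that("variance_components reproduces the line-mean heritability identity", {
  vc <- variance_components(Vg = 1022.71, Ve = 1022.71, n_reps = 4)
  expect_equal(vc$h2, 0.80)
})

test_that("RR-BLUP matches an independent penalized least-squares oracle", {
  # 4 lines x 2 markers, lambda = 2: oracle solves the augmented LS system
  X <- rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2))
  rownames(X) <- paste0("L", 1:4)
  colnames(X) <- c("m1", "m2")
  y <- c(1.0, 2.5, 1.8, 3.9)
  lambda <- 2
  X_aug <- rbind(cbind(1, X), cbind(0, sqrt(lambda) * diag(2)))
  y_aug <- c(y, 0, 0)
  oracle <- qr.solve(X_aug, y_aug)

  for (m in c("primal", "dual")) {
    fit <- fit_rrblup(X, setNames(y, rownames(X)), lambda = lambda, method = m)
    expect_equal(fit$mu, oracle[1], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(fit$effects$effect, unname(oracle[2:3]), tolerance = 1e-10)
  }
})

test_that("primal and dual solves agree on random instances", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    m <- sample(3:120, 1)
    X <- matrix(sample(c(0, 2), n * m, replace = TRUE), n, m)
    rownames(X) <- paste0("L", 1:n)
    colnames(X) <- paste0("m", 1:m)
    y <- setNames(rnorm(n), rownames(X))
    lambda <- runif(1, 0.1, 50)
    fp <- fit_rrblup(X, y, lambda = lambda, method = "primal")
    fd <- fit_rrblup(X, y, lambda = lambda, method = "dual")
    scale <- max(abs(fp$effects$effect), 1e-10)
    expect_lt(max(abs(fp$effects$effect - fd$effects$effect)) / scale, 1e-8)
    expect_lt(abs(fp$mu - fd$mu) / max(abs(fp$mu), 1e-10), 1e-8)
  }
})

test_that("shrinkage behaves in its limits and is monotone", {
  set.seed(6)
  X <- matrix(sample(c(0, 2), 30 * 50, replace = TRUE), 30, 50)
  rownames(X) <- paste0("L", 1:30)
  colnames(X) <- paste0("m", 1:50)
  y <- setNames(rnorm(30, 10, 2), rownames(X))

  big <- fit_rrblup(X, y, lambda = 1e12)
  expect_lt(max(abs(big$effects$effect)), 1e-6 * sd(y))
  expect_equal(big$mu, mean(y), tolerance = 1e-4)

  const <- fit_rrblup(X, setNames(rep(7, 30), rownames(X)), lambda = 3)
  expect_equal(const$effects$effect, rep(0, 50), tolerance = 1e-10)
  expect_equal(const$mu, 7, tolerance = 1e-10)

  norms <- vapply(c(0.1, 1, 10, 100, 1000), function(l) {
    sqrt(sum(fit_rrblup(X, y, lambda = l)$effects$effect^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))

  expect_error(fit_rrblup(X, y, lambda = 0), "lambda")
  expect_error(fit_rrblup(X, y), "variance components")
})

test_that("lambda is assembled from variance components as Ve_eff / (Vg/N_M)", {
  X <- matrix(sample(c(0, 2), 20 * 10, replace = TRUE), 20, 10)
  rownames(X) <- paste0("L", 1:20)
  colnames(X) <- paste0("m", 1:10)
  y <- setNames(rnorm(20), rownames(X))
  vc <- variance_components(Vg = 50, Ve = 100, n_reps = 4)
  fit <- fit_rrblup(X, y, vc)
  expect_equal(fit$lambda, (100 / 4) / (50 / 10))
})

test_that("GEBV prediction is mu + Xg and validates the marker set", {
  fit <- structure(list(
    mu = 1, effects = tibble::tibble(marker = c("m1", "m2"),
                                     effect = c(0.5, -0.25)),
    lambda = 1, method = "primal", training_ids = NULL,
    markers = c("m1", "m2")), class = "gs_rrblup")
  Xn <- matrix(c(2, 2), 1, 2, dimnames = list("Lx", c("m1", "m2")))
  expect_equal(predict(fit, Xn)$gebv, 1 + 1 - 0.5)
  # all-zero genotype line predicts mu
  X0 <- matrix(0, 1, 2, dimnames = list("L0", c("m1", "m2")))
  expect_equal(predict(fit, X0)$gebv, 1)
  Xbad <- matrix(0, 1, 2, dimnames = list("L0", c("m1", "m9")))
  expect_error(predict(fit, Xbad), "marker set mismatch")

  # with near-zero shrinkage and full rank, fitted values are reproduced
  set.seed(9)
  X <- cbind(m1 = sample(c(0, 2), 12, replace = TRUE),
             m2 = sample(c(0, 2), 12, replace = TRUE))
  rownames(X) <- paste0("L", 1:12)
  y <- setNames(1 + 0.3 * X[, 1] - 0.2 * X[, 2] + rnorm(12, 0, 0.01),
                rownames(X))
  f <- fit_rrblup(X, y, lambda = 1e-8)
  ols <- lm(y ~ X[, 1] + X[, 2])
  expect_equal(predict(f, X)$gebv, unname(fitted(ols)), tolerance = 1e-5)
})

test_that("marker-effect predictions equal the genomic-relationship route", {
  # Goddard equivalence: RR-BLUP == BLUP on the marker-derived covariance
  set.seed(13)
  n <- 25; m <- 200
  X <- matrix(sample(c(0, 2), n * m, replace = TRUE), n, m)
  rownames(X) <- paste0("L", 1:n)
  colnames(X) <- paste0("m", 1:m)
  y <- setNames(rnorm(n), rownames(X))
  lambda <- 7
  tr <- 1:15; val <- 16:25
  fit <- fit_rrblup(X[tr, ], y[tr], lambda = lambda, method = "primal")
  pred <- predict(fit, X[val, ])$gebv

  Ctt <- tcrossprod(X[tr, ])
  V <- Ctt + lambda * diag(length(tr))
  Vi <- solve(V)
  ones <- rep(1, length(tr))
  mu <- as.numeric((ones %*% Vi %*% y[tr]) / (ones %*% Vi %*% ones))
  g_pred <- as.numeric(mu + X[val, ] %*% t(X[tr, ]) %*% Vi %*% (y[tr] - mu))
  expect_equal(pred, g_pred, tolerance = 1e-8)
})

test_that("accuracy rescales r_MP by the square root of heritability", {
  expect_equal(accuracy(c(1, 2, 3, 4), c(1, 2, 3, 4), h2 = 0.64)$r_MG,
               1 / 0.8)
  a <- accuracy(c(1, 2, 3.5), c(2, 1, 3), h2 = 1)
  expect_equal(a$r_MG, a$r_MP)
  expect_warning(out <- accuracy(c(1, 1, 1), c(1, 2, 3), h2 = 0.5),
                 "zero variance")
  expect_true(is.na(out$r_MG))
  expect_error(accuracy(c(1, 2), c(1, 2), 0.5), "3 paired")
})
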