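test_that("two groups give exactly one nonzero eigenvalue at 100%", {
  dat <- random_group_data(1, k = 2, p = 4)
  fit <- fit_cda(as_cda_table(dat$X, dat$g),
                 traits = paste0("tr", 1:4))
  expect_equal(length(fit$eigenvalues), 1)
  expect_gt(fit$eigenvalues[1], 0)
  expect_equal(fit$pct_variance[1], 100)
})

test_that("equal group means give all-zero eigenvalues", {
  base <- with_seed(2, matrix(rnorm(10 * 3), 10, 3))
  X <- rbind(base, base, base) # three groups with identical rows
  g <- factor(rep(c("a", "b", "c"), each = 10))
  fit <- fit_cda(as_cda_table(X, g), traits = paste0("tr", 1:3))
  expect_true(all(fit$eigenvalues < 1e-10))
})

test_that("eigenstructure matches the brute-force scatter oracle to 1e-8", {
  for (seed in c(3, 4)) {
    dat <- random_group_data(seed)
    tab <- as_cda_table(dat$X, dat$g)
    traits <- paste0("tr", 1:5)
    fit <- fit_cda(tab, traits = traits)
    oracle <- cda_oracle(dat$X, dat$g)
    expect_equal(fit$eigenvalues, oracle$eigenvalues, tolerance = 1e-8)
    expect_equal(fit$pct_variance,
                 100 * oracle$eigenvalues / sum(oracle$eigenvalues),
                 tolerance = 1e-8)
    # coefficients agree up to sign
    for (v in seq_along(fit$eigenvalues)) {
      a <- fit$coefficients[, v]; b <- oracle$vectors[, v]
      expect_equal(abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))), 1,
                   tolerance = 1e-8)
      expect_equal(abs(a), abs(b), tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("canonical scores have unit pooled within-group variance and no within-group correlation", {
  dat <- random_group_data(5)
  fit <- fit_cda(as_cda_table(dat$X, dat$g), traits = paste0("tr", 1:5))
  centered <- fit$scores -
    apply(fit$scores, 2, function(s) tapply(s, fit$groups, mean))[fit$groups, ]
  pooled <- crossprod(centered) / fit$pooled_df
  expect_equal(pooled, diag(ncol(pooled)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("eigenvalues are descending and loadings bounded by 1", {
  dat <- random_group_data(6)
  fit <- fit_cda(as_cda_table(dat$X, dat$g), traits = paste0("tr", 1:5))
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_true(all(abs(fit$loadings) <= 1 + 1e-12))
  # deterministic sign: top-loading trait positive per canonical variable
  for (v in seq_along(fit$eigenvalues)) {
    expect_gt(fit$loadings[which.max(abs(fit$loadings[, v])), v], 0)
  }
})

test_that("the analysis is invariant to affine rescaling of traits", {
  dat <- random_group_data(7)
  tab <- as_cda_table(dat$X, dat$g)
  traits <- paste0("tr", 1:5)
  fit <- fit_cda(tab, traits = traits)
  tab2 <- tab
  scales <- c(3, 0.2, 10, 1, 5); shifts <- c(1, -4, 0, 2, 100)
  for (i in seq_along(traits)) {
    tab2[[traits[i]]] <- tab2[[traits[i]]] * scales[i] + shifts[i]
  }
  fit2 <- fit_cda(tab2, traits = traits)
  expect_equal(fit2$eigenvalues, fit$eigenvalues, tolerance = 1e-8)
  for (v in seq_along(fit$eigenvalues)) {
    expect_equal(abs(fit2$scores[, v]  - mean(fit2$scores[, v])),
                 abs(fit$scores[, v] - mean(fit$scores[, v])),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  dat <- random_group_data(8, n_per = 6, p = 3, k = 3)
  tab <- as_cda_table(dat$X, dat$g)
  # collinear trait makes the within covariance singular
  tab$tr4 <- tab$tr1 + tab$tr2
  expect_error(fit_cda(tab, traits = paste0("tr", 1:4)), "condition number")
  # a singleton group
  tab2 <- as_cda_table(dat$X[-(1:5), ], dat$g[-(1:5)])
  expect_error(fit_cda(tab2, traits = paste0("tr", 1:3)), "n < 2")
  expect_error(fit_cda(tab, traits = "missing_trait"), "missing_trait")
})

test_that("listwise deletion drops incomplete pots with a message", {
  dat <- random_group_data(9)
  tab <- as_cda_table(dat$X, dat$g)
  tab$tr1[c(2, 5)] <- NA
  expect_message(fit <- fit_cda(tab, traits = paste0("tr", 1:5)),
                 "dropped 2")
  expect_equal(fit$n_dropped, 2)
  expect_equal(sum(fit$n_per_group), nrow(tab) - 2)
})

test_that("Mahalanobis D2 matrix is symmetric, zero-diagonal and affine-invariant", {
  dat <- random_group_data(10)
  tab <- as_cda_table(dat$X, dat$g)
  traits <- paste0("tr", 1:5)
  mh <- mahalanobis_tests(tab, traits = traits)
  expect_equal(mh$d2, t(mh$d2))
  expect_equal(diag(mh$d2), rep(0, nrow(mh$d2)), ignore_attr = TRUE)
  expect_true(all(mh$d2 >= 0))
  # invariance under an invertible linear map of the traits
  A <- with_seed(11, matrix(rnorm(25), 5, 5))
  X2 <- dat$X %*% A
  mh2 <- mahalanobis_tests(as_cda_table(X2, dat$g), traits = traits)
  expect_equal(mh2$d2, mh$d2, tolerance = 1e-8)
  expect_equal(mh2$p_values, mh$p_values, tolerance = 1e-8)
})

test_that("identical group means give D2 = 0 and p = 1", {
  base <- with_seed(12, matrix(rnorm(8 * 3), 8, 3))
  X <- rbind(base, base)
  g <- factor(rep(c("a", "b"), each = 8))
  mh <- mahalanobis_tests(as_cda_table(X, g), traits = paste0("tr", 1:3))
  expect_equal(mh$d2["a", "b"], 0, tolerance = 1e-12)
  expect_equal(mh$p_values["a", "b"], 1)
})

test_that("two-group case satisfies the Hotelling T2 identity", {
  dat <- random_group_data(13, n_per = 15, p = 4, k = 2)
  tab <- as_cda_table(dat$X, dat$g)
  traits <- paste0("tr", 1:4)
  mh <- mahalanobis_tests(tab, traits = traits)
  x1 <- dat$X[dat$g == "a", ]; x2 <- dat$X[dat$g == "b", ]
  n1 <- nrow(x1); n2 <- nrow(x2); p <- ncol(x1)
  # independent oracle: classical two-sample Hotelling T2
  S <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) /
    (n1 + n2 - 2)
  dm <- colMeans(x1) - colMeans(x2)
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(dm) %*% solve(S) %*% dm)
  expect_equal((n1 * n2 / (n1 + n2)) * mh$d2["a", "b"], T2,
               tolerance = 1e-10)
  f <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * T2
  expect_equal(mh$p_values["a", "b"],
               stats::pf(f, p, n1 + n2 - p - 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("CAN1 scores agree with MASS::lda up to sign and scale", {
  skip_if_not_installed("MASS")
  dat <- random_group_data(14)
  tab <- as_cda_table(dat$X, dat$g)
  fit <- fit_cda(tab, traits = paste0("tr", 1:5))
  ld <- MASS::lda(dat$X, grouping = dat$g)
  lda_scores <- dat$X %*% ld$scaling
  expect_equal(abs(stats::cor(fit$scores[, 1], lda_scores[, 1])), 1,
               tolerance = 1e-8)
})
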