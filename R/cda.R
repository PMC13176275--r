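#' Canonical discriminant analysis of traits across treatment groups
#'
#' Solves the generalized eigenproblem of the between-group scatter against
#' the pooled within-group scatter: canonical coefficients `a` maximize
#' `a' B a / a' W a`, where `B` is the between-group SSCP of group means
#' (weighted by group size) and `W` the pooled within-group SSCP.
#' Eigenvalues are the between/within variance ratios of the canonical
#' scores; percent variance is each eigenvalue over their sum. Canonical
#' variates are scaled to unit pooled within-group variance
#' (`a' S_w a = 1` with `S_w = W / (N - g)`), and each variable's sign is
#' fixed so the trait with the largest absolute structure loading loads
#' positively, making seeded runs comparable. Structure loadings are the
#' total-sample correlations between traits and canonical scores. Traits
#' enter unstandardized: the within-scatter whitening already makes the
#' analysis invariant to affine rescaling of individual traits.
#'
#' @param trait_table tibble with the trait columns and a grouping column.
#' @param group_column name of the grouping column (default `"treatment"`).
#' @param traits trait columns to use; default [analysis_traits()].
#' @param max_condition condition-number limit for the pooled within-group
#'   covariance; beyond it the fit aborts with the condition number reported.
#' @return List of class `cda_result`: `eigenvalues`, `pct_variance`,
#'   `coefficients` (traits x variables, unit within-group variance
#'   scaling), `loadings` (trait-score correlations), `centroids` (groups x
#'   variables), `scores`, `groups`, `n_per_group`, `n_dropped` (listwise
#'   deletions), `pooled_cov`, `pooled_df`.
#' @export
#' @examples
#' pots <- simulate_raw_experiment(scenario_config(), seed = 7)
#' fit <- fit_cda(derive_traits(pots))
#' fit$pct_variance
fit_cda <- function(trait_table, group_column = "treatment",
                    traits = analysis_traits(), max_condition = 1e12) {
  if (!group_column %in% names(trait_table)) {
    stop("fit_cda: no grouping column '", group_column, "'", call. = FALSE)
  }
  missing_tr <- setdiff(traits, names(trait_table))
  if (length(missing_tr) > 0) {
    stop("fit_cda: trait column(s) absent: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(as.data.frame(trait_table)[, traits, drop = FALSE])
  g <- as.factor(trait_table[[group_column]])
  keep <- stats::complete.cases(X) & !is.na(g)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("fit_cda: dropped ", n_dropped, " row(s) with missing values")
  }
  X <- X[keep, , drop = FALSE]
  g <- droplevels(g[keep])
  ng <- table(g)
  if (nlevels(g) < 2) stop("fit_cda: need >= 2 groups", call. = FALSE)
  if (any(ng < 2)) {
    stop("fit_cda: group(s) with n < 2: ",
         paste(names(ng)[ng < 2], collapse = ", "), call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X); k <- nlevels(g)

  means <- apply(X, 2, function(col) tapply(col, g, mean))
  grand <- colMeans(X)
  centered_means <- sweep(means, 2, grand)
  B <- crossprod(centered_means * sqrt(as.vector(ng)))
  Xw <- X - means[g, , drop = FALSE]
  W <- crossprod(Xw)
  Sw <- W / (n - k)

  cond <- kappa(Sw, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition) {
    stop("fit_cda: pooled within-group covariance is near-singular ",
         "(condition number ", format(cond, digits = 3),
         "); consider removing collinear traits", call. = FALSE)
  }

  # symmetric reduction of the generalized eigenproblem B a = lambda W a
  L <- t(chol(W)) # W = L L'
  M <- forwardsolve(L, t(forwardsolve(L, B)))
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  n_can <- min(p, k - 1)
  lambda <- pmax(eig$values[seq_len(n_can)], 0)
  V <- eig$vectors[, seq_len(n_can), drop = FALSE]
  A <- backsolve(t(L), V) # a' W a = I
  A <- A * sqrt(n - k)    # a' Sw a = I: unit pooled within-group variance

  scores <- sweep(X, 2, grand) %*% A
  loadings <- stats::cor(X, scores)

  # deterministic sign: largest-|loading| trait positive per variable
  for (v in seq_len(n_can)) {
    lead <- which.max(abs(loadings[, v]))
    if (loadings[lead, v] < 0) {
      A[, v] <- -A[, v]; scores[, v] <- -scores[, v]
      loadings[, v] <- -loadings[, v]
    }
  }
  centroids <- apply(scores, 2, function(col) tapply(col, g, mean))
  can_names <- paste0("CAN", seq_len(n_can))
  dimnames(A) <- list(traits, can_names)
  dimnames(loadings) <- list(traits, can_names)
  colnames(scores) <- can_names
  colnames(centroids) <- can_names

  structure(
    list(eigenvalues = lambda,
         pct_variance = if (sum(lambda) > 0) 100 * lambda / sum(lambda)
                        else rep(0, n_can),
         coefficients = A, loadings = loadings, centroids = centroids,
         scores = scores, groups = g, n_per_group = c(ng),
         n_dropped = n_dropped, pooled_cov = Sw, pooled_df = n - k),
    class = "cda_result"
  )
}

#' Pairwise Mahalanobis squared distances with Hotelling tests
#'
#' Computes `D^2(g, h) = (m_g - m_h)' S_w^{-1} (m_g - m_h)` between all group
#' centroids, with `S_w` the covariance pooled across *all* groups (df
#' nu = N - g). Each pair is tested through the Hotelling T-squared to F
#' transformation: `T^2 = n_g n_h / (n_g + n_h) * D^2`,
#' `F = (nu - p + 1) / (nu p) * T^2` on `(p, nu - p + 1)` degrees of
#' freedom. With exactly two groups nu reduces to `n_1 + n_2 - 2`, the
#' classical two-sample Hotelling test.
#'
#' @inheritParams fit_cda
#' @return List of class `mahalanobis_matrix`: `d2` (symmetric, zero
#'   diagonal), `p_values`, `n_per_group`, `pooled_df`.
#' @export
mahalanobis_tests <- function(trait_table, group_column = "treatment",
                              traits = analysis_traits(),
                              max_condition = 1e12) {
  fit <- fit_cda(trait_table, group_column, traits, max_condition)
  X <- as.matrix(as.data.frame(trait_table)[, traits, drop = FALSE])
  g <- as.factor(trait_table[[group_column]])
  keep <- stats::complete.cases(X) & !is.na(g)
  X <- X[keep, , drop = FALSE]
  g <- droplevels(g[keep])
  means <- apply(X, 2, function(col) tapply(col, g, mean))
  ng <- table(g)
  p <- ncol(X)
  nu <- fit$pooled_df
  Sinv <- solve(fit$pooled_cov)
  k <- nlevels(g)
  d2 <- matrix(0, k, k, dimnames = list(levels(g), levels(g)))
  pv <- matrix(1, k, k, dimnames = list(levels(g), levels(g)))
  for (a in seq_len(k - 1)) {
    for (b in seq((a + 1), k)) {
      dm <- means[a, ] - means[b, ]
      D2 <- drop(t(dm) %*% Sinv %*% dm)
      t2 <- (ng[a] * ng[b] / (ng[a] + ng[b])) * D2
      fstat <- (nu - p + 1) / (nu * p) * t2
      pval <- if (nu - p + 1 <= 0) NA_real_ else
        stats::pf(fstat, p, nu - p + 1, lower.tail = FALSE)
      d2[a, b] <- d2[b, a] <- D2
      pv[a, b] <- pv[b, a] <- pval
    }
  }
  structure(
    list(d2 = d2, p_values = pv, n_per_group = c(ng), pooled_df = nu),
    class = "mahalanobis_matrix"
  )
}
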