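# Shared fixtures built in code.

# Trait table with exactly the given group means and tiny (or zero) noise,
# for the nine-treatment layout used by the contrast/additivity plans.
make_group_table <- function(cell_means, replicates = 10, sd = 0,
                             seed = 1,
                             temp_levels = c("Tamb", "T1", "T2"),
                             water_levels = c("WW", "WS", "SS"),
                             trait = "shoot") {
  design <- build_design(design_spec(temp_levels, water_levels, replicates))
  mu <- cell_means[cbind(match(design$temp, temp_levels),
                         match(design$water, water_levels))]
  y <- if (sd > 0) with_seed(seed, mu + rnorm(nrow(design), 0, sd)) else mu
  out <- design
  out[[trait]] <- y
  out$treatment <- treatment_label(out$temp, out$water)
  out
}

# Independent brute-force split-plot SS decomposition via explicit
# projections (QR on design matrices), the oracle for fit_splitplot.
splitplot_projection_oracle <- function(y, temp, water, mainplot) {
  ssr <- function(X) {
    f <- qr.fitted(qr(X), y)
    sum(f^2)
  }
  X1 <- matrix(1, length(y), 1)
  Xt <- stats::model.matrix(~ 0 + temp)
  Xm <- stats::model.matrix(~ 0 + mainplot)
  Xw <- stats::model.matrix(~ 0 + water)
  Xc <- stats::model.matrix(~ 0 + temp:water)
  Xfull <- cbind(Xm, Xc)
  ss_temp <- ssr(Xt) - ssr(X1)
  ss_mpe <- ssr(Xm) - ssr(Xt)
  ss_water <- ssr(cbind(X1, Xw)) - ssr(X1)
  ss_int <- ssr(Xc) - ssr(X1) - ss_temp - ss_water
  ss_resid <- sum(y^2) - ssr(Xfull)
  c(Temperature = ss_temp, MainPlotError = ss_mpe, Water = ss_water,
    TemperaturexWater = ss_int, Residual = ss_resid)
}

# Gaussian k-group fixture for the CDA tests.
random_group_data <- function(seed, n_per = 12, p = 5, k = 4, sep = 1.5) {
  with_seed(seed, {
    means <- matrix(rnorm(k * p, 0, sep), k, p)
    X <- do.call(rbind, lapply(seq_len(k), function(g) {
      sweep(matrix(rnorm(n_per * p), n_per, p), 2, means[g, ], `+`)
    }))
    list(X = X, g = factor(rep(letters[seq_len(k)], each = n_per)))
  })
}

as_cda_table <- function(X, g) {
  colnames(X) <- paste0("tr", seq_len(ncol(X)))
  out <- tibble::as_tibble(as.data.frame(X))
  out$treatment <- g
  out
}

# Brute-force CDA oracle: explicit scatter matrices + generic eigensolver.
cda_oracle <- function(X, g) {
  g <- as.factor(g)
  n <- nrow(X); k <- nlevels(g); p <- ncol(X)
  grand <- colMeans(X)
  B <- matrix(0, p, p); W <- matrix(0, p, p)
  for (lev in levels(g)) {
    Xg <- X[g == lev, , drop = FALSE]
    mg <- colMeans(Xg)
    B <- B + nrow(Xg) * tcrossprod(mg - grand)
    for (r in seq_len(nrow(Xg))) {
      W <- W + tcrossprod(Xg[r, ] - mg)
    }
  }
  eig <- eigen(solve(W) %*% B)
  ord <- order(Re(eig$values), decreasing = TRUE)
  n_can <- min(p, k - 1)
  lambda <- Re(eig$values[ord])[seq_len(n_can)]
  vecs <- Re(eig$vectors[, ord, drop = FALSE])[, seq_len(n_can), drop = FALSE]
  # normalize to unit pooled within-group variance
  Sw <- W / (n - k)
  for (v in seq_len(n_can)) {
    s <- sqrt(drop(t(vecs[, v]) %*% Sw %*% vecs[, v]))
    vecs[, v] <- vecs[, v] / s
  }
  list(eigenvalues = lambda, vectors = vecs, B = B, W = W, Sw = Sw)
}
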