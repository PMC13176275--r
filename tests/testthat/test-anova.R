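make_anova_table <- function(y, temps = c("Tamb", "T1", "T2"),
                             waters = c("WW", "WS", "SS"), reps = 10,
                             trait = "shoot") {
  d <- build_design(design_spec(temps, waters, reps))
  d[[trait]] <- y
  d$treatment <- treatment_label(d$temp, d$water)
  d
}

test_that("noise-free cell means give zero error strata and full df budget", {
  cm <- matrix(c(10, 8, 6, 9, 7, 5, 11, 9, 4), 3, byrow = TRUE)
  tab <- make_group_table(cm, replicates = 10, sd = 0)
  fit <- fit_splitplot(tab, "shoot")
  ss <- setNames(fit$table$SS, fit$table$stratum)
  expect_equal(ss[["MainPlotError"]], 0, tolerance = 1e-10)
  expect_equal(ss[["Residual"]], 0, tolerance = 1e-10)
  expect_equal(setNames(fit$table$df, fit$table$stratum),
               c(Temperature = 2, MainPlotError = 27, Water = 2,
                 TemperaturexWater = 4, Residual = 54))
  expect_equal(sum(fit$table$df), 89)
})

test_that("stratum SS match the projection-matrix oracle to 1e-10", {
  for (seed in 1:3) {
    d <- build_design(design_spec(c("a", "b"), c("p", "q"), 3))
    y <- with_seed(seed, rnorm(nrow(d), 5, 2))
    tab <- d; tab$shoot <- y
    fit <- fit_splitplot(tab, "shoot")
    oracle <- splitplot_projection_oracle(
      y, d$temp, d$water, factor(d$mainplot_id))
    got <- setNames(fit$table$SS, fit$table$stratum)
    expect_equal(got, oracle[names(got)], tolerance = 1e-10)
    # SS decomposition is exhaustive
    expect_equal(sum(got), sum((y - mean(y))^2), tolerance = 1e-8)
  }
  # and on the full 3x3x10 layout
  d <- build_design(design_spec())
  y <- with_seed(9, rnorm(90, 10, 3))
  tab <- d; tab$shoot <- y
  fit <- fit_splitplot(tab, "shoot")
  oracle <- splitplot_projection_oracle(y, d$temp, d$water,
                                        factor(d$mainplot_id))
  expect_equal(setNames(fit$table$SS, fit$table$stratum),
               oracle[fit$table$stratum], tolerance = 1e-10)
})

test_that("F tests use the correct error strata", {
  d <- build_design(design_spec())
  y <- with_seed(2, rnorm(90))
  tab <- d; tab$shoot <- y
  t <- fit_splitplot(tab, "shoot")$table
  ms <- setNames(t$MS, t$stratum)
  f <- setNames(t$F, t$stratum)
  expect_equal(f[["Temperature"]], ms[["Temperature"]] / ms[["MainPlotError"]])
  expect_equal(f[["Water"]], ms[["Water"]] / ms[["Residual"]])
  expect_equal(f[["TemperaturexWater"]],
               ms[["TemperaturexWater"]] / ms[["Residual"]])
})

test_that("SS are invariant to shifts and scale as c^2", {
  d <- build_design(design_spec(replicates = 4))
  y <- with_seed(3, rnorm(nrow(d), 5))
  tab <- d; tab$shoot <- y
  base <- fit_splitplot(tab, "shoot")$table$SS
  tab$shoot <- y + 100
  expect_equal(fit_splitplot(tab, "shoot")$table$SS, base,
               tolerance = 1e-8)
  tab$shoot <- 3 * y
  expect_equal(fit_splitplot(tab, "shoot")$table$SS, 9 * base,
               tolerance = 1e-8)
})

test_that("permuting water labels within a main plot preserves whole-plot SS", {
  d <- build_design(design_spec(replicates = 5))
  y <- with_seed(4, rnorm(nrow(d), 2))
  tab <- d; tab$shoot <- y
  base <- fit_splitplot(tab, "shoot")$table
  perm <- with_seed(5, {
    tab2 <- tab
    for (mp in unique(tab2$mainplot_id)) {
      rows <- which(tab2$mainplot_id == mp)
      tab2$water[rows] <- sample(tab2$water[rows])
    }
    tab2
  })
  got <- fit_splitplot(perm, "shoot")$table
  s <- function(t, n) t$SS[t$stratum == n]
  expect_equal(s(got, "Temperature"), s(base, "Temperature"),
               tolerance = 1e-10)
  expect_equal(s(got, "MainPlotError"), s(base, "MainPlotError"),
               tolerance = 1e-10)
})

test_that("unbalanced or incomplete data are rejected outright", {
  tab <- make_group_table(matrix(5, 3, 3), replicates = 4, sd = 1, seed = 1)
  expect_error(fit_splitplot(tab[-1, ], "shoot"), "balanced")
  tab$shoot[2] <- NA
  expect_error(fit_splitplot(tab, "shoot"), tab$pot_id[2])
  expect_error(fit_splitplot(tab, "nope"), "no trait column")
})

test_that("transformations are applied on request", {
  tab <- make_group_table(matrix(c(10, 8, 6, 9, 7, 5, 11, 9, 4), 3,
                                 byrow = TRUE), sd = 0.5, seed = 6)
  flog <- fit_splitplot(tab, "shoot", transform = "log")
  direct <- tab; direct$shoot <- log(direct$shoot)
  expect_equal(flog$table$SS, fit_splitplot(direct, "shoot")$table$SS,
               tolerance = 1e-12)
  neg <- tab; neg$shoot[1] <- -1
  expect_error(fit_splitplot(neg, "shoot", transform = "log"), "positive")
})

test_that("blocked variant adds a replicate stratum with the right df", {
  tab <- make_group_table(matrix(5, 3, 3), replicates = 10, sd = 1, seed = 7)
  fit <- fit_splitplot(tab, "shoot", blocked = TRUE)
  expect_true("Block" %in% fit$table$stratum)
  df <- setNames(fit$table$df, fit$table$stratum)
  expect_equal(df[["Block"]], 9)
  expect_equal(df[["MainPlotError"]], 18) # t(r-1) - (r-1)
  expect_equal(sum(fit$table$df), 89)
})

test_that("residual diagnostics report Shapiro and Brown-Forsythe p-values", {
  tab <- make_group_table(matrix(c(10, 8, 6, 9, 7, 5, 11, 9, 4), 3,
                                 byrow = TRUE), sd = 0.5, seed = 8)
  fit <- fit_splitplot(tab, "shoot")
  d <- residual_diagnostics(fit)
  expect_true(d$available)
  expect_true(d$shapiro_p > 0 && d$shapiro_p <= 1)
  expect_true(d$levene_p > 0 && d$levene_p <= 1)
  expect_equal(d$transformation_applied, "none")
})

test_that("a 100x-variance group is flagged by the Brown-Forsythe test", {
  flagged <- vapply(1:20, function(s) {
    tab <- make_group_table(matrix(5, 3, 3), sd = 0.2, seed = 100 + s)
    hot <- tab$treatment == "SS(T2)"
    tab$shoot[hot] <- with_seed(200 + s, rnorm(sum(hot), 5, 2))
    residual_diagnostics(fit_splitplot(tab, "shoot"))$levene_p < 0.05
  }, logical(1))
  expect_gte(mean(flagged), 0.8)
})

test_that("constant residuals yield the diagnostics-unavailable flag", {
  tab <- make_group_table(matrix(c(10, 8, 6, 9, 7, 5, 11, 9, 4), 3,
                                 byrow = TRUE), sd = 0)
  d <- residual_diagnostics(fit_splitplot(tab, "shoot"))
  expect_false(d$available)
  expect_true(is.na(d$shapiro_p))
})

test_that("requested transformation is applied when assumptions fail", {
  # heavily right-skewed response violates normality
  tab <- make_group_table(matrix(5, 3, 3), sd = 0, seed = 1)
  tab$shoot <- with_seed(3, exp(rnorm(90, 0, 1.5)))
  fit <- fit_splitplot(tab, "shoot")
  d <- residual_diagnostics(fit, transform = "log")
  expect_true(d$shapiro_p < 0.05 || d$levene_p < 0.05)
  expect_equal(d$transformation_applied, "log")
  expect_s3_class(d$refit$fit, "splitplot_fit")
  expect_gt(d$refit$diagnostics$shapiro_p, d$shapiro_p)
})

test_that("Shapiro p-values are near-uniform under Gaussian residuals", {
  # needs the full-size design: subplot residuals are projections, and on
  # tiny layouts their dependence visibly distorts the null distribution
  pvals <- vapply(1:500, function(s) {
    tab <- make_group_table(matrix(5, 3, 3), replicates = 10, sd = 1,
                            seed = 300 + s)
    residual_diagnostics(fit_splitplot(tab, "shoot"))$shapiro_p
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})
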