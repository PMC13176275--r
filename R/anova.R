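#' Split-plot two-way ANOVA with nested error strata
#'
#' Fits the classical completely-randomized split-plot decomposition for one
#' trait: temperature (main-plot factor) is tested against the among-main-
#' plots-within-temperature error, while the water regime (subplot factor)
#' and the temperature x water interaction are tested against the subplot
#' residual. Main plots are the (temp, replicate) pairs, i.e. replicates are
#' nested within temperature; for a balanced t x w x r layout the degrees of
#' freedom are (t-1) + t(r-1) + (w-1) + (t-1)(w-1) + t(w-1)(r-1) = N - 1.
#' Optionally a `blocked` variant treats replicate as a crossed block (main-
#' plot error df then t(r-1) - (r-1)).
#'
#' The decomposition is computed with [stats::aov()] and a nested `Error()`
#' stratum, mirroring standard agronomic practice.
#'
#' @param trait_table tibble from [derive_traits()].
#' @param trait name of the trait column to analyse.
#' @param transform `"none"`, `"log"` or `"sqrt"`, applied before fitting.
#' @param blocked if `TRUE`, include a replicate block main effect.
#' @return List of class `splitplot_fit`: `table` (tibble with rows
#'   Temperature, MainPlotError, Water, TemperaturexWater, Residual and
#'   columns stratum, SS, df, MS, F, p), `residuals` (subplot residuals),
#'   `data`, `trait`, `transform`.
#' @export
#' @examples
#' pots <- simulate_raw_experiment(scenario_config(), seed = 7)
#' fit <- fit_splitplot(derive_traits(pots), "shoot")
#' fit$table
fit_splitplot <- function(trait_table, trait,
                          transform = c("none", "log", "sqrt"),
                          blocked = FALSE) {
  transform <- match.arg(transform)
  if (!trait %in% names(trait_table)) {
    stop("fit_splitplot: no trait column '", trait, "'", call. = FALSE)
  }
  df <- data.frame(
    y = trait_table[[trait]],
    temp = as.factor(trait_table$temp),
    water = as.factor(trait_table$water),
    replicate = as.factor(trait_table$replicate)
  )
  if (anyNA(df$y)) {
    bad <- trait_table$pot_id[is.na(df$y)]
    stop("fit_splitplot: missing values for trait '", trait, "' in pot(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- table(df$temp, df$water, df$replicate)
  if (length(unique(as.vector(table(df$temp, df$water)))) != 1 ||
      any(as.vector(counts) != 1)) {
    stop("fit_splitplot: design must be balanced with one pot per ",
         "(temp, water, replicate) cell", call. = FALSE)
  }
  df$y <- switch(transform,
    none = df$y,
    log = {
      if (any(df$y <= 0)) stop("fit_splitplot: log transform needs ",
                               "positive values", call. = FALSE)
      log(df$y)
    },
    sqrt = {
      if (any(df$y < 0)) stop("fit_splitplot: sqrt transform needs ",
                              "non-negative values", call. = FALSE)
      sqrt(df$y)
    }
  )
  df$mainplot <- interaction(df$temp, df$replicate, drop = TRUE)

  fit <- if (blocked) {
    stats::aov(y ~ replicate + temp * water + Error(mainplot), data = df)
  } else {
    stats::aov(y ~ temp * water + Error(mainplot), data = df)
  }
  s <- summary(fit)
  mp <- as.data.frame(s[["Error: mainplot"]][[1]])
  wi <- as.data.frame(s[["Error: Within"]][[1]])
  rn_mp <- trimws(rownames(mp)); rn_wi <- trimws(rownames(wi))

  grab <- function(tab, rn, name) unlist(tab[match(name, rn), 1:3])
  t_row <- grab(mp, rn_mp, "temp")
  e1_row <- grab(mp, rn_mp, "Residuals")
  w_row <- grab(wi, rn_wi, "water")
  tw_row <- grab(wi, rn_wi, "temp:water")
  e2_row <- grab(wi, rn_wi, "Residuals")

  f_temp <- t_row[3] / e1_row[3]
  f_water <- w_row[3] / e2_row[3]
  f_tw <- tw_row[3] / e2_row[3]
  tab <- tibble::tibble(
    stratum = c("Temperature", "MainPlotError", "Water",
                "TemperaturexWater", "Residual"),
    SS = c(t_row[2], e1_row[2], w_row[2], tw_row[2], e2_row[2]),
    df = c(t_row[1], e1_row[1], w_row[1], tw_row[1], e2_row[1]),
    MS = c(t_row[3], e1_row[3], w_row[3], tw_row[3], e2_row[3]),
    F = c(f_temp, NA, f_water, f_tw, NA),
    p = c(stats::pf(f_temp, t_row[1], e1_row[1], lower.tail = FALSE), NA,
          stats::pf(f_water, w_row[1], e2_row[1], lower.tail = FALSE),
          stats::pf(f_tw, tw_row[1], e2_row[1], lower.tail = FALSE), NA)
  )
  if (blocked) {
    b_row <- grab(mp, rn_mp, "replicate")
    f_b <- b_row[3] / e1_row[3]
    tab <- rbind(
      tibble::tibble(stratum = "Block", SS = b_row[2], df = b_row[1],
                     MS = b_row[3], F = f_b,
                     p = stats::pf(f_b, b_row[1], e1_row[1],
                                   lower.tail = FALSE)),
      tab
    )
  }

  # subplot residual: y - mainplot mean - cell mean + temp mean (balanced)
  mp_mean <- stats::ave(df$y, df$mainplot)
  cell_mean <- stats::ave(df$y, df$temp, df$water)
  temp_mean <- stats::ave(df$y, df$temp)
  resid <- df$y - mp_mean - cell_mean + temp_mean

  structure(
    list(table = tab, residuals = resid, data = df, trait = trait,
         transform = transform, blocked = blocked),
    class = "splitplot_fit"
  )
}

#' Residual diagnostics for a split-plot fit
#'
#' Shapiro-Wilk normality test on the subplot residuals and Brown-Forsythe
#' homogeneity test (median-centered Levene, via [car::leveneTest()]) across
#' the treatment groups (temp x water cells). If either p-value falls below
#' `alpha` and a `transform` is requested, the model is refitted on the
#' transformed response and both reports are returned.
#'
#' @param fit a `splitplot_fit` from [fit_splitplot()].
#' @param transform optional transformation (`"log"` or `"sqrt"`) to apply
#'   when assumptions fail; `NULL` (default) never refits.
#' @param alpha assumption-violation threshold (default 0.05).
#' @return List of class `diagnostics_report`: `shapiro_p`, `levene_p`,
#'   `transformation_applied`, `available`, and `refit` (a second report +
#'   fit when a transformation was triggered).
#' @export
residual_diagnostics <- function(fit, transform = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "splitplot_fit"))
  r <- fit$residuals
  if (length(r) < 3 || stats::sd(r) == 0) {
    return(structure(
      list(shapiro_p = NA_real_, levene_p = NA_real_,
           transformation_applied = "none", available = FALSE, refit = NULL),
      class = "diagnostics_report"
    ))
  }
  shapiro_p <- stats::shapiro.test(r)$p.value
  group <- interaction(fit$data$temp, fit$data$water, drop = TRUE)
  lev <- car::leveneTest(fit$data$y, group, center = stats::median)
  levene_p <- lev[["Pr(>F)"]][1]
  out <- list(shapiro_p = shapiro_p, levene_p = levene_p,
              transformation_applied = "none", available = TRUE,
              refit = NULL)
  if (!is.null(transform) && (shapiro_p < alpha || levene_p < alpha)) {
    # refit on the original trait values under the requested transform
    tt <- tibble::tibble(
      pot_id = seq_along(fit$data$y), temp = fit$data$temp,
      water = fit$data$water, replicate = fit$data$replicate
    )
    tt[[fit$trait]] <- fit$data$y
    refit <- fit_splitplot(tt, fit$trait, transform = transform,
                           blocked = fit$blocked)
    out$transformation_applied <- transform
    out$refit <- list(fit = refit,
                      diagnostics = residual_diagnostics(refit))
  }
  structure(out, class = "diagnostics_report")
}
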