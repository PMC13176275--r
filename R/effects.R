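#' Unpaired mean difference (effect size of estimation statistics)
#'
#' `mean(treatment) - mean(baseline)`; negative values are reductions
#' relative to the baseline.
#'
#' @param treatment,baseline numeric vectors (each n >= 1).
#' @return The mean difference, in trait units.
#' @export
#' @examples
#' mean_difference(c(2, 3, 4), c(1, 2, 3)) # +1
mean_difference <- function(treatment, baseline) {
  if (length(treatment) < 1 || length(baseline) < 1) {
    stop("mean_difference: both groups must be non-empty", call. = FALSE)
  }
  mean(treatment) - mean(baseline)
}

#' Bias-corrected and accelerated (BCa) bootstrap CI for a two-group statistic
#'
#' Resamples each group independently with replacement at its own size,
#' recomputes the statistic per iteration, and returns the BCa interval:
#' the bias correction `z0` is the normal quantile of the proportion of
#' bootstrap statistics below the observed value (ties counted half), and
#' the acceleration `a` comes from a leave-one-out jackknife across all
#' observations of both groups. Interval endpoints are percentiles of the
#' bootstrap distribution at the BCa-adjusted levels.
#'
#' If all values of both groups are identical the interval is degenerate at
#' the observed statistic. If an adjusted level falls outside (0, 1) (extreme
#' bias correction) it is clamped to the nearest achievable order statistic
#' and the result is flagged.
#'
#' @param treatment,baseline numeric vectors, each n >= 2.
#' @param n_boot bootstrap iterations (>= 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param statistic function of (treatment, baseline); default
#'   [mean_difference()]. The default uses a vectorised fast path.
#' @return List: `estimate`, `low`, `high`, `z0`, `acceleration`, `n_boot`,
#'   `degenerate`, `clamped`.
#' @export
#' @examples
#' bca_interval(rnorm(10, 1), rnorm(10), n_boot = 1000, seed = 1)
bca_interval <- function(treatment, baseline, n_boot = 5000, level = 0.95,
                         seed = 1L, statistic = mean_difference) {
  if (length(treatment) < 2 || length(baseline) < 2) {
    stop("bca_interval: each group needs n >= 2", call. = FALSE)
  }
  if (n_boot < 100) {
    stop("bca_interval: n_boot must be >= 100", call. = FALSE)
  }
  obs <- statistic(treatment, baseline)
  if (all(treatment == treatment[1]) && all(baseline == baseline[1])) {
    return(list(estimate = obs, low = obs, high = obs, z0 = 0,
                acceleration = 0, n_boot = as.integer(n_boot),
                degenerate = TRUE, clamped = FALSE))
  }
  fast <- identical(statistic, mean_difference)
  n1 <- length(treatment); n2 <- length(baseline)

  boot_stats <- with_seed(seed, {
    if (fast) {
      i1 <- matrix(sample.int(n1, n1 * n_boot, replace = TRUE), nrow = n1)
      i2 <- matrix(sample.int(n2, n2 * n_boot, replace = TRUE), nrow = n2)
      colMeans(matrix(treatment[i1], nrow = n1)) -
        colMeans(matrix(baseline[i2], nrow = n2))
    } else {
      vapply(seq_len(n_boot), function(b) {
        statistic(treatment[sample.int(n1, n1, replace = TRUE)],
                  baseline[sample.int(n2, n2, replace = TRUE)])
      }, numeric(1))
    }
  })

  # bias correction: ties between bootstrap statistic and observed count half
  p0 <- (sum(boot_stats < obs) + 0.5 * sum(boot_stats == obs)) / n_boot
  p0 <- min(max(p0, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
  z0 <- stats::qnorm(p0)

  # acceleration: jackknife over every observation of both groups
  jk <- c(
    vapply(seq_len(n1), function(i) statistic(treatment[-i], baseline),
           numeric(1)),
    vapply(seq_len(n2), function(i) statistic(treatment, baseline[-i]),
           numeric(1))
  )
  d <- mean(jk) - jk
  denom <- sum(d^2)^1.5
  a <- if (denom > 0) sum(d^3) / (6 * denom) else 0

  alpha <- (1 - level) / 2
  zq <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  clamped <- any(adj <= 0) || any(adj >= 1) || any(!is.finite(adj))
  adj[!is.finite(adj)] <- c(0, 1)[!is.finite(adj)]
  adj <- pmin(pmax(adj, 1 / n_boot), 1 - 1 / n_boot)
  # (B+1)*alpha order-statistic convention for bootstrap percentiles
  ci <- unname(stats::quantile(boot_stats, adj, type = 6))

  list(estimate = obs, low = ci[1], high = ci[2], z0 = z0, acceleration = a,
       n_boot = as.integer(n_boot), degenerate = FALSE, clamped = clamped)
}

#' Default contrast plan for a two-stress split-plot experiment
#'
#' Single-stress treatments are compared against the untreated control and
#' combined-stress treatments against their respective single-stress
#' baseline: with default 3x3 labels, T1, T2, WS, SS vs WW; WS(T1), WS(T2)
#' vs WS; SS(T1), SS(T2) vs SS.
#'
#' @param temp_levels,water_levels factor level labels, control first.
#' @return A tibble with columns `treatment` and `baseline`.
#' @export
default_contrast_plan <- function(temp_levels = c("Tamb", "T1", "T2"),
                                  water_levels = c("WW", "WS", "SS")) {
  t0 <- temp_levels[1]; w0 <- water_levels[1]
  warm <- temp_levels[-1]; stress <- water_levels[-1]
  single <- tibble::tibble(
    treatment = c(warm, stress),
    baseline = w0
  )
  combined <- do.call(rbind, lapply(stress, function(w) {
    tibble::tibble(treatment = paste0(w, "(", warm, ")"), baseline = w)
  }))
  rbind(single, combined)
}

#' Run a contrast plan over every analysis trait
#'
#' For each (trait, contrast) pair computes the unpaired mean difference and
#' its BCa bootstrap CI. Each pair draws from its own RNG substream derived
#' from `(seed, trait, treatment, baseline)`, so results do not depend on the
#' order of rows in the plan or of traits.
#'
#' @param trait_table tibble from [derive_traits()] (needs a `treatment`
#'   column).
#' @param plan contrast plan tibble (`treatment`, `baseline` columns);
#'   default from the factor levels of `trait_table`.
#' @param traits trait columns to analyse; default [analysis_traits()].
#' @param n_boot bootstrap iterations per contrast (default 5000).
#' @param level confidence level.
#' @param seed master seed.
#' @return Tibble with one row per (trait, contrast): `trait`, `contrast`,
#'   `treatment`, `baseline`, `delta_mean`, `ci_low`, `ci_high`, `n_boot`,
#'   `seed`, `n_treatment`, `n_baseline`, `degenerate`.
#' @export
run_contrast_plan <- function(trait_table, plan = NULL,
                              traits = analysis_traits(),
                              n_boot = 5000, level = 0.95, seed = 1L) {
  if (!"treatment" %in% names(trait_table)) {
    stop("run_contrast_plan: trait table needs a 'treatment' column",
         call. = FALSE)
  }
  if (is.null(plan)) {
    plan <- default_contrast_plan(levels(as.factor(trait_table$temp)),
                                  levels(as.factor(trait_table$water)))
  }
  groups <- as.character(trait_table$treatment)
  present <- unique(groups)
  wanted <- unique(c(plan$treatment, plan$baseline))
  absent <- setdiff(wanted, present)
  if (length(absent) > 0) {
    stop("run_contrast_plan: group(s) absent from data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  missing_tr <- setdiff(traits, names(trait_table))
  if (length(missing_tr) > 0) {
    stop("run_contrast_plan: trait column(s) absent: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (trait in traits) {
    vals <- trait_table[[trait]]
    for (k in seq_len(nrow(plan))) {
      tr <- plan$treatment[k]; bl <- plan$baseline[k]
      x <- vals[groups == tr & !is.na(vals)]
      y <- vals[groups == bl & !is.na(vals)]
      sub_seed <- derive_seed(seed, "contrast", trait, tr, bl)
      fit <- bca_interval(x, y, n_boot = n_boot, level = level,
                          seed = sub_seed)
      rows[[length(rows) + 1]] <- tibble::tibble(
        trait = trait, contrast = paste(tr, "vs", bl),
        treatment = tr, baseline = bl,
        delta_mean = fit$estimate, ci_low = fit$low, ci_high = fit$high,
        n_boot = fit$n_boot, seed = sub_seed,
        n_treatment = length(x), n_baseline = length(y),
        degenerate = fit$degenerate
      )
    }
  }
  do.call(rbind, rows)
}
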