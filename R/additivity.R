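#' Bootstrap Additivity Index for a double-stress treatment
#'
#' For two stressors i and j applied alone and in combination, with all
#' effect sizes measured against the same unstressed control (WW),
#' \deqn{AI = ES_{ij} - (ES_i + ES_j)}
#' where each ES is an unpaired mean difference vs the control. AI = 0 means
#' the combined stress equals the sum of the single-stress effects; the
#' bootstrap resamples all four groups jointly per iteration (one AI* per
#' iteration), the CI is a bias-corrected percentile interval (acceleration 0
#' by default; `method = "bca"` adds a grouped leave-one-pot-out jackknife
#' acceleration), and the two-sided p-value is
#' `2 * min(#\{AI* <= 0\} + 1, #\{AI* >= 0\} + 1) / (n_boot + 1)`.
#'
#' Classification: additive if the CI contains 0. Otherwise, with
#' `S = ES_i + ES_j` the expected additive effect, `sign(AI) == sign(S)`
#' means the combination overshoots the additive expectation (synergistic);
#' opposite signs mean it undershoots (antagonistic); `S == 0` yields
#' "non-additive-unsigned".
#'
#' @param values_ww control group values.
#' @param values_i single-stress i group (e.g. warming alone).
#' @param values_j single-stress j group (e.g. water stress alone).
#' @param values_ij combined-stress group.
#' @param n_boot bootstrap iterations (>= 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @param method `"bc"` (bias-corrected percentile, default) or `"bca"`.
#' @return List of class `additivity_result`: `index`, `ci_low`, `ci_high`,
#'   `p_value`, `classification`, `es_i`, `es_j`, `es_ij`,
#'   `expected_additive`, `pct_of_control`, `n_boot`, `seed`, `method`.
#' @export
#' @examples
#' additivity_index(rnorm(10, 10, .1), rnorm(10, 8, .1),
#'                  rnorm(10, 6, .1), rnorm(10, 4, .1),
#'                  n_boot = 1000, seed = 1)
additivity_index <- function(values_ww, values_i, values_j, values_ij,
                             n_boot = 5000, level = 0.95, seed = 1L,
                             method = c("bc", "bca")) {
  method <- match.arg(method)
  groups <- list(ww = values_ww, i = values_i, j = values_j, ij = values_ij)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) {
    stop("additivity_index: group(s) with n < 2: ",
         paste(names(groups)[ns < 2], collapse = ", "), call. = FALSE)
  }
  if (any(vapply(groups, function(g) any(is.na(g)), logical(1)))) {
    stop("additivity_index: missing values in input groups", call. = FALSE)
  }
  if (n_boot < 100) {
    stop("additivity_index: n_boot must be >= 100", call. = FALSE)
  }
  ai_stat <- function(ww, i, j, ij) {
    # (m_ij - m_ww) - (m_i - m_ww) - (m_j - m_ww) = m_ij + m_ww - m_i - m_j
    mean(ij) + mean(ww) - mean(i) - mean(j)
  }
  es_i <- mean(groups$i) - mean(groups$ww)
  es_j <- mean(groups$j) - mean(groups$ww)
  es_ij <- mean(groups$ij) - mean(groups$ww)
  ai <- es_ij - (es_i + es_j)

  boot <- with_seed(derive_seed(seed, "additivity-boot"), {
    bm <- function(v) {
      n <- length(v)
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
      colMeans(matrix(v[idx], nrow = n))
    }
    bm(groups$ij) + bm(groups$ww) - bm(groups$i) - bm(groups$j)
  })

  p0 <- (sum(boot < ai) + 0.5 * sum(boot == ai)) / n_boot
  p0 <- min(max(p0, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
  z0 <- stats::qnorm(p0)

  a <- 0
  if (method == "bca") {
    # grouped jackknife: drop one pot at a time from whichever group owns it
    jk <- unlist(lapply(names(groups), function(g) {
      vapply(seq_along(groups[[g]]), function(k) {
        gl <- groups
        gl[[g]] <- gl[[g]][-k]
        ai_stat(gl$ww, gl$i, gl$j, gl$ij)
      }, numeric(1))
    }))
    d <- mean(jk) - jk
    denom <- sum(d^2)^1.5
    a <- if (denom > 0) sum(d^3) / (6 * denom) else 0
  }

  degenerate <- stats::var(boot) == 0
  if (degenerate) {
    ci <- c(ai, ai)
  } else {
    alpha <- (1 - level) / 2
    zq <- stats::qnorm(c(alpha, 1 - alpha))
    adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    adj <- pmin(pmax(adj, 1 / n_boot), 1 - 1 / n_boot)
    ci <- unname(stats::quantile(boot, adj, type = 6))
  }

  p <- 2 * min(sum(boot <= 0) + 1, sum(boot >= 0) + 1) / (n_boot + 1)
  p <- min(p, 1)

  s <- es_i + es_j
  classification <- if (ci[1] <= 0 && ci[2] >= 0) {
    "additive"
  } else if (s == 0) {
    "non-additive-unsigned"
  } else if (sign(ai) == sign(s)) {
    "synergistic"
  } else {
    "antagonistic"
  }

  ww_mean <- mean(groups$ww)
  structure(
    list(index = ai, ci_low = ci[1], ci_high = ci[2], p_value = p,
         classification = classification,
         es_i = es_i, es_j = es_j, es_ij = es_ij, expected_additive = s,
         pct_of_control = if (ww_mean != 0) 100 * ai / ww_mean else NA_real_,
         n_boot = as.integer(n_boot), seed = seed, method = method),
    class = "additivity_result"
  )
}

#' Additivity Index for every (double-stress combo, trait) cell
#'
#' Runs [additivity_index()] for each combination of warming level and
#' water/salt stress level over each analysis trait. With the default 3x3
#' labels this is the 4 combos WS(T1), WS(T2), SS(T1), SS(T2) by 9 traits =
#' 36 cells. Each cell uses an RNG substream derived from
#' `(seed, trait, combo)`.
#'
#' @inheritParams run_contrast_plan
#' @param method passed to [additivity_index()].
#' @return Tibble: `trait`, `combo`, `index`, `ci_low`, `ci_high`,
#'   `p_value`, `classification`, `pct_of_control`, `significant`,
#'   `n_boot`, `seed`.
#' @export
run_additivity <- function(trait_table, traits = analysis_traits(),
                           n_boot = 5000, level = 0.95, seed = 1L,
                           method = c("bc", "bca")) {
  method <- match.arg(method)
  temp_lv <- levels(as.factor(trait_table$temp))
  water_lv <- levels(as.factor(trait_table$water))
  t0 <- temp_lv[1]; w0 <- water_lv[1]
  groups <- as.character(trait_table$treatment)
  rows <- list()
  for (trait in traits) {
    vals <- trait_table[[trait]]
    pick <- function(lab) vals[groups == lab & !is.na(vals)]
    for (w in water_lv[-1]) {
      for (tt in temp_lv[-1]) {
        combo <- paste0(w, "(", tt, ")")
        res <- additivity_index(
          values_ww = pick(w0), values_i = pick(tt), values_j = pick(w),
          values_ij = pick(combo),
          n_boot = n_boot, level = level,
          seed = derive_seed(seed, "additivity", trait, combo),
          method = method
        )
        rows[[length(rows) + 1]] <- tibble::tibble(
          trait = trait, combo = combo, index = res$index,
          ci_low = res$ci_low, ci_high = res$ci_high, p_value = res$p_value,
          classification = res$classification,
          pct_of_control = res$pct_of_control,
          significant = res$p_value < 0.05,
          n_boot = res$n_boot, seed = res$seed
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Heatmap matrix of additivity deviations as percent of control
#'
#' Reshapes [run_additivity()] results into a combos x traits matrix of
#' `100 * AI / mean(control)` plus a parallel logical matrix marking cells
#' with `p < 0.05` (significant departure from full additivity) and a
#' character matrix of classifications (synergistic vs antagonistic cells
#' are what a heatmap colours in opposing hues). Cells whose control mean is
#' zero are `NA` (undefined, not infinite).
#'
#' @param results tibble from [run_additivity()].
#' @param alpha significance mark threshold (default 0.05).
#' @return List: `pct` (numeric matrix), `significant` (logical matrix),
#'   `classification` (character matrix).
#' @export
heatmap_matrix <- function(results, alpha = 0.05) {
  combos <- unique(results$combo)
  traits <- unique(results$trait)
  shape <- function(col, what) {
    m <- matrix(what, nrow = length(combos), ncol = length(traits),
                dimnames = list(combos, traits))
    for (k in seq_len(nrow(results))) {
      m[results$combo[k], results$trait[k]] <- results[[col]][k]
    }
    m
  }
  if (anyDuplicated(results[, c("combo", "trait")])) {
    stop("heatmap_matrix: duplicate (combo, trait) cells", call. = FALSE)
  }
  list(
    pct = shape("pct_of_control", NA_real_),
    significant = shape("p_value", NA_real_) < alpha,
    classification = shape("classification", NA_character_)
  )
}
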