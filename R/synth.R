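#' Specify a balanced split-plot design
#'
#' A split-plot layout assigns one factor (here a temperature regime) to main
#' plots and a second factor (water regime) to subplots within each main plot.
#' Each (temperature, replicate) pair is one main plot containing every water
#' level exactly once, so a design with `t` temperature levels, `w` water
#' levels and `r` replicates has `t * r` main plots and `t * w * r` pots.
#'
#' @param temp_levels ordered character vector of temperature regime labels;
#'   the first level is the unwarmed control.
#' @param water_levels ordered character vector of water regime labels; the
#'   first level is the well-watered control.
#' @param replicates number of replicates (main plots per temperature level).
#' @return A `design_spec` list.
#' @export
#' @examples
#' design_spec() # 3 x 3 with 10 replicates, 90 pots
design_spec <- function(temp_levels = c("Tamb", "T1", "T2"),
                        water_levels = c("WW", "WS", "SS"),
                        replicates = 10) {
  temp_levels <- as.character(temp_levels)
  water_levels <- as.character(water_levels)
  if (anyDuplicated(temp_levels) || anyDuplicated(water_levels)) {
    stop("design_spec: factor level labels must be unique", call. = FALSE)
  }
  if (length(temp_levels) < 2 || length(water_levels) < 2) {
    stop("design_spec: each factor needs at least 2 levels", call. = FALSE)
  }
  if (!is.numeric(replicates) || length(replicates) != 1 ||
      replicates != round(replicates) || replicates < 2) {
    stop("design_spec: replicates must be an integer >= 2 (a single ",
         "replicate leaves no main-plot error df)", call. = FALSE)
  }
  structure(
    list(temp_levels = temp_levels, water_levels = water_levels,
         replicates = as.integer(replicates)),
    class = "design_spec"
  )
}

#' Build the pot-level design table for a split-plot experiment
#'
#' @param spec a [design_spec()].
#' @return A tibble with one row per pot: `pot_id`, `replicate`, `temp`,
#'   `water`, `mainplot_id`. `mainplot_id` identifies the (temp, replicate)
#'   main plot.
#' @export
#' @examples
#' d <- build_design(design_spec())
#' nrow(d) # 90
#' length(unique(d$mainplot_id)) # 30
build_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  grid <- expand.grid(
    water = spec$water_levels,
    temp = spec$temp_levels,
    replicate = seq_len(spec$replicates),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  tibble::tibble(
    pot_id = sprintf("pot%03d", seq_len(nrow(grid))),
    replicate = as.integer(grid$replicate),
    temp = factor(grid$temp, levels = spec$temp_levels),
    water = factor(grid$water, levels = spec$water_levels),
    mainplot_id = paste0(grid$temp, ".r", grid$replicate)
  )
}

#' Define the generative model of one raw measurement
#'
#' Pot values are generated as
#' \deqn{y = \mu + \alpha_i + \beta_j + (\alpha\beta)_{ij} + m_{ik} + e_{ijk}}
#' with sum-to-zero main effects \eqn{\alpha} (temperature) and \eqn{\beta}
#' (water), an interaction matrix with zero row and column sums, a Gaussian
#' main-plot random effect \eqn{m} shared by all pots of a main plot, and a
#' Gaussian subplot residual \eqn{e}. Sum-to-zero coding makes "additivity"
#' exact: the interaction matrix is precisely the departure from additive
#' expectation, so planted ground truth aligns with the Additivity Index.
#'
#' @param grand_mean trait grand mean (trait units).
#' @param temp_effects numeric, one per temperature level, summing to zero.
#' @param water_effects numeric, one per water level, summing to zero.
#' @param interaction_effects matrix (temp x water) with zero row and column
#'   sums, or NULL for no interaction.
#' @param sigma_mainplot main-plot random-effect SD (>= 0).
#' @param sigma_resid subplot residual SD (>= 0).
#' @return A `trait_model` list.
#' @seealso [trait_model_from_cell_means()] to specify the model as a table
#'   of cell means instead of coded effects.
#' @export
trait_model <- function(grand_mean,
                        temp_effects = c(0, 0, 0),
                        water_effects = c(0, 0, 0),
                        interaction_effects = NULL,
                        sigma_mainplot = 0,
                        sigma_resid = 0) {
  if (is.null(interaction_effects)) {
    interaction_effects <- matrix(
      0, length(temp_effects), length(water_effects))
  }
  interaction_effects <- as.matrix(interaction_effects)
  tol <- 1e-8
  ok <- is.finite(grand_mean) &&
    all(is.finite(temp_effects)) && all(is.finite(water_effects)) &&
    all(is.finite(interaction_effects)) &&
    is.finite(sigma_mainplot) && is.finite(sigma_resid)
  if (!ok) stop("trait_model: all parameters must be finite", call. = FALSE)
  if (sigma_mainplot < 0 || sigma_resid < 0) {
    stop("trait_model: sigmas must be >= 0", call. = FALSE)
  }
  if (abs(sum(temp_effects)) > tol || abs(sum(water_effects)) > tol) {
    stop("trait_model: main effects must sum to zero (sum-to-zero coding)",
         call. = FALSE)
  }
  if (!all(dim(interaction_effects) ==
           c(length(temp_effects), length(water_effects)))) {
    stop("trait_model: interaction matrix must be temp x water", call. = FALSE)
  }
  if (any(abs(rowSums(interaction_effects)) > tol) ||
      any(abs(colSums(interaction_effects)) > tol)) {
    stop("trait_model: interaction matrix needs zero row and column sums",
         call. = FALSE)
  }
  structure(
    list(grand_mean = grand_mean, temp_effects = temp_effects,
         water_effects = water_effects,
         interaction_effects = interaction_effects,
         sigma_mainplot = sigma_mainplot, sigma_resid = sigma_resid),
    class = "trait_model"
  )
}

#' Build a trait model from a table of cell means
#'
#' Decomposes a (temp x water) matrix of target cell means into grand mean,
#' sum-to-zero main effects and the interaction remainder.
#'
#' @param cell_means numeric matrix, rows = temperature levels, columns =
#'   water levels.
#' @inheritParams trait_model
#' @export
trait_model_from_cell_means <- function(cell_means, sigma_mainplot = 0,
                                        sigma_resid = 0) {
  cell_means <- as.matrix(cell_means)
  mu <- mean(cell_means)
  a <- rowMeans(cell_means) - mu
  b <- colMeans(cell_means) - mu
  ab <- cell_means - mu - outer(a, rep(1, ncol(cell_means))) -
    outer(rep(1, nrow(cell_means)), b)
  trait_model(mu, a, b, ab, sigma_mainplot, sigma_resid)
}

# Expected (noise-free) cell mean matrix implied by a trait model.
model_cell_means <- function(model) {
  model$grand_mean +
    outer(model$temp_effects, rep(1, length(model$water_effects))) +
    outer(rep(1, length(model$temp_effects)), model$water_effects) +
    model$interaction_effects
}

#' Simulate one trait over a split-plot design
#'
#' Draws one value per pot from the [trait_model()]: fixed cell mean plus a
#' main-plot random effect shared within each (temp, replicate) main plot
#' plus an independent subplot residual. Fully reproducible from `seed`;
#' main-plot and residual draws use separate named substreams so the values
#' do not depend on row order.
#'
#' @param design design table from [build_design()].
#' @param model a [trait_model()].
#' @param seed integer seed.
#' @param floor optional lower bound enforced by rejection sampling of the
#'   residual draw (at most `max_attempts` redraws per pot), or `NULL`.
#' @param ceiling optional upper bound, same mechanism.
#' @param max_attempts rejection-sampling budget per pot.
#' @return Numeric vector of per-pot values, aligned with `design` rows.
#' @export
simulate_trait <- function(design, model, seed, floor = NULL, ceiling = NULL,
                           max_attempts = 1000) {
  stopifnot(inherits(model, "trait_model"))
  check_design_table(design)
  temps <- levels(design$temp)
  waters <- levels(design$water)
  if (length(model$temp_effects) != length(temps) ||
      length(model$water_effects) != length(waters)) {
    stop("simulate_trait: model effect lengths do not match design levels",
         call. = FALSE)
  }
  cm <- model_cell_means(model)
  mu <- cm[cbind(match(design$temp, temps), match(design$water, waters))]

  mp_ids <- sort(unique(design$mainplot_id))
  mp_draw <- with_seed(derive_seed(seed, "mainplot"),
                       stats::rnorm(length(mp_ids), 0, model$sigma_mainplot))
  names(mp_draw) <- mp_ids
  mean_pot <- mu + mp_draw[design$mainplot_id]

  y <- with_seed(derive_seed(seed, "resid"), {
    val <- mean_pot + stats::rnorm(nrow(design), 0, model$sigma_resid)
    below <- function(v) {
      (!is.null(floor) & v < (floor %||% -Inf)) |
        (!is.null(ceiling) & v > (ceiling %||% Inf))
    }
    bad <- which(below(val))
    attempts <- 0
    while (length(bad) > 0 && attempts < max_attempts) {
      val[bad] <- mean_pot[bad] + stats::rnorm(length(bad), 0,
                                               model$sigma_resid)
      bad <- bad[below(val[bad])]
      attempts <- attempts + 1
    }
    if (length(bad) > 0) {
      stop("simulate_trait: rejection sampling failed to satisfy bounds ",
           "after ", max_attempts, " attempts (mean too far outside bounds)",
           call. = FALSE)
    }
    val
  })
  unname(y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_design_table <- function(design) {
  need <- c("pot_id", "replicate", "temp", "water", "mainplot_id")
  missing <- setdiff(need, names(design))
  if (length(missing) > 0) {
    stop("design table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.factor(design$temp) || !is.factor(design$water)) {
    stop("design table columns temp/water must be factors", call. = FALSE)
  }
  counts <- table(design$temp, design$water)
  if (length(unique(as.vector(counts))) != 1) {
    stop("design table is unbalanced across (temp, water) cells",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Default synthetic scenario for a 3x3x10 warming/water pot experiment
#'
#' Returns a `scenario_config`: the split-plot design plus one [trait_model()]
#' per raw measurement. The default cell means and dispersions emulate a
#' maize pot experiment combining two warming regimes with water and salt
#' stress at the vegetative stage: salt stress is the most damaging single
#' stressor, drought reduces shoot but slightly stimulates root growth,
#' warming increases water consumption, and 15N enrichment of plant tissue
#' sits well above natural abundance. Units: shoot/root dry weight g,
#' water applied L, N concentration mg g^-1, 15N abundance atom%, delta13C
#' per mil vs PDB.
#'
#' @param design a [design_spec()] (defaults to 3 temperature x 3 water
#'   regimes, 10 replicates).
#' @param raw_measurement_models named list of [trait_model()]s for
#'   `shoot_dw`, `root_dw`, `water_applied`, `n_conc`, `atom_pct_15N`,
#'   `delta13C`; defaults supplied for a 3x3 design.
#' @param constants [isotope_constants()] used to bound simulated 15N
#'   abundance.
#' @param seed default master seed stored with the scenario (overridable in
#'   [simulate_raw_experiment()]).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(design = design_spec(),
                            raw_measurement_models = NULL,
                            constants = isotope_constants(),
                            seed = 1L) {
  stopifnot(inherits(design, "design_spec"))
  if (is.null(raw_measurement_models)) {
    if (length(design$temp_levels) != 3 || length(design$water_levels) != 3) {
      stop("scenario_config: default measurement models require a 3x3 ",
           "design; supply raw_measurement_models for other layouts",
           call. = FALSE)
    }
    raw_measurement_models <- default_measurement_models()
  }
  need <- c("shoot_dw", "root_dw", "water_applied", "n_conc",
            "atom_pct_15N", "delta13C")
  missing <- setdiff(need, names(raw_measurement_models))
  if (length(missing) > 0) {
    stop("scenario_config: missing measurement model(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(design = design, raw_measurement_models = raw_measurement_models,
         constants = constants, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# Cell means (rows Tamb/T1/T2 x cols WW/WS/SS) chosen to emulate observed
# magnitudes in a vegetative-stage maize pot trial under warming x water/salt
# stress; residual SDs sized so 95% CIs of 10-replicate mean differences have
# realistic widths. See the methods vignette for the derivation.
default_measurement_models <- function() {
  cm <- function(m) matrix(m, nrow = 3, byrow = TRUE)
  list(
    shoot_dw = trait_model_from_cell_means(
      cm(c(1.240, 0.992, 0.628,
           1.173, 0.940, 0.580,
           1.182, 0.854, 0.563)),
      sigma_mainplot = 0.04, sigma_resid = 0.12),
    root_dw = trait_model_from_cell_means(
      cm(c(0.687, 0.758, 0.316,
           0.684, 0.729, 0.257,
           0.630, 0.694, 0.383)),
      sigma_mainplot = 0.03, sigma_resid = 0.09),
    water_applied = trait_model_from_cell_means(
      cm(c(1.640, 1.403, 0.953,
           1.784, 1.466, 1.004,
           1.873, 1.554, 1.141)),
      sigma_mainplot = 0.03, sigma_resid = 0.08),
    n_conc = trait_model_from_cell_means(
      cm(c(23.6, 23.7, 27.4,
           23.6, 24.3, 28.4,
           23.2, 23.8, 26.9)),
      sigma_mainplot = 0.4, sigma_resid = 1.2),
    atom_pct_15N = trait_model_from_cell_means(
      cm(c(1.13, 0.91, 1.02,
           1.27, 0.89, 0.97,
           1.21, 0.90, 0.84)),
      sigma_mainplot = 0.03, sigma_resid = 0.09),
    delta13C = trait_model_from_cell_means(
      cm(c(-13.94, -14.12, -14.09,
           -13.91, -14.11, -13.94,
           -13.97, -14.00, -13.99)),
      sigma_mainplot = 0.03, sigma_resid = 0.09)
  )
}

#' Simulate a raw split-plot pot experiment
#'
#' Generates one row per pot with all six raw measurements, each drawn from
#' its [trait_model()] on an independent named RNG substream (so adding or
#' reordering measurements never perturbs the others). Masses and water are
#' kept strictly positive, and 15N abundance inside
#' \[natural abundance, fertilizer atom%\], by bounded rejection sampling.
#'
#' @param config a [scenario_config()].
#' @param seed master seed; defaults to the seed stored in `config`.
#' @return A tibble of pot records: design columns plus `shoot_dw_g`,
#'   `root_dw_g`, `water_applied_L`, `n_conc_mg_g`, `atom_pct_15N`,
#'   `delta13C_permil`.
#' @export
#' @examples
#' pots <- simulate_raw_experiment(scenario_config(), seed = 7)
#' dim(pots)
simulate_raw_experiment <- function(config = scenario_config(),
                                    seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  design <- build_design(config$design)
  k <- config$constants
  bounds <- list(
    shoot_dw = c(1e-3, Inf),
    root_dw = c(1e-3, Inf),
    water_applied = c(1e-3, Inf),
    n_conc = c(1e-2, Inf),
    atom_pct_15N = c(k$natural_abundance_atom_pct, k$fert_atom_pct_15N),
    delta13C = c(-Inf, Inf)
  )
  out <- design
  colmap <- c(shoot_dw = "shoot_dw_g", root_dw = "root_dw_g",
              water_applied = "water_applied_L", n_conc = "n_conc_mg_g",
              atom_pct_15N = "atom_pct_15N", delta13C = "delta13C_permil")
  for (meas in names(colmap)) {
    b <- bounds[[meas]]
    out[[colmap[[meas]]]] <- simulate_trait(
      design, config$raw_measurement_models[[meas]],
      seed = derive_seed(seed, "measurement", meas),
      floor = if (is.finite(b[1])) b[1] else NULL,
      ceiling = if (is.finite(b[2])) b[2] else NULL
    )
  }
  out$mainplot_id <- NULL
  out
}

#' Write / read a pot-record table as CSV
#'
#' Fixed header contract: `pot_id, replicate, temp, water, shoot_dw_g,
#' root_dw_g, water_applied_L, n_conc_mg_g, atom_pct_15N, delta13C_permil`.
#'
#' @param pots pot-record tibble from [simulate_raw_experiment()] (or
#'   measured data with the same columns).
#' @param path CSV file path.
#' @param temp_levels,water_levels optional explicit factor level order for
#'   reading; defaults to order of first appearance.
#' @return `write_pot_csv` returns `path` invisibly; `read_pot_csv` returns
#'   the pot tibble.
#' @export
write_pot_csv <- function(pots, path) {
  need <- pot_csv_columns()
  missing <- setdiff(need, names(pots))
  if (length(missing) > 0) {
    stop("pot table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(as.data.frame(pots)[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pot_csv
#' @export
read_pot_csv <- function(path, temp_levels = NULL, water_levels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(pot_csv_columns(), names(df))
  if (length(missing) > 0) {
    stop("pot CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$temp <- factor(df$temp, levels = temp_levels %||% unique(df$temp))
  df$water <- factor(df$water, levels = water_levels %||% unique(df$water))
  tibble::as_tibble(df)
}

pot_csv_columns <- function() {
  c("pot_id", "replicate", "temp", "water", "shoot_dw_g", "root_dw_g",
    "water_applied_L", "n_conc_mg_g", "atom_pct_15N", "delta13C_permil")
}
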