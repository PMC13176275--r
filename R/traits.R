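#' Isotope and fertilizer constants
#'
#' Constants used by the isotope-based trait equations: the natural abundance
#' of 15N (0.3663 atom%), the delta13C of atmospheric CO2 (-8.15 per mil vs
#' PDB), the 15N enrichment of the labelled fertilizer (10 atom%) and the
#' amount of fertilizer applied per pot used as the denominator of percent
#' recovery. The default `fert_amount_g` is the fertilizer *nitrogen* mass
#' per pot (190 mg ammonium sulfate x 0.212 g N per g = 0.0403 g N); set
#' `fert_basis = "fertilizer"` (with the corresponding mass, e.g. 0.190 g)
#' to express recovery per unit fertilizer mass instead.
#'
#' @param natural_abundance_atom_pct natural 15N abundance, atom%.
#' @param delta13C_air_permil delta13C of air, per mil.
#' @param fert_atom_pct_15N fertilizer 15N abundance, atom%.
#' @param fert_amount_g amount of fertilizer per pot, g (N basis by default).
#' @param fert_basis `"N"` or `"fertilizer"`; metadata recording what
#'   `fert_amount_g` measures.
#' @return An `isotope_constants` list.
#' @export
isotope_constants <- function(natural_abundance_atom_pct = 0.3663,
                              delta13C_air_permil = -8.15,
                              fert_atom_pct_15N = 10,
                              fert_amount_g = 0.0403,
                              fert_basis = c("N", "fertilizer")) {
  fert_basis <- match.arg(fert_basis)
  if (fert_atom_pct_15N <= natural_abundance_atom_pct) {
    stop("isotope_constants: fertilizer atom% must exceed natural abundance",
         call. = FALSE)
  }
  if (fert_amount_g <= 0) {
    stop("isotope_constants: fert_amount_g must be > 0", call. = FALSE)
  }
  structure(
    list(natural_abundance_atom_pct = natural_abundance_atom_pct,
         delta13C_air_permil = delta13C_air_permil,
         fert_atom_pct_15N = fert_atom_pct_15N,
         fert_amount_g = fert_amount_g,
         fert_basis = fert_basis),
    class = "isotope_constants"
  )
}

#' Total nitrogen uptake
#'
#' N content of the biomass, `N_t = biomass (g) x N concentration (mg g^-1)
#' / 1000`, in g N per pot.
#'
#' @param biomass_g biomass dry weight, g.
#' @param n_conc_mg_g N concentration of the biomass, mg N per g dry weight.
#' @return g N per pot.
#' @export
#' @examples
#' n_uptake(2.0, 15) # 0.030 g
n_uptake <- function(biomass_g, n_conc_mg_g) {
  if (any(biomass_g < 0, na.rm = TRUE) || any(n_conc_mg_g < 0, na.rm = TRUE)) {
    stop("n_uptake: inputs must be >= 0", call. = FALSE)
  }
  biomass_g * n_conc_mg_g / 1000
}

#' Fertilizer-derived nitrogen by isotope dilution
#'
#' The amount of fertilizer-derived N recovered in the plant,
#' \deqn{^{15}N_{rec} = N_t \frac{atom\%^{15}N_{plant} - 0.3663}
#'       {atom\%^{15}N_{fert} - 0.3663},}
#' i.e. plant N times the ratio of plant to fertilizer 15N excess over
#' natural abundance, and the percent recovery
#' \eqn{100 \cdot {}^{15}N_{rec} / f} where `f` is the amount of fertilizer
#' applied per pot (`constants$fert_amount_g`).
#'
#' @param n_uptake_g plant N content, g per pot.
#' @param atom_pct_plant 15N abundance of the plant material, atom%.
#' @param constants an [isotope_constants()].
#' @return A list with `amount_g` (g N per pot) and `percent`.
#' @export
#' @examples
#' n15_recovery(0.040, 1.3297, isotope_constants(fert_amount_g = 0.040))
n15_recovery <- function(n_uptake_g, atom_pct_plant,
                         constants = isotope_constants()) {
  na <- constants$natural_abundance_atom_pct
  if (any(atom_pct_plant < na - 1e-12, na.rm = TRUE)) {
    stop("n15_recovery: plant atom% 15N below natural abundance (",
         na, ")", call. = FALSE)
  }
  excess_ratio <- (atom_pct_plant - na) / (constants$fert_atom_pct_15N - na)
  amount <- n_uptake_g * excess_ratio
  list(amount_g = amount, percent = 100 * amount / constants$fert_amount_g)
}

#' Carbon-isotope discrimination
#'
#' \deqn{\Delta = \frac{\delta^{13}C_{air} - \delta^{13}C_{plant}}
#'       {1 + \delta^{13}C_{plant}/1000}}
#' with \eqn{\delta^{13}C_{air} = -8.15} per mil by default. Delta
#' integrates the plant's depletion in 13C relative to source air and is
#' strictly decreasing in the plant delta13C.
#'
#' @param delta13C_plant plant delta13C, per mil vs PDB; must be > -1000.
#' @param constants an [isotope_constants()].
#' @return Discrimination, per mil.
#' @export
#' @examples
#' discrimination(-12.15) # about 4.05
discrimination <- function(delta13C_plant,
                           constants = isotope_constants()) {
  if (any(delta13C_plant <= -1000, na.rm = TRUE)) {
    stop("discrimination: delta13C_plant must be > -1000 per mil",
         call. = FALSE)
  }
  (constants$delta13C_air_permil - delta13C_plant) /
    (1 + delta13C_plant / 1000)
}

#' Water- and nitrogen-use efficiency
#'
#' `wue()` is biomass produced per litre of water applied (g L^-1); `nue()`
#' is biomass produced per g of N taken up (g g^-1).
#'
#' @param biomass_g biomass dry weight, g.
#' @param water_L total water applied, L (> 0).
#' @param n_uptake_g plant N content, g (> 0).
#' @return Numeric ratio.
#' @export
#' @examples
#' wue(2.0, 4.0) # 0.5
#' nue(1.5, 0.030) # 50
wue <- function(biomass_g, water_L) {
  if (any(water_L <= 0, na.rm = TRUE)) {
    stop("wue: water_L must be > 0", call. = FALSE)
  }
  biomass_g / water_L
}

#' @rdname wue
#' @export
nue <- function(biomass_g, n_uptake_g) {
  if (any(n_uptake_g <= 0, na.rm = TRUE)) {
    stop("nue: n_uptake_g must be > 0", call. = FALSE)
  }
  biomass_g / n_uptake_g
}

#' Names of the nine analysis traits
#'
#' The trait set entering the contrast plan, the Additivity Index, the
#' split-plot ANOVA and the canonical discriminant analysis. Percent
#' fertilizer recovery (`n15_recovery_pct`) is the recovery trait analysed;
#' the absolute amount (`n15_recovery_g`) is carried alongside in the trait
#' table.
#'
#' @return Character vector of length 9.
#' @export
analysis_traits <- function() {
  c("shoot", "root", "water_consumption", "WUE", "n_concentration",
    "n_uptake", "n15_recovery_pct", "NUE", "delta13C_discrimination")
}

#' Derive the full trait table from raw pot records
#'
#' Computes the nine analysis traits for every pot: shoot and root biomass
#' (g), water consumption (L), WUE (g L^-1), N concentration (mg g^-1), N
#' uptake (g), 15N fertilizer recovery (g and %), NUE (g g^-1) and
#' carbon-isotope discrimination (per mil). Biomass entering N uptake, WUE
#' and NUE is shoot + root by default (the composite shoot+root sample is
#' what gets analysed for N and isotopes); set `biomass = "shoot"` for
#' shoot-only accounting.
#'
#' Rows with missing raw fields propagate `NA` trait values with a warning;
#' missing columns are an error naming the column.
#'
#' @param pot_table pot records with the columns written by
#'   [write_pot_csv()].
#' @param constants an [isotope_constants()].
#' @param biomass `"total"` (shoot + root) or `"shoot"`.
#' @return A tibble: design columns (`pot_id`, `replicate`, `temp`, `water`,
#'   `treatment`) plus ten trait columns (`n15_recovery_g` and
#'   `n15_recovery_pct` jointly represent the recovery trait).
#' @export
#' @examples
#' pots <- simulate_raw_experiment(scenario_config(), seed = 7)
#' traits <- derive_traits(pots)
derive_traits <- function(pot_table, constants = isotope_constants(),
                          biomass = c("total", "shoot")) {
  biomass <- match.arg(biomass)
  need <- setdiff(pot_csv_columns(), "pot_id")
  missing <- setdiff(need, names(pot_table))
  if (length(missing) > 0) {
    stop("derive_traits: input is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw_cols <- c("shoot_dw_g", "root_dw_g", "water_applied_L", "n_conc_mg_g",
                "atom_pct_15N", "delta13C_permil")
  n_missing <- sum(!stats::complete.cases(pot_table[, raw_cols]))
  if (n_missing > 0) {
    warning("derive_traits: ", n_missing, " row(s) with missing raw ",
            "measurements; trait values propagated as NA", call. = FALSE)
  }
  bm <- if (biomass == "total") {
    pot_table$shoot_dw_g + pot_table$root_dw_g
  } else {
    pot_table$shoot_dw_g
  }
  nt <- n_uptake(bm, pot_table$n_conc_mg_g)
  rec <- n15_recovery(nt, pot_table$atom_pct_15N, constants)
  out <- tibble::tibble(
    pot_id = if ("pot_id" %in% names(pot_table)) pot_table$pot_id else
      sprintf("pot%03d", seq_len(nrow(pot_table))),
    replicate = pot_table$replicate,
    temp = as.factor(pot_table$temp),
    water = as.factor(pot_table$water),
    shoot = pot_table$shoot_dw_g,
    root = pot_table$root_dw_g,
    water_consumption = pot_table$water_applied_L,
    WUE = wue(bm, pot_table$water_applied_L),
    n_concentration = pot_table$n_conc_mg_g,
    n_uptake = nt,
    n15_recovery_g = rec$amount_g,
    n15_recovery_pct = rec$percent,
    NUE = nue(bm, nt),
    delta13C_discrimination = discrimination(pot_table$delta13C_permil,
                                             constants)
  )
  out$treatment <- treatment_label(out$temp, out$water)
  out
}

#' Compound treatment labels for a two-factor stress experiment
#'
#' Maps (temp, water) pairs to the conventional nine treatment labels: the
#' double control is named by the water control ("WW"), warming alone by its
#' temperature level ("T1", "T2"), water/salt stress alone by its water
#' level ("WS", "SS"), and combinations as "WS(T1)" etc. The first level of
#' each factor is taken as its control.
#'
#' @param temp,water factors of equal length.
#' @return Factor of treatment labels, ordered control first.
#' @export
treatment_label <- function(temp, water) {
  temp <- as.factor(temp); water <- as.factor(water)
  t0 <- levels(temp)[1]; w0 <- levels(water)[1]
  lab <- ifelse(
    temp == t0 & water == w0, w0,
    ifelse(water == w0, as.character(temp),
           ifelse(temp == t0, as.character(water),
                  paste0(water, "(", temp, ")")))
  )
  lvls <- unlist(lapply(levels(water), function(w) {
    lapply(levels(temp), function(t) {
      if (t == t0 && w == w0) w0
      else if (w == w0) t
      else if (t == t0) w
      else paste0(w, "(", t, ")")
    })
  }))
  factor(lab, levels = unique(lvls))
}

#' Write / read the trait table as CSV
#'
#' Fixed trait column contract: `shoot, root, water_consumption, WUE,
#' n_concentration, n_uptake, n15_recovery_g, n15_recovery_pct, NUE,
#' delta13C_discrimination`, preceded by the design columns.
#'
#' @param traits trait tibble from [derive_traits()].
#' @param path CSV file path.
#' @export
write_trait_csv <- function(traits, path) {
  cols <- c("pot_id", "replicate", "temp", "water", "treatment",
            "shoot", "root", "water_consumption", "WUE", "n_concentration",
            "n_uptake", "n15_recovery_g", "n15_recovery_pct", "NUE",
            "delta13C_discrimination")
  missing <- setdiff(cols, names(traits))
  if (length(missing) > 0) {
    stop("trait table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(as.data.frame(traits)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_csv
#' @export
read_trait_csv <- function(path, temp_levels = NULL, water_levels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$temp <- factor(df$temp, levels = temp_levels %||% unique(df$temp))
  df$water <- factor(df$water, levels = water_levels %||% unique(df$water))
  df$treatment <- treatment_label(df$temp, df$water)
  tibble::as_tibble(df)
}

#' @rdname write_trait_csv
#' @param temp_levels,water_levels optional explicit factor level order.
#' @name write_trait_csv
NULL
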