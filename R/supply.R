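#' Colonic bacterial biomass model
#'
#' Constants describing the bacterial biomass in the human colon that is
#' available as a vitamin source.  Intracellular vitamins are assumed to
#' become available to the host on cell lysis, so the available biomass is
#' `n_cells * cell_dry_mass * dead_fraction`.
#'
#' @param n_cells Bacterial cells in the colonic space (default `1e14`).
#' @param cell_dry_mass Dry mass per cell in gDW (default `4.89e-13`,
#'   measured for *E. coli*).
#' @param dead_fraction Fraction of cells lysed and releasing their
#'   contents (default `0.317`, the measured dead-cell ratio in feces).
#' @param cell_volume Cell volume in litres (default `1.1e-15`, i.e.
#'   1.1 cubic micrometres, *E. coli*).
#' @param growth_rate Anaerobic growth rate in per hour (default `0.26`,
#'   *E. coli*), used to integrate production-rate measurements.
#' @return A `cell_model` list.
#' @examples
#' cell_model()
#' @export
cell_model <- function(n_cells = 1e14, cell_dry_mass = 4.89e-13,
                       dead_fraction = 0.317, cell_volume = 1.1e-15,
                       growth_rate = 0.26) {
  vals <- c(n_cells = n_cells, cell_dry_mass = cell_dry_mass,
            dead_fraction = dead_fraction, cell_volume = cell_volume,
            growth_rate = growth_rate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    vs_stop("all cell model constants must be strictly positive")
  if (dead_fraction > 1)
    vs_stop("dead_fraction must lie in (0, 1]")
  structure(as.list(vals), class = "cell_model")
}

#' Avogadro constant used by the package
#' @return mol^-1.
#' @export
avogadro <- function() 6.02214e23

#' Convert an intracellular vitamin measurement to mmol/gDW
#'
#' Literature measurements of intracellular vitamin content come in
#' heterogeneous units; this converts them to the common basis of
#' millimole per gram cell dry weight using the cell model constants.
#'
#' Conversions by unit:
#' \describe{
#'   \item{`molar`}{mol/L: `value * cell_volume / cell_dry_mass`.}
#'   \item{`mass_per_volume`}{g/L: divided by `molar_mass` first.}
#'   \item{`molecules_per_cell`}{`value / (Avogadro * cell_dry_mass)`.}
#'   \item{`mass_per_gdw`}{g/gDW: `value / molar_mass`.}
#'   \item{`production_rate_per_mgdw`}{mol h^-1 mgDW^-1: divided by the
#'     growth rate (content at steady state) and rescaled mgDW to gDW.}
#' }
#'
#' @param value Positive measurement value in the SI base unit of its
#'   kind (mol/L, g/L, molecules, g/gDW, or mol h^-1 mgDW^-1).
#' @param unit One of the five unit kinds above.
#' @param cell A [cell_model()].
#' @param molar_mass g/mol; required for the mass-based units.
#' @return Concentration in mmol/gDW.
#' @examples
#' to_mmol_per_gdw(4e-6, "molar")               # 4 uM riboflavin
#' to_mmol_per_gdw(3e-6, "mass_per_gdw", molar_mass = 345.3)
#' @export
to_mmol_per_gdw <- function(value,
                            unit = c("molar", "mass_per_volume",
                                     "molecules_per_cell", "mass_per_gdw",
                                     "production_rate_per_mgdw"),
                            cell = cell_model(), molar_mass = NULL) {
  unit <- match.arg(unit)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0)
    vs_stop("measurement value must be a single positive number")
  needs_mm <- unit %in% c("mass_per_volume", "mass_per_gdw")
  if (needs_mm && (is.null(molar_mass) || molar_mass <= 0))
    vs_stop("molar_mass is required for unit '", unit, "'")
  mol_per_gdw <- switch(unit,
    molar = value * cell$cell_volume / cell$cell_dry_mass,
    mass_per_volume = (value / molar_mass) * cell$cell_volume /
      cell$cell_dry_mass,
    molecules_per_cell = value / (avogadro() * cell$cell_dry_mass),
    mass_per_gdw = value / molar_mass,
    production_rate_per_mgdw = value / cell$growth_rate * 1000)
  mol_per_gdw * 1000
}

#' Percent of the dietary reference intake suppliable by the microbiota
#'
#' The maximal daily vitamin amount the gut microbiota could provide is
#' the intracellular concentration times the lysed biomass
#' (`n_cells * cell_dry_mass * dead_fraction`) times the molar mass
#' (mmol times g/mol is numerically mg), scaled by the fraction of gut
#' genomes predicted to produce the vitamin, and expressed relative to
#' the human dietary reference intake:
#' `%DRI = conc * biomass * molar_mass * hgm_ratio / dri * 100`.
#'
#' @param conc_mmol_per_gdw Intracellular concentration, mmol/gDW.
#' @param dri_mg_per_day Dietary reference intake, mg/day (must be > 0).
#' @param hgm_ratio Fraction of gut genomes predicted producers, in
#'   `[0, 1]`.
#' @param molar_mass g/mol of the measured vitamin form.
#' @param cell A [cell_model()].
#' @return Percent of the DRI.
#' @examples
#' percent_dri(9.0e-7, 0.03, 0.40, 244.31)   # biotin
#' @export
percent_dri <- function(conc_mmol_per_gdw, dri_mg_per_day, hgm_ratio,
                        molar_mass, cell = cell_model()) {
  if (!is.numeric(dri_mg_per_day) || dri_mg_per_day <= 0)
    vs_stop("DRI must be strictly positive")
  if (hgm_ratio < 0 || hgm_ratio > 1)
    vs_stop("hgm_ratio must lie in [0, 1]")
  if (conc_mmol_per_gdw < 0 || molar_mass <= 0)
    vs_stop("concentration must be >= 0 and molar mass > 0")
  biomass_g <- cell$n_cells * cell$cell_dry_mass * cell$dead_fraction
  vitamin_mg <- conc_mmol_per_gdw * biomass_g * molar_mass
  vitamin_mg * hgm_ratio / dri_mg_per_day * 100
}

#' Packaged supply-model parameters
#'
#' Reads the per-vitamin constants shipped with the package (or a
#' user-supplied YAML of the same layout): canonical intracellular
#' concentration in mmol/gDW, DRI in mg/day, predicted producer ratio in
#' the gut cohort, and the molar mass of the measured chemical form
#' (dihydrofolic acid, nicotinic acid, pyridoxine 5'-phosphate and
#' thiamine monophosphate where applicable).
#'
#' @param path YAML constants file; defaults to the packaged one.
#' @return List with `cell` (a [cell_model()]) and `vitamins` (data frame
#'   with one row per vitamin in canonical order).
#' @export
supply_parameters <- function(path = system.file("extdata",
                                                 "supply_constants.yaml",
                                                 package = "vitasynth",
                                                 mustWork = TRUE)) {
  cfg <- yaml::read_yaml(path)
  cm <- do.call(cell_model, cfg$cell_model)
  vits <- bvitamins()
  missing_v <- setdiff(vits, names(cfg$vitamins))
  if (length(missing_v))
    vs_stop("supply constants missing vitamin(s): ",
            paste(missing_v, collapse = ", "))
  tab <- do.call(rbind, lapply(vits, function(v) {
    p <- cfg$vitamins[[v]]
    data.frame(vitamin = v,
               conc_mmol_per_gdw = p$conc_mmol_per_gdw,
               dri_mg_per_day = p$dri_mg_per_day,
               hgm_producer_ratio = p$hgm_producer_ratio,
               molar_mass = p$molar_mass)
  }))
  if (any(tab$hgm_producer_ratio < 0 | tab$hgm_producer_ratio > 1))
    vs_stop("hgm_producer_ratio must lie in [0, 1]")
  if (any(tab[, -1] <= 0)) vs_stop("supply constants must be positive")
  list(cell = cm, vitamins = tab)
}

#' Read intracellular vitamin measurements
#'
#' TSV with columns `vitamin`, `organism`, `value`, `unit`, one row per
#' vitamin; values in the SI base unit of their kind (see
#' [to_mmol_per_gdw()]).  Defaults to the packaged literature
#' transcription.
#'
#' @param path Measurement TSV path.
#' @return Data frame of measurements.
#' @export
read_measurements <- function(path = system.file("extdata",
                                                 "vitamin_measurements.tsv",
                                                 package = "vitasynth",
                                                 mustWork = TRUE)) {
  df <- read_tsv(path)
  need <- c("vitamin", "organism", "value", "unit")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    vs_stop("measurements file missing column(s): ",
            paste(missing_cols, collapse = ", "))
  df$value <- as.numeric(df$value)
  bad <- setdiff(unique(df$vitamin), bvitamins())
  if (length(bad))
    vs_stop("measurement vitamin(s) outside the canonical list: ",
            paste(bad, collapse = ", "))
  if (anyDuplicated(df$vitamin))
    vs_stop("more than one measurement per vitamin: ",
            df$vitamin[duplicated(df$vitamin)][1])
  df
}

#' Build the microbiota vitamin supply table
#'
#' Chains measurement conversion and the supply formula into the
#' per-vitamin summary table: intracellular concentration (mmol/gDW), DRI
#' (mg/day), predicted gut producer ratio, and the percent of the DRI the
#' gut microbiota could maximally supply.
#'
#' The %DRI column is always computed from the canonical concentration in
#' `params`; when `measurements` are given, the independently converted
#' concentration is reported alongside (`conc_converted`) and any row
#' where the two disagree by more than 5% relative (i.e. beyond mere
#' rounding of the canonical 2-significant-figure value) is flagged in
#' the `discrepant` column and reported via a warning.  Two literature
#' values (biotin, a hundredfold, and niacin, about 15%) are known to
#' disagree with the canonical column this way.
#'
#' @param measurements Optional measurement data frame
#'   (see [read_measurements()]).
#' @param params Supply parameters (see [supply_parameters()]).
#' @param cell A [cell_model()]; defaults to the one in `params`.
#' @return Data frame with one row per vitamin in canonical order and
#'   columns `vitamin`, `conc_mmol_per_gdw`, `conc_converted` (NA without
#'   measurements), `dri_mg_per_day`, `hgm_producer_ratio`,
#'   `percent_dri`, `discrepant`.
#' @examples
#' tab <- build_supply_table()
#' tab[, c("vitamin", "percent_dri")]
#' @export
build_supply_table <- function(measurements = NULL,
                               params = supply_parameters(),
                               cell = params$cell) {
  tab <- params$vitamins
  tab$conc_converted <- NA_real_
  if (!is.null(measurements)) {
    idx <- match(tab$vitamin, measurements$vitamin)
    for (k in seq_len(nrow(tab))) {
      if (is.na(idx[k])) next
      m <- measurements[idx[k], ]
      tab$conc_converted[k] <- to_mmol_per_gdw(
        m$value, m$unit, cell = cell, molar_mass = tab$molar_mass[k])
    }
  }
  tab$percent_dri <- mapply(percent_dri, tab$conc_mmol_per_gdw,
                            tab$dri_mg_per_day, tab$hgm_producer_ratio,
                            tab$molar_mass, MoreArgs = list(cell = cell))
  tab$discrepant <- !is.na(tab$conc_converted) &
    abs(tab$conc_converted - tab$conc_mmol_per_gdw) /
      tab$conc_mmol_per_gdw > 0.05
  if (any(tab$discrepant))
    warning("converted measurement disagrees with the canonical ",
            "concentration for: ",
            paste(tab$vitamin[tab$discrepant], collapse = ", "),
            " (canonical column used for %DRI)")
  tab[, c("vitamin", "conc_mmol_per_gdw", "conc_converted",
          "dri_mg_per_day", "hgm_producer_ratio", "molar_mass",
          "percent_dri", "discrepant")]
}
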