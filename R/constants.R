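#' Physical and accounting constants
#'
#' Bundles the constants used throughout the inorganic-carbon accounting
#' pipeline. Defaults follow the values used in the global compilation the
#' package implements:
#'
#' * `lambda_pb210`: decay constant of lead-210, `log(2)/22.3` yr^-1
#'   (half-life 22.3 yr).
#' * `f_c`: carbon mass fraction of CaCO3, 0.12 (the rounded mass ratio used
#'   for all Cinorg conversions; the molar-exact value 12.011/100.087 can be
#'   supplied instead).
#' * `psi`: mol CO2 emitted to the atmosphere-seawater system per mol CaCO3
#'   precipitated, ~0.6.
#' * `seagrass_area_low`/`seagrass_area_high`: global seagrass extent range,
#'   150,000-600,000 km^2.
#' * `mangrove_area`: global mangrove extent, 137,760 km^2.
#' * `tropical_area_fraction`: fraction of seagrass area in the tropical and
#'   subtropical zone, 2/3.
#'
#' @param lambda_pb210 210Pb decay constant, yr^-1.
#' @param f_c Carbon mass fraction of CaCO3, in (0, 1).
#' @param psi Mol CO2 emitted per mol CaCO3 precipitated, in (0, 1).
#' @param seagrass_area_low,seagrass_area_high Global seagrass area bounds, km^2.
#' @param mangrove_area Global mangrove area, km^2.
#' @param tropical_area_fraction Fraction of seagrass area in the tropics, (0, 1).
#' @param caco3_molar_mass,carbon_molar_mass Molar masses, g mol^-1.
#' @return An object of class `bc_constants` (a validated named list).
#' @examples
#' cst <- bc_constants()
#' cst$f_c    # 0.12
#' cst$psi    # 0.6
#' @export
bc_constants <- function(lambda_pb210 = log(2) / 22.3,
                         f_c = 0.12,
                         psi = 0.6,
                         seagrass_area_low = 150000,
                         seagrass_area_high = 600000,
                         mangrove_area = 137760,
                         tropical_area_fraction = 2 / 3,
                         caco3_molar_mass = 100.087,
                         carbon_molar_mass = 12.011) {
  cst <- list(
    lambda_pb210 = lambda_pb210, f_c = f_c, psi = psi,
    seagrass_area_low = seagrass_area_low,
    seagrass_area_high = seagrass_area_high,
    mangrove_area = mangrove_area,
    tropical_area_fraction = tropical_area_fraction,
    caco3_molar_mass = caco3_molar_mass,
    carbon_molar_mass = carbon_molar_mass
  )
  for (nm in names(cst)) {
    if (!is_scalar_number(cst[[nm]]))
      stop_with("config_error", "constant '%s' must be a finite number", nm)
  }
  if (cst$lambda_pb210 <= 0)
    stop_with("config_error", "lambda_pb210 must be > 0")
  if (cst$f_c <= 0 || cst$f_c >= 1)
    stop_with("config_error", "f_c must lie in (0, 1)")
  if (cst$psi <= 0 || cst$psi >= 1)
    stop_with("config_error", "psi must lie in (0, 1)")
  if (cst$seagrass_area_low <= 0 || cst$seagrass_area_high <= 0 ||
      cst$mangrove_area <= 0)
    stop_with("config_error", "areal extents must be > 0")
  if (cst$seagrass_area_low > cst$seagrass_area_high)
    stop_with("config_error",
              "seagrass_area_low (%g) exceeds seagrass_area_high (%g)",
              cst$seagrass_area_low, cst$seagrass_area_high)
  if (cst$tropical_area_fraction <= 0 || cst$tropical_area_fraction >= 1)
    stop_with("config_error", "tropical_area_fraction must lie in (0, 1)")
  structure(cst, class = "bc_constants")
}

#' Load constants, optionally overridden from a YAML file
#'
#' With no file, returns [bc_constants()] defaults. A YAML file may override
#' individual fields; unknown fields and out-of-range values are rejected.
#'
#' @param path Path to a YAML file of overrides, or `NULL` for defaults.
#' @return A `bc_constants` object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(bc_constants())
  if (!file.exists(path))
    stop_with("config_error", "config file not found: %s", path)
  overrides <- yaml::read_yaml(path)
  if (!is.list(overrides))
    stop_with("config_error", "config file must be a YAML mapping")
  allowed <- names(formals(bc_constants))
  bad <- setdiff(names(overrides), allowed)
  if (length(bad) > 0)
    stop_with("config_error", "unknown config field(s): %s",
              paste(bad, collapse = ", "))
  do.call(bc_constants, overrides)
}

#' @export
print.bc_constants <- function(x, ...) {
  cat("Blue Carbon inorganic-carbon accounting constants:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %g\n", nm, x[[nm]]))
  invisible(x)
}
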