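#' Mean CaCO3 content of post-1900 slices
#'
#' @param core A [sediment_core()].
#' @param mask Logical per-slice mask, normally from [post1900_mask()].
#' @return Unweighted arithmetic mean CaCO3 %DW over masked-in slices with a
#'   measured value.
#' @export
mean_caco3_post1900 <- function(core, mask) {
  vals <- core$slices$caco3_pct[mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    stop_with("validation_error",
              "core '%s': no post-1900 slice with measured CaCO3", core$core_id)
  mean(vals)
}

#' Inorganic-carbon concentration from bulk density and CaCO3 content
#'
#' `Cinorg = DBD x (CaCO3%/100) x f_c`, with `f_c` the carbon mass fraction
#' of CaCO3 (0.12 by default).
#'
#' @param dbd_mean Dry bulk density, g cm^-3.
#' @param caco3_pct CaCO3 content, % dry weight.
#' @param constants A [bc_constants()].
#' @return Concentration in gC cm^-3 (multiply by 1000 for mgC cm^-3).
#' @examples
#' cinorg_concentration(1.0, 61)  # 0.0732 gC cm-3 = 73.2 mgC cm-3
#' @export
cinorg_concentration <- function(dbd_mean, caco3_pct,
                                 constants = bc_constants()) {
  if (any(dbd_mean <= 0))
    stop_with("validation_error", "dry bulk density must be > 0")
  if (any(caco3_pct < 0 | caco3_pct > 100))
    stop_with("validation_error", "caco3_pct must lie in [0, 100]")
  dbd_mean * (caco3_pct / 100) * constants$f_c
}

#' Inorganic-carbon burial rate
#'
#' Product of the sediment accretion rate and the Cinorg concentration,
#' converted from per-cm^2 to per-m^2. Cores with negligible CaCO3 yield a
#' burial rate of zero and are retained in all downstream statistics.
#'
#' @param sar Sediment accretion rate, cm yr^-1.
#' @param cinorg_conc Cinorg concentration, gC cm^-3.
#' @return Burial rate, gC m^-2 yr^-1.
#' @export
burial_rate <- function(sar, cinorg_conc) {
  if (any(sar <= 0)) stop_with("validation_error", "sar must be > 0")
  if (any(cinorg_conc < 0))
    stop_with("validation_error", "cinorg_conc must be >= 0")
  sar * cinorg_conc * 1e4
}

#' Convert between CaCO3 and Cinorg mass rates
#'
#' Cinorg mass is the fraction `f_c` (12% by default) of CaCO3 mass; the two
#' conversions are exact inverses.
#'
#' @param caco3_rate Rate in gCaCO3 m^-2 yr^-1.
#' @param cinorg_rate Rate in gCinorg m^-2 yr^-1.
#' @param constants A [bc_constants()].
#' @return The converted rate.
#' @examples
#' cinorg_from_caco3(1886)  # 226.3 gCinorg m-2 yr-1
#' caco3_from_cinorg(6)     # 50 gCaCO3 m-2 yr-1
#' @export
cinorg_from_caco3 <- function(caco3_rate, constants = bc_constants()) {
  if (any(caco3_rate < 0)) stop_with("validation_error", "rate must be >= 0")
  caco3_rate * constants$f_c
}

#' @rdname cinorg_from_caco3
#' @export
caco3_from_cinorg <- function(cinorg_rate, constants = bc_constants()) {
  if (any(cinorg_rate < 0)) stop_with("validation_error", "rate must be >= 0")
  cinorg_rate / constants$f_c
}

#' Vertical accretion rate equivalent of a CaCO3 burial rate
#'
#' @param caco3_burial Burial rate, gCaCO3 m^-2 yr^-1.
#' @param effective_density Density converting mass flux to thickness,
#'   g cm^-3 (bulk sediment or CaCO3 mineral density, at the user's choice;
#'   no default is claimed).
#' @return Accretion, cm yr^-1.
#' @export
caco3_accretion <- function(caco3_burial, effective_density) {
  if (any(effective_density <= 0))
    stop_with("validation_error", "effective_density must be > 0")
  (caco3_burial / 1e4) / effective_density
}

#' Per-core carbonate accounting
#'
#' Chains the post-1900 window, CaCO3 averaging, Cinorg concentration and
#' burial-rate steps for one core. The dry bulk density entering the
#' concentration is the mean DBD over the same post-1900 window as the CaCO3
#' mean. For undated cores (`chron = NULL`) only the concentration-level
#' quantities are produced, over all slices, and the rates are `NA`.
#'
#' @param core A [sediment_core()].
#' @param chron A `cfcs_chronology`, or `NULL` for undated cores.
#' @param constants A [bc_constants()].
#' @return One-row `data.frame`: `core_id`, `caco3_pct_post1900`,
#'   `dbd_post1900`, `cinorg_conc` (gC cm^-3), `cinorg_burial`
#'   (gC m^-2 yr^-1), `caco3_burial` (gCaCO3 m^-2 yr^-1), `caco3_accretion`
#'   (cm yr^-1, using the post-1900 bulk density), `sar`, `n_slices_used`.
#' @export
core_carbonate <- function(core, chron, constants = bc_constants()) {
  mask <- if (is.null(chron)) rep(TRUE, nrow(core$slices))
  else post1900_mask(core, chron)
  caco3 <- mean_caco3_post1900(core, mask)
  dbd <- mean(core$slices$dry_bulk_density[mask])
  conc <- cinorg_concentration(dbd, caco3, constants)
  if (is.null(chron)) {
    burial <- caco3_b <- accr <- sar <- NA_real_
  } else {
    sar <- chron$sar
    burial <- burial_rate(sar, conc)
    caco3_b <- caco3_from_cinorg(burial, constants)
    accr <- caco3_accretion(caco3_b, dbd)
  }
  data.frame(core_id = core$core_id, caco3_pct_post1900 = caco3,
             dbd_post1900 = dbd, cinorg_conc = conc, cinorg_burial = burial,
             caco3_burial = caco3_b, caco3_accretion = accr, sar = sar,
             n_slices_used = sum(mask & !is.na(core$slices$caco3_pct)))
}
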