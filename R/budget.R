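#' CO2 emission from net calcification
#'
#' Calcification releases CO2 to the atmosphere-seawater system at a ratio
#' of ~0.6 mol CO2 per mol CaCO3 precipitated (`psi`). In carbon-mass units
#' the emission is simply `psi` times the net calcification rate expressed
#' as Cinorg. Negative net calcification (net dissolution) yields a negative
#' emission - a CO2 uptake - and is reported signed, never clamped.
#'
#' @param net_calcification_c Net community calcification (calcification
#'   minus dissolution), gC m^-2 yr^-1 in Cinorg units; may be negative.
#' @param psi Mol CO2 emitted per mol CaCO3 precipitated, in (0, 1).
#' @return Emission, gC m^-2 yr^-1.
#' @examples
#' co2_emission(6, 0.6)   # 3.6
#' @export
co2_emission <- function(net_calcification_c, psi = 0.6) {
  if (psi <= 0 || psi >= 1)
    stop_with("validation_error", "psi must lie in (0, 1)")
  psi * net_calcification_c
}

#' Net CO2 sequestration of a site
#'
#' Net uptake by primary production minus the calcification-driven CO2
#' emission; dissolution (negative emission) adds to the sink.
#'
#' @param npp_uptake Net CO2 uptake by primary production, gC m^-2 yr^-1.
#' @param co2_emission Emission from [co2_emission()], gC m^-2 yr^-1.
#' @return Net sequestration, gC m^-2 yr^-1.
#' @examples
#' net_sequestration(8.4, 3.6)  # 4.8
#' @export
net_sequestration <- function(npp_uptake, co2_emission) {
  npp_uptake - co2_emission
}

#' Offset of a CO2 sink by calcification emission
#'
#' @param emission CO2 emission, gC m^-2 yr^-1 (or any matching units).
#' @param reference_uptake Reference CO2 uptake (e.g. net primary
#'   production), same units, must be > 0.
#' @return Percentage offset, unrounded; round for presentation.
#' @export
offset_fraction <- function(emission, reference_uptake) {
  if (any(reference_uptake <= 0))
    stop_with("validation_error", "reference_uptake must be > 0")
  100 * emission / reference_uptake
}

#' Allochthonous fraction of the buried carbonate
#'
#' Mass balance: burial not supported by local net calcification must come
#' from allochthonous inputs, so the fraction is
#' `1 - max(net_calcification, 0) / burial`, clamped to `[0, 1]`. When local
#' production exceeds burial the fraction is 0 and the result carries the
#' attribute `note = "local production exceeds burial"`.
#'
#' @param net_calcification_c Net calcification, gC m^-2 yr^-1 (Cinorg units).
#' @param cinorg_burial Cinorg burial rate, gC m^-2 yr^-1, must be > 0.
#' @return Fraction in `[0, 1]`.
#' @examples
#' allochthonous_fraction(6, 226)   # 0.973
#' allochthonous_fraction(45, 149)  # 0.698
#' @export
allochthonous_fraction <- function(net_calcification_c, cinorg_burial) {
  if (cinorg_burial <= 0)
    stop_with("validation_error", "cinorg_burial must be > 0")
  local_prod <- max(net_calcification_c, 0)
  frac <- 1 - local_prod / cinorg_burial
  if (frac < 0) {
    frac <- 0
    attr(frac, "note") <- "local production exceeds burial"
  }
  frac
}

#' Site carbon budget
#'
#' Combines the emission, sequestration and mass-balance terms for one site
#' and classifies it as a net CO2 sink, source, or neutral by the sign of
#' the net sequestration.
#'
#' @param npp_uptake Net CO2 uptake by primary production, gC m^-2 yr^-1.
#' @param net_calcification_c Net calcification, gC m^-2 yr^-1 (Cinorg units).
#' @param cinorg_burial Optional Cinorg burial rate, gC m^-2 yr^-1 (enables
#'   the allochthonous fraction).
#' @param corg_burial Optional Corg burial rate, gC m^-2 yr^-1, carried
#'   through for ratio reporting.
#' @param psi Emission factor, see [co2_emission()].
#' @return Object of class `carbon_budget`: `co2_emission`,
#'   `net_sequestration`, `offset_pct`, `allochthonous_fraction` (`NA`
#'   without burial), `classification`, plus the inputs.
#' @examples
#' site_budget(npp_uptake = 8.4, net_calcification_c = 6, cinorg_burial = 226)
#' @export
site_budget <- function(npp_uptake, net_calcification_c,
                        cinorg_burial = NA_real_, corg_burial = NA_real_,
                        psi = 0.6) {
  emission <- co2_emission(net_calcification_c, psi)
  seq <- net_sequestration(npp_uptake, emission)
  offset <- if (npp_uptake > 0) offset_fraction(emission, npp_uptake)
  else NA_real_
  alloch <- if (!is.na(cinorg_burial))
    as.numeric(allochthonous_fraction(net_calcification_c, cinorg_burial))
  else NA_real_
  tol <- 1e-9 * max(1, abs(npp_uptake), abs(emission))
  classification <- if (seq > tol) "net_sink"
  else if (seq < -tol) "net_source" else "neutral"
  structure(list(npp_uptake = npp_uptake,
                 net_calcification_c = net_calcification_c,
                 cinorg_burial = cinorg_burial, corg_burial = corg_burial,
                 psi = psi, co2_emission = emission,
                 net_sequestration = seq, offset_pct = offset,
                 allochthonous_fraction = alloch,
                 classification = classification),
            class = "carbon_budget")
}

#' @export
print.carbon_budget <- function(x, ...) {
  cat(sprintf("<carbon_budget> emission %.3g, net sequestration %.3g gC m-2 yr-1 (%s)\n",
              x$co2_emission, x$net_sequestration, x$classification))
  if (!is.na(x$offset_pct))
    cat(sprintf("  offset of NPP uptake: %.1f%%\n", x$offset_pct))
  if (!is.na(x$allochthonous_fraction))
    cat(sprintf("  allochthonous fraction of burial: %.2f\n",
                x$allochthonous_fraction))
  invisible(x)
}

#' Global emission and offset implied by a burial range
#'
#' Worst-case accounting: if all buried CaCO3 were produced in situ, global
#' Cinorg burial would imply an emission of `psi` times the burial bounds,
#' offsetting the Corg-burial CO2 sink by the emission-to-Corg ratio. Bounds
#' are paired index-wise (low emission against low Corg burial, high against
#' high) by default; `pairing = "envelope"` instead forms the min/max
#' envelope over the cross pairings.
#'
#' @param cinorg_burial_tg Length-2 Cinorg burial range, Tg yr^-1.
#' @param corg_burial_tg Length-2 Corg burial range, Tg yr^-1.
#' @param psi Emission factor.
#' @param pairing `"indexwise"` (default) or `"envelope"`.
#' @return List: `emissions_tg` (length-2), `offset_pct` (length-2,
#'   unrounded), `presented_emissions`, `presented_offset`.
#' @examples
#' global_offset(c(13, 62), c(48, 112))
#' @export
global_offset <- function(cinorg_burial_tg, corg_burial_tg, psi = 0.6,
                          pairing = c("indexwise", "envelope")) {
  pairing <- match.arg(pairing)
  stopifnot(length(cinorg_burial_tg) == 2, length(corg_burial_tg) == 2)
  if (any(cinorg_burial_tg < 0) || any(corg_burial_tg <= 0))
    stop_with("validation_error", "ranges must be positive")
  emissions <- psi * cinorg_burial_tg
  offsets <- if (pairing == "indexwise") {
    100 * emissions / corg_burial_tg
  } else {
    all_pairs <- 100 * outer(emissions, corg_burial_tg, "/")
    range(all_pairs)
  }
  # Presentation convention: a range whose upper bound reaches 10 Tg is
  # printed with integer bounds, and presented offsets are recomputed from
  # those printed emissions (so 7.8-37.2 Tg prints "8"/"37" and, against
  # 48-112 Tg Corg, offsets of "17"/"33").
  pres_em <- if (max(emissions) >= 10) round(emissions) else round(emissions, 1)
  pres_off <- if (pairing == "indexwise") 100 * pres_em / corg_burial_tg
  else range(100 * outer(pres_em, corg_burial_tg, "/"))
  list(emissions_tg = emissions, offset_pct = offsets,
       presented_emissions = if (max(emissions) >= 10)
         sprintf("%d", as.integer(pres_em)) else format_tg(emissions),
       presented_offset = sprintf("%d", as.integer(round(pres_off))))
}

#' Cinorg burial as a percentage of Corg burial
#'
#' @param cinorg_tg_range,corg_tg_range Length-2 ranges, Tg yr^-1, paired
#'   index-wise.
#' @return Percentage range (length-2, unrounded) with attribute
#'   `presented` (nearest integers).
#' @examples
#' equivalence_ratio(c(15, 62), c(48, 112))  # 31.25 55.36 -> "31-55%"
#' @export
equivalence_ratio <- function(cinorg_tg_range, corg_tg_range) {
  stopifnot(length(cinorg_tg_range) == 2, length(corg_tg_range) == 2)
  if (any(cinorg_tg_range < 0) || any(corg_tg_range <= 0))
    stop_with("validation_error", "ranges must be positive")
  pct <- 100 * cinorg_tg_range / corg_tg_range
  attr(pct, "presented") <- sprintf("%d", as.integer(round(pct)))
  pct
}
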