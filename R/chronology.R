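#' Estimate supported 210Pb activity
#'
#' The constant flux-constant sedimentation (CF:CS) model works on excess
#' (unsupported) 210Pb, i.e. total activity minus the component in secular
#' equilibrium with 226Ra. When a measured supported activity is available
#' (`method = "given"`) the mean of the per-slice values is used; otherwise
#' the asymptote of the profile is estimated from the deepest slices
#' (`method = "deep_plateau"`), where excess 210Pb has decayed away.
#'
#' @param core A [sediment_core()].
#' @param method `"deep_plateau"` (mean total activity of the `n_deep`
#'   deepest slices) or `"given"` (mean of the `pb210_supported` column).
#' @param n_deep Number of deepest slices for the plateau estimate.
#' @return Supported activity, Bq kg^-1. A warning is raised when the
#'   estimate exceeds the minimum total activity shallower in the profile
#'   (the plateau may not have been reached).
#' @export
estimate_supported <- function(core, method = c("deep_plateau", "given"),
                               n_deep = 3) {
  method <- match.arg(method)
  sl <- core$slices
  if (method == "given") {
    if (anyNA(sl$pb210_supported))
      stop_with("estimation_error",
                "core '%s': pb210_supported missing on some slices",
                core$core_id)
    supported <- mean(sl$pb210_supported)
  } else {
    if (nrow(sl) < n_deep)
      stop_with("estimation_error",
                "core '%s': %d slices < n_deep = %d", core$core_id,
                nrow(sl), n_deep)
    deep <- utils::tail(sl$pb210_total, n_deep)
    supported <- mean(deep)
    upper <- utils::head(sl$pb210_total, nrow(sl) - n_deep)
    if (length(upper) > 0 && supported > min(upper, na.rm = TRUE))
      warning(sprintf(
        "core '%s': supported estimate (%.3g Bq/kg) exceeds minimum total activity in the upper profile; plateau may not be reached",
        core$core_id, supported), call. = FALSE)
  }
  supported
}

#' Cumulative dry mass at slice midpoints
#'
#' Converts the depth scale into the mass-depth coordinate on which CF:CS is
#' defined: `m_i` is the dry mass per unit area (g cm^-2) accumulated above
#' the midpoint of slice `i`, i.e. the full mass of all shallower slices
#' plus half of slice `i`'s own mass.
#'
#' @param core A [sediment_core()].
#' @return Numeric vector, strictly increasing, g cm^-2.
#' @export
cumulative_mass <- function(core) {
  sl <- core$slices
  if (anyNA(sl$dry_bulk_density))
    stop_with("validation_error", "core '%s': missing dry bulk density",
              core$core_id)
  slice_mass <- sl$dry_bulk_density * slice_thickness(sl)
  mid <- slice_midpoints(sl)
  cumsum(c(0, slice_mass[-length(slice_mass)])) +
    sl$dry_bulk_density * (mid - sl$depth_top)
}

#' Fit the constant flux-constant sedimentation (CF:CS) 210Pb model
#'
#' Under CF:CS, excess 210Pb decays exponentially with cumulative dry mass:
#' `A_xs(m) = A_0 exp(-lambda m / MAR)`, so a least-squares regression of
#' `ln(A_xs)` on cumulative mass `m` has slope `-lambda / MAR`. The mass
#' accumulation rate is `MAR = lambda / |slope|` (g cm^-2 yr^-1), the
#' sediment accretion rate is `SAR = MAR / DBD` with `DBD` the mass-weighted
#' mean dry bulk density of the fitted slices, and the age of slice `i` is
#' `m_i / MAR` years before coring. Slices with non-positive excess are
#' excluded from the regression (never clamped into the log domain) but
#' still receive ages by extrapolation of the fitted rate.
#'
#' @param core A [sediment_core()].
#' @param constants A [bc_constants()] (supplies `lambda_pb210`).
#' @param supported Supported 210Pb level, Bq kg^-1. Default: the `given`
#'   method when a full `pb210_supported` column exists, otherwise the
#'   deep-plateau estimate with `n_deep = 3` (see [estimate_supported()]).
#' @param coordinate `"mass"` (regression on cumulative mass, the default)
#'   or `"depth"` (regression on midpoint depth, for sensitivity analyses;
#'   then `SAR = lambda / |slope|` and `MAR = SAR x DBD`).
#' @param weighting `"none"` (ordinary least squares, default) or
#'   `"activity_err"` (inverse-variance weights `(A_xs / err)^2` on the log
#'   scale, requires `pb210_total_err`).
#' @return Object of class `cfcs_chronology`: `mar`, `sar`, `surface_excess`,
#'   `slope`, `r_squared`, `n_points`, `supported_level`, `slice_ages` (yr
#'   before coring, one per slice), `slice_years` (calendar year CE),
#'   `coordinate`, `weighting`.
#' @examples
#' cst <- bc_constants()
#' m <- (0:9) + 0.5
#' sl <- data.frame(depth_top = 0:9, depth_bottom = 1:10,
#'                  dry_bulk_density = 1,
#'                  pb210_total = 25 + 500 * exp(-cst$lambda_pb210 * m / 0.10),
#'                  caco3_pct = 50)
#' core <- sediment_core("demo", sl, coring_year = 2015)
#' ch <- fit_cfcs(core, cst, supported = 25)
#' ch$mar   # 0.10 g cm-2 yr-1
#' @export
fit_cfcs <- function(core, constants = bc_constants(), supported = NULL,
                     coordinate = c("mass", "depth"),
                     weighting = c("none", "activity_err")) {
  coordinate <- match.arg(coordinate)
  weighting <- match.arg(weighting)
  sl <- core$slices
  if (is.null(supported)) {
    supported <- if (!anyNA(sl$pb210_supported))
      estimate_supported(core, "given")
    else estimate_supported(core, "deep_plateau", n_deep = 3)
  }
  excess <- sl$pb210_total - supported
  m <- cumulative_mass(core)
  x <- if (coordinate == "mass") m else slice_midpoints(sl)
  use <- !is.na(excess) & excess > 0
  if (sum(use) < 3)
    stop_with("fit_error",
              "core '%s': only %d slice(s) with positive excess 210Pb (need >= 3)",
              core$core_id, sum(use))
  w <- NULL
  if (weighting == "activity_err") {
    if (anyNA(sl$pb210_total_err[use]))
      stop_with("fit_error", "core '%s': activity errors required for weighting",
                core$core_id)
    w <- (excess[use] / sl$pb210_total_err[use])^2
  }
  fit <- stats::lm(log(excess[use]) ~ x[use], weights = w)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop_with("fit_error", "core '%s': no decay trend (slope >= 0)",
              core$core_id)
  lambda <- constants$lambda_pb210
  slice_mass <- sl$dry_bulk_density * slice_thickness(sl)
  dbd_mw <- stats::weighted.mean(sl$dry_bulk_density[use], slice_mass[use])
  if (coordinate == "mass") {
    mar <- lambda / abs(slope)
    sar <- mar / dbd_mw
    ages <- m / mar
  } else {
    sar <- lambda / abs(slope)
    mar <- sar * dbd_mw
    ages <- slice_midpoints(sl) / sar
  }
  structure(
    list(mar = mar, sar = sar,
         surface_excess = exp(unname(stats::coef(fit)[1])),
         slope = slope,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         n_points = sum(use),
         supported_level = supported,
         slice_ages = ages,
         slice_years = core$coring_year - ages,
         coordinate = coordinate, weighting = weighting),
    class = "cfcs_chronology"
  )
}

#' @export
print.cfcs_chronology <- function(x, ...) {
  cat(sprintf(
    "<cfcs_chronology> MAR %.4g g cm-2 yr-1, SAR %.4g cm yr-1 (r2 %.3f, n %d)\n",
    x$mar, x$sar, x$r_squared, x$n_points))
  cat(sprintf("  supported %.3g Bq/kg; %s-coordinate regression, %s weights\n",
              x$supported_level, x$coordinate, x$weighting))
  invisible(x)
}

#' Mask of slices deposited since 1900
#'
#' Contemporary (twentieth-century) accounting uses only slices whose
#' midpoint, per the fitted chronology, is younger than calendar year 1900.
#'
#' @param core A [sediment_core()].
#' @param chron A `cfcs_chronology` for that core.
#' @return Logical vector, `TRUE` where the slice midpoint year is >= 1900.
#' @export
post1900_mask <- function(core, chron) {
  if (length(chron$slice_years) != nrow(core$slices))
    stop_with("validation_error",
              "chronology has %d ages but core '%s' has %d slices",
              length(chron$slice_years), core$core_id, nrow(core$slices))
  chron$slice_years >= 1900
}
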