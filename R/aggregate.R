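#' Group cores into global locations
#'
#' Cores from the same site or area with the same presence/absence of
#' allochthonous CaCO3 sources (coral reef or lithogenic) are treated as
#' replicates of one global location and averaged; cores sharing a
#' `location_key` but differing in source flags are split into distinct
#' groups.
#'
#' @param cores List of [sediment_core()].
#' @param carbonate `data.frame` of per-core results from [core_carbonate()]
#'   (row-bound), keyed by `core_id`.
#' @return `data.frame`, one row per (location_key, ecosystem, source state):
#'   `n_cores`, mean and SE (`NA` when `n_cores < 2`) of `sar`,
#'   `caco3_pct`, `cinorg_conc` and `cinorg_burial`, plus `is_tropical` and
#'   `has_alloch_source`.
#' @export
group_locations <- function(cores, carbonate) {
  per_core <- do.call(rbind, lapply(cores, function(co) {
    row <- carbonate[carbonate$core_id == co$core_id, , drop = FALSE]
    if (nrow(row) != 1)
      stop_with("validation_error",
                "carbonate table must have exactly one row for core '%s'",
                co$core_id)
    data.frame(core_id = co$core_id, location_key = co$location_key,
               ecosystem = co$ecosystem, is_tropical = co$is_tropical,
               has_alloch_source = co$coral_reef_present || co$lithogenic_present,
               sar = row$sar, caco3_pct = row$caco3_pct_post1900,
               cinorg_conc = row$cinorg_conc,
               cinorg_burial = row$cinorg_burial)
  }))
  key <- interaction(per_core$location_key, per_core$ecosystem,
                     per_core$has_alloch_source, drop = TRUE)
  out <- lapply(split(per_core, key), function(grp) {
    mse <- function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) return(c(NA_real_, NA_real_))
      c(mean(x), if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_)
    }
    stats_tab <- vapply(grp[c("sar", "caco3_pct", "cinorg_conc",
                              "cinorg_burial")], mse, numeric(2))
    data.frame(location_key = grp$location_key[1],
               ecosystem = grp$ecosystem[1],
               n_cores = nrow(grp),
               is_tropical = any(grp$is_tropical),
               has_alloch_source = grp$has_alloch_source[1],
               sar_mean = stats_tab[1, "sar"], sar_se = stats_tab[2, "sar"],
               caco3_pct_mean = stats_tab[1, "caco3_pct"],
               caco3_pct_se = stats_tab[2, "caco3_pct"],
               cinorg_conc_mean = stats_tab[1, "cinorg_conc"],
               cinorg_conc_se = stats_tab[2, "cinorg_conc"],
               cinorg_burial_mean = stats_tab[1, "cinorg_burial"],
               cinorg_burial_se = stats_tab[2, "cinorg_burial"])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize a distribution the way skewed burial data demand
#'
#' Reports both the median (IQR) and the mean (SE); burial-rate and CaCO3
#' distributions in this field are strongly non-normal, so the median (IQR)
#' is the preferred central tendency and the normality screen (Shapiro-Wilk
#' at alpha = 0.05) is attached as an advisory flag. Quantiles use linear
#' interpolation between order statistics (the convention interpolating at
#' index `p(n-1)`, R's default type 7); IQR values depend on this choice.
#'
#' @param values Numeric vector (NAs dropped).
#' @return Object of class `distribution_summary`: `n`, `median`, `iqr`,
#'   `mean`, `se`, `normal_flag` (`NA` when `n < 3` or the values are
#'   constant).
#' @examples
#' summarize_distribution(c(1, 2, 3, 100))  # median 2.5, IQR 25.5
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0)
    stop_with("validation_error", "no non-missing values to summarize")
  n <- length(values)
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  se <- if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_
  normal_flag <- NA
  if (n >= 3 && n <= 5000 && stats::sd(values) > 0)
    normal_flag <- stats::shapiro.test(values)$p.value > 0.05
  structure(list(n = n, median = qs[2], iqr = qs[3] - qs[1],
                 mean = mean(values), se = se, normal_flag = normal_flag),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("n = %d: median (IQR) %.4g (%.4g); mean (SE) %.4g (%.4g)%s\n",
              x$n, x$median, x$iqr, x$mean,
              if (is.na(x$se)) NA else x$se,
              if (isTRUE(x$normal_flag)) ""
              else if (isFALSE(x$normal_flag)) " [non-normal]"
              else ""))
  invisible(x)
}

#' Scale an areal burial rate to a global annual burial
#'
#' `Tg yr^-1 = rate (g m^-2 yr^-1) x area (km^2) x 10^6 (m^2/km^2) / 10^12
#' (g/Tg)`.
#'
#' @param rate Areal rate, gC m^-2 yr^-1.
#' @param area_low,area_high Global areal extent bounds, km^2.
#' @return Object of class `global_estimate`: `burial_low`, `burial_high`
#'   (TgC yr^-1, unrounded) and `presented` (character, whole Tg at >= 10,
#'   one decimal below).
#' @examples
#' global_burial(87, 150000, 600000)   # 13.05 and 52.2 -> "13" "52"
#' global_burial(6, 137760, 137760)    # 0.83 -> "0.8"
#' @export
global_burial <- function(rate, area_low, area_high = area_low) {
  if (any(rate < 0)) stop_with("validation_error", "rate must be >= 0")
  if (area_low <= 0 || area_high <= 0)
    stop_with("validation_error", "areas must be > 0")
  if (area_low > area_high)
    stop_with("validation_error", "area_low exceeds area_high")
  lo <- rate * area_low * 1e-6
  hi <- rate * area_high * 1e-6
  structure(list(rate = rate, area_low = area_low, area_high = area_high,
                 burial_low = lo, burial_high = hi,
                 presented = format_tg(c(lo, hi))),
            class = "global_estimate")
}

#' @export
print.global_estimate <- function(x, ...) {
  cat(sprintf(
    "global burial: %s to %s Tg yr-1 (rate %.4g gC m-2 yr-1 x %g-%g km2)\n",
    x$presented[1], x$presented[2], x$rate, x$area_low, x$area_high))
  invisible(x)
}

#' Global burial partitioned between tropical and higher-latitude zones
#'
#' Applies zone-specific areal rates to an areal split of the global extent:
#' the tropical zone receives `tropical_fraction` of the area (2/3 for
#' seagrass by default), the higher-latitude zone the remainder; the `sum`
#' row adds the zone bounds. With equal rates in both zones the sum
#' reproduces the unpartitioned [global_burial()] exactly.
#'
#' @param tropical_rate,highlat_rate Areal rates, gC m^-2 yr^-1.
#' @param area_low,area_high Global extent bounds, km^2.
#' @param tropical_fraction Fraction of the extent in the tropics, (0, 1).
#' @return `data.frame` with rows `tropical`, `higher_lat`, `sum`:
#'   `rate`, `area_low`, `area_high`, `burial_low`, `burial_high`,
#'   `presented_low`, `presented_high`.
#' @export
partitioned_global <- function(tropical_rate, highlat_rate,
                               area_low, area_high,
                               tropical_fraction = 2 / 3) {
  if (tropical_rate < 0 || highlat_rate < 0)
    stop_with("validation_error", "rates must be >= 0")
  if (tropical_fraction <= 0 || tropical_fraction >= 1)
    stop_with("validation_error", "tropical_fraction must lie in (0, 1)")
  trop <- global_burial(tropical_rate, tropical_fraction * area_low,
                        tropical_fraction * area_high)
  high <- global_burial(highlat_rate, (1 - tropical_fraction) * area_low,
                        (1 - tropical_fraction) * area_high)
  lo <- c(trop$burial_low, high$burial_low,
          trop$burial_low + high$burial_low)
  hi <- c(trop$burial_high, high$burial_high,
          trop$burial_high + high$burial_high)
  data.frame(zone = c("tropical", "higher_lat", "sum"),
             rate = c(tropical_rate, highlat_rate, NA),
             area_low = c(trop$area_low, high$area_low, area_low),
             area_high = c(trop$area_high, high$area_high, area_high),
             burial_low = lo, burial_high = hi,
             presented_low = format_tg(lo), presented_high = format_tg(hi))
}
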