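#' Hedges' g standardized mean difference
#'
#' Standardized difference between an experimental and a control group with
#' the small-sample bias correction `J`:
#' \deqn{g = \frac{(\bar X_E - \bar X_C)\,J}{SD_{pooled}}, \quad
#'   SD_{pooled} = \sqrt{\frac{(n_E-1)SD_E^2 + (n_C-1)SD_C^2}{n_E+n_C-2}},}
#' \deqn{J = 1 - \frac{3}{4(n_E+n_C-2)-1}, \quad
#'   V_g = \frac{n_E+n_C}{n_E n_C} + \frac{g^2}{2(n_E+n_C)}.}
#'
#' @param mean_exp,sd_exp,n_exp Mean, SD and sample size of the experimental
#'   group (e.g. vegetated cores); `n >= 2`.
#' @param mean_ctrl,sd_ctrl,n_ctrl Same for the control group (e.g.
#'   unvegetated cores).
#' @param study_id Optional label carried through to pooling.
#' @return Object of class `effect_size`: `g`, `v_g`, `sd_pooled`, `j`,
#'   `n_exp`, `n_ctrl`, `study_id`.
#' @examples
#' es <- hedges_g(10, 2, 5, 8, 2, 5)
#' es$g    # 0.90323
#' es$v_g  # 0.44079
#' @export
hedges_g <- function(mean_exp, sd_exp, n_exp, mean_ctrl, sd_ctrl, n_ctrl,
                     study_id = NA_character_) {
  if (n_exp < 2 || n_ctrl < 2)
    stop_with("validation_error",
              "both groups need n >= 2 for a variance-bearing effect size")
  if (sd_exp < 0 || sd_ctrl < 0)
    stop_with("validation_error", "standard deviations must be >= 0")
  sd_pooled <- sqrt(((n_exp - 1) * sd_exp^2 + (n_ctrl - 1) * sd_ctrl^2) /
                      (n_exp + n_ctrl - 2))
  if (sd_pooled == 0)
    stop_with("undefined_effect_error",
              "pooled SD is zero; effect size undefined")
  j <- 1 - 3 / (4 * (n_exp + n_ctrl - 2) - 1)
  g <- (mean_exp - mean_ctrl) * j / sd_pooled
  v_g <- (n_exp + n_ctrl) / (n_exp * n_ctrl) + g^2 / (2 * (n_exp + n_ctrl))
  structure(list(g = g, v_g = v_g, sd_pooled = sd_pooled, j = j,
                 n_exp = n_exp, n_ctrl = n_ctrl, study_id = study_id),
            class = "effect_size")
}

#' Random-effects pooling of effect sizes (DerSimonian-Laird)
#'
#' Pools per-study Hedges' g values under a one-level random-effects model:
#' the DerSimonian-Laird moment estimator gives the between-study variance
#' `tau^2`, studies are weighted by `1/(V_g + tau^2)`, and the pooled effect
#' is tested against zero with a normal z-test.
#'
#' @param effects List of [hedges_g()] objects, or a numeric vector of g
#'   values (then `v` must be given).
#' @param v Numeric vector of effect-size variances when `effects` is
#'   numeric.
#' @return Object of class `pooled_effect`: `g_pooled`, `se_pooled`,
#'   `z_value`, `p_value`, `tau2`, `k`.
#' @export
pool_random_effects <- function(effects, v = NULL) {
  if (is.list(effects) && inherits(effects[[1]], "effect_size")) {
    g <- vapply(effects, `[[`, numeric(1), "g")
    v <- vapply(effects, `[[`, numeric(1), "v_g")
  } else {
    g <- as.numeric(effects)
    if (is.null(v) || length(v) != length(g))
      stop_with("validation_error", "variances v must accompany numeric g")
  }
  if (any(v <= 0)) stop_with("validation_error", "variances must be > 0")
  k <- length(g)
  if (k == 1) {
    tau2 <- 0
  } else {
    w_fixed <- 1 / v
    g_fixed <- sum(w_fixed * g) / sum(w_fixed)
    q <- sum(w_fixed * (g - g_fixed)^2)
    c_dl <- sum(w_fixed) - sum(w_fixed^2) / sum(w_fixed)
    tau2 <- max(0, (q - (k - 1)) / c_dl)
  }
  w <- 1 / (v + tau2)
  g_pooled <- sum(w * g) / sum(w)
  se_pooled <- sqrt(1 / sum(w))
  z <- g_pooled / se_pooled
  structure(list(g_pooled = g_pooled, se_pooled = se_pooled,
                 z_value = z, p_value = 2 * stats::pnorm(-abs(z)),
                 tau2 = tau2, k = k),
            class = "pooled_effect")
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf(
    "<pooled_effect> k = %d: g = %.3f (SE %.3f), z = %.2f, p = %.3f, tau2 = %.3f\n",
    x$k, x$g_pooled, x$se_pooled, x$z_value, x$p_value, x$tau2))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test. The U statistic is reported for the first argument
#' (`U = R_a - n_a(n_a+1)/2` with `R_a` the rank sum of `a` in the pooled
#' sample). P-values are exact by enumeration of the null permutation
#' distribution when `n_a + n_b <= 12` and the data are tie-free, otherwise
#' a tie-corrected, continuity-corrected normal approximation is used
#' (delegating to [stats::wilcox.test()]). Two-sided by default.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param method `"auto"` (exact when small and tie-free), `"exact"` or
#'   `"normal"`.
#' @param alternative Passed to the test; default `"two.sided"`.
#' @return List: `U`, `p_value`, `method` (the method actually used).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "normal"),
                         alternative = "two.sided") {
  method <- match.arg(method)
  if (length(a) == 0 || length(b) == 0)
    stop_with("validation_error", "both groups must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (method == "auto")
    method <- if (na + nb <= 12 && !has_ties) "exact" else "normal"
  if (method == "exact" && has_ties) method <- "normal"
  if (length(unique(c(a, b))) == 1L)  # fully tied: U at its null mean
    return(list(U = u, p_value = 1, method = "degenerate"))
  p <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = alternative,
    exact = (method == "exact"), correct = TRUE
  )$p.value)
  if (is.nan(p)) p <- 1
  list(U = u, p_value = p, method = method)
}

#' Vegetated-versus-unvegetated paired contrast
#'
#' Meta-analysis of paired vegetated/unvegetated CaCO3 %DW comparisons: one
#' Hedges' g per study (vegetated as the experimental group), pooled under
#' the one-level random-effects model of [pool_random_effects()]. Studies
#' where either habitat has fewer than two cores are excluded, since their
#' SD cannot be calculated.
#'
#' @param studies `data.frame` with columns `study_id`, `mean_veg`,
#'   `sd_veg`, `n_veg`, `mean_unveg`, `sd_unveg`, `n_unveg`.
#' @return A `pooled_effect` with extra fields `effects` (the per-study
#'   effect-size table) and `excluded` (character vector of dropped study
#'   ids).
#' @export
paired_vegetation_contrast <- function(studies) {
  need <- c("study_id", "mean_veg", "sd_veg", "n_veg",
            "mean_unveg", "sd_unveg", "n_unveg")
  miss <- setdiff(need, names(studies))
  if (length(miss) > 0)
    stop_with("schema_error", "studies table missing column(s): %s",
              paste(miss, collapse = ", "))
  ok <- studies$n_veg >= 2 & studies$n_unveg >= 2
  excluded <- as.character(studies$study_id[!ok])
  studies <- studies[ok, , drop = FALSE]
  if (nrow(studies) == 0)
    stop_with("validation_error",
              "no study has n >= 2 in both habitat groups")
  effects <- lapply(seq_len(nrow(studies)), function(i)
    hedges_g(studies$mean_veg[i], studies$sd_veg[i], studies$n_veg[i],
             studies$mean_unveg[i], studies$sd_unveg[i], studies$n_unveg[i],
             study_id = as.character(studies$study_id[i])))
  pooled <- pool_random_effects(effects)
  pooled$effects <- data.frame(
    study_id = vapply(effects, `[[`, character(1), "study_id"),
    g = vapply(effects, `[[`, numeric(1), "g"),
    v_g = vapply(effects, `[[`, numeric(1), "v_g"))
  pooled$excluded <- excluded
  pooled
}
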