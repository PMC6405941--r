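# Independent oracles and fixture builders used across the suite.

# Build a core from a vector of total 210Pb activities; one slice per value.
make_core <- function(totals, dbd = 1, thickness = 1, caco3 = 50,
                      coring_year = 2015, core_id = "T1", ...) {
  n <- length(totals)
  sediment_core(
    core_id,
    data.frame(depth_top = (seq_len(n) - 1) * thickness,
               depth_bottom = seq_len(n) * thickness,
               dry_bulk_density = rep_len(dbd, n),
               pb210_total = totals,
               caco3_pct = rep_len(caco3, n)),
    coring_year = coring_year, ...
  )
}

# Noiseless CF:CS core: excess decays exactly as exp(-lambda*m/mar).
make_cfcs_core <- function(mar, n = 10, dbd = 1, thickness = 1,
                           surface_excess = 500, supported = 25,
                           lambda = log(2) / 22.3, ...) {
  mid <- (seq_len(n) - 0.5) * thickness
  m <- dbd * mid
  make_core(supported + surface_excess * exp(-lambda * m / mar),
            dbd = dbd, thickness = thickness, ...)
}

# Direct transcription of the printed effect-size equations, kept separate
# from the implementation.
oracle_hedges <- function(xe, sde, ne, xc, sdc, nc) {
  sd_pooled <- sqrt(((ne - 1) * sde^2 + (nc - 1) * sdc^2) / (ne + nc - 2))
  j <- 1 - 3 / (4 * (ne + nc - 2) - 1)
  g <- (xe - xc) * j / sd_pooled
  v_g <- (ne + nc) / (ne * nc) + g^2 / (2 * (ne + nc))
  list(g = g, v_g = v_g, sd_pooled = sd_pooled, j = j)
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all rank
# assignments (tie-free data only).
oracle_mw_exact_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  stopifnot(anyDuplicated(c(a, b)) == 0)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * (n - na) / 2
  combs <- utils::combn(n, na)
  us <- colSums(combs) - na * (na + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
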