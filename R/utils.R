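# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL runs in the current
# stream (used when a caller already owns the stream).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Presentation rounding for global burial figures: whole Tg at >= 10,
# one decimal below.
format_tg <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (abs(v) >= 10) sprintf("%d", as.integer(round(v))) else sprintf("%.1f", v)
  }, character(1))
}

stop_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "blueCinorg_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

slice_midpoints <- function(slices) (slices$depth_top + slices$depth_bottom) / 2
slice_thickness <- function(slices) slices$depth_bottom - slices$depth_top
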