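#' Construct a sediment core
#'
#' A `sediment_core` holds one cored profile: per-core metadata plus an
#' ordered table of depth slices. Slices must be non-overlapping and sorted
#' by increasing depth below the sediment surface; depth intervals are
#' half-open `[top, bottom)` in cm and the slice midpoint `(top + bottom)/2`
#' is used wherever a single depth is needed.
#'
#' @param core_id Core identifier (non-empty string).
#' @param slices `data.frame` with columns `depth_top`, `depth_bottom` (cm),
#'   `dry_bulk_density` (g cm^-3), `pb210_total` (Bq kg^-1), `caco3_pct`
#'   (% dry weight); optional `pb210_total_err` (Bq kg^-1, 1 sigma),
#'   `pb210_supported` (Bq kg^-1, e.g. from 226Ra) and `corg_pct` (%DW).
#' @param ecosystem One of `"seagrass"`, `"mangrove"`, `"saltmarsh"`,
#'   `"unvegetated"`.
#' @param coring_year Calendar year CE the core was taken.
#' @param latitude,longitude Decimal degrees (optional).
#' @param climate_class Koppen climate code (optional).
#' @param is_tropical Logical; tropical or hot-desert climate.
#' @param coral_reef_present,lithogenic_present Logical flags for adjacent
#'   allochthonous CaCO3 sources.
#' @param location_key Site/area grouping label (defaults to `core_id`);
#'   cores sharing a key are treated as replicates of one global location.
#' @return An object of class `sediment_core`.
#' @examples
#' sl <- data.frame(depth_top = 0:4, depth_bottom = 1:5,
#'                  dry_bulk_density = 1, pb210_total = c(200, 120, 80, 50, 35),
#'                  caco3_pct = 60)
#' core <- sediment_core("C1", sl, ecosystem = "seagrass", coring_year = 2015)
#' @export
sediment_core <- function(core_id, slices, ecosystem = "seagrass",
                          coring_year, latitude = NA_real_,
                          longitude = NA_real_, climate_class = NA_character_,
                          is_tropical = FALSE, coral_reef_present = FALSE,
                          lithogenic_present = FALSE, location_key = core_id) {
  if (!is.character(core_id) || length(core_id) != 1L || !nzchar(core_id))
    stop_with("validation_error", "core_id must be a non-empty string")
  if (!is.character(location_key) || !nzchar(location_key))
    stop_with("validation_error", "core '%s': location_key must be non-empty",
              core_id)
  ecosystem <- match.arg(ecosystem,
                         c("seagrass", "mangrove", "saltmarsh", "unvegetated"))
  if (!is_scalar_number(coring_year))
    stop_with("validation_error", "core '%s': coring_year must be numeric",
              core_id)
  slices <- validate_slices(as.data.frame(slices), core_id)
  structure(
    list(core_id = core_id, ecosystem = ecosystem,
         latitude = latitude, longitude = longitude,
         coring_year = coring_year, climate_class = climate_class,
         is_tropical = isTRUE(is_tropical),
         coral_reef_present = isTRUE(coral_reef_present),
         lithogenic_present = isTRUE(lithogenic_present),
         location_key = location_key, slices = slices),
    class = "sediment_core"
  )
}

REQUIRED_SLICE_COLS <- c("depth_top", "depth_bottom", "dry_bulk_density",
                         "pb210_total", "caco3_pct")
OPTIONAL_SLICE_COLS <- c("pb210_total_err", "pb210_supported", "corg_pct")

validate_slices <- function(slices, core_id) {
  missing_cols <- setdiff(REQUIRED_SLICE_COLS, names(slices))
  if (length(missing_cols) > 0)
    stop_with("schema_error", "core '%s': missing slice column(s): %s",
              core_id, paste(missing_cols, collapse = ", "))
  for (col in OPTIONAL_SLICE_COLS)
    if (is.null(slices[[col]])) slices[[col]] <- NA_real_
  slices <- slices[c(REQUIRED_SLICE_COLS, OPTIONAL_SLICE_COLS)]
  for (col in names(slices)) slices[[col]] <- as.numeric(slices[[col]])

  bad <- which(is.na(slices$depth_top) | is.na(slices$depth_bottom) |
                 is.na(slices$dry_bulk_density))
  if (length(bad) > 0)
    stop_with("validation_error",
              "core '%s': missing depth or dry bulk density in row(s) %s",
              core_id, paste(bad, collapse = ", "))
  slices <- slices[order(slices$depth_top), , drop = FALSE]
  rownames(slices) <- NULL

  bad <- which(!(slices$depth_bottom > slices$depth_top) | slices$depth_top < 0)
  if (length(bad) > 0)
    stop_with("validation_error",
              "core '%s': depth_bottom <= depth_top (or negative depth) in row(s) %s",
              core_id, paste(bad, collapse = ", "))
  n <- nrow(slices)
  if (n > 1) {
    overlap <- which(slices$depth_top[-1] < slices$depth_bottom[-n] - 1e-9)
    if (length(overlap) > 0)
      stop_with("validation_error",
                "core '%s': overlapping or non-monotone slices at row(s) %s",
                core_id, paste(overlap + 1, collapse = ", "))
  }
  bad <- which(slices$dry_bulk_density <= 0)
  if (length(bad) > 0)
    stop_with("validation_error",
              "core '%s': non-positive dry bulk density in row(s) %s",
              core_id, paste(bad, collapse = ", "))
  for (col in c("pb210_total", "pb210_total_err", "pb210_supported")) {
    bad <- which(!is.na(slices[[col]]) & slices[[col]] < 0)
    if (length(bad) > 0)
      stop_with("validation_error",
                "core '%s': negative %s in row(s) %s", core_id, col,
                paste(bad, collapse = ", "))
  }
  bad <- which(!is.na(slices$caco3_pct) &
                 (slices$caco3_pct < 0 | slices$caco3_pct > 100))
  if (length(bad) > 0)
    stop_with("validation_error",
              "core '%s': caco3_pct outside [0, 100] in row(s) %s",
              core_id, paste(bad, collapse = ", "))
  slices
}

#' @export
print.sediment_core <- function(x, ...) {
  cat(sprintf("<sediment_core> %s (%s), %d slices, 0-%g cm, cored %d\n",
              x$core_id, x$ecosystem, nrow(x$slices),
              max(x$slices$depth_bottom), as.integer(x$coring_year)))
  cat(sprintf("  location '%s'%s; coral reef: %s; lithogenic: %s\n",
              x$location_key, if (x$is_tropical) " (tropical)" else "",
              x$coral_reef_present, x$lithogenic_present))
  invisible(x)
}

META_COLS <- c("core_id", "ecosystem", "latitude", "longitude", "coring_year",
               "climate_class", "is_tropical", "coral_reef_present",
               "lithogenic_present", "location_key")

#' Read sediment cores from delimited text
#'
#' Reads the two-file interchange layout: a slice table (one row per depth
#' interval) and a core metadata table, joined on `core_id`. Column names may
#' be remapped through `schema`, a named character vector
#' `c(canonical = "file_column")`, so arbitrary published compilations can be
#' ingested without editing the files.
#'
#' @param slice_path CSV of slices (columns of [sediment_core()] `slices`
#'   plus `core_id`).
#' @param meta_path CSV of per-core metadata (`core_id`, `ecosystem`,
#'   `coring_year`, `location_key`, and optionally coordinates, climate and
#'   allochthonous-source flags).
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names.
#' @return List of `sediment_core`, ordered as in the metadata table.
#' @seealso [write_core_table()] for the inverse.
#' @export
read_core_table <- function(slice_path, meta_path, schema = NULL) {
  for (p in c(slice_path, meta_path))
    if (!file.exists(p)) stop_with("schema_error", "file not found: %s", p)
  slices <- utils::read.csv(slice_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    remap <- function(df) {
      hit <- match(names(df), unname(schema))
      names(df)[!is.na(hit)] <- names(schema)[hit[!is.na(hit)]]
      df
    }
    slices <- remap(slices); meta <- remap(meta)
  }
  need_slice <- c("core_id", REQUIRED_SLICE_COLS)
  miss <- setdiff(need_slice, names(slices))
  if (length(miss) > 0)
    stop_with("schema_error", "slice table missing column(s): %s",
              paste(miss, collapse = ", "))
  need_meta <- c("core_id", "ecosystem", "coring_year", "location_key")
  miss <- setdiff(need_meta, names(meta))
  if (length(miss) > 0)
    stop_with("schema_error", "metadata table missing column(s): %s",
              paste(miss, collapse = ", "))
  if (anyDuplicated(meta$core_id))
    stop_with("validation_error", "duplicate core_id in metadata: %s",
              paste(unique(meta$core_id[duplicated(meta$core_id)]),
                    collapse = ", "))
  orphan <- setdiff(slices$core_id, meta$core_id)
  if (length(orphan) > 0)
    stop_with("validation_error", "slices reference unknown core_id: %s",
              paste(orphan, collapse = ", "))

  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    sl <- slices[slices$core_id == m$core_id,
                 setdiff(names(slices), "core_id"), drop = FALSE]
    if (nrow(sl) == 0)
      stop_with("validation_error", "core '%s' has no slices", m$core_id)
    sediment_core(
      core_id = as.character(m$core_id), slices = sl,
      ecosystem = as.character(m$ecosystem),
      coring_year = m$coring_year,
      latitude = if (!is.null(m$latitude)) m$latitude else NA_real_,
      longitude = if (!is.null(m$longitude)) m$longitude else NA_real_,
      climate_class = if (!is.null(m$climate_class))
        as.character(m$climate_class) else NA_character_,
      is_tropical = isTRUE(as.logical(m$is_tropical)),
      coral_reef_present = isTRUE(as.logical(m$coral_reef_present)),
      lithogenic_present = isTRUE(as.logical(m$lithogenic_present)),
      location_key = as.character(m$location_key)
    )
  })
}

#' Write sediment cores to delimited text
#'
#' Inverse of [read_core_table()]. Numeric fields are serialized with full
#' double precision ("%.17g") so that a write/read round trip reproduces
#' every value bit-identically.
#'
#' @param cores List of `sediment_core`.
#' @param slice_path,meta_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_core_table <- function(cores, slice_path, meta_path) {
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    else x
  }
  slice_df <- do.call(rbind, lapply(cores, function(co)
    cbind(core_id = co$core_id, co$slices)))
  meta_df <- do.call(rbind, lapply(cores, function(co)
    data.frame(core_id = co$core_id, ecosystem = co$ecosystem,
               latitude = co$latitude, longitude = co$longitude,
               coring_year = co$coring_year, climate_class = co$climate_class,
               is_tropical = co$is_tropical,
               coral_reef_present = co$coral_reef_present,
               lithogenic_present = co$lithogenic_present,
               location_key = co$location_key)))
  slice_df[] <- lapply(slice_df, fmt)
  meta_df[] <- lapply(meta_df, fmt)
  utils::write.csv(slice_df, slice_path, row.names = FALSE, quote = TRUE)
  utils::write.csv(meta_df, meta_path, row.names = FALSE, quote = TRUE)
  invisible(c(slice_path, meta_path))
}
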