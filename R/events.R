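#' Read and validate an observation-event table
#'
#' One row per counted sighting: a selection event at a site on a day, one
#' species in one habitat class performing one behavior class, with the number
#' of individuals. All tokens are validated against the closed vocabularies
#' and the species catalog; row order is preserved.
#'
#' @param path Path to a CSV with header
#'   `event_id,date,site_id,regime,habitat,species_id,behavior_class,count`.
#' @param catalog A validated species catalog (see [species_catalog()]).
#' @return A validated data.frame of observation events (possibly 0 rows).
#' @export
read_events <- function(path, catalog) {
  if (!file.exists(path)) {
    stop("events file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(count = "numeric"))
  validate_events(df, catalog)
}

#' Write an observation-event table
#'
#' Inverse of [read_events()]: `read_events(write_events(x, p), catalog)` is
#' the identity on validated event tables.
#'
#' @param events Validated event data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

EVENT_COLUMNS <- c("event_id", "date", "site_id", "regime", "habitat",
                   "species_id", "behavior_class", "count")

#' Validate an observation-event table
#'
#' @param df data.frame with the event columns.
#' @param catalog A validated species catalog.
#' @return The validated data.frame (columns reordered to the canonical
#'   order, `count` as integer).
#' @export
validate_events <- function(df, catalog) {
  missing <- setdiff(EVENT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("events table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, EVENT_COLUMNS]
  check_tokens <- function(values, valid, what) {
    bad <- which(!(values %in% valid))
    if (length(bad) > 0) {
      stop("invalid ", what, " '", values[bad[1]], "' in events row ", bad[1],
           call. = FALSE)
    }
  }
  check_tokens(df$regime, SBAN_REGIMES, "regime")
  check_tokens(df$habitat, SBAN_HABITATS, "habitat")
  check_tokens(df$behavior_class, SBAN_BEHAVIORS, "behavior_class")
  check_tokens(df$species_id, catalog$species_id, "species_id")
  if (any(is.na(df$count))) {
    stop("non-numeric count in events row ", which(is.na(df$count))[1],
         call. = FALSE)
  }
  if (any(df$count < 0)) {
    stop("negative count in events row ", which(df$count < 0)[1],
         call. = FALSE)
  }
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (nrow(df) > 0 && anyNA(dates)) {
    stop("unparseable ISO-8601 date in events row ", which(is.na(dates))[1],
         call. = FALSE)
  }
  df$date <- as.character(df$date)
  df$count <- as.integer(round(df$count))
  rownames(df) <- NULL
  df
}

#' Keep only the richest selection event per site and day
#'
#' When a site recorded several selection events on one day, only the event
#' with the highest species richness (number of distinct species across all
#' habitats) is retained; all rows of the winning event are kept. Ties are
#' broken by larger total individual count, then by lexicographically
#' smallest `event_id`. Idempotent.
#'
#' @param events Validated event data.frame.
#' @return The filtered event data.frame (original row order preserved).
#' @export
filter_daily_best <- function(events) {
  if (nrow(events) == 0) return(events)
  richness <- tapply(events$species_id, events$event_id,
                     function(s) length(unique(s)))
  total <- tapply(events$count, events$event_id, sum)
  key <- !duplicated(events$event_id)
  ev <- data.frame(
    event_id = events$event_id[key],
    site_id = events$site_id[key],
    date = events$date[key],
    stringsAsFactors = FALSE
  )
  ev$richness <- as.integer(richness[ev$event_id])
  ev$total <- as.integer(total[ev$event_id])
  ord <- order(ev$site_id, ev$date,
               -ev$richness, -ev$total, ev$event_id)
  ev <- ev[ord, ]
  winners <- ev$event_id[!duplicated(ev[, c("site_id", "date")])]
  out <- events[events$event_id %in% winners, ]
  rownames(out) <- NULL
  out
}

#' Pivot events into a per-stratum abundance matrix
#'
#' Builds the event x node abundance matrix for one (regime, habitat)
#' stratum: one row per retained selection event observed in that stratum,
#' one column per (species, behavior class) node of the full catalog
#' universe. Cells sum the counts of matching rows; species never seen in
#' the stratum keep all-zero columns so the node universe stays fixed at
#' `nrow(catalog) * 5`.
#'
#' @param events Validated (and typically daily-filtered) event data.frame.
#' @param catalog A validated species catalog.
#' @param regime One of `"R1"`, `"R2"`.
#' @param habitat One of `"BG"`, `"DW"`, `"GL"`, `"SW"`, `"MF"`.
#' @return Numeric matrix with event ids as row names and node labels as
#'   column names; attribute `stratum` holds `c(regime, habitat)`.
#' @export
pivot_abundance <- function(events, catalog, regime, habitat) {
  stopifnot(regime %in% SBAN_REGIMES, habitat %in% SBAN_HABITATS)
  labels <- node_labels(catalog)
  sel <- events[events$regime == regime & events$habitat == habitat, ]
  event_ids <- unique(sel$event_id)
  mat <- matrix(0, nrow = length(event_ids), ncol = length(labels),
                dimnames = list(event_ids, labels))
  if (nrow(sel) > 0) {
    node <- paste(sel$species_id, sel$behavior_class, sep = ":")
    cell <- (match(node, labels) - 1L) * length(event_ids) +
      match(sel$event_id, event_ids)
    agg <- rowsum(sel$count, group = cell)
    mat[as.integer(rownames(agg))] <- agg[, 1]
  } else {
    message("no events in stratum ", regime, "-", habitat)
  }
  attr(mat, "stratum") <- c(regime = regime, habitat = habitat)
  mat
}
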