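#' Closed vocabularies of the SBAN data model
#'
#' The observation model is built on four closed sets: two hydrological
#' regimes (R1 = managed/restored lakes, R2 = unmanaged), five dry-season
#' habitat classes, and five behavior classes per species -- two activities
#' (foraging, roosting) and three short-term behaviors (competition,
#' aggression, courtship). Every species contributes exactly one network node
#' per behavior class, so a 14-species catalog spans a fixed 70-node universe.
#'
#' @format Character vectors of valid tokens.
#' @name sban-vocabulary
NULL

#' @rdname sban-vocabulary
#' @export
SBAN_REGIMES <- c("R1", "R2")

#' @rdname sban-vocabulary
#' @export
SBAN_HABITATS <- c("BG", "DW", "GL", "SW", "MF")

#' @rdname sban-vocabulary
#' @export
SBAN_BEHAVIORS <- c("forage", "roost", "competition", "aggression", "courtship")

#' @rdname sban-vocabulary
#' @export
SBAN_GUILDS <- paste0("G", 1:5)

#' Default wintering-waterbird species catalog
#'
#' Fourteen migratory waterbird species in five foraging guilds:
#' G1 fish/clam/invertebrate eaters, G2 tuber feeders, G3 sedge/grass
#' foragers, G4 invertebrate eaters, G5 fish eaters. The catalog fixes the
#' node universe of every network built in one run (14 species x 5 behavior
#' classes = 70 nodes).
#'
#' @param path Optional path to a catalog CSV with header
#'   `species_id,scientific_name,guild`. When `NULL` (default) the packaged
#'   default catalog is loaded.
#' @return A data.frame of class `sban_catalog` with columns `species_id`,
#'   `scientific_name`, `guild`.
#' @examples
#' cat14 <- species_catalog()
#' nrow(cat14)              # 14
#' table(cat14$guild)
#' @export
species_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_catalog.csv", package = "sban",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("catalog file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_catalog(df)
}

#' Validate a species catalog
#'
#' @param df A data.frame with columns `species_id`, `scientific_name`,
#'   `guild`.
#' @return The validated data.frame, classed `sban_catalog`.
#' @export
validate_catalog <- function(df) {
  required <- c("species_id", "scientific_name", "guild")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$species_id)) {
    stop("catalog species_id values must be unique; duplicated: ",
         paste(unique(df$species_id[duplicated(df$species_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$guild), SBAN_GUILDS)
  if (length(bad) > 0) {
    stop("catalog guild tokens outside {", paste(SBAN_GUILDS, collapse = ","),
         "}: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- df[, required]
  class(df) <- c("sban_catalog", "data.frame")
  df
}

#' Node labels of the fixed SBAN universe
#'
#' One label per (species, behavior class), ordered catalog-major then by
#' behavior class: `"<species_id>:<behavior_class>"`.
#'
#' @param catalog A validated species catalog.
#' @return Character vector of length `nrow(catalog) * 5`.
#' @export
node_labels <- function(catalog) {
  as.vector(t(outer(catalog$species_id, SBAN_BEHAVIORS, paste, sep = ":")))
}

#' Split node labels into species and behavior class
#'
#' @param labels Character vector of `"species:behavior"` node labels.
#' @return data.frame with columns `node`, `species_id`, `behavior_class`.
#' @export
parse_node_labels <- function(labels) {
  parts <- strsplit(labels, ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) {
    stop("malformed node label(s): ", paste(labels[bad], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    node = labels,
    species_id = vapply(parts, `[[`, character(1), 1L),
    behavior_class = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}
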