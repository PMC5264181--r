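#' The five dominant halophytes of the lagoon marshes
#'
#' `Spartina maritima` is the low-marsh pioneer; the remaining four species
#' occupy the mid-high marsh. This zoning drives the low vs mid-high
#' partition of lagoon stock totals.
#'
#' @return Named character vector mapping species to marsh zone (`"low"` or
#'   `"mid_high"`).
#' @export
marsh_species <- function() {
  c("Spartina maritima"       = "low",
    "Juncus maritimus"        = "mid_high",
    "Halimione portulacoides" = "mid_high",
    "Sarcocornia perennis"    = "mid_high",
    "Bolboschoenus maritimus" = "mid_high")
}

#' Area covered by a species within a water body
#'
#' Coverage tables give, per water body and marsh zone, the zone area (ha)
#' and the fraction of that zone covered by each species. The species area
#' is `zone_area_ha x coverage_fraction`, summed over the zones where the
#' species occurs.
#'
#' @param coverage Data frame with columns `water_body`, `species`,
#'   `marsh_zone`, `zone_area_ha`, `coverage_fraction`.
#' @param water_body,species Identifiers to look up.
#' @return Area in hectares.
#' @export
species_area <- function(coverage, water_body, species) {
  stopifnot(is.data.frame(coverage))
  rows <- coverage[coverage$water_body == water_body &
                     coverage$species == species, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no coverage entry for species '", species, "' in water body '",
         water_body, "'", call. = FALSE)
  }
  sum(rows$zone_area_ha * rows$coverage_fraction)
}

#' Validate a coverage table
#'
#' Checks that coverage fractions lie in \[0, 1\], zone areas are
#' non-negative, and summed species fractions within each (water body, zone)
#' do not exceed 1 (up to numerical tolerance; uncovered area is bare
#' sediment, not an error).
#'
#' @inheritParams species_area
#' @return Invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_coverage <- function(coverage) {
  need <- c("water_body", "species", "marsh_zone", "zone_area_ha",
            "coverage_fraction")
  missing <- setdiff(need, names(coverage))
  if (length(missing)) {
    stop("coverage table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(coverage$coverage_fraction < 0 | coverage$coverage_fraction > 1)) {
    stop("coverage fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(coverage$zone_area_ha < 0)) {
    stop("zone areas must be >= 0", call. = FALSE)
  }
  sums <- coverage %>%
    dplyr::group_by(.data$water_body, .data$marsh_zone) %>%
    dplyr::summarise(total = sum(.data$coverage_fraction), .groups = "drop")
  bad <- sums[sums$total > 1 + 1e-9, , drop = FALSE]
  if (nrow(bad)) {
    stop("species coverage fractions exceed 1 in ",
         paste0(bad$water_body, "/", bad$marsh_zone, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Upscale a per-area stock to an absolute mass
#'
#' Multiplies a per-area standing stock by the area it covers. The stock
#' must be a standing stock (`Mg_per_ha` or `g_per_m2`); passing an annual
#' rate is an error because a rate times an area is a flux, not a stock.
#'
#' @param value Per-area stock.
#' @param unit Unit of `value` (`"Mg_per_ha"` or `"g_per_m2"`).
#' @param area_ha Area in hectares.
#' @return Mass in Mg.
#' @examples
#' upscale(15.17, "Mg_per_ha", 100)  # 1517 Mg
#' @export
upscale <- function(value, unit, area_ha) {
  .check_unit(unit)
  if (.unit_dimension[[unit]] != "areal") {
    stop("upscale expects a standing areal stock, got unit '", unit, "'",
         call. = FALSE)
  }
  if (any(area_ha < 0)) stop("area must be >= 0", call. = FALSE)
  convert_quantity(value, unit, "Mg_per_ha") * area_ha
}

#' Merge measured per-species stocks with reference-marsh values
#'
#' Species not sampled in the focal system may be covered by stocks measured
#' at a comparable reference marsh. Reference entries must name their
#' provenance and must not overlap the measured species; every entry in the
#' merged set is tagged `measured` or `inferred` so inferred values stay
#' traceable through reports.
#'
#' @param measured Data frame of stock entries (`element`, `species`,
#'   `compartment`, `stock_mg`, ...).
#' @param reference Data frame in the same shape plus a non-empty
#'   `provenance` column.
#' @return Combined tibble with `status` (`"measured"`/`"inferred"`) and
#'   `provenance` columns.
#' @export
merge_reference_stocks <- function(measured, reference) {
  measured <- tibble::as_tibble(measured)
  reference <- tibble::as_tibble(reference)
  if (!"status" %in% names(measured)) measured$status <- "measured"
  if (!"provenance" %in% names(measured)) measured$provenance <- NA_character_
  if (nrow(reference) == 0L) return(measured)
  if (!"provenance" %in% names(reference) ||
      any(is.na(reference$provenance) | reference$provenance == "")) {
    stop("every reference stock must carry a non-empty provenance",
         call. = FALSE)
  }
  overlap <- intersect(unique(measured$species), unique(reference$species))
  if (length(overlap)) {
    stop("species present in both measured and reference sets: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  reference$status <- "inferred"
  dplyr::bind_rows(measured, reference)
}

#' Build the lagoon stock table from per-species absolute stocks
#'
#' Assembles element x species x compartment (`plant`, `sediment`) stocks in
#' Mg into the standard reporting shape: per-compartment row totals,
#' per-species totals, low vs mid-high zone subtotals, grand totals per
#' element and the mid-high share. A species absent from the input is
#' treated as absent, not zero; a duplicated (element, species, compartment)
#' entry is an error.
#'
#' @param entries Data frame with columns `element` (C/N/P), `species`,
#'   `compartment` (`"plant"` or `"sediment"`), `stock_mg`; optional
#'   `status` and `provenance` (see [merge_reference_stocks()]).
#' @param zones Named character vector mapping species to `"low"` /
#'   `"mid_high"`; defaults to [marsh_species()], with unlisted species
#'   assigned to `mid_high`.
#' @return A `stock_table` object.
#' @export
build_stock_table <- function(entries, zones = marsh_species()) {
  entries <- tibble::as_tibble(entries)
  need <- c("element", "species", "compartment", "stock_mg")
  missing <- setdiff(need, names(entries))
  if (length(missing)) {
    stop("entries missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(entries$compartment %in% c("plant", "sediment"))) {
    stop("compartment must be 'plant' or 'sediment'", call. = FALSE)
  }
  if (!all(entries$element %in% stock_elements())) {
    stop("element must be one of ", paste(stock_elements(), collapse = ", "),
         call. = FALSE)
  }
  if (any(entries$stock_mg < 0)) stop("stocks must be >= 0", call. = FALSE)
  key <- paste(entries$element, entries$species, entries$compartment)
  if (anyDuplicated(key)) {
    stop("duplicate stock entry for ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  entries$zone <- ifelse(entries$species %in% names(zones),
                         unname(zones[entries$species]), "mid_high")

  row_totals <- entries %>%
    dplyr::group_by(.data$element, .data$compartment) %>%
    dplyr::summarise(stock_mg = sum(.data$stock_mg), .groups = "drop")
  species_totals <- entries %>%
    dplyr::group_by(.data$element, .data$species, .data$zone) %>%
    dplyr::summarise(stock_mg = sum(.data$stock_mg), .groups = "drop")
  zone_subtotals <- species_totals %>%
    dplyr::group_by(.data$element, .data$zone) %>%
    dplyr::summarise(stock_mg = sum(.data$stock_mg), .groups = "drop")
  grand_totals <- species_totals %>%
    dplyr::group_by(.data$element) %>%
    dplyr::summarise(stock_mg = sum(.data$stock_mg), .groups = "drop")

  shares <- grand_totals
  mid <- zone_subtotals[zone_subtotals$zone == "mid_high", , drop = FALSE]
  shares$mid_high_share_percent <- vapply(seq_len(nrow(shares)), function(i) {
    g <- shares$stock_mg[i]
    if (g <= 0) return(NA_real_)  # undefined for an all-zero element
    m <- mid$stock_mg[match(shares$element[i], mid$element)]
    if (is.na(m)) m <- 0
    100 * m / g
  }, numeric(1))

  structure(
    list(entries = entries, row_totals = row_totals,
         species_totals = species_totals, zone_subtotals = zone_subtotals,
         grand_totals = grand_totals,
         mid_high_share_percent = stats::setNames(
           shares$mid_high_share_percent, shares$element)),
    class = "stock_table")
}

#' Share of an element's stock held in the mid-high marsh
#'
#' 100 x (grand total - low-marsh total) / grand total. Undefined (NA with a
#' warning) when the grand total is zero; invariant under uniform rescaling
#' of all stocks.
#'
#' @param table A `stock_table`.
#' @param element `"C"`, `"N"` or `"P"`.
#' @return Percentage in \[0, 100\].
#' @export
mid_high_share <- function(table, element) {
  stopifnot(inherits(table, "stock_table"))
  if (!element %in% names(table$mid_high_share_percent)) {
    stop("element '", element, "' not present in table", call. = FALSE)
  }
  out <- table$mid_high_share_percent[[element]]
  if (is.na(out)) {
    warning("grand total for ", element, " is zero; share undefined",
            call. = FALSE)
  }
  out
}

#' Total stock of an element across the table
#' @param table A `stock_table`.
#' @param element `"C"`, `"N"` or `"P"`.
#' @return Stock in Mg.
#' @export
total_stock <- function(table, element) {
  stopifnot(inherits(table, "stock_table"))
  i <- match(element, table$grand_totals$element)
  if (is.na(i)) stop("element '", element, "' not present", call. = FALSE)
  table$grand_totals$stock_mg[i]
}

#' @export
print.stock_table <- function(x, ...) {
  cat("<stock_table> ", nrow(x$entries), " entries, ",
      length(unique(x$entries$species)), " species\n", sep = "")
  for (el in x$grand_totals$element) {
    share <- x$mid_high_share_percent[[el]]
    cat(sprintf("  %s: %s Mg total (mid-high share %s%%)\n", el,
                format(round(total_stock(x, el)), big.mark = ""),
                ifelse(is.na(share), "NA", format(round(share, 1)))))
  }
  invisible(x)
}

#' @export
as.data.frame.stock_table <- function(x, ...) {
  as.data.frame(x$entries)
}
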