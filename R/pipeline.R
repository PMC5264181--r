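#' Upscale per-area survey stocks to lagoon totals
#'
#' Joins per-area stocks (from [survey_stocks()]) with a coverage table:
#' each species' per-area plant and sediment stock, averaged over the sites
#' where it was sampled, is multiplied by the area the species covers across
#' all water bodies. Plant stocks use the `plant_total` compartment
#' (aboveground + belowground).
#'
#' @param stocks The `stocks` tibble from [survey_stocks()].
#' @param coverage Coverage table (see [species_area()]).
#' @return Tibble of absolute stocks: `element`, `species`, `compartment`
#'   (`plant`/`sediment`), `stock_mg`, `area_ha`.
#' @export
lagoon_stocks <- function(stocks, coverage) {
  validate_coverage(coverage)
  comp_map <- c(plant_total = "plant", sediment = "sediment")
  per_area <- stocks %>%
    dplyr::filter(.data$compartment %in% names(comp_map)) %>%
    dplyr::group_by(.data$element, .data$species, .data$compartment) %>%
    dplyr::summarise(value = mean(.data$value), unit = .data$unit[1],
                     .groups = "drop")
  areas <- coverage %>%
    dplyr::group_by(.data$species) %>%
    dplyr::summarise(
      area_ha = sum(.data$zone_area_ha * .data$coverage_fraction),
      .groups = "drop")
  out <- per_area %>%
    dplyr::inner_join(areas, by = "species") %>%
    dplyr::mutate(
      compartment = comp_map[.data$compartment],
      stock_mg = upscale(convert_quantity(.data$value, .data$unit[1],
                                          "Mg_per_ha"),
                         "Mg_per_ha", .data$area_ha)) %>%
    dplyr::select("element", "species", "compartment", "stock_mg", "area_ha")
  out
}

.flatten_stock_table <- function(table) {
  entries <- table$entries %>%
    dplyr::select("element", "species", "compartment", "stock_mg")
  species_totals <- table$species_totals %>%
    dplyr::mutate(compartment = "total") %>%
    dplyr::select("element", "species", "compartment", "stock_mg")
  row_totals <- table$row_totals %>%
    dplyr::mutate(species = "ALL") %>%
    dplyr::select("element", "species", "compartment", "stock_mg")
  grand <- table$grand_totals %>%
    dplyr::mutate(species = "ALL", compartment = "total") %>%
    dplyr::select("element", "species", "compartment", "stock_mg")
  share <- tibble::tibble(
    element = names(table$mid_high_share_percent), species = "ALL",
    compartment = "mid_high_share_percent",
    stock_mg = unname(table$mid_high_share_percent))
  dplyr::bind_rows(entries, species_totals, row_totals, grand, share)
}

#' Render a lagoon stock table
#'
#' Renders a [build_stock_table()] result as a markdown table (elements as
#' row blocks, species as columns, Plant/Sediment/TOTAL rows, a zone
#' subtotal and a mid-high-share footnote; Mg rounded to integers), or as a
#' tidy CSV-ready data frame / JSON string carrying full-precision values.
#' The CSV and JSON forms contain identical numbers.
#'
#' @param table A `stock_table`.
#' @param format `"markdown"`, `"csv"` or `"json"`.
#' @return A character scalar (markdown, json) or a data frame (csv).
#' @export
report_stock_table <- function(table,
                               format = c("markdown", "csv", "json")) {
  stopifnot(inherits(table, "stock_table"))
  format <- match.arg(format)
  if (format == "csv") return(as.data.frame(.flatten_stock_table(table)))
  if (format == "json") {
    return(jsonlite::toJSON(.flatten_stock_table(table), digits = NA,
                            dataframe = "rows", pretty = TRUE))
  }
  species <- unique(table$entries$species)
  zones <- table$entries$zone[match(species, table$entries$species)]
  species <- species[order(zones, decreasing = FALSE)]  # low first
  lines <- character(0)
  header <- paste0("| Element | Compartment | ",
                   paste(species, collapse = " | "), " | Total |")
  rule <- paste0("|", paste(rep("---|", length(species) + 3), collapse = ""))
  lines <- c(header, rule)
  fmt <- function(x) ifelse(is.na(x), "--", format(round(x)))
  for (el in table$grand_totals$element) {
    for (comp in c("plant", "sediment")) {
      vals <- vapply(species, function(sp) {
        i <- which(table$entries$element == el &
                     table$entries$species == sp &
                     table$entries$compartment == comp)
        if (length(i)) table$entries$stock_mg[i] else NA_real_
      }, numeric(1))
      tot <- table$row_totals$stock_mg[
        table$row_totals$element == el & table$row_totals$compartment == comp]
      lines <- c(lines, paste0(
        "| ", el, " | ", tools::toTitleCase(comp), " | ",
        paste(fmt(vals), collapse = " | "), " | ",
        if (length(tot)) fmt(tot) else "--", " |"))
    }
    tots <- vapply(species, function(sp) {
      i <- which(table$species_totals$element == el &
                   table$species_totals$species == sp)
      if (length(i)) table$species_totals$stock_mg[i] else NA_real_
    }, numeric(1))
    lines <- c(lines, paste0(
      "| ", el, " | **TOTAL** | ",
      paste(fmt(tots), collapse = " | "), " | ",
      fmt(total_stock(table, el)), " |"))
  }
  shares <- table$mid_high_share_percent
  foot <- paste0(
    "Mid-high marsh share of total stock: ",
    paste(vapply(names(shares), function(el) {
      sprintf("%s %.1f%%", el, shares[[el]])
    }, character(1)), collapse = ", "), ".")
  low_tot <- table$zone_subtotals[table$zone_subtotals$zone == "low", ,
                                  drop = FALSE]
  if (nrow(low_tot)) {
    foot <- paste0(foot, " Low-marsh subtotal (Mg): ",
                   paste(sprintf("%s %s", low_tot$element,
                                 fmt(low_tot$stock_mg)), collapse = ", "), ".")
  }
  paste(c(lines, "", foot), collapse = "\n")
}

.config_fingerprint <- function(x) {
  .stream_seed(0, paste(deparse(x), collapse = ""))
}

#' Run the full stock-accounting pipeline
#'
#' Orchestrates the stages in order: read/validate the survey, compute
#' per-area stocks and annual production, upscale to lagoon totals through
#' the coverage table (optionally merging reference-marsh stocks for
#' unsampled species), run the seasonal multivariate analysis (PCO plus a
#' one-way PERMANOVA on species when two or more species are present,
#' otherwise on sampling event), and render a report. Identical inputs and
#' seed produce byte-identical outputs. Validation errors abort before any
#' computation; the returned log records record counts and warnings so no
#' record is silently dropped.
#'
#' @param survey A `marsh_survey`, or a named list of CSV paths
#'   (`biomass`, `contents`, `sediment`) passed to [read_survey()].
#' @param coverage Optional coverage table or CSV path; enables upscaling.
#' @param reference Optional reference-marsh stock entries
#'   (see [merge_reference_stocks()]).
#' @param depth_cm Sediment depth for standing stocks (default 25).
#' @param sedimentation_rate_cm_yr Optional accretion rate for annual
#'   sediment stocks.
#' @param n_perm,seed Permutation count and seed for the PERMANOVA.
#' @param s_depth_cm Depth basis of the sediment stock ordination variables.
#' @param out_dir Optional directory; when given, all artifacts are written
#'   there as CSV/JSON plus the rendered report.
#' @param report_format Passed to [report_stock_table()].
#' @return List: `stocks`, `production`, `lagoon` (`stock_table` or `NULL`),
#'   `ordination` (`pco`), `variable_scores`, `permanova`, `report`, `log`.
#' @export
run_pipeline <- function(survey, coverage = NULL, reference = NULL,
                         depth_cm = 25, sedimentation_rate_cm_yr = NULL,
                         n_perm = 999, seed = 1, s_depth_cm = 1,
                         out_dir = NULL, report_format = "markdown") {
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))

  # stage: read
  if (!inherits(survey, "marsh_survey")) {
    if (!is.list(survey)) stop("read stage: survey must be a marsh_survey or a list of paths",
                               call. = FALSE)
    survey <- read_survey(biomass = survey$biomass,
                          contents = survey$contents,
                          sediment = survey$sediment)
  }
  n_in <- nrow(survey$biomass) + nrow(survey$contents) + nrow(survey$sediment)
  say("read: ", nrow(survey$biomass), " biomass / ", nrow(survey$contents),
      " content / ", nrow(survey$sediment), " sediment records")

  # stage: validate
  report <- validate_survey(survey)
  if (!is_valid(report)) {
    stop("validation stage: ", nrow(report$errors), " error(s); first: ",
         report$errors$message[1], call. = FALSE)
  }
  say("validate: 0 errors, ", nrow(report$warnings), " warning(s)")

  # stage: stocks and production
  acc <- survey_stocks(survey, depth_cm = depth_cm,
                       sedimentation_rate_cm_yr = sedimentation_rate_cm_yr)
  say("stocks: ", nrow(acc$stocks), " stock rows, ", nrow(acc$production),
      " production rows")

  # stage: upscale
  lagoon <- NULL
  if (!is.null(coverage)) {
    if (is.character(coverage)) {
      coverage <- utils::read.csv(coverage, stringsAsFactors = FALSE)
    }
    entries <- lagoon_stocks(acc$stocks, coverage)
    entries$status <- "measured"
    entries$provenance <- "field survey"
    if (!is.null(reference)) {
      entries <- merge_reference_stocks(entries, reference)
    }
    lagoon <- build_stock_table(entries)
    say("upscale: ", nrow(entries), " species x compartment x element entries")
  }

  # stage: ordination
  vm <- build_variable_matrix(survey, s_depth_cm = s_depth_cm)
  d <- euclidean_distances(log1_transform(vm$matrix))
  ord <- pco(d)
  scores <- weighted_average_scores(log1_transform(vm$matrix), ord$points)
  group_var <- if (length(unique(vm$meta$species)) > 1L) "species" else "date"
  pmv <- permanova(d, vm$meta[[group_var]], n_perm = n_perm, seed = seed)
  say("ordination: ", nrow(vm$matrix), " observations, ",
      ncol(vm$matrix), " variables; permanova on ", group_var,
      ": p = ", format(pmv$p_value))

  rendered <- if (!is.null(lagoon)) {
    report_stock_table(lagoon, format = report_format)
  }

  result <- list(stocks = acc$stocks, production = acc$production,
                 lagoon = lagoon, ordination = ord,
                 variable_scores = scores, permanova = pmv,
                 report = rendered, log = log)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    w <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                         row.names = FALSE, quote = FALSE)
    w(acc$stocks, "stocks.csv")
    w(acc$production, "production.csv")
    if (!is.null(lagoon)) w(.flatten_stock_table(lagoon), "lagoon_stocks.csv")
    coords <- data.frame(vm$meta, vm_row = seq_len(nrow(vm$meta)),
                         ord$points, check.names = FALSE)
    w(coords, "pco_coordinates.csv")
    w(data.frame(axis = seq_along(ord$eig), eigenvalue = ord$eig),
      "pco_eigenvalues.csv")
    w(data.frame(variable = rownames(scores), scores, check.names = FALSE),
      "variable_scores.csv")
    jsonlite::write_json(
      list(pseudo_f = pmv$pseudo_f, r2 = pmv$r2, p_value = pmv$p_value,
           n_perm = pmv$n_perm, seed = pmv$seed, group = group_var),
      file.path(out_dir, "permanova.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = seed, depth_cm = depth_cm,
           sedimentation_rate_cm_yr = sedimentation_rate_cm_yr,
           n_perm = n_perm, s_depth_cm = s_depth_cm,
           config_fingerprint = .config_fingerprint(
             list(depth_cm, sedimentation_rate_cm_yr, n_perm, seed,
                  s_depth_cm)),
           input_records = n_in, log = log),
      file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(rendered) && report_format == "markdown") {
      writeLines(rendered, file.path(out_dir, "report.md"))
    }
  }
  result
}
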