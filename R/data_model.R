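#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# canonical column layouts of the three long-format survey tables
.biomass_cols <- c("species", "site", "water_body", "date", "replicate",
                   "compartment", "dry_mass_g_m2")
.contents_cols <- c("species", "site", "date", "replicate", "matrix",
                    "element", "percent")
.sediment_cols <- c("species", "site", "date", "replicate",
                    "bulk_density_g_cm3", "loi_percent",
                    "g1000", "g500", "g250", "g125", "g063", "g0063",
                    "ph", "temperature_c")

.particle_cols <- c("g1000", "g500", "g250", "g125", "g063", "g0063")

#' Biomass compartments recognised by the pipeline
#'
#' `aboveground` is leaves and stems, `belowground` roots and rhizomes,
#' `litter` dead plant material remaining on the marsh surface. Litter is
#' carried for the multivariate seasonal analysis but excluded from plant
#' element stocks.
#' @return Character vector.
#' @export
biomass_compartments <- function() c("aboveground", "belowground", "litter")

#' Elements tracked by the stock accounting
#' @return Character vector.
#' @export
stock_elements <- function() c("C", "N", "P")

.parse_numeric <- function(x, file, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(x) != "" & !toupper(trimws(x)) %in% "NA")
  if (length(bad)) {
    stop("malformed numeric value in ", file, ", column '", column,
         "', data row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": '", x[bad[1]], "'", call. = FALSE)
  }
  out
}

.parse_date <- function(x, file) {
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop("unparseable ISO date in ", file, ", data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": '", x[bad[1]], "'",
         call. = FALSE)
  }
  out
}

.read_table <- function(path, required, numeric_cols, label) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, strip.white = TRUE)
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop(label, " file '", path, "' is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[required]
  for (col in numeric_cols) raw[[col]] <- .parse_numeric(raw[[col]], path, col)
  if ("date" %in% required) raw$date <- .parse_date(raw$date, path)
  if ("replicate" %in% required) raw$replicate <- as.integer(raw$replicate)
  tibble::as_tibble(raw)
}

#' Read a long-format field survey from CSV
#'
#' Reads up to three tables: quadrat biomass (`species, site, water_body,
#' date, replicate, compartment, dry_mass_g_m2`), elemental contents
#' (`species, site, date, replicate, matrix, element, percent`, percent of
#' dry weight) and rhizosediment properties (`species, site, date, replicate,
#' bulk_density_g_cm3, loi_percent, g1000, g500, g250, g125, g063, g0063,
#' ph, temperature_c`). Files are UTF-8 CSV with a header row, `.` decimal
#' separator and ISO 8601 dates. Missing mandatory columns or malformed
#' numeric cells are hard errors naming the column and row.
#'
#' A species absent from a site is represented by absence of rows, never by
#' zeros.
#'
#' @param biomass,contents,sediment Paths to the three CSV files; any may be
#'   `NULL`, in which case that table is returned empty.
#' @return A `marsh_survey` object: a list of tibbles `biomass`, `contents`
#'   and `sediment`.
#' @seealso [write_survey()], [validate_survey()]
#' @export
read_survey <- function(biomass = NULL, contents = NULL, sediment = NULL) {
  empty <- function(cols) {
    out <- tibble::as_tibble(stats::setNames(rep(list(character(0)), length(cols)), cols))
    out
  }
  b <- if (is.null(biomass)) empty(.biomass_cols) else
    .read_table(biomass, .biomass_cols, "dry_mass_g_m2", "biomass")
  ct <- if (is.null(contents)) empty(.contents_cols) else
    .read_table(contents, .contents_cols, "percent", "contents")
  s <- if (is.null(sediment)) empty(.sediment_cols) else
    .read_table(sediment, .sediment_cols,
                c("bulk_density_g_cm3", "loi_percent", .particle_cols,
                  "ph", "temperature_c"), "sediment")
  if (nrow(b) + nrow(ct) + nrow(s) == 0L) {
    warning("survey contains no data rows", call. = FALSE)
  }
  new_marsh_survey(biomass = b, contents = ct, sediment = s)
}

#' Construct a survey object from in-memory tables
#'
#' @param biomass,contents,sediment Data frames in the layouts documented at
#'   [read_survey()]; any may be omitted.
#' @return A `marsh_survey` object.
#' @export
new_marsh_survey <- function(biomass = NULL, contents = NULL, sediment = NULL) {
  as_tbl <- function(x, cols) {
    if (is.null(x)) {
      x <- stats::setNames(rep(list(character(0)), length(cols)), cols)
    }
    x <- tibble::as_tibble(x)
    missing <- setdiff(cols, names(x))
    if (length(missing)) {
      stop("table is missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x[cols]
  }
  structure(
    list(
      biomass  = as_tbl(biomass, .biomass_cols),
      contents = as_tbl(contents, .contents_cols),
      sediment = as_tbl(sediment, .sediment_cols)
    ),
    class = "marsh_survey"
  )
}

#' @export
print.marsh_survey <- function(x, ...) {
  cat("<marsh_survey>\n")
  cat("  biomass observations:", nrow(x$biomass), "\n")
  cat("  element contents:    ", nrow(x$contents), "\n")
  cat("  sediment samples:    ", nrow(x$sediment), "\n")
  sp <- sort(unique(c(x$biomass$species, x$contents$species, x$sediment$species)))
  if (length(sp)) cat("  species:", paste(sp, collapse = ", "), "\n")
  invisible(x)
}

#' Write a survey to CSV
#'
#' Inverse of [read_survey()]: emits the three long-format tables into
#' `dir` as `biomass.csv`, `contents.csv` and `sediment.csv`.
#'
#' @param survey A `marsh_survey` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "marsh_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("biomass.csv", "contents.csv", "sediment.csv"))
  utils::write.csv(survey$biomass,  paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(survey$contents, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(survey$sediment, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

.report_row <- function(locator, rule, message) {
  tibble::tibble(record = locator, rule = rule, message = message)
}

#' Validate a survey against the data-model invariants
#'
#' Checks every type invariant: non-negative dry mass, recognised
#' compartments and elements, percent contents within \[0, 100\], positive
#' bulk density, particle-size fractions summing to 100 within a +/- 1
#' measurement-rounding tolerance, pH within \[0, 14\], and uniqueness of the
#' (species, site, date, replicate, compartment) key. Problems are reported,
#' never thrown. Incomplete replicate sets (fewer than `replicates` per
#' sampling date) yield warnings, not errors, so fragmentary surveys remain
#' usable.
#'
#' @param survey A `marsh_survey` object.
#' @param replicates Designed number of replicates per sampling date
#'   (default 3).
#' @return A `validation_report`: list of tibbles `errors` and `warnings`,
#'   each with columns `record`, `rule`, `message`.
#' @export
validate_survey <- function(survey, replicates = 3L) {
  stopifnot(inherits(survey, "marsh_survey"))
  errors <- list()
  warns <- list()
  b <- survey$biomass
  ct <- survey$contents
  s <- survey$sediment

  loc <- function(tbl, i, table) {
    paste0(table, " row ", i, " (", tbl$species[i], "/", tbl$site[i], "/",
           format(tbl$date[i]), "/rep", tbl$replicate[i], ")")
  }

  if (nrow(b)) {
    bad <- which(b$dry_mass_g_m2 < 0)
    for (i in bad) {
      errors[[length(errors) + 1L]] <- .report_row(
        loc(b, i, "biomass"), "dry_mass_nonnegative",
        paste0("dry mass ", b$dry_mass_g_m2[i], " g m-2 is negative"))
    }
    bad <- which(!b$compartment %in% biomass_compartments())
    for (i in bad) {
      errors[[length(errors) + 1L]] <- .report_row(
        loc(b, i, "biomass"), "compartment_enum",
        paste0("unknown compartment '", b$compartment[i], "'"))
    }
    key <- paste(b$species, b$site, b$date, b$replicate, b$compartment)
    dup <- which(duplicated(key))
    for (i in dup) {
      errors[[length(errors) + 1L]] <- .report_row(
        loc(b, i, "biomass"), "unique_observation_key",
        "duplicate (species, site, date, replicate, compartment)")
    }
    # replicate completeness per species/site/date/compartment: warning only
    counts <- b %>%
      dplyr::count(.data$species, .data$site, .data$date, .data$compartment)
    short <- counts[counts$n < replicates, , drop = FALSE]
    for (i in seq_len(nrow(short))) {
      warns[[length(warns) + 1L]] <- .report_row(
        paste0("biomass ", short$species[i], "/", short$site[i], "/",
               format(short$date[i]), "/", short$compartment[i]),
        "replicate_completeness",
        paste0(short$n[i], " of ", replicates, " designed replicates present"))
    }
  }

  if (nrow(ct)) {
    bad <- which(ct$percent < 0 | ct$percent > 100)
    for (i in bad) {
      errors[[length(errors) + 1L]] <- .report_row(
        loc(ct, i, "contents"), "percent_range",
        paste0("content ", ct$percent[i], "% outside [0, 100]"))
    }
    bad <- which(!ct$element %in% stock_elements())
    for (i in bad) {
      errors[[length(errors) + 1L]] <- .report_row(
        loc(ct, i, "contents"), "element_enum",
        paste0("unknown element '", ct$element[i], "'"))
    }
    bad <- which(!ct$matrix %in% c("aboveground", "belowground", "sediment"))
    for (i in bad) {
      errors[[length(errors) + 1L]] <- .report_row(
        loc(ct, i, "contents"), "matrix_enum",
        paste0("unknown matrix '", ct$matrix[i], "'"))
    }
  }

  if (nrow(s)) {
    bad <- which(s$bulk_density_g_cm3 <= 0)
    for (i in bad) {
      errors[[length(errors) + 1L]] <- .report_row(
        loc(s, i, "sediment"), "bulk_density_positive",
        paste0("bulk density ", s$bulk_density_g_cm3[i], " g cm-3 not > 0"))
    }
    bad <- which(s$loi_percent < 0 | s$loi_percent > 100)
    for (i in bad) {
      errors[[length(errors) + 1L]] <- .report_row(
        loc(s, i, "sediment"), "loi_range",
        paste0("LOI ", s$loi_percent[i], "% outside [0, 100]"))
    }
    frac <- as.matrix(s[.particle_cols])
    bad <- which(apply(frac, 1, function(r) any(r < 0)))
    for (i in bad) {
      errors[[length(errors) + 1L]] <- .report_row(
        loc(s, i, "sediment"), "particle_fraction_nonnegative",
        "negative particle-size fraction")
    }
    sums <- rowSums(frac)
    bad <- which(abs(sums - 100) > 1)  # measurement rounding tolerance
    for (i in bad) {
      errors[[length(errors) + 1L]] <- .report_row(
        loc(s, i, "sediment"), "particle_fractions_sum_100",
        paste0("particle-size fractions sum to ", round(sums[i], 3),
               ", outside 100 +/- 1"))
    }
    bad <- which(s$ph < 0 | s$ph > 14)
    for (i in bad) {
      errors[[length(errors) + 1L]] <- .report_row(
        loc(s, i, "sediment"), "ph_range",
        paste0("pH ", s$ph[i], " outside [0, 14]"))
    }
  }

  if (nrow(b) + nrow(ct) + nrow(s) == 0L) {
    warns[[length(warns) + 1L]] <- .report_row(
      "survey", "empty_input", "survey contains no data rows")
  }

  bind <- function(lst) {
    if (length(lst)) dplyr::bind_rows(lst) else
      tibble::tibble(record = character(0), rule = character(0),
                     message = character(0))
  }
  structure(list(errors = bind(errors), warnings = bind(warns)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x$errors), " error(s), ",
      nrow(x$warnings), " warning(s)\n", sep = "")
  show <- function(tbl, tag) {
    for (i in seq_len(min(nrow(tbl), 10L))) {
      cat("  ", tag, " [", tbl$rule[i], "] ", tbl$record[i], ": ",
          tbl$message[i], "\n", sep = "")
    }
    if (nrow(tbl) > 10L) cat("  ... and", nrow(tbl) - 10L, "more\n")
  }
  show(x$errors, "ERROR")
  show(x$warnings, "warn ")
  invisible(x)
}

#' Does a validation report contain no errors?
#' @param report A `validation_report`.
#' @return `TRUE` when the dataset passes every invariant.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  nrow(report$errors) == 0L
}
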