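#' Per-date replicate means and standard errors
#'
#' Collapses replicate measurements to one mean per sampling date, the unit
#' on which annual production and mean annual stocks are defined. The
#' standard error is SD/sqrt(n); with a single replicate it is `NA` (flagged,
#' not an error).
#'
#' @param values Numeric vector of per-replicate values.
#' @param dates Vector of sampling dates (`Date` or coercible), parallel to
#'   `values`.
#' @return Tibble with one row per date in chronological order: `date`,
#'   `mean`, `se`, `n`.
#' @export
per_date_means <- function(values, dates) {
  if (length(values) == 0L) stop("empty series", call. = FALSE)
  if (length(values) != length(dates)) {
    stop("values and dates must have equal length", call. = FALSE)
  }
  dates <- as.Date(dates)
  out <- tibble::tibble(date = dates, value = as.numeric(values)) %>%
    dplyr::group_by(.data$date) %>%
    dplyr::summarise(
      mean = mean(.data$value),
      se = ifelse(dplyr::n() > 1L,
                  stats::sd(.data$value) / sqrt(dplyr::n()), NA_real_),
      n = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$date)
  out
}

#' Annual production as the range of per-date means
#'
#' Production is the annual increase (or decrease) of a biomass or element
#' stock: the maximum per-date mean stock of the year minus the minimum,
#' in g m^-2 y^-1. Ties are broken by the earliest date so output is
#' deterministic.
#'
#' @param means A tibble from [per_date_means()], or any data frame with
#'   `date` and `mean` columns covering at least two dates.
#' @return One-row tibble: `production` (max - min), `max_date`, `min_date`,
#'   `unit` (`g_per_m2_per_yr`).
#' @examples
#' m <- per_date_means(c(10, 12, 14, 30, 32, 34),
#'                     rep(as.Date(c("2012-02-15", "2012-06-15")), each = 3))
#' annual_production(m)  # 20 g m-2 y-1
#' @export
annual_production <- function(means) {
  stopifnot(is.data.frame(means), all(c("date", "mean") %in% names(means)))
  if (nrow(means) < 2L) {
    stop("annual production needs at least two sampling dates", call. = FALSE)
  }
  means <- means[order(as.Date(means$date)), , drop = FALSE]
  i_max <- which.max(means$mean)  # which.max/min return the first = earliest
  i_min <- which.min(means$mean)
  tibble::tibble(
    production = means$mean[i_max] - means$mean[i_min],
    max_date = as.Date(means$date[i_max]),
    min_date = as.Date(means$date[i_min]),
    unit = "g_per_m2_per_yr"
  )
}

#' Plant element stock from biomass and content
#'
#' Stock of an element in plant tissue: content (% of dry weight) times
#' biomass (g DW m^-2), giving g m^-2.
#'
#' @param biomass_g_m2 Mean annual (or per-date) dry biomass, g DW m^-2,
#'   non-negative.
#' @param content_percent Element content, % of dry weight in \[0, 100\].
#' @return Numeric stock in g m^-2.
#' @examples
#' plant_element_stock(1000, 40)  # 400 g m-2
#' @export
plant_element_stock <- function(biomass_g_m2, content_percent) {
  if (any(biomass_g_m2 < 0)) stop("biomass must be >= 0", call. = FALSE)
  if (any(content_percent < 0 | content_percent > 100)) {
    stop("content percent must lie in [0, 100]", call. = FALSE)
  }
  content_percent / 100 * biomass_g_m2
}

#' Sediment element stock over a depth
#'
#' Stock of an element in rhizosediment: content (% DW) x dry bulk density
#' (g DW cm^-3) x depth (cm), scaled by 10^4 cm^2 m^-2 to give g m^-2.
#' The default 25 cm is the depth of the living root/rhizome layer.
#'
#' @param content_percent Element content, % of dry weight.
#' @param bulk_density_g_cm3 Dry bulk density, g DW cm^-3, > 0.
#' @param depth_cm Sediment depth, cm, > 0 (default 25).
#' @return Numeric stock in g m^-2.
#' @examples
#' sediment_stock(1, 1.0, 25)  # 2500 g m-2
#' @export
sediment_stock <- function(content_percent, bulk_density_g_cm3, depth_cm = 25) {
  if (any(content_percent < 0 | content_percent > 100)) {
    stop("content percent must lie in [0, 100]", call. = FALSE)
  }
  if (any(bulk_density_g_cm3 <= 0)) stop("bulk density must be > 0", call. = FALSE)
  if (any(depth_cm <= 0)) stop("depth must be > 0", call. = FALSE)
  content_percent / 100 * bulk_density_g_cm3 * depth_cm * 1e4
}

#' Annual sediment element stock (accumulation rate)
#'
#' Annual gain of an element in sediment: content (% DW) x dry bulk density
#' x sedimentation rate (cm y^-1), in g m^-2 y^-1. For carbon this is the
#' carbon accumulation rate (CAR). Numerically equal to [sediment_stock()]
#' with the sedimentation rate as the depth.
#'
#' @inheritParams sediment_stock
#' @param sedimentation_rate_cm_yr Vertical accretion rate, cm y^-1, >= 0.
#' @return Numeric rate in g m^-2 y^-1.
#' @export
annual_sediment_stock <- function(content_percent, bulk_density_g_cm3,
                                  sedimentation_rate_cm_yr) {
  if (any(content_percent < 0 | content_percent > 100)) {
    stop("content percent must lie in [0, 100]", call. = FALSE)
  }
  if (any(bulk_density_g_cm3 <= 0)) stop("bulk density must be > 0", call. = FALSE)
  if (any(sedimentation_rate_cm_yr < 0)) {
    stop("sedimentation rate must be >= 0", call. = FALSE)
  }
  content_percent / 100 * bulk_density_g_cm3 * sedimentation_rate_cm_yr * 1e4
}

#' Mean annual plant element stock from a paired survey slice
#'
#' For one species/site/compartment/element: pairs per-replicate biomass with
#' the matching content measurement, forms the per-replicate per-date stock
#' content/100 x biomass, collapses replicates to per-date means, and
#' averages over dates. The reported standard error is the empirical SE of
#' the per-date stock means across dates.
#'
#' Two pairing orders are exposed. The default, `"per_date"`, computes
#' stocks per date first, which preserves any covariance between biomass and
#' content; `"annual_mean"` multiplies the annual mean content by the annual
#' mean biomass. When content is constant the two coincide exactly.
#'
#' @param biomass Data frame with columns `date`, `replicate`,
#'   `dry_mass_g_m2` for the slice.
#' @param content Data frame with columns `date`, `replicate`, `percent`
#'   for the same slice.
#' @param order `"per_date"` (default) or `"annual_mean"`.
#' @return One-row tibble: `stock` (g m^-2), `se`, `n_dates`, `unit`.
#' @export
mean_annual_plant_stock <- function(biomass, content,
                                    order = c("per_date", "annual_mean")) {
  order <- match.arg(order)
  stopifnot(is.data.frame(biomass), is.data.frame(content))
  paired <- dplyr::inner_join(
    biomass[c("date", "replicate", "dry_mass_g_m2")],
    content[c("date", "replicate", "percent")],
    by = c("date", "replicate")
  )
  if (nrow(paired) == 0L) {
    stop("no paired biomass and content records", call. = FALSE)
  }
  if (order == "per_date") {
    stocks <- plant_element_stock(paired$dry_mass_g_m2, paired$percent)
    pdm <- per_date_means(stocks, paired$date)
  } else {
    stock <- plant_element_stock(mean(paired$dry_mass_g_m2),
                                 mean(paired$percent))
    return(tibble::tibble(stock = stock, se = NA_real_,
                          n_dates = length(unique(paired$date)),
                          unit = "g_per_m2"))
  }
  tibble::tibble(
    stock = mean(pdm$mean),
    se = if (nrow(pdm) > 1L) stats::sd(pdm$mean) / sqrt(nrow(pdm)) else NA_real_,
    n_dates = nrow(pdm),
    unit = "g_per_m2"
  )
}

#' Belowground/aboveground biomass ratio
#'
#' Ratio of annual-mean belowground to annual-mean aboveground dry biomass
#' for one species x site slice. Annual means are means of per-date
#' replicate means. Values above 1 indicate root/rhizome dominance, the
#' usual situation in perennial halophyte marshes.
#'
#' @param biomass Data frame with columns `date`, `replicate`, `compartment`,
#'   `dry_mass_g_m2` containing both `aboveground` and `belowground` rows.
#' @return Scalar ratio (belowground / aboveground).
#' @export
biomass_ratio <- function(biomass) {
  stopifnot(is.data.frame(biomass),
            all(c("date", "compartment", "dry_mass_g_m2") %in% names(biomass)))
  annual_mean <- function(comp) {
    slice <- biomass[biomass$compartment == comp, , drop = FALSE]
    if (nrow(slice) == 0L) {
      stop("compartment '", comp, "' absent from slice", call. = FALSE)
    }
    mean(per_date_means(slice$dry_mass_g_m2, slice$date)$mean)
  }
  above <- annual_mean("aboveground")
  below <- annual_mean("belowground")
  if (above == 0) stop("aboveground annual mean biomass is zero", call. = FALSE)
  below / above
}

#' Per-area stocks and production for every group in a survey
#'
#' Runs the stock calculators over all (element, species, site) combinations
#' present in a survey: mean annual plant stocks for the aboveground and
#' belowground compartments (litter is excluded from stocks), their sum as
#' `plant_total`, sediment stocks over `depth_cm`, and -- when a
#' sedimentation rate is supplied -- annual sediment stocks. Also returns
#' annual biomass and element-stock production per compartment.
#'
#' @param survey A `marsh_survey`.
#' @param depth_cm Sediment depth for standing stocks (default 25 cm).
#' @param sedimentation_rate_cm_yr Optional accretion rate; when `NULL`
#'   annual sediment stocks are skipped.
#' @return List of tibbles: `stocks` (columns `element`, `species`, `site`,
#'   `compartment`, `value`, `unit`, `se`, `depth_cm`) and `production`
#'   (columns `quantity`, `element`, `species`, `site`, `compartment`,
#'   `production`, `max_date`, `min_date`, `unit`).
#' @export
survey_stocks <- function(survey, depth_cm = 25,
                          sedimentation_rate_cm_yr = NULL) {
  stopifnot(inherits(survey, "marsh_survey"))
  b <- survey$biomass
  ct <- survey$contents
  sed <- survey$sediment
  stocks <- list()
  production <- list()
  comp_map <- c(aboveground = "plant_above", belowground = "plant_below")

  groups <- unique(b[b$compartment %in% names(comp_map), c("species", "site")])
  for (g in seq_len(nrow(groups))) {
    sp <- groups$species[g]; si <- groups$site[g]
    b_g <- b[b$species == sp & b$site == si, , drop = FALSE]
    ct_g <- ct[ct$species == sp & ct$site == si, , drop = FALSE]
    sed_g <- sed[sed$species == sp & sed$site == si, , drop = FALSE]

    # biomass production per compartment (incl. litter, a dynamics variable)
    for (comp in intersect(biomass_compartments(), unique(b_g$compartment))) {
      slice <- b_g[b_g$compartment == comp, , drop = FALSE]
      pdm <- per_date_means(slice$dry_mass_g_m2, slice$date)
      if (nrow(pdm) >= 2L) {
        pr <- annual_production(pdm)
        production[[length(production) + 1L]] <- tibble::tibble(
          quantity = "biomass", element = NA_character_, species = sp,
          site = si, compartment = comp, production = pr$production,
          max_date = pr$max_date, min_date = pr$min_date, unit = pr$unit)
      }
    }

    for (el in intersect(stock_elements(), unique(ct_g$element))) {
      # plant compartments
      for (comp in intersect(names(comp_map), unique(b_g$compartment))) {
        content <- ct_g[ct_g$element == el & ct_g$matrix == comp, , drop = FALSE]
        slice <- b_g[b_g$compartment == comp, , drop = FALSE]
        if (nrow(content) == 0L || nrow(slice) == 0L) next
        st <- mean_annual_plant_stock(slice, content)
        stocks[[length(stocks) + 1L]] <- tibble::tibble(
          element = el, species = sp, site = si,
          compartment = comp_map[[comp]], value = st$stock,
          unit = st$unit, se = st$se, depth_cm = NA_real_)
        # element-stock production from the per-date stock series
        paired <- dplyr::inner_join(
          slice[c("date", "replicate", "dry_mass_g_m2")],
          content[c("date", "replicate", "percent")],
          by = c("date", "replicate"))
        if (nrow(paired)) {
          pdm <- per_date_means(
            plant_element_stock(paired$dry_mass_g_m2, paired$percent),
            paired$date)
          if (nrow(pdm) >= 2L) {
            pr <- annual_production(pdm)
            production[[length(production) + 1L]] <- tibble::tibble(
              quantity = "element_stock", element = el, species = sp,
              site = si, compartment = comp_map[[comp]],
              production = pr$production, max_date = pr$max_date,
              min_date = pr$min_date, unit = pr$unit)
          }
        }
      }
      # sediment standing stock over depth_cm
      s_content <- ct_g[ct_g$element == el & ct_g$matrix == "sediment", ,
                        drop = FALSE]
      if (nrow(s_content) && nrow(sed_g)) {
        paired <- dplyr::inner_join(
          sed_g[c("date", "replicate", "bulk_density_g_cm3")],
          s_content[c("date", "replicate", "percent")],
          by = c("date", "replicate"))
        if (nrow(paired)) {
          st <- sediment_stock(paired$percent, paired$bulk_density_g_cm3,
                               depth_cm)
          pdm <- per_date_means(st, paired$date)
          stocks[[length(stocks) + 1L]] <- tibble::tibble(
            element = el, species = sp, site = si, compartment = "sediment",
            value = mean(pdm$mean), unit = "g_per_m2",
            se = if (nrow(pdm) > 1L) stats::sd(pdm$mean) / sqrt(nrow(pdm))
                 else NA_real_,
            depth_cm = depth_cm)
          if (!is.null(sedimentation_rate_cm_yr)) {
            ann <- annual_sediment_stock(paired$percent,
                                         paired$bulk_density_g_cm3,
                                         sedimentation_rate_cm_yr)
            pdm_a <- per_date_means(ann, paired$date)
            stocks[[length(stocks) + 1L]] <- tibble::tibble(
              element = el, species = sp, site = si,
              compartment = "sediment_annual", value = mean(pdm_a$mean),
              unit = "g_per_m2_per_yr",
              se = if (nrow(pdm_a) > 1L)
                     stats::sd(pdm_a$mean) / sqrt(nrow(pdm_a)) else NA_real_,
              depth_cm = sedimentation_rate_cm_yr)
          }
        }
      }
    }
  }

  stocks <- if (length(stocks)) dplyr::bind_rows(stocks) else
    tibble::tibble(element = character(0), species = character(0),
                   site = character(0), compartment = character(0),
                   value = numeric(0), unit = character(0), se = numeric(0),
                   depth_cm = numeric(0))
  # conservation: plant_total = plant_above + plant_below where both exist
  totals <- stocks %>%
    dplyr::filter(.data$compartment %in% c("plant_above", "plant_below")) %>%
    dplyr::group_by(.data$element, .data$species, .data$site) %>%
    dplyr::filter(dplyr::n() == 2L) %>%
    dplyr::summarise(value = sum(.data$value),
                     se = sqrt(sum(.data$se^2)),
                     .groups = "drop") %>%
    dplyr::mutate(compartment = "plant_total", unit = "g_per_m2",
                  depth_cm = NA_real_)
  stocks <- dplyr::bind_rows(stocks, totals) %>%
    dplyr::arrange(.data$element, .data$species, .data$site, .data$compartment)

  production <- if (length(production)) dplyr::bind_rows(production) else
    tibble::tibble(quantity = character(0), element = character(0),
                   species = character(0), site = character(0),
                   compartment = character(0), production = numeric(0),
                   max_date = as.Date(character(0)),
                   min_date = as.Date(character(0)), unit = character(0))
  list(stocks = stocks, production = production)
}
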