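#' Default configuration for the synthetic field-survey generator
#'
#' Encodes the sampling design and magnitudes the analysis assumes: two
#' focal halophytes (Juncus maritimus across three sites, Spartina maritima
#' at two -- the low marsh at the northern site being too fragmented to
#' sample), six bimonthly sampling dates from February to December, three
#' replicate quadrats per date, single-harmonic seasonal biomass with a
#' spring-summer peak, lognormal replicate noise, truncated-normal element
#' contents and sediment properties drawn within configured ranges.
#'
#' Defaults reflect the qualitative field structure: belowground biomass
#' exceeds aboveground for both species (belowground/aboveground annual-mean
#' ratios 1.9 for S. maritima and 1.6 for J. maritimus), J. maritimus has
#' the higher biomass and litter and the more organic sediment (LOI 12-28%
#' vs 6-12%), and rhizosediment pH sits in the 5.9-7.2 range.
#'
#' @return Nested configuration list; see the vignette for the meaning and
#'   units of every field.
#' @export
default_sim_config <- function() {
  plant_contents <- list(
    aboveground = list(C = c(mean = 38, sd = 2),
                       N = c(mean = 1.2, sd = 0.15),
                       P = c(mean = 0.15, sd = 0.03)),
    belowground = list(C = c(mean = 36, sd = 2),
                       N = c(mean = 0.9, sd = 0.10),
                       P = c(mean = 0.12, sd = 0.02))
  )
  list(
    design = list(
      sites = c("site1", "site2", "site3"),
      water_bodies = c(site1 = "WB5", site2 = "WB2", site3 = "WB1"),
      dates = as.Date(c("2012-02-15", "2012-04-15", "2012-06-15",
                        "2012-08-15", "2012-10-15", "2012-12-15")),
      replicates = 3L,
      presence = list(
        "Juncus maritimus"  = c("site1", "site2", "site3"),
        "Spartina maritima" = c("site2", "site3")
      )
    ),
    species = list(
      "Juncus maritimus" = list(
        biomass = list(
          aboveground = list(peak = 1250, amplitude = 0.5, peak_month = 6),
          belowground = list(peak = 2000, amplitude = 0.5, peak_month = 6),
          litter      = list(peak = 300,  amplitude = 0.6, peak_month = 2)
        ),
        replicate_cv = 0.20,
        contents = c(plant_contents, list(
          sediment = list(C = c(mean = 6,    sd = 0.8),
                          N = c(mean = 0.35, sd = 0.05),
                          P = c(mean = 0.05, sd = 0.01)))),
        sediment = list(
          bulk_density = c(mean = 0.9, sd = 0.08),
          loi_range = c(12, 28), ph_range = c(5.9, 7.0),
          particle_weights = c(g1000 = 4, g500 = 6, g250 = 10, g125 = 14,
                               g063 = 11, g0063 = 55))
      ),
      "Spartina maritima" = list(
        biomass = list(
          aboveground = list(peak = 500, amplitude = 0.6, peak_month = 5),
          belowground = list(peak = 950, amplitude = 0.6, peak_month = 5),
          litter      = list(peak = 100, amplitude = 0.6, peak_month = 2)
        ),
        replicate_cv = 0.25,
        contents = c(plant_contents, list(
          sediment = list(C = c(mean = 2.5,  sd = 0.4),
                          N = c(mean = 0.15, sd = 0.03),
                          P = c(mean = 0.03, sd = 0.008)))),
        sediment = list(
          bulk_density = c(mean = 1.3, sd = 0.08),
          loi_range = c(6, 12), ph_range = c(6.1, 7.2),
          particle_weights = c(g1000 = 8, g500 = 10, g250 = 15, g125 = 12,
                               g063 = 10, g0063 = 45))
      )
    ),
    temperature = list(mean = 15.35, amplitude = 6.85, peak_month = 6,
                       sd = 1.5),
    coverage = list(
      total_area_ha = 4400,
      water_bodies = paste0("WB", 1:5),
      low_fraction_range = c(0.10, 0.30),
      low_species = "Spartina maritima",
      low_species_water_bodies = c("WB1", "WB2", "WB5"),
      mid_high_presence = list(
        "Juncus maritimus"        = paste0("WB", 1:5),
        "Halimione portulacoides" = c("WB1", "WB2", "WB3"),
        "Sarcocornia perennis"    = c("WB2", "WB4"),
        "Bolboschoenus maritimus" = c("WB3", "WB5")
      ),
      cover_range = c(0.70, 0.95)
    )
  )
}

#' Validate a simulation configuration
#'
#' @param config Configuration list in the shape of [default_sim_config()].
#' @return Invisibly `TRUE`; otherwise stops listing every violation found.
#' @export
validate_sim_config <- function(config) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  d <- config$design
  if (is.null(d$sites) || !length(d$sites)) note("design$sites is empty")
  if (is.null(d$dates) || length(d$dates) < 1L) note("design$dates is empty")
  if (!is.null(d$dates) && is.unsorted(d$dates, strictly = TRUE)) {
    note("design$dates must be strictly increasing")
  }
  if (is.null(d$replicates) || d$replicates < 1L) {
    note("design$replicates must be >= 1")
  }
  for (sp in names(config$species)) {
    cfg <- config$species[[sp]]
    for (comp in names(cfg$biomass)) {
      bc <- cfg$biomass[[comp]]
      if (bc$peak < 0) note(paste0(sp, "/", comp, ": peak biomass < 0"))
      if (bc$amplitude < 0 || bc$amplitude > 1) {
        note(paste0(sp, "/", comp, ": amplitude outside [0, 1]"))
      }
    }
    if (cfg$replicate_cv < 0) note(paste0(sp, ": replicate_cv < 0"))
    for (mat in names(cfg$contents)) {
      for (el in names(cfg$contents[[mat]])) {
        p <- cfg$contents[[mat]][[el]]
        if (p[["mean"]] < 0 || p[["mean"]] > 100) {
          note(paste0(sp, "/", mat, "/", el, ": mean content outside [0, 100]"))
        }
        if (p[["sd"]] < 0) note(paste0(sp, "/", mat, "/", el, ": sd < 0"))
      }
    }
  }
  if (length(problems)) {
    stop("invalid simulation config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

# deterministic per-stream seed: hash the stream labels into [0, 2^31-2]
# so adding a species or compartment never perturbs other streams' draws
.stream_seed <- function(seed, ...) {
  h <- 0
  for (ch in utf8ToInt(paste(c(...), collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer((as.numeric(seed) + h) %% 2147483629)
}

#' Deterministic single-harmonic seasonal biomass
#'
#' `peak * (1 - a/2 + (a/2) * cos(2 pi (month - peak_month) / 12))`: equal to
#' `peak` at the peak month and `peak * (1 - a)` half a year away.
#'
#' @param peak Peak dry biomass, g DW m^-2.
#' @param amplitude Seasonal amplitude as a fraction of peak, in \[0, 1\].
#' @param peak_month Month (1-12) of maximum biomass.
#' @param month Month(s) to evaluate.
#' @return Biomass in g DW m^-2.
#' @export
seasonal_biomass <- function(peak, amplitude, peak_month, month) {
  peak * (1 - amplitude / 2 +
            amplitude / 2 * cos(2 * pi * (month - peak_month) / 12))
}

#' Noise-free annual mean biomass implied by a configuration
#'
#' Mean of the deterministic seasonal curve over the design's sampling
#' months; the quantity the mean-annual-stock estimator targets.
#'
#' @param config Simulation configuration.
#' @param species,compartment Which seasonal curve.
#' @return Mean biomass, g DW m^-2.
#' @export
expected_mean_biomass <- function(config, species, compartment) {
  bc <- config$species[[species]]$biomass[[compartment]]
  if (is.null(bc)) stop("no such species/compartment in config", call. = FALSE)
  months <- as.integer(format(config$design$dates, "%m"))
  mean(seasonal_biomass(bc$peak, bc$amplitude, bc$peak_month, months))
}

#' Noise-free belowground/aboveground ratio implied by a configuration
#' @param config Simulation configuration.
#' @param species Species name.
#' @return Ratio of annual-mean belowground to aboveground biomass.
#' @export
expected_biomass_ratio <- function(config, species) {
  expected_mean_biomass(config, species, "belowground") /
    expected_mean_biomass(config, species, "aboveground")
}

# normal truncated to [lo, hi] by redraw; means are far from the bounds in
# all default configurations so rejection is cheap
.rtruncnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  for (it in 1:100) {
    bad <- which(out < lo | out > hi)
    if (!length(bad)) break
    out[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  pmin(pmax(out, lo), hi)
}

.rdirichlet1 <- function(weights) {
  g <- stats::rgamma(length(weights), shape = weights, rate = 1)
  g / sum(g)
}

#' Generate a synthetic field survey
#'
#' Draws a complete survey (biomass, element contents, sediment properties)
#' under the configured design. Biomass is the deterministic seasonal curve
#' times lognormal replicate noise with unit mean and the configured
#' coefficient of variation; contents are truncated-normal per replicate;
#' sediment LOI and pH are uniform within the configured ranges, bulk
#' density truncated-normal, particle-size fractions Dirichlet (summing to
#' 100 exactly) and temperature seasonal with Gaussian noise. Fully
#' deterministic given `seed`; each species x site x variable has its own
#' seeded stream.
#'
#' @param config Configuration list (default [default_sim_config()]).
#' @param seed Integer master seed.
#' @return A `marsh_survey` object.
#' @export
generate_survey <- function(config = default_sim_config(), seed = 1) {
  validate_sim_config(config)
  des <- config$design
  months <- as.integer(format(des$dates, "%m"))
  n_rep <- des$replicates
  reps <- seq_len(n_rep)
  grid <- expand.grid(replicate = reps, date_i = seq_along(des$dates))

  biomass <- list(); contents <- list(); sediment <- list()
  for (sp in names(des$presence)) {
    cfg <- config$species[[sp]]
    if (is.null(cfg)) stop("species '", sp, "' has no parameters", call. = FALSE)
    cv <- cfg$replicate_cv
    sdlog <- sqrt(log(1 + cv^2))
    for (site in des$presence[[sp]]) {
      wb <- unname(des$water_bodies[[site]])
      for (comp in names(cfg$biomass)) {
        bc <- cfg$biomass[[comp]]
        set.seed(.stream_seed(seed, sp, site, comp, "biomass"))
        det <- seasonal_biomass(bc$peak, bc$amplitude, bc$peak_month,
                                months[grid$date_i])
        noise <- if (cv == 0) 1 else
          stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        biomass[[length(biomass) + 1L]] <- tibble::tibble(
          species = sp, site = site, water_body = wb,
          date = des$dates[grid$date_i], replicate = grid$replicate,
          compartment = comp, dry_mass_g_m2 = det * noise)
      }
      for (mat in names(cfg$contents)) {
        for (el in names(cfg$contents[[mat]])) {
          p <- cfg$contents[[mat]][[el]]
          set.seed(.stream_seed(seed, sp, site, mat, el, "content"))
          contents[[length(contents) + 1L]] <- tibble::tibble(
            species = sp, site = site, date = des$dates[grid$date_i],
            replicate = grid$replicate, matrix = mat, element = el,
            percent = .rtruncnorm(nrow(grid), p[["mean"]], p[["sd"]]))
        }
      }
      sc <- cfg$sediment
      set.seed(.stream_seed(seed, sp, site, "sediment"))
      bd <- .rtruncnorm(nrow(grid), sc$bulk_density[["mean"]],
                        sc$bulk_density[["sd"]], lo = 0.05, hi = 3)
      loi <- stats::runif(nrow(grid), sc$loi_range[1], sc$loi_range[2])
      ph <- stats::runif(nrow(grid), sc$ph_range[1], sc$ph_range[2])
      tc <- config$temperature
      temp <- tc$mean + tc$amplitude *
        cos(2 * pi * (months[grid$date_i] - tc$peak_month) / 12) +
        stats::rnorm(nrow(grid), 0, tc$sd)
      frac <- t(vapply(seq_len(nrow(grid)),
                       function(i) 100 * .rdirichlet1(sc$particle_weights),
                       numeric(6)))
      colnames(frac) <- names(sc$particle_weights)
      sediment[[length(sediment) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(species = sp, site = site,
                       date = des$dates[grid$date_i],
                       replicate = grid$replicate,
                       bulk_density_g_cm3 = bd, loi_percent = loi),
        tibble::as_tibble(frac),
        tibble::tibble(ph = ph, temperature_c = temp))
    }
  }
  new_marsh_survey(
    biomass = dplyr::bind_rows(biomass),
    contents = dplyr::bind_rows(contents),
    sediment = dplyr::bind_rows(sediment))
}

#' Generate a synthetic water-body coverage table
#'
#' Splits the configured total marsh area across five water bodies
#' (Dirichlet shares), splits each water body into a low and a mid-high
#' zone, and assigns species coverage fractions: the low-marsh pioneer
#' occupies the low zone of the water bodies where it forms stands, and the
#' mid-high species share the mid-high zone with fractions scaled so their
#' sum stays below 1. Deterministic given `seed`.
#'
#' @param config Configuration list (default [default_sim_config()]).
#' @param seed Integer seed.
#' @return Tibble with columns `water_body`, `species`, `marsh_zone`,
#'   `zone_area_ha`, `coverage_fraction`.
#' @export
generate_coverage <- function(config = default_sim_config(), seed = 1) {
  cc <- config$coverage
  set.seed(.stream_seed(seed, "coverage"))
  wbs <- cc$water_bodies
  wb_area <- cc$total_area_ha * .rdirichlet1(rep(2, length(wbs)))
  # a low zone exists only where the pioneer forms stands; elsewhere the
  # whole water body is mid-high marsh, so distinct zone areas sum to total
  low_frac <- ifelse(wbs %in% cc$low_species_water_bodies,
                     stats::runif(length(wbs), cc$low_fraction_range[1],
                                  cc$low_fraction_range[2]), 0)
  out <- list()
  for (i in seq_along(wbs)) {
    wb <- wbs[i]
    low_area <- wb_area[i] * low_frac[i]
    mid_area <- wb_area[i] - low_area
    if (wb %in% cc$low_species_water_bodies) {
      out[[length(out) + 1L]] <- tibble::tibble(
        water_body = wb, species = cc$low_species, marsh_zone = "low",
        zone_area_ha = low_area,
        coverage_fraction = stats::runif(1, cc$cover_range[1],
                                         cc$cover_range[2]))
    }
    present <- names(cc$mid_high_presence)[vapply(
      cc$mid_high_presence, function(v) wb %in% v, logical(1))]
    if (length(present)) {
      total_cover <- stats::runif(1, cc$cover_range[1], cc$cover_range[2])
      shares <- .rdirichlet1(rep(2, length(present)))
      # dominant mid-high species listed first gets the largest share
      shares <- sort(shares, decreasing = TRUE)
      out[[length(out) + 1L]] <- tibble::tibble(
        water_body = wb, species = present, marsh_zone = "mid_high",
        zone_area_ha = mid_area,
        coverage_fraction = total_cover * shares)
    }
  }
  cov <- dplyr::bind_rows(out)
  validate_coverage(cov)
  cov
}

#' Published lagoon-scale stock estimates for the Ria de Aveiro marshes
#'
#' Per-species, per-compartment C, N and P stocks (Mg) for the five dominant
#' halophytes of the Ria de Aveiro coastal lagoon (~4400 ha of salt marsh),
#' over the plant biomass and the top 25 cm of rhizosediment. Stocks for
#' J. maritimus and S. maritima come from the lagoon field survey; those for
#' H. portulacoides, S. perennis and B. maritimus were inferred from
#' comparable reference marshes (Tagus and Mondego estuaries) and are tagged
#' `inferred` with their provenance.
#'
#' The published per-species values are internally consistent with every
#' species-level and grand total; one printed compartment row total
#' (sediment N) disagrees with the sum of its own components by 300 Mg, so
#' totals here are always recomputed from the per-species values.
#'
#' @return Tibble with columns `element`, `species`, `compartment`,
#'   `stock_mg`, `status`, `provenance` (30 rows: 3 elements x 5 species x
#'   2 compartments).
#' @export
lagoon_stock_fixture <- function() {
  path <- system.file("extdata", "aveiro_lagoon_stocks.csv",
                      package = "marshstocks", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(out)
}
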