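test_that("per-date means and standard errors are the replicate statistics", {
  d <- as.Date("2012-02-15")
  out <- per_date_means(c(10, 12, 14), rep(d, 3))
  expect_equal(out$mean, 12)
  expect_equal(out$se, 2 / sqrt(3))
  expect_equal(out$n, 3L)

  # single replicate: mean kept, SE flagged as NA
  out1 <- per_date_means(5, d)
  expect_equal(out1$mean, 5)
  expect_true(is.na(out1$se))

  # replicate order is immaterial; dates come back chronologically
  dates <- rep(as.Date(c("2012-06-15", "2012-02-15")), each = 3)
  vals <- c(30, 32, 34, 10, 12, 14)
  perm <- sample(6)
  expect_equal(per_date_means(vals[perm], dates[perm]),
               per_date_means(vals, dates))
  expect_equal(per_date_means(vals, dates)$date,
               as.Date(c("2012-02-15", "2012-06-15")))
  expect_error(per_date_means(numeric(0), as.Date(character(0))), "empty")
})

test_that("annual production is the range of per-date means with earliest-date ties", {
  m <- per_date_means(c(10, 12, 14, 30, 32, 34),
                      rep(as.Date(c("2012-02-15", "2012-06-15")), each = 3))
  pr <- annual_production(m)
  expect_equal(pr$production, 20)
  expect_equal(pr$max_date, as.Date("2012-06-15"))
  expect_equal(pr$min_date, as.Date("2012-02-15"))
  expect_equal(pr$unit, "g_per_m2_per_yr")

  # constant series and chronological position of the maximum
  const <- data.frame(date = as.Date(c("2012-02-01", "2012-04-01")),
                      mean = c(7, 7))
  expect_equal(annual_production(const)$production, 0)
  up <- data.frame(date = as.Date(c("2012-02-01", "2012-04-01")),
                   mean = c(10, 30))
  dn <- data.frame(date = as.Date(c("2012-02-01", "2012-04-01")),
                   mean = c(30, 10))
  expect_equal(annual_production(up)$production,
               annual_production(dn)$production)

  # ties: earliest date wins for both extremes
  tie <- data.frame(date = as.Date(c("2012-02-01", "2012-04-01",
                                     "2012-06-01", "2012-08-01")),
                    mean = c(5, 9, 9, 5))
  pr <- annual_production(tie)
  expect_equal(pr$max_date, as.Date("2012-04-01"))
  expect_equal(pr$min_date, as.Date("2012-02-01"))

  expect_error(annual_production(const[1, ]), "two sampling dates")
})

test_that("annual production equals the brute-force range over all date pairs", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    m <- data.frame(date = as.Date("2012-01-01") + sort(sample(365, n)),
                    mean = runif(n, 0, 500))
    best <- 0
    for (a in seq_len(n)) {
      for (b in seq_len(n)) best <- max(best, m$mean[a] - m$mean[b])
    }
    expect_equal(annual_production(m)$production, best)
  }
})

test_that("plant and sediment stock formulas follow the unit chain", {
  expect_equal(plant_element_stock(1000, 40), 400)
  expect_equal(plant_element_stock(1000, 0), 0)
  expect_equal(plant_element_stock(2 * 1000, 40),
               2 * plant_element_stock(1000, 40))
  expect_error(plant_element_stock(100, 120), "\\[0, 100\\]")

  # content/100 (g per g DW) x BD (g DW cm^-3) x depth (cm) x 1e4 cm^2 m^-2
  expect_equal(sediment_stock(1, 1.0, 25), 2500)
  expect_equal(sediment_stock(2, 0.8, 25), 4000)
  expect_equal(sediment_stock(0, 1.2, 25), 0)
  expect_error(sediment_stock(1, 0, 25), "bulk density")
  expect_error(sediment_stock(1, 1, -5), "depth")

  expect_equal(annual_sediment_stock(1, 1.0, 0.5), 50)
  expect_equal(annual_sediment_stock(1, 1.0, 0), 0)
  expect_error(annual_sediment_stock(1, 1.0, -0.1), ">= 0")
  # proportionality to the standing-stock formula at any depth
  for (d in c(1, 10, 25)) {
    expect_equal(annual_sediment_stock(3, 0.9, 0.4),
                 sediment_stock(3, 0.9, d) / d * 0.4)
  }
})

test_that("mean annual plant stock averages per-date stocks and reduces to the simple product", {
  one <- data.frame(date = as.Date("2012-02-15"), replicate = 1L,
                    dry_mass_g_m2 = 100)
  ct <- data.frame(date = as.Date("2012-02-15"), replicate = 1L, percent = 10)
  st <- mean_annual_plant_stock(one, ct)
  expect_equal(st$stock, 10)
  expect_true(is.na(st$se))

  # two dates with per-date stocks 10 and 30: mean 20, SE over dates 10
  b2 <- data.frame(date = rep(as.Date(c("2012-02-15", "2012-06-15")), 2),
                   replicate = rep(1:2, each = 2),
                   dry_mass_g_m2 = c(100, 300, 100, 300))
  c2 <- data.frame(date = b2$date, replicate = b2$replicate, percent = 10)
  st <- mean_annual_plant_stock(b2, c2)
  expect_equal(st$stock, 20)
  expect_equal(st$se, 10)
  expect_equal(st$n_dates, 2L)

  # constant content: per-date-first pairing collapses to content x mean biomass
  set.seed(7)
  b <- data.frame(date = rep(as.Date(c("2012-02-15", "2012-06-15",
                                       "2012-10-15")), each = 3),
                  replicate = rep(1:3, 3),
                  dry_mass_g_m2 = runif(9, 50, 400))
  ct <- data.frame(date = b$date, replicate = b$replicate, percent = 42)
  pdm <- per_date_means(b$dry_mass_g_m2, b$date)
  expect_equal(mean_annual_plant_stock(b, ct)$stock,
               42 / 100 * mean(pdm$mean))
  expect_equal(mean_annual_plant_stock(b, ct)$stock,
               mean_annual_plant_stock(b, ct, order = "annual_mean")$stock)
  expect_error(mean_annual_plant_stock(b[0, ], ct), "no paired")
})

test_that("biomass ratio is belowground over aboveground annual means", {
  b <- data.frame(
    date = rep(as.Date(c("2012-02-15", "2012-06-15")), 2),
    replicate = 1L,
    compartment = rep(c("aboveground", "belowground"), each = 2),
    dry_mass_g_m2 = c(90, 110, 180, 200))
  expect_equal(biomass_ratio(b), 190 / 100)
  swapped <- b
  swapped$compartment <- rev(b$compartment)[c(2, 1, 4, 3)]
  swapped$compartment <- ifelse(b$compartment == "aboveground",
                                "belowground", "aboveground")
  expect_equal(biomass_ratio(swapped), 100 / 190)
  b$dry_mass_g_m2[b$compartment == "aboveground"] <- 0
  expect_error(biomass_ratio(b), "zero")
})

test_that("survey stocks conserve plant_total = above + below everywhere", {
  s <- generate_survey(seed = 5)
  acc <- survey_stocks(s, sedimentation_rate_cm_yr = 0.4)
  wide <- tidyr::pivot_wider(
    acc$stocks[acc$stocks$compartment %in%
                 c("plant_above", "plant_below", "plant_total"),
               c("element", "species", "site", "compartment", "value")],
    names_from = "compartment", values_from = "value")
  expect_gt(nrow(wide), 0L)
  expect_equal(wide$plant_total, wide$plant_above + wide$plant_below)

  # annual sediment stocks scale with the sedimentation rate, not the depth
  ann <- acc$stocks[acc$stocks$compartment == "sediment_annual", ]
  std <- acc$stocks[acc$stocks$compartment == "sediment", ]
  expect_equal(nrow(ann), nrow(std))
  merged <- merge(ann, std, by = c("element", "species", "site"))
  expect_equal(merged$value.x, merged$value.y / 25 * 0.4)
})

test_that("tiny survey stocks match hand arithmetic end to end", {
  acc <- survey_stocks(tiny_survey())
  # aboveground biomass per-date means are 100 and 300 -> annual mean 200;
  # C content 40% -> 80 g C m-2
  above_c <- acc$stocks[acc$stocks$element == "C" &
                          acc$stocks$compartment == "plant_above", ]
  expect_equal(above_c$value, 80)
  sed_c <- acc$stocks[acc$stocks$element == "C" &
                        acc$stocks$compartment == "sediment", ]
  expect_equal(sed_c$value, 40 / 100 * 1.0 * 25 * 1e4)
  prod_b <- acc$production[acc$production$quantity == "biomass" &
                             acc$production$compartment == "aboveground", ]
  expect_equal(prod_b$production, 200)  # 400 - 200
})
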