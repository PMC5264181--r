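test_that("the generator is deterministic in the seed", {
  s1 <- generate_survey(seed = 42)
  s2 <- generate_survey(seed = 42)
  expect_identical(s1, s2)
  s3 <- generate_survey(seed = 43)
  expect_false(identical(s1$biomass$dry_mass_g_m2,
                         s3$biomass$dry_mass_g_m2))
  expect_identical(generate_coverage(seed = 42), generate_coverage(seed = 42))
})

test_that("streams are independent: removing a species leaves the other untouched", {
  cfg <- default_sim_config()
  full <- generate_survey(cfg, seed = 7)
  cfg$design$presence[["Spartina maritima"]] <- NULL
  juncus_only <- generate_survey(cfg, seed = 7)
  keep <- full$biomass$species == "Juncus maritimus"
  expect_identical(full$biomass[keep, ], juncus_only$biomass)
})

test_that("zero amplitude and zero noise give constant biomass and zero production", {
  cfg <- default_sim_config()
  for (sp in names(cfg$species)) {
    cfg$species[[sp]]$replicate_cv <- 0
    for (comp in names(cfg$species[[sp]]$biomass)) {
      cfg$species[[sp]]$biomass[[comp]]$amplitude <- 0
    }
  }
  s <- generate_survey(cfg, seed = 1)
  ag <- s$biomass[s$biomass$species == "Juncus maritimus" &
                    s$biomass$site == "site1" &
                    s$biomass$compartment == "aboveground", ]
  expect_equal(unique(ag$dry_mass_g_m2),
               cfg$species[["Juncus maritimus"]]$biomass$aboveground$peak)
  pdm <- per_date_means(ag$dry_mass_g_m2, ag$date)
  expect_equal(annual_production(pdm)$production, 0)
})

test_that("noise-free ratios equal the configured closed form exactly", {
  cfg <- default_sim_config()
  for (sp in names(cfg$species)) cfg$species[[sp]]$replicate_cv <- 0
  s <- generate_survey(cfg, seed = 1)
  for (sp in names(cfg$design$presence)) {
    slice <- s$biomass[s$biomass$species == sp &
                         s$biomass$site == cfg$design$presence[[sp]][1], ]
    expect_equal(biomass_ratio(slice), expected_biomass_ratio(cfg, sp))
  }
  # the defaults encode root-dominated biomass: 1.6 and 1.9
  expect_equal(expected_biomass_ratio(cfg, "Juncus maritimus"), 1.6)
  expect_equal(expected_biomass_ratio(cfg, "Spartina maritima"), 1.9)
})

test_that("generated surveys always satisfy the data-model invariants", {
  for (seed in c(1, 99, 4242)) {
    rep <- validate_survey(generate_survey(seed = seed))
    expect_equal(nrow(rep$errors), 0L)
  }
})

test_that("generated surveys reflect the designed structure and magnitudes", {
  s <- generate_survey(seed = 3)
  b <- s$biomass
  # design: J. maritimus at 3 sites, S. maritima at 2, 6 dates x 3 replicates
  expect_setequal(unique(b$site[b$species == "Juncus maritimus"]),
                  c("site1", "site2", "site3"))
  expect_setequal(unique(b$site[b$species == "Spartina maritima"]),
                  c("site2", "site3"))
  expect_equal(length(unique(b$date)), 6L)
  expect_equal(max(b$replicate), 3L)
  # J. maritimus carries more biomass and a more organic sediment
  mean_b <- tapply(b$dry_mass_g_m2, b$species, mean)
  expect_gt(mean_b[["Juncus maritimus"]], mean_b[["Spartina maritima"]])
  loi <- tapply(s$sediment$loi_percent, s$sediment$species, range)
  expect_true(all(loi[["Juncus maritimus"]] >= 12 &
                    loi[["Juncus maritimus"]] <= 28))
  expect_true(all(loi[["Spartina maritima"]] >= 6 &
                    loi[["Spartina maritima"]] <= 12))
  expect_true(all(s$sediment$ph >= 5.9 & s$sediment$ph <= 7.2))
})

test_that("invalid configurations are rejected with a list of violations", {
  cfg <- default_sim_config()
  cfg$species[["Juncus maritimus"]]$biomass$aboveground$amplitude <- 1.4
  cfg$species[["Spartina maritima"]]$replicate_cv <- -1
  err <- tryCatch(generate_survey(cfg), error = conditionMessage)
  expect_match(err, "amplitude")
  expect_match(err, "replicate_cv")
})

test_that("coverage tables partition the configured lagoon area", {
  for (seed in c(1, 7)) {
    cov <- generate_coverage(seed = seed)
    zones <- cov[!duplicated(paste(cov$water_body, cov$marsh_zone)), ]
    expect_equal(sum(zones$zone_area_ha), 4400, tolerance = 1e-9)
    sums <- tapply(cov$coverage_fraction,
                   paste(cov$water_body, cov$marsh_zone), sum)
    expect_true(all(sums <= 1 + 1e-9))
    # the pioneer occupies only the low zone, in three water bodies
    sm <- cov[cov$species == "Spartina maritima", ]
    expect_true(all(sm$marsh_zone == "low"))
    expect_equal(length(unique(sm$water_body)), 3L)
    jm <- cov[cov$species == "Juncus maritimus", ]
    expect_setequal(unique(jm$water_body), paste0("WB", 1:5))
    expect_true(all(jm$marsh_zone == "mid_high"))
  }
})

test_that("the lagoon stock fixture is complete and traceable", {
  fix <- lagoon_stock_fixture()
  expect_equal(nrow(fix), 30L)  # 3 elements x 5 species x 2 compartments
  expect_setequal(unique(fix$species), names(marsh_species()))
  expect_equal(
    fix$stock_mg[fix$element == "C" & fix$species == "Juncus maritimus" &
                   fix$compartment == "plant"], 17368)
  expect_equal(
    fix$stock_mg[fix$element == "P" &
                   fix$species == "Bolboschoenus maritimus" &
                   fix$compartment == "sediment"], 160)
  expect_setequal(fix$status[fix$species %in%
                               c("Juncus maritimus", "Spartina maritima")],
                  "measured")
  expect_true(all(fix$provenance != ""))
})
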