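# small in-code fixtures shared across test files

# a hand-sized survey: one species, one site, two dates, two replicates
tiny_survey <- function() {
  dates <- as.Date(c("2012-02-15", "2012-06-15"))
  biomass <- expand.grid(
    date = dates, replicate = 1:2,
    compartment = c("aboveground", "belowground"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  biomass$species <- "Juncus maritimus"
  biomass$site <- "site1"
  biomass$water_body <- "WB5"
  biomass$dry_mass_g_m2 <- c(100, 300, 100, 300, 200, 600, 200, 600)
  contents <- expand.grid(
    date = dates, replicate = 1:2,
    matrix = c("aboveground", "belowground", "sediment"),
    element = c("C", "N", "P"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  contents$species <- "Juncus maritimus"
  contents$site <- "site1"
  contents$percent <- rep(c(40, 1.0, 0.1), each = 12)
  sediment <- expand.grid(
    date = dates, replicate = 1:2,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sediment$species <- "Juncus maritimus"
  sediment$site <- "site1"
  sediment$bulk_density_g_cm3 <- 1.0
  sediment$loi_percent <- 20
  sediment$g1000 <- 5; sediment$g500 <- 5; sediment$g250 <- 10
  sediment$g125 <- 15; sediment$g063 <- 10; sediment$g0063 <- 55
  sediment$ph <- 6.5
  sediment$temperature_c <- 15
  new_marsh_survey(biomass = biomass, contents = contents,
                   sediment = sediment)
}

# brute-force Euclidean distances by explicit double loop (test oracle)
brute_distances <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    }
  }
  d
}

# brute-force one-way pseudo-F with explicit group loops (test oracle)
brute_pseudo_f <- function(d, groups) {
  groups <- factor(groups)
  n <- nrow(d)
  a <- nlevels(groups)
  ss_total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) ss_total <- ss_total + d[i, j]^2
  }
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    acc <- 0
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in (i + 1):length(idx)) acc <- acc + d[idx[i], idx[j]]^2
    }
    ss_within <- ss_within + acc / length(idx)
  }
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

# exhaustive two-group permutation p-value for a 3-vs-3 design (test oracle)
exhaustive_p_3v3 <- function(d, f_obs) {
  combs <- utils::combn(6, 3)
  fs <- apply(combs, 2, function(idx) {
    g <- factor(ifelse(seq_len(6) %in% idx, "A", "B"))
    brute_pseudo_f(d, g)
  })
  mean(fs >= f_obs)
}
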