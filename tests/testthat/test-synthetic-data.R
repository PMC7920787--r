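test_that("default config has the documented structure", {
  cfg <- make_default_config(the_catalog)
  expect_s3_class(cfg, "sban_sim_config")
  expect_identical(nrow(cfg$catalog), 14L)
  expect_setequal(unique(cfg$habitat_suitability$habitat), SBAN_HABITATS)
  expect_setequal(unique(cfg$habitat_suitability$regime), SBAN_REGIMES)
  # managed strata at least as suitable as unmanaged, species by species
  suit <- cfg$habitat_suitability
  wide <- merge(suit[suit$regime == "R1", ], suit[suit$regime == "R2", ],
                by = c("habitat", "species_id"))
  expect_true(all(wide$p_include.x >= wide$p_include.y))
  # guild-mates share a common nonzero loading on the activity nodes
  g3 <- the_catalog$species_id[the_catalog$guild == "G3"]
  l <- cfg$loadings[cfg$loadings$node %in% paste0(g3, ":forage"), "loading"]
  expect_identical(length(unique(l)), 1L)
  expect_gt(unique(l), 0)
})

test_that("config validation names the offending field", {
  cfg <- make_default_config(the_catalog)
  bad <- cfg; bad$dispersion <- -1
  expect_error(validate_sim_config(bad), "dispersion")
  bad <- cfg; bad$activity_split <- 1.4
  expect_error(validate_sim_config(bad), "activity_split")
  bad <- cfg; bad$behavior_rates["courtship"] <- 2
  expect_error(validate_sim_config(bad), "behavior_rates")
  bad <- cfg; bad$habitat_suitability$p_include[1] <- -0.1
  expect_error(simulate_events(bad), "habitat_suitability")
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- make_default_config(the_catalog, n_days = 6, seed = 9)
  a <- simulate_events(cfg)
  b <- simulate_events(cfg)
  expect_identical(a, b)
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(a, simulate_events(cfg2)))
  # one selection event per site per day
  a$key <- paste(a$site_id, a$date)
  expect_true(all(tapply(a$event_id, a$key,
                         function(x) length(unique(x))) == 1))
})

test_that("zero behavior rates produce no behavior rows, and counts nest", {
  cfg <- make_default_config(the_catalog, n_days = 6, seed = 2)
  cfg$behavior_rates[] <- 0
  events <- simulate_events(cfg)
  expect_true(all(events$behavior_class %in% c("forage", "roost")))

  # behavior counts never exceed the species' activity total in an event
  cfg <- make_default_config(the_catalog, n_days = 10, seed = 4)
  events <- simulate_events(cfg)
  key <- paste(events$event_id, events$habitat, events$species_id)
  act <- events$behavior_class %in% c("forage", "roost")
  totals <- tapply(events$count[act], key[act], sum)
  beh <- tapply(events$count[!act], key[!act], max)
  shared <- intersect(names(beh), names(totals))
  expect_identical(length(setdiff(names(beh), names(totals))), 0L)
  expect_true(all(beh[shared] <= totals[shared]))
})

test_that("simulated foraging means match the configured value (LLN)", {
  # 2,000 R1 events (2 sites x 1,000 days), loadings zeroed
  cfg <- make_default_config(the_catalog, n_days = 1000, seed = 21)
  cfg$loadings$loading <- 0
  events <- simulate_events(cfg)
  n_events <- 2 * cfg$n_days
  sel <- events$regime == "R1" & events$habitat == "MF" &
    events$species_id == "A_alba" & events$behavior_class == "forage"
  counts <- c(events$count[sel], rep(0, n_events - sum(sel)))
  expected <- 0.55 * 30 * 0.7   # p_include * mean * activity_split
  mc_se <- stats::sd(counts) / sqrt(n_events)
  expect_lt(abs(mean(counts) - expected), 3 * mc_se)
})

# a one-site, mudflat-only configuration for correlation-planting checks
planting_config <- function(n_days, seed, species = the_catalog$species_id,
                            split = 0.7, rates = c(competition = 0.2,
                                                   aggression = 0.15,
                                                   courtship = 0.1)) {
  cfg <- make_default_config(the_catalog, n_days = n_days, seed = seed)
  cfg$sites <- data.frame(site_id = "L1", regime = "R1",
                          stringsAsFactors = FALSE)
  suit <- cfg$habitat_suitability
  cfg$habitat_suitability$p_include <-
    ifelse(suit$habitat == "MF" & suit$species_id %in% species, 1, 0)
  cfg$abundance_mean$mean <- 30
  cfg$activity_split <- split
  cfg$behavior_rates <- rates
  cfg$loadings <- cfg$loadings[0, ]
  cfg
}

planted_corr <- function(cfg) {
  events <- simulate_events(cfg)
  mat <- pivot_abundance(events, the_catalog, "R1", "MF")
  suppressWarnings(stats::cor(mat))
}

test_that("plant_block_correlation validates its inputs", {
  cfg <- planting_config(10, 1)
  expect_error(plant_block_correlation(cfg, list("A_alba:forage"), 1.2),
               "rho")
  expect_error(plant_block_correlation(cfg, list("A_alba:forage"), -0.1),
               "rho")
  expect_error(plant_block_correlation(cfg, list(c("A_alba:forage",
                                                   "A_alba:forage")), 0.5),
               "repeats")
  expect_error(plant_block_correlation(cfg, list("Dodo:forage"), 0.5),
               "unknown node")
  # rho = 0 is the null planting: all loadings vanish
  null <- plant_block_correlation(cfg, list(c("A_alba:forage",
                                              "C_nigra:forage")), 0)
  expect_identical(nrow(null$loadings), 0L)
})

test_that("two planted blocks separate within- from between-group correlation", {
  g1 <- paste0(c("A_alba", "A_cinerea", "C_nigra"), ":forage")
  g2 <- paste0(c("A_fabalis", "G_grus", "A_albifrons"), ":forage")
  cfg <- plant_block_correlation(planting_config(1000, 31), list(g1, g2), 0.6)
  corr <- planted_corr(cfg)
  within <- c(corr[g1, g1][upper.tri(corr[g1, g1])],
              corr[g2, g2][upper.tri(corr[g2, g2])])
  between <- as.vector(corr[g1, g2])
  expect_gt(mean(within), mean(between))
  expect_gt(mean(within), 0.4)          # near the planted rho
  expect_lt(abs(mean(between)), 0.1)    # approximately uncorrelated
})

test_that("one all-node block makes every pairwise correlation positive", {
  cfg <- planting_config(1000, 32)
  all_nodes <- node_labels(the_catalog)
  cfg <- plant_block_correlation(cfg, list(all_nodes), 0.6)
  corr <- planted_corr(cfg)
  off <- corr[upper.tri(corr)]
  expect_true(all(off > 0))
})
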