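test_that("merging fills gaps from the supplement, keeps primary precedence, appends new species", {
  primary <- toy_traits()
  primary$litter_size[1] <- NA  # Aa_aa missing litter size
  supplement <- data.frame(
    species = c("Aa_aa", "Bb_bb", "Dd_dd"),
    clade = c("Mammalia", "Mammalia", "Reptilia"),
    adult_body_mass = c(999, 999, 40),
    litter_size = c(4, 4, 6),
    litters_per_year = c(NA, NA, 2),
    mass_at_independence = c(NA, NA, 4),
    max_longevity = c(NA, NA, 10),
    female_maturity_age = c(NA, NA, 1),
    svl_min = NA_real_, svl_max = NA_real_,
    stringsAsFactors = FALSE
  )
  merged <- merge_trait_sources(primary, supplement)

  # gap filled from supplement, tagged
  expect_equal(merged$litter_size[merged$species == "Aa_aa"], 4)
  expect_equal(merged$litter_size_source[merged$species == "Aa_aa"], "supplement")
  # primary wins where both present
  expect_equal(merged$litter_size[merged$species == "Bb_bb"], 3)
  expect_equal(merged$adult_body_mass[merged$species == "Aa_aa"], 100)
  expect_equal(merged$litter_size_source[merged$species == "Bb_bb"], "primary")
  # supplement-only species appended whole with supplement provenance
  expect_true("Dd_dd" %in% merged$species)
  dd <- merged[merged$species == "Dd_dd", ]
  expect_equal(dd$litter_size_source, "supplement")
  expect_equal(nrow(merged), length(union(primary$species, supplement$species)))
})

test_that("merging rejects duplicate species and schema mismatches", {
  tab <- toy_traits()
  dup <- rbind(tab, tab[1, ])
  expect_error(merge_trait_sources(dup, tab), "Aa_aa")
  bad <- tab[, setdiff(names(tab), "litter_size")]
  expect_error(merge_trait_sources(tab, bad), "schema mismatch")
})

test_that("snout-vent-length allometry follows the power law and validates input", {
  p11 <- allometry_params("Anura", a = 1, b = 1)
  expect_equal(svl_to_mass(10, p11), 10)
  expect_equal(svl_to_mass(10, allometry_params("Anura", a = 2, b = 3)), 2000)
  expect_error(svl_to_mass(0, p11), "positive")
  expect_error(allometry_params("Anura", a = -1, b = 1), "'a'")

  expect_equal(amphibian_mean_mass(10, 10, p11), 10)
  expect_equal(amphibian_mean_mass(10, 30, p11), 20)
  expect_error(amphibian_mean_mass(20, 10, p11), "svl_min")
})

test_that("adult lifespan is longevity minus maturity, with degenerate records undefined", {
  rec <- data.frame(max_longevity = c(12, 5, 100), female_maturity_age = c(2, 5, 1))
  expect_equal(adult_lifespan(rec), c(10, NA, 99))
  expect_equal(adult_lifespan(rec, mode = "raw_longevity"), c(12, 5, 100))
})

test_that("dimensionless metrics match their defining ratios", {
  rec <- data.frame(
    litter_size = 2, litters_per_year = 1, mass_at_independence = 10,
    adult_body_mass = 100, max_longevity = 7, female_maturity_age = 2
  )
  expect_equal(compute_lre(rec), 1.0)   # 2*1*10/100 * 5
  expect_equal(compute_rrl(rec), 2.5)   # (7-2)/2
  expect_equal(compute_ros(rec), 0.1)

  unit <- data.frame(
    litter_size = 1, litters_per_year = 1, mass_at_independence = 50,
    adult_body_mass = 50, max_longevity = 2, female_maturity_age = 1
  )
  expect_equal(compute_lre(unit), 1.0)
  expect_equal(compute_ros(unit), 1.0)

  # missing components leave the metric undefined, never zero
  rec_na <- rec; rec_na$litter_size <- NA
  expect_true(is.na(compute_lre(rec_na)))
})

test_that("metrics are exactly invariant under common unit rescaling", {
  rec <- data.frame(
    litter_size = 2.5, litters_per_year = 1.3, mass_at_independence = 11,
    adult_body_mass = 123, max_longevity = 9, female_maturity_age = 1.7
  )
  mass_k <- rec; mass_k$mass_at_independence <- rec$mass_at_independence / 1000
  mass_k$adult_body_mass <- rec$adult_body_mass / 1000
  expect_identical(compute_lre(rec), compute_lre(mass_k))
  expect_identical(compute_ros(rec), compute_ros(mass_k))
  time_k <- rec; time_k$max_longevity <- rec$max_longevity * 365
  time_k$female_maturity_age <- rec$female_maturity_age * 365
  expect_identical(compute_rrl(rec), compute_rrl(time_k))
})

test_that("metric table keeps complete species only and reports the drops", {
  tab <- toy_traits()
  extra <- tab[1:2, ]
  extra$species <- c("Ee_ee", "Ff_ff")
  extra$female_maturity_age <- NA
  tab <- rbind(tab, extra)
  mt <- build_metric_table(tab)
  expect_equal(nrow(mt$metrics), 3L)
  expect_equal(mt$report$n_dropped, 2L)
  expect_equal(mt$report$dropped_missing_field$female_maturity_age, 2L)
  expect_equal(mt$metrics$log_lre, log(mt$metrics$lre))
  expect_equal(mt$metrics$log_mass, log(mt$metrics$mass_g))

  # flagged records: maturity >= longevity
  bad <- toy_traits()
  bad$female_maturity_age[1] <- bad$max_longevity[1]
  mtb <- build_metric_table(bad)
  expect_equal(nrow(mtb$metrics), 2L)
  expect_equal(mtb$report$flagged_maturity_ge_longevity, "Aa_aa")
})

test_that("metric table is order-independent", {
  bundle <- generate_trait_database(sim_config(
    n_tips = c(Mammalia = 20, Aves = 15),
    crown_ages = c(Mammalia = 170, Aves = 110),
    mass_model = list(
      Mammalia = list(model = "lambda", sigma2 = 0.05, z0 = 6, param = 0.99),
      Aves = list(model = "lambda", sigma2 = 0.04, z0 = 4.5, param = 0.99)
    ),
    missingness = c(adult_body_mass = 0, litter_size = 0, litters_per_year = 0,
                    mass_at_independence = 0, max_longevity = 0,
                    female_maturity_age = 0),
    supplement_only_rate = 0, seed = 42
  ))
  tab <- bundle$primary
  set.seed(99)
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(build_metric_table(tab)$metrics,
               build_metric_table(shuffled)$metrics)
})

test_that("recomputed metrics round-trip the generating values exactly", {
  cfg <- sim_config(
    n_tips = c(Amphibia = 25, Mammalia = 30),
    crown_ages = c(Amphibia = 310, Mammalia = 170),
    mass_model = list(
      Amphibia = list(model = "OU", sigma2 = 0.05, z0 = 3.5, param = 0.01),
      Mammalia = list(model = "lambda", sigma2 = 0.05, z0 = 6, param = 0.99)
    ),
    missingness = c(adult_body_mass = 0, litter_size = 0, litters_per_year = 0,
                    mass_at_independence = 0, max_longevity = 0,
                    female_maturity_age = 0),
    supplement_only_rate = 0, seed = 7
  )
  bundle <- generate_trait_database(cfg)
  mt <- build_metric_table(bundle$primary)
  truth <- bundle$ground_truth[match(mt$metrics$species, bundle$ground_truth$species), ]
  expect_equal(mt$metrics$lre, truth$lre, tolerance = 1e-12)
  expect_equal(mt$metrics$rrl, truth$rrl, tolerance = 1e-12)
  expect_equal(mt$metrics$ros, truth$ros, tolerance = 1e-12)
  expect_equal(mt$report$n_dropped, 0L)
})

test_that("amphibian mass can be rebuilt from the length range", {
  tab <- toy_traits()
  tab$clade[3] <- "Amphibia"
  tab$order <- c(NA, NA, "Anura")
  tab$svl_min[3] <- 20; tab$svl_max[3] <- 40
  al <- list(Anura = allometry_params("Anura", a = 0.1, b = 2))
  mt <- build_metric_table(tab, amphibian_mass_mode = "mean_mass_from_svl",
                           allometry = al)
  amph <- mt$metrics[mt$metrics$clade == "Amphibia", ]
  expect_equal(amph$mass_g, (0.1 * 400 + 0.1 * 1600) / 2)
  expect_error(build_metric_table(tab, amphibian_mass_mode = "mean_mass_from_svl"),
               "allometry")
})
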