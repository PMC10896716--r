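# Synthetic-data generator: restrictions, determinism, censoring mechanics.

test_that("generated preferences satisfy demand-theory restrictions", {
  cfg <- tiny_cfg()
  prefs <- generate_preferences(cfg)
  expect_identical(prefs$A, t(prefs$A))
  expect_identical(prefs$D, t(prefs$D))
  expect_lt(max(abs(rowSums(prefs$A))), 1e-12)
  expect_lt(max(abs(rowSums(prefs$D))), 1e-12)
  ev <- eigen(prefs$Sigma_e, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
  # baseline shares admissible
  expect_true(all(prefs$w0 > 0.01 & prefs$w0 < 0.6))
  # dispersion-free two-group case still restriction-valid
  cfg2 <- synth_config(n_households = 10, n_waves = 1, n_clusters = 2,
                       n_groups = 2, price_dispersion = 0,
                       share_error_scale = 0, seed = 1)
  p2 <- generate_preferences(cfg2)
  expect_equal(dim(p2$A), c(2, 2))
  expect_lt(max(abs(rowSums(p2$A)), abs(rowSums(p2$D))), 1e-12)
})

test_that("same seed gives bit-identical preferences and panel", {
  cfg <- tiny_cfg(seed = 9)
  p1 <- generate_preferences(cfg)
  p2 <- generate_preferences(cfg)
  expect_identical(p1$b, p2$b)
  expect_identical(p1$Sigma_e, p2$Sigma_e)
  pan1 <- generate_panel(cfg, p1)
  pan2 <- generate_panel(cfg, p2)
  expect_identical(pan1$records, pan2$records)
  expect_identical(pan1$households, pan2$households)
})

test_that("implied latent shares are finite and add up with the numeraire", {
  cfg <- synth_config(n_households = 100, n_waves = 1, n_clusters = 10,
                      n_groups = 6, poly_degree_true = 2, seed = 1)
  prefs <- generate_preferences(cfg)
  set.seed(42)
  n <- 100
  lnp <- matrix(rnorm(n * 6, 0, 0.2), n, 6)
  lnx <- rnorm(n, easidemand:::typical_y(cfg), 0.6)
  z <- matrix(rnorm(n * 4, 0, 0.5), n, 4)
  pr <- predict_shares(prefs, lnp, lnx, z = z)
  expect_true(all(is.finite(pr$w)))
  expect_lt(max(abs(rowSums(pr$w) + pr$w_num - 1)), 1e-12)
})

test_that("observed budget shares sum to one for every household-wave", {
  fx <- get_tiny()
  tot <- rowSums(fx$pan$truth$w_obs) + fx$pan$truth$w_num
  expect_lt(max(abs(tot - 1)), 1e-12)
  # item-level accounting: value = 0 exactly when quantity = 0
  expect_true(all((fx$pan$records$value == 0) == (fx$pan$records$quantity == 0)))
  expect_true(all(fx$pan$records$quantity >= 0))
})

test_that("with noise and confounding disabled, observed shares equal the model mean", {
  cfg <- noiseless_cfg()
  prefs <- noiseless_prefs(cfg)
  pan <- generate_panel(cfg, prefs)
  expect_equal(mean(pan$truth$w_obs == 0), 0)
  pr <- predict_shares(prefs, pan$truth$lnp, pan$truth$lnx,
                       z = pan$truth$shifters[pan$households$hh, ])
  expect_identical(pr$w, pan$truth$w_latent)
  expect_lt(max(abs(pr$w - pan$truth$w_obs)), 1e-14)
})

test_that("large share errors produce zero-consumption records", {
  cfg <- tiny_cfg(share_error_scale = 0.15)
  prefs <- generate_preferences(cfg)
  pan <- generate_panel(cfg, prefs)
  expect_gt(sum(pan$truth$w_obs == 0), 0)
})

test_that("censoring rate is monotone in the share error scale", {
  rates <- vapply(c(0.01, 0.05, 0.12), function(s) {
    cfg <- tiny_cfg(seed = 5, share_error_scale = s)
    pan <- generate_panel(cfg, generate_preferences(cfg))
    mean(pan$truth$w_obs == 0)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("panel means match the censored model prediction across seeds", {
  # Monte-Carlo oracle: mean observed share over independent replicates
  cfg0 <- synth_config(n_households = 2000, n_waves = 3, seed = 7)
  prefs <- generate_preferences(cfg0)
  pan <- generate_panel(cfg0, prefs)
  obs_mean <- colMeans(pan$truth$w_obs)
  reps <- vapply(1:12, function(k) {
    cfgk <- synth_config(n_households = 400, n_waves = 1, seed = 5000 + k)
    colMeans(generate_panel(cfgk, prefs)$truth$w_obs)
  }, numeric(cfg0$n_groups))
  mc_mean <- rowMeans(reps)
  mc_se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(obs_mean - mc_mean) <= 3 * pmax(mc_se, 1e-3)))
})

test_that("default composition is deterministic and nutritionally coherent", {
  c1 <- default_composition(6, seed = 4)
  c2 <- default_composition(6, seed = 4)
  expect_identical(c1, c2)
  comp <- unclass(c1)
  expect_true(all(comp >= 0))
  expect_true(all(comp[, "energy_kcal"] > 0))
  atwater <- 4 * comp[, "carb_g"] + 4 * comp[, "protein_g"] + 9 * comp[, "fat_g"]
  expect_true(all(abs(atwater - comp[, "energy_kcal"]) <= 0.05 * comp[, "energy_kcal"]))
  # staple archetype: most energy from carbohydrate
  staple <- which(attr(c1, "archetype") == "staple")[1]
  expect_gt(4 * comp[staple, "carb_g"] / comp[staple, "energy_kcal"], 0.7)
  # archetype coverage for the policy categories
  expect_setequal(unique(stats::na.omit(default_category_map(c1)$category)),
                  c("SG", "PN", "ASF", "FFV", "SS"))
})

test_that("panel round-trips through CSV", {
  fx <- get_tiny()
  dir <- withr::local_tempdir()
  write_panel(fx$pan, dir)
  back <- read_panel(dir)
  expect_equal(back$households, fx$pan$households)
  expect_equal(back$records, fx$pan$records, tolerance = 1e-12)
  expect_equal(unclass(back$composition), unclass(fx$pan$composition),
               tolerance = 1e-12, ignore_attr = TRUE)
  # prepared table built from the CSV round-trip matches
  prep2 <- prepare_observations(back)
  expect_equal(prep2$lnp_g1, fx$prep$lnp_g1, tolerance = 1e-9)
})
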