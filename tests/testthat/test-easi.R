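# Demand-system core: implicit utility, share prediction, censoring stage,
# restricted IV estimation, degree selection.

test_that("implicit utility reduces to the Stone-deflated form", {
  expect_equal(implicit_utility(2, c(0.5, 0.5, 0), c(1, 1, 0)), 1)
  # base prices: y equals log expenditures
  expect_equal(implicit_utility(c(1.3, 2.1), c(0.4, 0.3, 0.3), c(0, 0, 0)),
               c(1.3, 2.1))
  # adding a constant to all log prices lowers y by that constant
  w <- c(0.2, 0.3, 0.5); lnp <- c(0.1, -0.3, 0.2)
  y0 <- implicit_utility(1.7, w, lnp)
  expect_equal(implicit_utility(1.7, w, lnp + 0.25), y0 - 0.25)
})

test_that("exact-affine utility matches its defining equation", {
  p <- rand_params(J = 3, seed = 2)
  w <- c(0.2, 0.25, 0.15, 0.4); lnp <- c(0.1, -0.2, 0.05, 0)
  y <- implicit_utility(2.5, w, lnp, A = p$A, D = p$D)
  lp <- lnp[1:3]
  lhs <- y * (1 - 0.5 * drop(lp %*% p$D %*% lp))
  rhs <- 2.5 - sum(w * lnp) + 0.5 * drop(lp %*% p$A %*% lp)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("share prediction solves the joint fixed point", {
  # scalar root-finder oracle on y - lnx + sum w_k(y) lnp_k (exact form)
  for (sd in 1:5) {
    p <- rand_params(J = 3, seed = sd)
    set.seed(100 + sd)
    lnp <- matrix(rnorm(3, 0, 0.25), 1, 3)
    lnx <- rnorm(1, 3, 0.5)
    pr <- predict_shares(p, lnp, lnx, tol = 1e-13)
    qA <- drop(lnp %*% p$A %*% t(lnp)); qD <- drop(lnp %*% p$D %*% t(lnp))
    g <- function(y) {
      W <- drop(easidemand:::poly_matrix(y, p$degree) %*% t(p$b)) +
        drop(p$A %*% t(lnp)) + y * drop(p$D %*% t(lnp))
      y * (1 - 0.5 * qD) - (lnx - sum(W * lnp) + 0.5 * qA)
    }
    y_root <- uniroot(g, c(pr$y - 1, pr$y + 1), tol = 1e-12)$root
    expect_equal(pr$y, y_root, tolerance = 1e-8)
    expect_lt(abs(sum(pr$w) + pr$w_num - 1), 1e-12)
  }
})

test_that("Cobb-Douglas preferences give constant shares", {
  w0 <- c(0.15, 0.2, 0.1)
  p <- cobb_douglas_params(w0)
  lnp <- matrix(rnorm(15, 0, 0.4), 5, 3)
  pr <- predict_shares(p, lnp, ln_x = rnorm(5, 3, 1))
  expect_equal(pr$w, matrix(w0, 5, 3, byrow = TRUE), tolerance = 1e-12)
})

test_that("at base prices shares are a polynomial in log expenditures", {
  p <- rand_params(J = 3, seed = 7)
  lnx <- c(2, 3, 4)
  pr <- predict_shares(p, matrix(0, 3, 3), lnx)
  expect_equal(pr$y, lnx)
  expect_equal(pr$w, easidemand:::poly_matrix(lnx, p$degree) %*% t(p$b),
               tolerance = 1e-12)
  expect_equal(pr$iterations, 1L)
})

test_that("participation stage returns proper probabilities and beats the base rate", {
  cfg <- tiny_cfg(seed = 11)
  pan <- generate_panel(cfg, generate_preferences(cfg))
  prep <- prepare_observations(pan)
  cs <- fit_censoring_stage(prep, degree = 2)
  expect_true(all(is.finite(cs$Phi)) && all(is.finite(cs$phi)))
  expect_true(all(cs$Phi > 0 & cs$Phi < 1 | !rep(cs$censored, each = nrow(prep))))
  for (j in which(cs$censored)) {
    expect_gt(cs$Phi[, j][which.max(cs$phi[, j])], 0)
    expect_gte(cs$accuracy[j], cs$base_rate[j] - 1e-12)
  }
  # a group with (almost) no zeros collapses to the uncorrected equation
  uncens <- which(!cs$censored)
  expect_true(length(uncens) == 0 ||
                all(cs$Phi[, uncens] == 1 & cs$phi[, uncens] == 0))
})

test_that("noiseless censoring-free data are recovered exactly", {
  cfg <- noiseless_cfg()
  prefs <- noiseless_prefs(cfg)
  pan <- generate_panel(cfg, prefs)
  expect_equal(mean(pan$truth$w_obs == 0), 0)  # precondition: no censoring
  prep <- prepare_from_truth(pan)
  fit <- easi_fit(prep, degree = 2)
  expect_lt(max(abs(fit$A - prefs$A)), 1e-4)
  expect_lt(max(abs(fit$b - prefs$b)), 1e-4)
  expect_lt(max(abs(fit$D - prefs$D)), 1e-4)
  expect_lt(max(abs(fit$G[, 1:4] - prefs$G)), 1e-4)
})

test_that("estimated matrices satisfy the imposed restrictions", {
  fit <- get_tiny()$fit
  expect_lt(max(abs(fit$A - t(fit$A))), 1e-10)
  expect_lt(max(abs(fit$D - t(fit$D))), 1e-10)
  expect_lt(max(abs(rowSums(fit$A))), 1e-10)
  expect_lt(max(abs(rowSums(fit$D))), 1e-10)
})

test_that("predicted shares sum to one at every observation", {
  fx <- get_tiny()
  pr <- predict_shares(fx$fit, as.matrix(fx$prep[, paste0("lnp_g", 1:6)]),
                       fx$prep$lnx,
                       z = cbind(as.matrix(fx$prep[, grep("^z_", names(fx$prep))]),
                                 easidemand:::wave_dummies(fx$prep$wave)),
                       cm = as.matrix(fx$prep[, grep("^cm_", names(fx$prep))]),
                       adjust = "censored")
  expect_lt(max(abs(rowSums(pr$w) + pr$w_num - 1)), 1e-10)
  expect_lt(max(abs(rowSums(pr$w_adj) + pr$w_num_adj - 1)), 1e-10)
})

test_that("estimation is equivariant to relabelling food groups", {
  cfg <- noiseless_cfg(seed = 6)
  prefs <- noiseless_prefs(cfg, sigma_e = 0.02)
  pan <- generate_panel(cfg, prefs)
  prep <- prepare_from_truth(pan)
  fit <- easi_fit(prep, degree = 2, censor = FALSE)
  # permute groups 1 and 3 in the prepared table
  perm <- c(3, 2, 1, 4, 5, 6)
  prep2 <- prep
  for (pref in c("w", "q", "lnp", "pl", "iv", "cm_lnp")) {
    cols <- paste0(pref, "_g", 1:6)
    prep2[, cols] <- prep[, paste0(pref, "_g", perm)]
  }
  wbar <- attr(prep, "wbar")
  attr(prep2, "wbar") <- c(wbar[perm], wbar[7])
  prep2$stone_avg <- avg_share_stone_index(attr(prep2, "wbar")[1:6],
                                           as.matrix(prep2[, paste0("lnp_g", 1:6)]))
  fit2 <- easi_fit(prep2, degree = 2, censor = FALSE)
  expect_equal(fit2$A, fit$A[perm, perm], tolerance = 1e-6)
  expect_equal(fit2$b, fit$b[perm, ], tolerance = 1e-6)
})

test_that("IV estimation beats the naive estimator under confounding", {
  cfg <- synth_config(n_households = 600, n_waves = 2, n_clusters = 25, seed = 13)
  prefs <- generate_preferences(cfg)
  pan <- generate_panel(cfg, prefs)
  prep <- prepare_observations(pan)
  fe <- function(f) sqrt(sum((f$A - prefs$A)^2))
  fit_iv <- easi_fit(prep, degree = 2)
  fit_no <- easi_fit(prep, degree = 2, use_iv = FALSE)
  expect_lt(fe(fit_iv), fe(fit_no))
  expect_true(all(fit_iv$report$first_stage$r_squared > 0.1))
})

test_that("degree selection records all criteria and finds the true degree", {
  fx <- get_tiny()
  sel <- select_degree(fx$prep, degrees = 1:3)
  expect_equal(sel$criterion$degree, 1:3)
  expect_true(all(is.finite(sel$criterion$bic)))
  expect_equal(sel$degree, sel$criterion$degree[which.min(sel$criterion$bic)])
  # a linear-Engel-curve process is identified as degree 1 in most seeds
  hits <- vapply(1:5, function(sd) {
    cfg <- synth_config(n_households = 350, n_waves = 2, n_clusters = 20,
                        seed = 20 + sd, poly_degree_true = 1)
    pan <- generate_panel(cfg, generate_preferences(cfg))
    prep <- prepare_observations(pan)
    select_degree(prep, degrees = 1:2)$degree == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("fitted models round-trip through the JSON bundle", {
  fx <- get_tiny()
  dir <- withr::local_tempdir()
  write_model(fx$fit, dir)
  unlink(file.path(dir, "model.rds"))  # force the JSON path
  back <- read_model(dir)
  expect_equal(back$A, fx$fit$A, tolerance = 1e-12)
  expect_equal(back$b, fx$fit$b, tolerance = 1e-10)
  expect_equal(back$free, fx$fit$free, tolerance = 1e-12)
  # predictions agree
  lnp <- as.matrix(fx$prep[, paste0("lnp_g", 1:6)])
  z <- cbind(as.matrix(fx$prep[, grep("^z_", names(fx$prep))]),
             easidemand:::wave_dummies(fx$prep$wave))
  cm <- as.matrix(fx$prep[, grep("^cm_", names(fx$prep))])
  p1 <- predict_shares(fx$fit, lnp, fx$prep$lnx, z = z, cm = cm, adjust = "censored")
  p2 <- predict_shares(back, lnp, fx$prep$lnx, z = z, cm = cm, adjust = "censored")
  expect_equal(p2$w_adj, p1$w_adj, tolerance = 1e-9)
})
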