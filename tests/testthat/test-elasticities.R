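# Elasticities: closed forms, theory identities, numerical oracle, nutrient
# algebra, simulated standard errors.

test_that("Cobb-Douglas preferences are unit elastic", {
  w0 <- c(0.15, 0.2, 0.1)
  p <- cobb_douglas_params(w0)
  es <- elasticities(p, ln_p = matrix(rnorm(6, 0, 0.3), 2, 3),
                     ln_x = c(2.5, 3.5))
  expect_equal(max(abs(es$eta - 1)), 0)
  Em <- es$marshallian[1, 1:3, 1:3]
  expect_equal(Em, diag(-1, 3), ignore_attr = TRUE)
  expect_equal(diag(es$hicksian[1, 1:3, 1:3]), -1 + es$w[1, 1:3],
               ignore_attr = TRUE)
})

test_that("aggregation and symmetry identities hold at machine tolerance", {
  for (sd in 1:10) {
    p <- rand_params(J = 4, seed = sd)
    set.seed(500 + sd)
    n <- 5
    es <- elasticities(p, ln_p = matrix(rnorm(n * 4, 0, 0.25), n, 4),
                       ln_x = rnorm(n, 3, 0.6))
    # Engel aggregation
    expect_lt(max(abs(rowSums(es$w * es$eta) - 1)), 1e-8)
    # Cournot aggregation, all prices including the numeraire
    for (k in 1:5)
      expect_lt(max(abs(rowSums(es$w * es$marshallian[, , k]) + es$w[, k])), 1e-8)
    # homogeneity
    expect_lt(max(abs(apply(es$marshallian, c(1, 2), sum) + es$eta)), 1e-8)
    # Hicksian Slutsky symmetry
    for (i in 1:n) {
      WH <- es$w[i, ] * es$hicksian[i, , ]
      expect_lt(max(abs(WH - t(WH))), 1e-8)
    }
  }
})

test_that("analytic elasticities match central finite differences", {
  for (util in c("exact", "stone")) {
    worst <- 0
    for (sd in 1:10) {
      p <- rand_params(J = 4, seed = 40 + sd, utility = util)
      set.seed(900 + sd)
      n <- 3
      lnp <- matrix(rnorm(n * 4, 0, 0.2), n, 4)
      lnx <- rnorm(n, 3, 0.5)
      es <- elasticities(p, ln_p = lnp, ln_x = lnx)
      h <- 1e-5
      fw <- function(lp, lx) predict_shares(p, lp, lx, tol = 1e-13)$w
      W0 <- fw(lnp, lnx)
      eta_fd <- 1 + (fw(lnp, lnx + h) - fw(lnp, lnx - h)) / (2 * h) / W0
      worst <- max(worst, abs(es$eta[, 1:4] - eta_fd) / pmax(abs(eta_fd), 1e-8))
      for (k in 1:4) {
        up <- lnp; up[, k] <- up[, k] + h
        dn <- lnp; dn[, k] <- dn[, k] - h
        dW <- (fw(up, lnx) - fw(dn, lnx)) / (2 * h)
        for (j in 1:4) {
          fd <- -(j == k) + dW[, j] / W0[, j]
          worst <- max(worst, abs(es$marshallian[, j, k] - fd) / pmax(abs(fd), 1e-8))
        }
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("median tables are permutation invariant and respect the share floor", {
  fx <- get_tiny()
  es <- elasticities(fx$fit, fx$prep)
  tab <- median_elasticity_table(es)
  set.seed(3)
  perm <- sample(nrow(fx$prep))
  prep2 <- fx$prep[perm, ]
  for (a in c("J", "wbar", "composition", "z_cols", "cm_cols"))
    attr(prep2, a) <- attr(fx$prep, a)
  class(prep2) <- class(fx$prep)
  tab2 <- median_elasticity_table(elasticities(fx$fit, prep2))
  expect_equal(tab2$eta, tab$eta, tolerance = 1e-12)
  expect_equal(tab2$own_price, tab$own_price, tolerance = 1e-12)
})

test_that("nutrient source shares follow the weighted-intake definition", {
  comp <- default_composition(2, seed = 1)
  # worked example: q = (2, 1) kg, contents 5 and 10 per 100 g
  comp2 <- unclass(comp)
  comp2[, "iron_mg"] <- c(5, 10)
  s <- nutrient_source_shares(c(2, 1), comp2)
  expect_equal(s$shares[1, , "iron_mg"], c(0.5, 0.5))
  expect_equal(unname(s$intake[1, "iron_mg"]), 2 * 10 * 5 + 1 * 10 * 10)
  # single-source nutrient: indicator shares
  comp2[, "vita_ug"] <- c(0, 40)
  s2 <- nutrient_source_shares(c(2, 1), comp2)
  expect_equal(s2$shares[1, , "vita_ug"], c(0, 1))
  # equal quantities and contents: uniform shares
  comp2[, "zinc_mg"] <- c(3, 3)
  s3 <- nutrient_source_shares(c(1, 1), comp2)
  expect_equal(s3$shares[1, , "zinc_mg"], c(0.5, 0.5))
  # shares sum to one wherever intake is positive
  sums <- apply(s$shares[1, , ], 2, sum)
  expect_true(all(abs(sums[!s$zero_intake[1, ]] - 1) < 1e-12))
  expect_true(all(is.na(s$shares[1, , s$zero_intake[1, ]])))
  expect_error(nutrient_source_shares(c(-1, 1), comp2), "negative")
})

test_that("nutrient elasticities are share-weighted sums", {
  expect_equal(nutrient_elasticities(c(0.25, 0.75), c(2, 0.8),
                                     diag(-1, 2))$e_x, 1.1)
  # constant expenditure elasticity passes through
  expect_equal(nutrient_elasticities(c(0.3, 0.7), c(1.3, 1.3),
                                     diag(-1, 2))$e_x, 1.3)
  # single-source nutrient inherits that good's price row
  E <- matrix(c(-0.8, 0.1, 0.3, -1.2), 2, 2, byrow = TRUE)
  ne <- nutrient_elasticities(c(1, 0), c(1.1, 0.9), E)
  expect_equal(ne$e_p, E[1, ])
  expect_error(nutrient_elasticities(c(0.5, 0.5, 0), c(1, 1), diag(-1, 2)))
})

test_that("own/cross price decomposition adds up", {
  E <- matrix(c(-0.8, 0.05, 0.3, -1.2), 2, 2, byrow = TRUE)
  # worked example: s = (0.4, 0.6), price of good 1
  d <- decompose_price_effect(c(0.4, 0.6), matrix(c(-0.8, -0.2, 0, 0), 2, 2), 1)
  expect_equal(d$own, -0.32)
  expect_equal(d$cross, -0.12)
  expect_equal(d$total, -0.44)
  # nutrient absent from the staple: all cross
  d0 <- decompose_price_effect(c(0, 1), E, 1)
  expect_equal(d0$own, 0)
  expect_equal(d0$cross, d0$total)
  # single-source with diagonal matrix: no cross effect
  d1 <- decompose_price_effect(c(1, 0), diag(c(-0.9, -1.1)), 1)
  expect_equal(d1$cross, 0)
  # consistency with the aggregate nutrient-price elasticity
  s <- c(0.35, 0.65)
  ne <- nutrient_elasticities(s, c(1, 1), E)
  dd <- decompose_price_effect(s, E, 2)
  expect_equal(dd$total, ne$e_p[2], tolerance = 1e-12)
})

test_that("simulated standard errors behave like the sampling distribution", {
  fx <- get_tiny()
  # degenerate covariance: all SEs zero
  m0 <- fx$fit
  m0$Cov_free <- m0$Cov_free * 0
  se0 <- simulate_standard_errors(m0, fx$prep, n_draws = 8, seed = 2)
  expect_equal(max(se0$eta_se, na.rm = TRUE), 0)
  # determinism under a fixed seed
  se1 <- simulate_standard_errors(fx$fit, fx$prep, n_draws = 15, seed = 5,
                                  subsample = 200)
  se2 <- simulate_standard_errors(fx$fit, fx$prep, n_draws = 15, seed = 5,
                                  subsample = 200)
  expect_identical(se1$eta_se, se2$eta_se)
  # delta-method oracle: the sd of a linear functional of the draws matches
  # the analytic value within 5% at large draw counts
  draws <- draw_parameters(fx$fit, 10000, seed = 7)
  cvec <- rnorm(ncol(draws))
  analytic <- sqrt(drop(cvec %*% fx$fit$Cov_free %*% cvec))
  expect_lt(abs(sd(draws %*% cvec) - analytic) / analytic, 0.05)
  # restrictions hold for every draw
  pd <- easidemand:::free_to_params(fx$fit, draws[1, ])
  expect_lt(max(abs(pd$A - t(pd$A))), 1e-12)
  expect_lt(max(abs(rowSums(pd$A))), 1e-10)
})
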