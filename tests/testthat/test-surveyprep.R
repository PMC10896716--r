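# Survey preparation: unit values, Fisher indices, instruments, aggregates.

test_that("unit values divide, impute by cell median, and fall through levels", {
  households <- data.frame(hh = 1:8, wave = 1,
                           cluster = c(1, 1, 1, 1, 1, 1, 2, 2),
                           stratum = 1,
                           nonfood_value = 10)
  # cluster 1 has 6 purchases of item 1 (>= min_n = 5); cluster 2 has none
  records <- data.frame(
    hh = c(1:6, 1), wave = 1, group = 1,
    item = c(rep(1, 6), 2),
    quantity = c(4, 1, 1, 1, 1, 1, 2),
    value = c(12, 2, 3, 10, 2, 3, 8),
    source = "purchase")
  uv <- unit_values(records, households, min_n = 5)
  # own purchase: value / quantity
  own <- uv$records$unit_value[uv$records$hh == 1 & uv$records$item == 1]
  expect_equal(own, 3.0)
  # non-purchasers in cluster 1 get the cluster median of {3,2,3,10,2,3}
  g <- uv$grid
  expect_equal(g$unit_value[g$hh == 7 & g$item == 1],
               median(c(3, 2, 3, 10, 2, 3)), tolerance = 1e-12)
  # median oracle for the documented example {2, 3, 10}
  expect_equal(median(c(2, 3, 10)), 3)
  # cluster 2 below min count -> stratum-level fall-through, flagged
  expect_equal(unique(g$impute_level[g$hh %in% 7:8 & g$item == 1]), "stratum")
  # item 2 has one purchase: cluster cell too small everywhere -> national
  expect_equal(unique(g$impute_level[g$hh == 8 & g$item == 2]), "national")
  # an item never purchased anywhere errors with its name
  records2 <- records
  records2$source[7] <- "own"
  expect_error(unit_values(records2, households), "never purchased")
})

test_that("Fisher index reproduces the textbook cases", {
  # proportional doubling
  expect_equal(fisher_index(p1 = c(2, 4), q1 = c(1, 1), p0 = c(1, 2), q0 = c(3, 2)), 2)
  # single item
  expect_equal(fisher_index(1.5, 2, 1, 5), 1.5)
  # two-good case: Laspeyres 1.5, Paasche 1.25, Fisher sqrt(1.875)
  f <- fisher_index(p1 = c(2, 1), q1 = c(1, 3), p0 = c(1, 1), q0 = c(1, 1))
  expect_equal(f, sqrt(1.5 * 1.25), tolerance = 1e-12)
  expect_equal(f, 1.36931, tolerance = 1e-5)
  # empty current basket falls back to Laspeyres
  expect_equal(fisher_index(c(2, 1), c(0, 0), c(1, 1), c(1, 1)), 1.5)
  expect_error(fisher_index(c(-1, 1), c(1, 1), c(1, 1), c(1, 1)), "price")
})

test_that("Fisher index is invariant to splitting an item in two", {
  whole <- fisher_index(p1 = c(3, 2), q1 = c(2, 1), p0 = c(2, 2), q0 = c(4, 1))
  split <- fisher_index(p1 = c(3, 3, 2), q1 = c(1, 1, 1),
                        p0 = c(2, 2, 2), q0 = c(2, 2, 1))
  expect_equal(whole, split, tolerance = 1e-12)
})

test_that("Stone index and its average-share variant satisfy the identities", {
  expect_equal(stone_index(c(0.5, 0.5, 0), c(0, 0, 0)), 0)
  expect_equal(stone_index(c(0.5, 0.5, 0), c(log(2), log(2), 0)), log(2))
  expect_equal(stone_index(c(0.3, 0.2, 0.5), c(0.1, -0.2, 0)), -0.01)
  # difference identity against the average-share index
  w <- c(0.3, 0.2, 0.5); wbar <- c(0.25, 0.3, 0.45); lnp <- c(0.1, -0.2, 0)
  expect_equal(stone_index(w, lnp) - avg_share_stone_index(wbar, lnp),
               sum((w - wbar) * lnp), tolerance = 1e-15)
  # matrix form
  lnpM <- rbind(c(0.1, -0.2, 0), c(0, 0.3, -0.1))
  expect_equal(avg_share_stone_index(wbar, lnpM), as.numeric(lnpM %*% wbar))
})

test_that("neighbour price instrument is the leave-one-out cluster mean", {
  lnp <- matrix(c(0.2, 0.4), 2, 1)
  iv <- neighbour_price_instrument(lnp, cluster = c(1, 1), wave = c(1, 1))
  expect_equal(as.numeric(iv$iv), c(0.4, 0.2))
  # identical prices: instrument equals own price
  lnp2 <- matrix(0.3, 3, 1)
  iv2 <- neighbour_price_instrument(lnp2, cluster = rep(1, 3), wave = rep(1, 3))
  expect_equal(as.numeric(iv2$iv), rep(0.3, 3))
  # three-household cluster arithmetic-mean oracle
  lnp3 <- matrix(c(0.1, 0.2, 0.6), 3, 1)
  iv3 <- neighbour_price_instrument(lnp3, cluster = rep(1, 3), wave = rep(1, 3))
  expect_equal(iv3$iv[1, 1], mean(c(0.2, 0.6)))
  # singleton cluster falls back to the stratum mean and is flagged
  lnp4 <- matrix(c(0.1, 0.2, 0.6), 3, 1)
  iv4 <- neighbour_price_instrument(lnp4, cluster = c(1, 2, 2), wave = rep(1, 3),
                                    stratum = rep(1, 3))
  expect_true(iv4$fallback[1])
  expect_equal(iv4$iv[1, 1], mean(c(0.2, 0.6)))
})

test_that("expenditure groups follow the poverty-line cutoffs", {
  x <- c(1.50, 2.50, 6.00)
  expect_equal(as.character(assign_quartile(x)), c("Q1", "Q2", "Q4"))
  # boundaries are lower-inclusive
  expect_equal(as.character(assign_quartile(c(1.90, 3.20, 5.50))),
               c("Q2", "Q3", "Q4"))
  # every observation gets exactly one label
  set.seed(1)
  q <- assign_quartile(exp(rnorm(500, 1, 1)))
  expect_false(any(is.na(q)))
  expect_equal(sum(table(q)), 500)
  expect_error(quartile_scheme(cutoffs = c(2, 2, 3)), "increasing")
})

test_that("adult equivalents apply the age scale and require a roster", {
  roster <- data.frame(hh = c(1, 1, 1, 2), age = c(30, 10, 65, 40),
                       female = c(0, 1, 1, 1))
  ae <- adult_equivalents(roster)
  expect_equal(unname(ae[c("1", "2")]), c(1 + 0.5 + 0.8, 1))
  expect_error(adult_equivalents(roster[0, ]), "empty")
})

test_that("expenditure aggregate totals food at unit values plus non-food", {
  households <- data.frame(hh = 1:2, wave = 1, cluster = 1, stratum = 1,
                           nonfood_value = c(5, 7))
  recs <- data.frame(hh = c(1, 1, 2), wave = 1, group = 1, item = c(1, 2, 1),
                     quantity = c(2, 1, 3), value = c(4, 3, 9),
                     source = "purchase", unit_value = c(2, 3, 3))
  x <- expenditure_aggregate(recs, households)
  expect_equal(x, c(5 + 7, 7 + 9))
  households$nonfood_value <- c(-20, 7)
  expect_error(expenditure_aggregate(recs, households), "nonpositive")
})

test_that("prepared observations are internally consistent", {
  fx <- get_tiny()
  prep <- fx$prep
  W <- as.matrix(prep[, paste0("w_g", 1:6)])
  expect_true(all(W >= 0 & W <= 1))
  expect_lt(max(abs(rowSums(W) + prep$w_num - 1)), 1e-12)
  expect_true(all(is.finite(as.matrix(prep[, paste0("lnp_g", 1:6)]))))
  expect_true(all(prep$ae > 0))
  expect_true(all(prep$x_week > 0))
  # prepared table round-trips through CSV with metadata
  path <- file.path(withr::local_tempdir(), "prep.csv")
  write_prepared(prep, path)
  back <- read_prepared(path)
  expect_equal(attr(back, "wbar"), attr(prep, "wbar"), tolerance = 1e-12)
  expect_equal(back$w_g3, prep$w_g3, tolerance = 1e-12)
  expect_identical(levels(back$quartile), levels(prep$quartile))
})
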