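## Cash-transfer and price-discount microsimulation through the fitted
## demand system, with diet-quality outcomes and programme cost accounting.
## Prices are partial-equilibrium: interventions never feed back into
## producer prices or wages.

## model-consistent outcome at given expenditures / prices
policy_state <- function(model, prep, roster, composition, requirements,
                         x_week, lnp, price_level) {
  lnx <- log(x_week)
  pred <- predict_shares(model, lnp, lnx, z = model_design_z(model, prep),
                         cm = prep_cm(prep), adjust = "censored")
  W <- if (!is.null(pred$w_adj)) pred$w_adj else pred$w
  W <- pmax(W, 0)  # quantity accounting floor for adjusted shares
  q <- W * x_week / price_level
  dq <- diet_quality(q, prep$hh, roster, composition, requirements)
  out <- list(w = W, q = q, x_week = x_week, lnp = lnp,
              price_level = price_level,
              food_exp = rowSums(W) * x_week, dq = dq)
  ## predicted probability of sufficiency: simulate the latent-share error
  ## distribution around the model mean with the same truncation-at-zero
  ## mechanism that generates censoring, and average the sufficiency
  ## indicator over draws.  Draws are keyed to the household-wave order so
  ## the result is invariant to row permutations.
  Sig <- model$Sigma_latent %||% model$Sigma
  if (!is.null(Sig) && any(Sig != 0)) {
    W_lat <- pred$w
    J <- ncol(W_lat); n <- nrow(W_lat)
    if (!is.null(model$latent_shift))
      W_lat <- W_lat + matrix(model$latent_shift, n, J, byrow = TRUE)
    rt <- mat_sqrt(Sig)
    ord <- order(prep$hh, prep$wave)
    rnk <- match(seq_len(n), ord)
    mc_draws <- 48L
    comp <- unclass(composition)
    nut <- ADEQUACY_NUTRIENTS
    req <- as.matrix(dq[, paste0("req_", nut)])
    acc <- matrix(0, n, length(nut), dimnames = list(NULL, nut))
    with_seed(sub_seed(20421L, mc_draws), {
      for (d in seq_len(mc_draws)) {
        E <- (matrix(stats::rnorm(n * J), n, J) %*% rt)[rnk, , drop = FALSE]
        Wd <- pmax(W_lat + E, 0)
        qd <- Wd * x_week / price_level
        intake <- 10 * qd %*% comp[, nut]
        acc <- acc + (intake >= req)
      }
    })
    out$suf_prob <- acc / mc_draws
  }
  out
}

#' Cash-transfer size rule
#'
#' 20% of the median monthly total expenditures of extreme-poor (Q1)
#' households, flat per household (not adjusted for size or composition).
#'
#' @param prep prepared observations with quartile labels.
#' @param fraction transfer as a fraction of median Q1 monthly expenditures.
#' @return monthly transfer in US$ PPP.
#' @export
ct_transfer_size <- function(prep, fraction = 0.20) {
  q1 <- prep$x_week[prep$quartile == "Q1"]
  if (!length(q1)) stop_ed("no Q1 households to anchor the transfer size")
  fraction * med(q1) * WEEKS_PER_MONTH
}

#' Simulate a cash transfer
#'
#' Adds a flat transfer to every household's total expenditures (a fraction
#' `kappa` of it is spent), re-solves demand at unchanged prices, and
#' recomputes quantities, nutrient intakes, sufficiency, macronutrient
#' balance and NRFI.
#'
#' @param model fitted [easi_fit] (or any [easi_params]).
#' @param prep prepared observations.
#' @param roster household roster (for requirements).
#' @param composition,requirements nutrient tables; default to the panel's
#'   composition attribute and [default_requirements()].
#' @param ct_monthly monthly transfer, US$ PPP; default [ct_transfer_size()].
#' @param kappa fraction of the transfer spent on consumption (default 1).
#' @return object of class `policy_outcome`: list with `scenario`, `pre`
#'   and `post` states, `mpc_food` per household, `ct_monthly`, `quartile`,
#'   and summary tables from [policy_summary()].
#' @export
simulate_cash_transfer <- function(model, prep, roster,
                                   composition = attr(prep, "composition"),
                                   requirements = default_requirements(),
                                   ct_monthly = NULL, kappa = 1) {
  lnp <- prep_matrix(prep, "lnp"); pl <- prep_matrix(prep, "pl")
  ct_monthly <- ct_monthly %||% ct_transfer_size(prep)
  ct_week <- ct_monthly / WEEKS_PER_MONTH
  pre <- policy_state(model, prep, roster, composition, requirements,
                      prep$x_week, lnp, pl)
  post <- policy_state(model, prep, roster, composition, requirements,
                       prep$x_week + kappa * ct_week, lnp, pl)
  mpc <- if (ct_week > 0) (post$food_exp - pre$food_exp) / (kappa * ct_week) else
    rep(0, nrow(prep))
  out <- structure(list(scenario = "ct", pre = pre, post = post,
                        mpc_food = mpc, ct_monthly = ct_monthly, kappa = kappa,
                        quartile = prep$quartile, ae = prep$ae),
                   class = "policy_outcome")
  out$summary <- policy_summary(out)
  out
}

#' Simulate a price discount on a food category
#'
#' Applies a proportional discount to all consumption of the food groups in
#' a policy category (SG, SS, PN, FFV or ASF), re-solves demand at
#' unchanged total expenditures, and recomputes the diet-quality outcomes.
#'
#' @inheritParams simulate_cash_transfer
#' @param category one of the category codes in `category_map`.
#' @param discount proportional price reduction (default 0.25).
#' @param category_map data.frame `group`/`category`; defaults to
#'   [default_category_map()] of the composition table.
#' @return `policy_outcome` with additionally `category`, `groups`,
#'   `discount` and the per-household monthly cost from [pd_cost()].
#' @export
simulate_price_discount <- function(model, prep, roster, category,
                                    discount = 0.25,
                                    composition = attr(prep, "composition"),
                                    requirements = default_requirements(),
                                    category_map = default_category_map(composition)) {
  check_number(discount, "discount", lower = 0, upper = 0.999)
  groups <- category_map$group[!is.na(category_map$category) &
                                 category_map$category == category]
  if (!length(groups)) stop_ed("no food groups mapped to category %s", category)
  lnp <- prep_matrix(prep, "lnp"); pl <- prep_matrix(prep, "pl")
  lnp2 <- lnp; pl2 <- pl
  lnp2[, groups] <- lnp2[, groups] + log(1 - discount)
  pl2[, groups] <- pl2[, groups] * (1 - discount)
  pre <- policy_state(model, prep, roster, composition, requirements,
                      prep$x_week, lnp, pl)
  post <- policy_state(model, prep, roster, composition, requirements,
                       prep$x_week, lnp2, pl2)
  out <- structure(list(scenario = paste0("pd_", category), pre = pre,
                        post = post, category = category, groups = groups,
                        discount = discount, quartile = prep$quartile,
                        ae = prep$ae),
                   class = "policy_outcome")
  out$cost <- pd_cost(out)
  out$summary <- policy_summary(out)
  out
}

#' Cost of a price-discount programme
#'
#' The government cost equals the discount's redeemed value: the discount
#' share of the pre-discount price times the post-discount quantity of each
#' targeted group, converted to a monthly basis; summarised as quartile
#' medians.
#'
#' @param outcome a price-discount `policy_outcome`.
#' @return list with `per_household` (monthly US$ PPP) and
#'   `quartile_median`.
#' @export
pd_cost <- function(outcome) {
  stopifnot(inherits(outcome, "policy_outcome"), !is.null(outcome$groups))
  g <- outcome$groups
  redeemed_week <- rowSums(outcome$discount *
                             outcome$pre$price_level[, g, drop = FALSE] *
                             outcome$post$q[, g, drop = FALSE])
  per_month <- redeemed_week * WEEKS_PER_MONTH
  list(per_household = per_month,
       quartile_median = tapply(per_month, outcome$quartile, med))
}

## adequacy nutrients reported in summaries
ADEQUACY_NUTRIENTS <- c("energy_kcal", "carb_g", "protein_g", "fat_g",
                        "iron_mg", "zinc_mg", "vita_ug", "folate_ug")

## share of households with sufficient intake, by quartile; model states
## with an intake distribution use the predicted probability, data-side
## reports use the realised indicator
sufficiency_shares <- function(x, quartile) {
  suf <- if (!is.null(x$suf_prob)) x$suf_prob else
    as.matrix((x$dq %||% x)[, paste0("suf_", ADEQUACY_NUTRIENTS)])
  out <- apply(suf, 2, function(s) tapply(s, quartile, mean))
  colnames(out) <- ADEQUACY_NUTRIENTS
  out
}

#' Summarise a policy outcome by expenditure quartile
#'
#' @param outcome a `policy_outcome`.
#' @return list with pre/post sufficiency shares, pre/post NRFI medians,
#'   pre/post balance-class shares, and -- per scenario -- median MPC on
#'   food or median monthly discount cost by quartile.
#' @export
policy_summary <- function(outcome) {
  qv <- outcome$quartile
  bal_share <- function(dq) {
    sapply(c("protein_class", "fat_class", "carb_class"), function(cl)
      t(sapply(levels(qv), function(qq)
        prop.table(table(dq[[cl]][qv == qq]))[c("below", "within", "above")])),
      simplify = FALSE)
  }
  out <- list(
    sufficiency_pre = sufficiency_shares(outcome$pre, qv),
    sufficiency_post = sufficiency_shares(outcome$post, qv),
    nrfi_pre = tapply(outcome$pre$dq$nrfi, qv, med),
    nrfi_post = tapply(outcome$post$dq$nrfi, qv, med),
    balance_pre = bal_share(outcome$pre$dq),
    balance_post = bal_share(outcome$post$dq)
  )
  if (!is.null(outcome$mpc_food))
    out$mpc_food_median <- tapply(outcome$mpc_food, qv, med)
  if (!is.null(outcome$cost)) out$cost_median <- outcome$cost$quartile_median
  if (!is.null(outcome$ct_monthly)) out$ct_monthly <- outcome$ct_monthly
  out
}

#' Ground-truth post-intervention sufficiency shares
#'
#' Brute-force oracle for validating model-based policy simulations on
#' synthetic data: regenerates the panel from the true preferences with the
#' intervention applied (same seed, hence identical error and price draws),
#' computes observed nutrient intakes from the regenerated quantities, and
#' returns sufficiency shares by a fixed (baseline) quartile assignment.
#'
#' @param panel baseline synthetic `household_panel`.
#' @param quartile baseline quartile labels, one per household-wave row.
#' @param x_add_weekly,lnp_shift intervention, as in [generate_panel()].
#' @param requirements requirements table.
#' @return quartile x nutrient matrix of sufficiency shares.
#' @export
truth_policy_shares <- function(panel, quartile, x_add_weekly = 0,
                                lnp_shift = NULL,
                                requirements = default_requirements()) {
  sim <- generate_panel(panel$config, panel$truth$prefs, panel$composition,
                        x_add_weekly = x_add_weekly, lnp_shift = lnp_shift)
  ## group demand valued at the faced group price: the oracle isolates the
  ## demand-response channel from item-level measurement noise
  q_true <- sim$truth$w_obs * sim$truth$x_week / sim$truth$price_level
  dq <- diet_quality(q_true, sim$households$hh, sim$roster,
                     sim$composition, requirements)
  sufficiency_shares(dq, quartile)
}

#' Smoothed sufficiency probability against household expenditures
#'
#' Local-averaging (Nadaraya-Watson, Gaussian kernel) smoother of the
#' binary sufficiency indicator on log expenditures per adult equivalent
#' per day, evaluated pre and post intervention on a common grid trimmed to
#' the central mass of the expenditure distribution.
#'
#' @param outcome a `policy_outcome`.
#' @param nutrient adequacy nutrient (default dietary energy).
#' @param n_grid grid size.
#' @param bandwidth kernel bandwidth on the log scale; default 0.3 s.d.
#' @param trim tail probability trimmed from each end of the grid.
#' @return data.frame with `log_x_ae_day`, `pre`, `post`, and the quartile
#'   cutoffs in `attr(, "cutoffs")` (log scale).
#' @export
sufficiency_curve <- function(outcome, nutrient = "energy_kcal",
                              n_grid = 50, bandwidth = NULL, trim = 0.05) {
  if (length(outcome$quartile) < 100)
    stop_ed("sufficiency_curve needs at least 100 households")
  lx <- log(outcome$pre$x_week / DAYS_PER_WEEK / outcome$ae)
  pick <- function(st) if (!is.null(st$suf_prob)) st$suf_prob[, nutrient] else
    as.numeric(st$dq[[paste0("suf_", nutrient)]])
  pre <- pick(outcome$pre)
  post <- pick(outcome$post)
  bw <- bandwidth %||% (0.3 * stats::sd(lx))
  grid <- seq(stats::quantile(lx, trim), stats::quantile(lx, 1 - trim),
              length.out = n_grid)
  smooth <- function(yv) vapply(grid, function(g) {
    k <- stats::dnorm((lx - g) / bw)
    sum(k * yv) / sum(k)
  }, numeric(1))
  out <- data.frame(log_x_ae_day = grid, pre = smooth(pre), post = smooth(post))
  attr(out, "cutoffs") <- log(quartile_scheme()$cutoffs)
  out
}
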