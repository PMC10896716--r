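## Synthetic household-panel generator.
##
## All random draws are made up front in a fixed order, after which the panel
## is assembled deterministically; policy-style perturbations
## (`x_add_weekly`, `lnp_shift`) therefore reuse bit-identical error and
## price draws, which is what makes ground-truth re-simulation of an
## intervention possible.  Item prices carry quality and price-search premia
## computed from *baseline* expenditures and preference errors, so an
## expenditure shock changes demand but not the price-formation process.

## symmetric matrix square root (tolerates semi-definite input)
mat_sqrt <- function(S) {
  if (all(S == 0)) return(S)
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate a synthetic LSMS-style household consumption panel
#'
#' Simulates a multi-wave household panel from ground-truth EASI preferences:
#' cluster-by-wave base prices, item-level prices with quality and
#' price-search premia, latent budget shares with correlated errors,
#' censoring by truncation at zero (with the removed budget reassigned to
#' the numeraire), and item-level quantities, values and acquisition
#' sources over a 7-day recall period.
#'
#' @param config a [synth_config].
#' @param prefs ground-truth preferences from [generate_preferences()];
#'   dimensions must match `config`.
#' @param composition optional [default_composition()]-style table attached
#'   to the panel for downstream nutrient accounting.
#' @param x_add_weekly intervention hook: amount added to every household's
#'   weekly total expenditures (scalar or per-observation vector) after all
#'   random draws are made.
#' @param lnp_shift intervention hook: length-J log price shift (for example
#'   `log(1 - 0.25)` on discounted groups) applied to all item prices.
#' @param max_retries bound on redraws for households with no food
#'   consumption at all.
#' @return an object of class `household_panel`: list with data.frames
#'   `households` (one row per household-wave: ids, cluster, stratum, urban,
#'   weight, non-food expenditure), `roster`, `records` (consumed items:
#'   quantity kg, value US$ PPP, source), the `composition` table, the
#'   `config`, and a `truth` list carrying the generating preferences, latent
#'   and observed shares, group log prices, expected group price levels and
#'   error draws for validation.
#' @export
generate_panel <- function(config, prefs, composition = NULL,
                           x_add_weekly = 0, lnp_shift = NULL,
                           max_retries = 20L) {
  stopifnot(inherits(config, "synth_config"), inherits(prefs, "easi_params"))
  J <- config$n_groups
  if (prefs$J != J) stop_ed("prefs have %d groups, config has %d", prefs$J, J)
  if (ncol(prefs$b) - 1L != config$poly_degree_true)
    stop_ed("prefs polynomial degree does not match config")
  nh <- config$n_households; nw <- config$n_waves; nobs <- nh * nw
  ni <- config$n_items_per_group; nitems <- J * ni
  item_group <- rep(seq_len(J), each = ni)
  item_off <- rep(seq(-0.15, 0.15, length.out = ni), times = J)
  if (ni == 1L) item_off <- rep(0, J)
  mu <- config$expenditure_lognormal[["mu"]]
  sigma <- config$expenditure_lognormal[["sigma"]]
  if (is.null(composition)) composition <- default_composition(J, config$seed)
  lnp_shift <- lnp_shift %||% rep(0, J)
  stopifnot(length(lnp_shift) == J)

  with_seed(sub_seed(config$seed, 1L), {
    ## -- all random draws, fixed order ------------------------------------
    cluster <- sample(rep_len(seq_len(config$n_clusters), nh))
    urban_cl <- stats::rbinom(config$n_clusters, 1, 0.3)
    size <- pmin(1L + stats::rpois(nh, 2.2), 9L)
    head_age <- pmin(pmax(round(stats::rnorm(nh, 42, 13)), 18), 90)
    head_female <- stats::rbinom(nh, 1, 0.3)
    extra <- sum(size) - nh
    member_age <- round(stats::runif(extra, 0, 75))
    member_female <- stats::rbinom(extra, 1, 0.5)
    u_h <- stats::rnorm(nh, 0, sigma * sqrt(0.7))
    v_hw <- stats::rnorm(nobs, 0, sigma * sqrt(0.3))
    p0_g <- exp(log(2.0) + 0.25 * stats::rnorm(J))
    bp <- array(stats::rnorm(J * config$n_clusters * nw, 0, config$price_dispersion),
                dim = c(J, config$n_clusters, nw))
    E <- matrix(stats::rnorm(nobs * J), nobs, J) %*% mat_sqrt(prefs$Sigma_e)
    price_noise <- matrix(stats::rnorm(nobs * nitems, 0, config$price_noise), nobs, nitems)
    split_g <- matrix(stats::rgamma(nobs * nitems, shape = 4), nobs, nitems)
    src_u <- matrix(stats::runif(nobs * nitems), nobs, nitems)
  })

  ## -- deterministic assembly ----------------------------------------------
  roster <- data.frame(
    hh = c(seq_len(nh), rep(seq_len(nh), times = size - 1L)),
    age = c(head_age, member_age),
    female = c(head_female, member_female)
  )
  roster <- roster[order(roster$hh), ]
  roster$member <- stats::ave(roster$hh, roster$hh, FUN = seq_along)
  urban <- urban_cl[cluster]
  Z <- shifter_matrix(roster, urban)
  ae <- as.numeric(adult_equivalents(roster))

  obs <- data.frame(hh = rep(seq_len(nh), times = nw),
                    wave = rep(seq_len(nw), each = nh))
  o_h <- obs$hh; o_w <- obs$wave
  lnxae_day <- mu + u_h[o_h] + v_hw
  x_week0 <- exp(lnxae_day) * ae[o_h] * DAYS_PER_WEEK
  zx <- if (sigma > 0) (lnxae_day - mu) / sigma else rep(0, nobs)
  sd_e <- sqrt(diag(prefs$Sigma_e))
  e_std <- sweep(E, 2, ifelse(sd_e > 0, sd_e, 1), "/")

  ## item log price levels and relative group log prices
  bpm <- matrix(bp, J, config$n_clusters * nw)  # columns indexed by (cluster, wave)
  bp_obs <- t(bpm[, cluster[o_h] + (o_w - 1L) * config$n_clusters, drop = FALSE])
  qual <- config$quality_loading * zx
  lprice_item <- matrix(log(p0_g)[item_group] + item_off, nobs, nitems, byrow = TRUE) +
    bp_obs[, item_group, drop = FALSE] + qual +
    config$search_loading * e_std[, item_group, drop = FALSE] +
    price_noise +
    matrix(lnp_shift[item_group], nobs, nitems, byrow = TRUE)
  mean_noise <- t(rowsum(t(price_noise), item_group)) / ni
  lnp <- bp_obs + qual + config$search_loading * e_std + mean_noise +
    matrix(lnp_shift, nobs, J, byrow = TRUE)

  x_week <- x_week0 + x_add_weekly
  if (any(x_week <= 0)) stop_ed("intervention drives total expenditures nonpositive")
  lnx <- log(x_week)
  Zobs <- Z[o_h, , drop = FALSE]

  pred <- predict_shares(prefs, lnp, lnx, z = Zobs, offset = E)
  W_lat <- pred$w
  all_zero <- rowSums(W_lat > 0) == 0L
  attempt <- 0L
  while (any(all_zero) && attempt < max_retries) {
    attempt <- attempt + 1L
    rows <- which(all_zero)
    with_seed(sub_seed(config$seed, 1000L + attempt), {
      E[rows, ] <- matrix(stats::rnorm(length(rows) * J), length(rows), J) %*%
        mat_sqrt(prefs$Sigma_e)
    })
    sub <- predict_shares(prefs, lnp[rows, , drop = FALSE], lnx[rows],
                          z = Zobs[rows, , drop = FALSE],
                          offset = E[rows, , drop = FALSE])
    W_lat[rows, ] <- sub$w
    pred$y[rows] <- sub$y
    all_zero[rows] <- rowSums(W_lat[rows, , drop = FALSE] > 0) == 0L
  }
  if (any(all_zero))
    stop_ed("%d households have no food consumption after %d error redraws",
            sum(all_zero), max_retries)

  ## censor: truncate negatives, reassign removed mass to the numeraire,
  ## renormalise if the numeraire share falls below its floor
  W_obs <- pmax(W_lat, 0)
  w_num <- 1 - rowSums(W_obs)
  low <- w_num < 0.01
  if (any(low)) {
    W_obs[low, ] <- W_obs[low, , drop = FALSE] * (0.99 / rowSums(W_obs[low, , drop = FALSE]))
    w_num[low] <- 0.01
  }

  gv <- W_obs * x_week
  split_norm <- split_g / t(rowsum(t(split_g), item_group))[, item_group, drop = FALSE]
  value_item <- gv[, item_group, drop = FALSE] * split_norm
  qty_item <- value_item / exp(lprice_item)
  source_item <- matrix("purchase", nobs, nitems)
  source_item[src_u < config$own_production_fraction + 0.05] <- "gift"
  source_item[src_u < config$own_production_fraction] <- "own"

  pos <- which(qty_item > 0, arr.ind = TRUE)
  records <- data.frame(
    hh = o_h[pos[, 1]], wave = o_w[pos[, 1]],
    group = item_group[pos[, 2]], item = pos[, 2],
    quantity = qty_item[pos], value = value_item[pos],
    source = source_item[pos]
  )
  records <- records[order(records$hh, records$wave, records$item), ]
  rownames(records) <- NULL

  households <- data.frame(
    hh = o_h, wave = o_w, cluster = cluster[o_h],
    stratum = (cluster[o_h] - 1L) %/% 5L + 1L,
    urban = urban[o_h], weight = 1,
    nonfood_value = w_num * x_week
  )

  ## expected group price level faced by the household, US$ PPP per kg
  price_level <- exp(matrix(log(p0_g), nobs, J, byrow = TRUE) + lnp)

  q_g <- t(rowsum(t(qty_item), item_group))
  structure(list(
    households = households, roster = roster[, c("hh", "member", "age", "female")],
    records = records, composition = composition, config = config,
    truth = list(prefs = prefs, lnp = lnp, w_latent = W_lat, w_obs = W_obs,
                 w_num = w_num, y = pred$y, lnx = lnx, x_week = x_week,
                 lnxae_day = lnxae_day, ae = ae, shifters = Z, e = E,
                 price_level = price_level, q_g = q_g, p0_g = p0_g,
                 error_redraws = attempt)
  ), class = "household_panel")
}

#' @export
print.household_panel <- function(x, ...) {
  cat(sprintf("Synthetic household panel: %d household-waves, %d consumption records, %d food groups\n",
              nrow(x$households), nrow(x$records), x$config$n_groups))
  cat(sprintf("  censoring rate (zero household-group records): %.1f%%\n",
              100 * mean(x$truth$w_obs == 0)))
  invisible(x)
}
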