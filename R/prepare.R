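#' Prepare estimation-ready observations from a household panel
#'
#' Runs the full survey-preparation chain: unit-value imputation, Fisher
#' Ideal group price indices against a wave-1 base, budget shares of food
#' groups and the numeraire, adult equivalents and expenditure quartiles,
#' demand shifters, leave-one-out neighbour price instruments, the
#' average-share Stone index instrument, and cluster means for correlated
#' random effects.
#'
#' @param panel a `household_panel` (from [generate_panel()] or
#'   [read_panel()]).
#' @param min_n minimum purchase observations per imputation cell.
#' @param ae_scale adult-equivalent scale passed to [adult_equivalents()].
#' @param scheme expenditure-group scheme, see [quartile_scheme()].
#' @return data.frame of class `prepared_observations`, one row per
#'   household-wave, with budget shares `w_*` (plus `w_num`), log Fisher
#'   price indices `lnp_*`, group price levels `pl_*` (US$ PPP/kg), observed
#'   group quantities `q_*` (kg/week), `lnx`, `x_week`, `x_ae_day`,
#'   `quartile`, shifters `z_*`, instruments `iv_*` and `stone_avg`, and
#'   cluster means `cm_*`.  Sample-average shares, group labels and the
#'   composition table travel as attributes.
#' @export
prepare_observations <- function(panel, min_n = 5,
                                 ae_scale = c(child = 0.5, adult = 1, elderly = 0.8),
                                 scheme = quartile_scheme()) {
  stopifnot(inherits(panel, "household_panel"))
  hhw <- panel$households
  n <- nrow(hhw)
  J <- panel$config$n_groups
  uv <- unit_values(panel$records, hhw, min_n = min_n)
  items <- sort(unique(uv$grid$item))
  nitems <- length(items)
  item_group <- uv$grid$group[match(items, uv$grid$item)]

  okey <- paste(hhw$hh, hhw$wave)
  oi <- match(paste(uv$grid$hh, uv$grid$wave), okey)
  ii <- match(uv$grid$item, items)
  P1 <- matrix(NA_real_, n, nitems)
  P1[cbind(oi, ii)] <- uv$grid$unit_value
  Q1 <- matrix(0, n, nitems)
  ri <- match(paste(uv$records$hh, uv$records$wave), okey)
  Q1[cbind(ri, match(uv$records$item, items))] <- uv$records$quantity

  ## wave-1 base: sample-mean purchaser unit values and mean quantities
  w1 <- hhw$wave == min(hhw$wave)
  purch <- uv$records[uv$records$source == "purchase" & uv$records$quantity > 0 &
                        uv$records$wave == min(hhw$wave), ]
  p0 <- tapply(purch$value / purch$quantity, match(purch$item, items), mean)[as.character(seq_len(nitems))]
  p0 <- as.numeric(p0)
  if (any(is.na(p0))) stop_ed("some items have no wave-1 purchases; cannot form Fisher base")
  q0 <- colMeans(Q1[w1, , drop = FALSE])
  if (any(q0 <= 0)) stop_ed("zero base quantity for some item")

  ## Fisher legs, vectorised over observations within each group
  lnp <- matrix(NA_real_, n, J)
  pl <- matrix(NA_real_, n, J)
  for (g in seq_len(J)) {
    gi <- which(item_group == g)
    L <- (P1[, gi, drop = FALSE] %*% q0[gi]) / sum(p0[gi] * q0[gi])
    pa_num <- rowSums(P1[, gi, drop = FALSE] * Q1[, gi, drop = FALSE])
    pa_den <- Q1[, gi, drop = FALSE] %*% p0[gi]
    P <- ifelse(pa_den > 0, pa_num / pa_den, L)
    fi <- sqrt(L * P)
    if (any(!is.finite(fi) | fi <= 0)) stop_ed("invalid Fisher index in group %d", g)
    lnp[, g] <- log(fi)
    pl[, g] <- fi * sum(p0[gi] * q0[gi]) / sum(q0[gi])
  }

  ## budget shares: food valued at unit values, all sources
  food_val <- P1 * Q1
  gv <- t(rowsum(t(food_val), item_group))
  x_week <- rowSums(gv) + hhw$nonfood_value
  if (any(x_week <= 0)) stop_ed("nonpositive total expenditures")
  W <- gv / x_week
  w_num <- hhw$nonfood_value / x_week
  q_g <- t(rowsum(t(Q1), item_group))

  ae <- adult_equivalents(panel$roster, scale = ae_scale)
  ae <- as.numeric(ae[as.character(hhw$hh)])
  x_ae_day <- x_week / DAYS_PER_WEEK / ae
  quart <- assign_quartile(x_ae_day, scheme)

  Z <- shifter_matrix(panel$roster,
                      stats::setNames(hhw$urban[!duplicated(hhw$hh)],
                                      hhw$hh[!duplicated(hhw$hh)])[as.character(sort(unique(hhw$hh)))])
  Zobs <- Z[match(hhw$hh, as.integer(rownames(Z))), , drop = FALSE]

  ivp <- neighbour_price_instrument(lnp, hhw$cluster, hhw$wave, hhw$stratum)
  wbar <- c(colMeans(W), num = mean(w_num))
  stone_avg <- avg_share_stone_index(wbar[seq_len(J)], lnp)

  ## cluster means over all waves (correlated random effects regressors);
  ## cluster-constant columns (for example an urban flag) are dropped since
  ## their mean duplicates the column itself
  cm_src <- cbind(lnp, lnx = log(x_week), Zobs)
  colnames(cm_src) <- c(paste0("lnp_g", seq_len(J)), "lnx", colnames(Zobs))
  cm <- apply(cm_src, 2, function(col) stats::ave(col, hhw$cluster))
  keep <- colSums(abs(cm_src - cm)) > 1e-8 * n
  cm <- cm[, keep, drop = FALSE]

  out <- data.frame(hh = hhw$hh, wave = hhw$wave, cluster = hhw$cluster,
                    stratum = hhw$stratum, weight = hhw$weight,
                    ae = ae, x_week = x_week, lnx = log(x_week),
                    x_ae_day = x_ae_day, quartile = quart,
                    stone_avg = stone_avg, iv_fallback = ivp$fallback)
  add <- function(m, prefix) {
    colnames(m) <- paste0(prefix, "_g", seq_len(ncol(m)))
    m
  }
  out <- cbind(out, add(W, "w"), w_num = w_num, add(q_g, "q"),
               add(lnp, "lnp"), add(pl, "pl"), add(ivp$iv, "iv"),
               `colnames<-`(Zobs, paste0("z_", colnames(Zobs))),
               `colnames<-`(cm, paste0("cm_", colnames(cm))))
  rownames(out) <- NULL
  attr(out, "J") <- J
  attr(out, "wbar") <- wbar
  attr(out, "composition") <- panel$composition
  attr(out, "z_cols") <- paste0("z_", colnames(Zobs))
  attr(out, "cm_cols") <- paste0("cm_", colnames(cm))
  class(out) <- c("prepared_observations", class(out))
  out
}

#' Estimation-ready table from the generator's ground truth
#'
#' Builds a `prepared_observations` table directly from the exact group
#' prices, shares and expenditures carried in a synthetic panel's `truth`
#' slot, bypassing unit-value imputation and Fisher aggregation.  Price
#' levels are only identified up to group constants from survey data, so
#' estimator-recovery oracles that compare fitted coefficients with the
#' generating values at machine-level tolerances need this exact path; the
#' survey path [prepare_observations()] is the realistic one.
#'
#' @param panel a synthetic `household_panel`.
#' @param scheme expenditure-group scheme.
#' @return a `prepared_observations` data.frame.
#' @export
prepare_from_truth <- function(panel, scheme = quartile_scheme()) {
  stopifnot(inherits(panel, "household_panel"))
  tr <- panel$truth
  hhw <- panel$households
  J <- panel$config$n_groups
  n <- nrow(hhw)
  W <- tr$w_obs
  lnp <- tr$lnp
  ivp <- neighbour_price_instrument(lnp, hhw$cluster, hhw$wave, hhw$stratum)
  wbar <- c(colMeans(W), num = mean(tr$w_num))
  Zobs <- tr$shifters[hhw$hh, , drop = FALSE]
  cm_src <- cbind(lnp, lnx = tr$lnx, Zobs)
  colnames(cm_src) <- c(paste0("lnp_g", seq_len(J)), "lnx", colnames(Zobs))
  cm <- apply(cm_src, 2, function(col) stats::ave(col, hhw$cluster))
  keep <- colSums(abs(cm_src - cm)) > 1e-8 * n
  cm <- cm[, keep, drop = FALSE]
  x_ae_day <- tr$x_week / DAYS_PER_WEEK / tr$ae[hhw$hh]
  out <- data.frame(hh = hhw$hh, wave = hhw$wave, cluster = hhw$cluster,
                    stratum = hhw$stratum, weight = hhw$weight,
                    ae = tr$ae[hhw$hh], x_week = tr$x_week, lnx = tr$lnx,
                    x_ae_day = x_ae_day,
                    quartile = assign_quartile(x_ae_day, scheme),
                    stone_avg = avg_share_stone_index(wbar[seq_len(J)], lnp),
                    iv_fallback = ivp$fallback)
  add <- function(m, prefix) {
    colnames(m) <- paste0(prefix, "_g", seq_len(ncol(m)))
    m
  }
  out <- cbind(out, add(W, "w"), w_num = tr$w_num, add(tr$q_g, "q"),
               add(lnp, "lnp"), add(tr$price_level, "pl"), add(ivp$iv, "iv"),
               `colnames<-`(Zobs, paste0("z_", colnames(Zobs))),
               `colnames<-`(cm, paste0("cm_", colnames(cm))))
  rownames(out) <- NULL
  attr(out, "J") <- J
  attr(out, "wbar") <- wbar
  attr(out, "composition") <- panel$composition
  attr(out, "z_cols") <- paste0("z_", colnames(Zobs))
  attr(out, "cm_cols") <- paste0("cm_", colnames(cm))
  class(out) <- c("prepared_observations", class(out))
  out
}

## column helpers used across estimation / elasticity / policy stages
prep_matrix <- function(prep, prefix) {
  as.matrix(prep[, grep(paste0("^", prefix, "_g[0-9]+$"), names(prep)), drop = FALSE])
}
prep_z <- function(prep) as.matrix(prep[, attr(prep, "z_cols"), drop = FALSE])
prep_cm <- function(prep) as.matrix(prep[, attr(prep, "cm_cols"), drop = FALSE])
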