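## Survey preparation: from raw consumption records to estimation-ready
## budget shares, group price indices, instruments and expenditure groups.

#' Item unit values with median imputation
#'
#' Purchased records are valued at `value / quantity`.  For non-purchased
#' and non-consuming household-waves, the unit value is imputed as the
#' median unit value among purchasing households at the smallest geographic
#' level with at least `min_n` purchase observations, in the order cluster,
#' stratum, national; the level used is recorded.
#'
#' @param records data.frame with columns `hh`, `wave`, `group`, `item`,
#'   `quantity`, `value`, `source`.
#' @param households data.frame with columns `hh`, `wave`, `cluster`,
#'   `stratum` (one row per household-wave).
#' @param min_n minimum purchase observations in a cell before its median
#'   is used (default 5).
#' @return list with `records` (input plus `unit_value`, `impute_level`) and
#'   `grid`, a complete household-wave by item data.frame of unit values
#'   (`hh`, `wave`, `item`, `group`, `unit_value`, `impute_level`) covering
#'   non-consuming households as well.
#' @export
unit_values <- function(records, households, min_n = 5) {
  purch <- records[records$source == "purchase" & records$quantity > 0, ]
  if (nrow(purch) == 0L) stop_ed("no purchase records to derive unit values from")
  purch$uv <- purch$value / purch$quantity
  hkey <- paste(households$hh, households$wave)
  cl <- households$cluster[match(paste(records$hh, records$wave), hkey)]
  pcl <- households$cluster[match(paste(purch$hh, purch$wave), hkey)]
  pst <- households$stratum[match(paste(purch$hh, purch$wave), hkey)]

  cell_stats <- function(keys) {
    m <- tapply(purch$uv, keys, stats::median)
    n <- tapply(purch$uv, keys, length)
    list(med = m, n = n)
  }
  cw <- cell_stats(paste(purch$item, purch$wave, pcl, sep = "|"))
  sw <- cell_stats(paste(purch$item, purch$wave, pst, sep = "|"))
  nw <- cell_stats(paste(purch$item, purch$wave, sep = "|"))

  items <- sort(unique(records$item))
  item_group <- records$group[match(items, records$item)]
  grid <- expand.grid(obs = seq_len(nrow(households)), item = items,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- data.frame(hh = households$hh[grid$obs], wave = households$wave[grid$obs],
                     cluster = households$cluster[grid$obs],
                     stratum = households$stratum[grid$obs],
                     item = grid$item,
                     group = item_group[match(grid$item, items)])

  lookup <- function(stats, keys) {
    i <- match(keys, names(stats$med))
    list(med = as.numeric(stats$med)[i],
         n = ifelse(is.na(i), 0L, as.integer(stats$n)[i]))
  }
  g_cw <- lookup(cw, paste(grid$item, grid$wave, grid$cluster, sep = "|"))
  g_sw <- lookup(sw, paste(grid$item, grid$wave, grid$stratum, sep = "|"))
  g_nw <- lookup(nw, paste(grid$item, grid$wave, sep = "|"))
  if (any(g_nw$n == 0L)) {
    missing <- unique(grid$item[g_nw$n == 0L])
    stop_ed("item(s) never purchased anywhere in a wave: %s",
            paste(missing, collapse = ", "))
  }
  uv <- ifelse(g_cw$n >= min_n, g_cw$med,
               ifelse(g_sw$n >= min_n, g_sw$med, g_nw$med))
  level <- ifelse(g_cw$n >= min_n, "cluster",
                  ifelse(g_sw$n >= min_n, "stratum", "national"))

  ## overwrite with the household's own unit value where it purchased
  pkey <- paste(purch$hh, purch$wave, purch$item)
  gi <- match(paste(grid$hh, grid$wave, grid$item), pkey)
  own <- !is.na(gi)
  uv[own] <- purch$uv[gi[own]]
  level[own] <- "observed"
  grid$unit_value <- uv
  grid$impute_level <- level
  if (any(!is.finite(uv) | uv <= 0)) stop_ed("nonpositive or missing unit value produced")

  ri <- match(paste(records$hh, records$wave, records$item),
              paste(grid$hh, grid$wave, grid$item))
  records$unit_value <- grid$unit_value[ri]
  records$impute_level <- grid$impute_level[ri]
  list(records = records, grid = grid[, c("hh", "wave", "item", "group",
                                          "unit_value", "impute_level")])
}

#' Fisher Ideal price index for one basket
#'
#' `sqrt(Laspeyres x Paasche)` of current prices `p1` against base prices
#' `p0`, with base quantities `q0` and current quantities `q1`.  When the
#' current basket is empty (all `q1 = 0`) the Paasche leg is undefined and
#' the index falls back to the Laspeyres leg.
#'
#' @param p1,q1 current item prices and quantities.
#' @param p0,q0 base item prices and quantities.
#' @return scalar index (base = 1).
#' @export
fisher_index <- function(p1, q1, p0, q0) {
  if (any(p1 <= 0) || any(p0 <= 0)) stop_ed("nonpositive price in Fisher index")
  L <- sum(p1 * q0) / sum(p0 * q0)
  P <- if (sum(q1) > 0) sum(p1 * q1) / sum(p0 * q1) else L
  sqrt(L * P)
}

#' Stone price index
#'
#' Budget-share-weighted sum of log prices, `sum_k w_k ln p_k`.  Shares may
#' include the numeraire provided its log price entry is 0 (the package's
#' normalisation).
#'
#' @param w shares (vector, or matrix with observations in rows).
#' @param ln_p log prices aligned with `w`.
#' @return scalar or vector of Stone indices.
#' @export
stone_index <- function(w, ln_p) {
  if (is.null(dim(w))) return(sum(w * ln_p))
  rowSums(w * as.matrix(ln_p))
}

#' Average-share Stone index (Stone-index instrument)
#'
#' The Stone index computed with sample-average budget shares in place of
#' the household's own shares; used to instrument the own-share Stone index
#' inside real expenditures.
#'
#' @param wbar sample-average shares (length J).
#' @param ln_p `n x J` matrix (or length-J vector) of log prices.
#' @return vector of modified Stone indices.
#' @export
avg_share_stone_index <- function(wbar, ln_p) {
  if (is.null(dim(ln_p))) return(sum(wbar * ln_p))
  as.numeric(as.matrix(ln_p) %*% wbar)
}

#' Leave-one-out neighbour price instrument
#'
#' For each household-wave, the mean of `ln_p` over the *other* households
#' in the same cluster-wave; a household alone in its cluster-wave falls
#' back to the leave-one-out stratum-wave mean, flagged.
#'
#' @param ln_p `n x J` matrix of log group price indices.
#' @param cluster,wave,stratum vectors of length n.
#' @return list with `iv` (`n x J`) and logical `fallback` flag vector.
#' @export
neighbour_price_instrument <- function(ln_p, cluster, wave, stratum = NULL) {
  ln_p <- as.matrix(ln_p)
  key <- paste(cluster, wave)
  n_cell <- as.numeric(table(key)[key])
  iv <- ln_p
  for (g in seq_len(ncol(ln_p))) {
    s <- tapply(ln_p[, g], key, sum)[key]
    iv[, g] <- (s - ln_p[, g]) / (n_cell - 1)
  }
  fallback <- n_cell < 2
  if (any(fallback)) {
    if (is.null(stratum)) stop_ed("singleton cluster-wave present but no stratum given")
    skey <- paste(stratum, wave)
    s_n <- as.numeric(table(skey)[skey])
    if (any(fallback & s_n < 2)) stop_ed("singleton stratum-wave; cannot build price instrument")
    for (g in seq_len(ncol(ln_p))) {
      s <- tapply(ln_p[, g], skey, sum)[skey]
      iv[fallback, g] <- ((s - ln_p[, g]) / (s_n - 1))[fallback]
    }
  }
  list(iv = iv, fallback = fallback)
}

#' Expenditure-group scheme at the international poverty lines
#'
#' Cutoffs in US$ PPP per adult equivalent per day at 1.90 (extreme
#' poverty), 3.20 (poverty) and 5.50, labelling four expenditure groups
#' Q1-Q4 with half-open, lower-inclusive intervals.
#'
#' @param cutoffs strictly increasing cutoffs.
#' @param labels group labels.
#' @return object of class `quartile_scheme`.
#' @export
quartile_scheme <- function(cutoffs = c(1.90, 3.20, 5.50),
                            labels = c("Q1", "Q2", "Q3", "Q4")) {
  if (any(diff(cutoffs) <= 0)) stop_ed("cutoffs must be strictly increasing")
  stopifnot(length(labels) == length(cutoffs) + 1L)
  structure(list(cutoffs = cutoffs, labels = labels), class = "quartile_scheme")
}

#' Assign expenditure quartile labels
#'
#' @param x_ae_day expenditures per adult equivalent per day, US$ PPP.
#' @param scheme a [quartile_scheme()].
#' @return factor of labels (levels in scheme order).
#' @export
assign_quartile <- function(x_ae_day, scheme = quartile_scheme()) {
  idx <- findInterval(x_ae_day, scheme$cutoffs) + 1L
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Total weekly expenditure aggregate
#'
#' Food consumption from all sources valued at unit values, plus non-food
#' expenditures.
#'
#' @param valued_records records carrying a `unit_value` column (from
#'   [unit_values()]).
#' @param households household-wave table with `nonfood_value`.
#' @return numeric vector of weekly total expenditures aligned with
#'   `households` rows.
#' @export
expenditure_aggregate <- function(valued_records, households) {
  food <- valued_records$quantity * valued_records$unit_value
  key <- paste(valued_records$hh, valued_records$wave)
  tot <- tapply(food, key, sum)
  x <- households$nonfood_value +
    ifelse(is.na(tot[paste(households$hh, households$wave)]), 0,
           tot[paste(households$hh, households$wave)])
  if (any(x <= 0)) stop_ed("nonpositive total expenditures for some household-waves")
  as.numeric(x)
}
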