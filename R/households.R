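## Household roster utilities shared by the generator and the survey-prep
## stage: adult-equivalent scales and demand shifters.

#' Adult equivalents of a household roster
#'
#' Rescales household size by an age-based consumption scale.  The default
#' scale counts children under 15 as 0.5, working-age members (15-59) as
#' 1.0 and members 60+ as 0.8 adult equivalents; it is configurable because
#' surveys differ in the scale they apply.
#'
#' @param roster data.frame with columns `hh` and `age` (years; `sex`
#'   ignored by the default scale).
#' @param scale named vector `c(child, adult, elderly)` of weights.
#' @param child_max,elderly_min age bounds of the child and elderly classes.
#' @return named numeric vector of adult equivalents per household id.
#' @export
adult_equivalents <- function(roster, scale = c(child = 0.5, adult = 1, elderly = 0.8),
                              child_max = 14, elderly_min = 60) {
  if (nrow(roster) == 0L) stop_ed("roster is empty")
  w <- ifelse(roster$age <= child_max, scale[["child"]],
              ifelse(roster$age >= elderly_min, scale[["elderly"]], scale[["adult"]]))
  out <- tapply(w, roster$hh, sum)
  stats::setNames(as.numeric(out), names(out))
}

## centred demand shifters per household: log household size, urban flag,
## standardised head age, head sex.  Centring keeps the generator's median
## household at z = 0.
shifter_matrix <- function(roster, urban) {
  hh_ids <- sort(unique(roster$hh))
  size <- tapply(rep(1, nrow(roster)), roster$hh, sum)[as.character(hh_ids)]
  head_row <- roster[!duplicated(roster$hh), ]
  head_row <- head_row[match(hh_ids, head_row$hh), ]
  z <- cbind(
    log_hhsize_c  = log(size) - log(4),
    urban_c       = urban[hh_ids] - 0.5,
    head_age_z    = (head_row$age - 42) / 15,
    head_female_c = as.numeric(head_row$female) - 0.5
  )
  rownames(z) <- hh_ids
  z
}
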