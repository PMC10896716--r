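## Household diet-quality scoring: nutrient adequacy against household
## requirements, WHO macronutrient balance, and a nutrient-rich food index.

## map roster members to requirement classes
requirement_class <- function(age, female, req) {
  idx <- integer(length(age))
  for (i in seq_along(age)) {
    sex <- if (age[i] <= 8) "both" else if (female[i] == 1) "female" else "male"
    hit <- which(req$sex == sex & age[i] >= req$age_min & age[i] <= req$age_max)
    if (length(hit) != 1L)
      stop_ed("no requirement class for member of age %s, sex %s", age[i], sex)
    idx[i] <- hit
  }
  idx
}

#' Household 7-day nutrient requirements
#'
#' Sums the daily estimated requirements (EER for energy, EAR per nutrient)
#' of every household member over a 7-day period.
#'
#' @param roster data.frame with columns `hh`, `age`, `female`.
#' @param requirements requirement table, see [default_requirements()].
#' @return matrix households x nutrients (7-day totals), household ids as
#'   rownames.
#' @export
household_requirement <- function(roster, requirements = default_requirements()) {
  if (nrow(roster) == 0L) stop_ed("roster is empty")
  nut <- setdiff(names(requirements), c("class", "sex", "age_min", "age_max"))
  cls <- requirement_class(roster$age, roster$female, requirements)
  daily <- as.matrix(requirements[cls, nut])
  out <- rowsum(daily, roster$hh) * DAYS_PER_WEEK
  colnames(out) <- nut
  out
}

#' Nutrient intake sufficiency flags
#'
#' A household's intake of a nutrient is sufficient when it is at least the
#' household-level requirement (boundary inclusive).
#'
#' @param intake,requirement matrices (or vectors) in identical units and
#'   layout.
#' @return logical flags of the same shape.
#' @export
intake_sufficiency <- function(intake, requirement) {
  if (any(intake < 0)) stop_ed("negative intake")
  intake >= requirement
}

#' WHO macronutrient balance
#'
#' Energy shares of protein, fat and carbohydrate (Atwater factors 4/9/4
#' kcal per g, shares over macronutrient-derived energy) classified against
#' the recommended ranges 10-15% protein, 15-30% fat, 55-75% carbohydrate,
#' boundary inclusive.
#'
#' @param protein_g,fat_g,carb_g intake in grams (vectors).
#' @return data.frame with the three energy shares and a class
#'   (`below` / `within` / `above`) per macronutrient.
#' @export
macronutrient_balance <- function(protein_g, fat_g, carb_g) {
  en_p <- 4 * protein_g; en_f <- 9 * fat_g; en_c <- 4 * carb_g
  tot <- en_p + en_f + en_c
  if (any(tot <= 0)) stop_ed("all-zero macronutrient intake")
  cls <- function(share, lo, hi)
    factor(ifelse(share < lo, "below", ifelse(share > hi, "above", "within")),
           levels = c("below", "within", "above"))
  data.frame(
    protein_share = en_p / tot, fat_share = en_f / tot, carb_share = en_c / tot,
    protein_class = cls(en_p / tot, 0.10, 0.15),
    fat_class = cls(en_f / tot, 0.15, 0.30),
    carb_class = cls(en_c / tot, 0.55, 0.75)
  )
}

#' Nutrient-rich food index (NRF9.3 style)
#'
#' Nutrient density score on a 2,000 kcal basis: the sum over nine
#' qualifying components (protein, fibre, vitamins A, C and E, calcium,
#' iron, magnesium, potassium) of `min(100, 100 density/reference)` minus
#' the sum over three moderation components (saturated fat, added sugar,
#' sodium) of `100 density/reference`.  Density normalisation makes the
#' score invariant to proportional misreporting of all quantities.
#'
#' @param intake named vector or matrix (columns named as in
#'   [default_composition()]) of intake amounts over any fixed period.
#' @param energy_kcal energy intake over the same period (> 0).
#' @param reference reference daily amounts, see the default in
#'   `nrfi_reference()`.
#' @return numeric score (vector if `intake` is a matrix).
#' @export
nrfi <- function(intake, energy_kcal, reference = nrfi_reference()) {
  if (is.null(dim(intake))) intake <- t(as.matrix(intake))
  if (any(energy_kcal <= 0)) stop_ed("energy intake must be positive")
  need <- c(names(reference$qualifying), names(reference$moderation))
  missing <- setdiff(need, colnames(intake))
  if (length(missing))
    stop_ed("intake is missing NRFI component(s): %s", paste(missing, collapse = ", "))
  dens <- intake[, need, drop = FALSE] * (2000 / energy_kcal)
  qual <- sapply(names(reference$qualifying), function(u)
    pmin(100, 100 * dens[, u] / reference$qualifying[[u]]))
  mod <- sapply(names(reference$moderation), function(u)
    100 * dens[, u] / reference$moderation[[u]])
  if (is.null(dim(qual))) qual <- t(qual)
  if (is.null(dim(mod))) mod <- t(mod)
  unname(rowSums(qual) - rowSums(mod))
}

#' Score household diets
#'
#' Computes, per household-wave, 7-day nutrient intakes from group
#' quantities and the composition table, requirement sufficiency flags,
#' WHO macronutrient balance classes and the NRFI score.
#'
#' @param q `n x J` matrix of weekly food-group quantities (kg).
#' @param hh,roster household ids per row of `q` and the roster table.
#' @param composition composition table (per 100 g).
#' @param requirements requirements table (daily, per class).
#' @return object of class `diet_quality_report`: data.frame with intake
#'   (`in_*`), requirement (`req_*`) and sufficiency (`suf_*`) columns for
#'   the adequacy nutrients, balance shares/classes, and `nrfi`.
#' @export
diet_quality <- function(q, hh, roster, composition,
                         requirements = default_requirements()) {
  comp <- unclass(composition)
  intake <- 10 * q %*% comp  # kg -> 100 g units
  colnames(intake) <- colnames(comp)
  req_all <- household_requirement(roster, requirements)
  req <- req_all[match(as.character(hh), rownames(req_all)), , drop = FALSE]
  nut <- colnames(req)
  suf <- intake_sufficiency(intake[, nut, drop = FALSE], req)
  bal <- macronutrient_balance(intake[, "protein_g"], intake[, "fat_g"],
                               intake[, "carb_g"])
  score <- nrfi(intake, intake[, "energy_kcal"])
  out <- data.frame(hh = hh)
  out <- cbind(out,
               `colnames<-`(as.data.frame(intake[, nut, drop = FALSE]), paste0("in_", nut)),
               `colnames<-`(as.data.frame(req), paste0("req_", nut)),
               `colnames<-`(as.data.frame(suf), paste0("suf_", nut)),
               bal, nrfi = score)
  class(out) <- c("diet_quality_report", class(out))
  out
}
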