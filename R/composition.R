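## Food-composition and nutrient-requirement defaults.
##
## Both tables are synthetic, documented stand-ins: archetype nutrient
## profiles per 100 g patterned on typical food-composition entries, and
## requirement values per age-sex class patterned on standard dietary
## reference intakes.  They are config-replaceable throughout the package.

NUTRIENTS <- c("energy_kcal", "carb_g", "protein_g", "fat_g",
               "iron_mg", "zinc_mg", "vita_ug", "folate_ug",
               "fibre_g", "vitc_mg", "vite_mg", "calcium_mg",
               "magnesium_mg", "potassium_mg",
               "satfat_g", "sugar_g", "sodium_mg")

## archetype profiles per 100 g (energy recomputed from Atwater factors)
composition_archetypes <- function() {
  a <- rbind(
    staple = c(NA, 75,  9,   3.5, 2.5, 1.8, 0,   25,  7,    0,  0.5, 15,  90,  280,  0.6, 1,   5),
    pulse  = c(NA, 60,  22,  1.5, 7,   3,   0,   400, 15,   2,  0.5, 110, 150, 1300, 0.3, 2,   10),
    asf    = c(NA, 2,   20,  12,  2.5, 4,   120, 15,  0,    0,  0.8, 60,  25,  300,  4.5, 0.5, 90),
    ffv    = c(NA, 12,  2,   0.4, 1.5, 0.5, 350, 80,  3.5,  40, 1,   60,  30,  350,  0.1, 6,   15),
    tuber  = c(NA, 38,  1.4, 0.3, 0.3, 0.3, 1,   27,  1.8,  20, 0.2, 16,  21,  270,  0.1, 1.7, 14),
    oils   = c(NA, 0.5, 0.2, 98,  0,   0,   0,   0,   0,    0,  15,  0,   0,   0,    35,  0,   2)
  )
  colnames(a) <- NUTRIENTS
  a
}

#' Build a default (synthetic) food-composition table
#'
#' Returns nutrient contents per 100 g for `n_groups` food groups, cycling
#' through six archetypes -- starchy staple, pulse, animal-source food,
#' fruit/vegetable, root/tuber, oils -- with small seed-controlled jitter.
#' Stated energy is tied to the Atwater factors (4/4/9 kcal per g of
#' carbohydrate/protein/fat) within 2%.
#'
#' @param n_groups number of food groups (>= 2).
#' @param seed integer seed for the jitter.
#' @return matrix `n_groups x 17` of class `composition_table`; row order
#'   follows the archetype cycle, recorded in `attr(, "archetype")`.
#' @export
default_composition <- function(n_groups, seed = 1L) {
  n_groups <- check_count(n_groups, "n_groups", min = 2L)
  arch <- composition_archetypes()
  idx <- rep_len(seq_len(nrow(arch)), n_groups)
  with_seed(sub_seed(seed, 7L), {
    comp <- arch[idx, , drop = FALSE]
    jitter <- matrix(stats::runif(length(comp), 0.92, 1.08), nrow(comp))
    comp <- comp * jitter
    comp[, "energy_kcal"] <-
      (4 * comp[, "carb_g"] + 4 * comp[, "protein_g"] + 9 * comp[, "fat_g"]) *
      stats::runif(n_groups, 0.98, 1.02)
    rownames(comp) <- paste0("g", seq_len(n_groups))
    attr(comp, "archetype") <- rownames(arch)[idx]
    class(comp) <- c("composition_table", class(comp))
    comp
  })
}

#' Map food groups to price-discount categories
#'
#' Produces the food group to policy category mapping (SG staple grains,
#' SS starchy staples, PN pulses and nuts, FFV fresh fruits and vegetables,
#' ASF animal-source foods) from the archetype labels of a composition table
#' built by [default_composition()].  Groups without a category (oils) map
#' to `NA` and are never discounted.
#'
#' @param composition a `composition_table`.
#' @return data.frame with columns `group` and `category`.
#' @export
default_category_map <- function(composition) {
  arch <- attr(composition, "archetype")
  if (is.null(arch)) stop_ed("composition table has no archetype labels; supply a category map")
  lookup <- c(staple = "SG", tuber = "SS", pulse = "PN", ffv = "FFV",
              asf = "ASF", oils = NA_character_)
  data.frame(group = seq_along(arch), category = unname(lookup[arch]),
             stringsAsFactors = FALSE)
}

#' Default household nutrient-requirements table
#'
#' Daily estimated energy requirements (EER, kcal) and estimated average
#' requirements (EAR) per nutrient for 14 age-sex classes: young children
#' (both sexes, ages 1-3 and 4-8) and male/female classes for ages 9-13,
#' 14-18, 19-30, 31-50, 51-70 and 70+.  Values are documented defaults
#' patterned on standard dietary reference intakes; the fat entry is a
#' pseudo-requirement at the lower bound of the recommended fat energy range
#' (15% of EER at 9 kcal/g), since fat has no EAR.
#'
#' @return data.frame with columns `class`, `sex`, `age_min`, `age_max`,
#'   `energy_kcal`, `carb_g`, `protein_g`, `fat_g`, `iron_mg`, `zinc_mg`,
#'   `vita_ug`, `folate_ug`; one row per age-sex class, daily basis.
#' @export
default_requirements <- function() {
  cls <- data.frame(
    class   = c("c1_3", "c4_8",
                "m9_13", "m14_18", "m19_30", "m31_50", "m51_70", "m70p",
                "f9_13", "f14_18", "f19_30", "f31_50", "f51_70", "f70p"),
    sex     = c("both", "both", rep("male", 6), rep("female", 6)),
    age_min = c(0, 4, 9, 14, 19, 31, 51, 71, 9, 14, 19, 31, 51, 71),
    age_max = c(3, 8, 13, 18, 30, 50, 70, 200, 13, 18, 30, 50, 70, 200),
    energy_kcal = c(1000, 1400, 1800, 2400, 2600, 2400, 2200, 2000,
                    1600, 1800, 2000, 1800, 1800, 1600),
    carb_g   = rep(100, 14),
    protein_g = c(11, 15, 27, 44, 46, 46, 46, 46, 28, 38, 38, 38, 38, 38),
    iron_mg  = c(3, 4.1, 5.9, 7.7, 6, 6, 6, 6, 5.7, 7.9, 8.1, 8.1, 5, 5),
    zinc_mg  = c(2.5, 4, 7, 8.5, 9.4, 9.4, 9.4, 9.4, 7, 7.3, 6.8, 6.8, 6.8, 6.8),
    vita_ug  = c(210, 275, 445, 630, 625, 625, 625, 625, 420, 485, 500, 500, 500, 500),
    folate_ug = c(120, 160, 250, 330, 320, 320, 320, 320, 250, 330, 320, 320, 320, 320),
    stringsAsFactors = FALSE
  )
  cls$fat_g <- 0.15 * cls$energy_kcal / 9
  cls[, c("class", "sex", "age_min", "age_max", "energy_kcal", "carb_g",
          "protein_g", "fat_g", "iron_mg", "zinc_mg", "vita_ug", "folate_ug")]
}

## NRF9.3-style reference daily amounts used by the nutrient-rich food index
nrfi_reference <- function() {
  list(
    qualifying = c(protein_g = 50, fibre_g = 28, vita_ug = 900, vitc_mg = 90,
                   vite_mg = 15, calcium_mg = 1300, iron_mg = 18,
                   magnesium_mg = 420, potassium_mg = 4700),
    moderation = c(satfat_g = 20, sugar_g = 50, sodium_mg = 2300)
  )
}
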