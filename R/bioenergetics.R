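#' Composition of fasting mass loss
#'
#' Fractions of total lost body mass during the molt fast: molted pelage,
#' fat, free water, and metabolizable fat-free mass (FFM). Defaults are the
#' literature composition for similarly sized molting female elephant seals:
#' 14% pelage, and the remaining 86% split as 41% fat, 25% water and 20% FFM
#' (all as fractions of the total). The FFM hydration parenthetical (5% dry
#' matter, 15% additional water) is stored for reference but deliberately
#' not used in the energy arithmetic: the 1 kcal/g equivalent applies to the
#' hydrated FFM, which is what reproduces the published energy budget.
#'
#' @param frac_pelage,frac_fat,frac_water,frac_ffm fractions of total lost
#'   mass; must sum to 1 within 1e-9
#' @param ffm_dry_frac,ffm_extra_water_frac FFM composition, stored only
#' @return list of class `composition_model`
#' @export
composition_model <- function(frac_pelage = 0.14, frac_fat = 0.41,
                              frac_water = 0.25, frac_ffm = 0.20,
                              ffm_dry_frac = 0.05, ffm_extra_water_frac = 0.15) {
  fr <- c(frac_pelage, frac_fat, frac_water, frac_ffm)
  if (any(fr < 0 | fr > 1))
    smt_stop("composition fractions must lie in [0, 1]", "sealmito_config_error")
  if (abs(sum(fr) - 1) > 1e-9)
    smt_stop(sprintf("composition fractions must sum to 1 (got %.12f)", sum(fr)),
             "sealmito_config_error")
  structure(list(frac_pelage = frac_pelage, frac_fat = frac_fat,
                 frac_water = frac_water, frac_ffm = frac_ffm,
                 ffm_dry_frac = ffm_dry_frac,
                 ffm_extra_water_frac = ffm_extra_water_frac),
            class = "composition_model")
}

#' Energy equivalents and scaling constants
#'
#' Constants of the fasting bioenergetic model: tissue energy densities
#' (fat 9 kcal/g = 37.7 kJ/g; fat-free mass 1 kcal/g = 4.2 kJ/g), the
#' kcal-to-kJ factor, the oxygen energy equivalent for predominantly fat
#' oxidation (19.7 kJ per litre O2), the molar gas volume at STP (22.4
#' l/mol, which reproduces the published flux-to-volume conversion), the
#' skeletal-muscle share of body mass (28%) and the field metabolic rate
#' coefficient for free-ranging animals (106.5 kJ per kg per day).
#'
#' @param fat_kcal_per_g,ffm_kcal_per_g,fat_kj_per_g,ffm_kj_per_g tissue
#'   energy densities
#' @param kj_per_kcal thermochemical conversion
#' @param o2_kj_per_l oxygen energy equivalent, kJ per litre O2
#' @param molar_volume_l_per_mol molar gas volume, l per mol
#' @param muscle_mass_fraction skeletal-muscle fraction of body mass
#' @param fmr_kj_per_kg_day field metabolic rate coefficient
#' @return list of class `energy_equivalents`
#' @export
energy_equivalents <- function(fat_kcal_per_g = 9, ffm_kcal_per_g = 1,
                               fat_kj_per_g = 37.7, ffm_kj_per_g = 4.2,
                               kj_per_kcal = 4.184, o2_kj_per_l = 19.7,
                               molar_volume_l_per_mol = 22.4,
                               muscle_mass_fraction = 0.28,
                               fmr_kj_per_kg_day = 106.5) {
  vals <- c(fat_kcal_per_g, ffm_kcal_per_g, fat_kj_per_g, ffm_kj_per_g,
            kj_per_kcal, o2_kj_per_l, molar_volume_l_per_mol,
            muscle_mass_fraction, fmr_kj_per_kg_day)
  if (any(!is.finite(vals) | vals <= 0))
    smt_stop("all energy constants must be positive", "sealmito_config_error")
  structure(list(fat_kcal_per_g = fat_kcal_per_g, ffm_kcal_per_g = ffm_kcal_per_g,
                 fat_kj_per_g = fat_kj_per_g, ffm_kj_per_g = ffm_kj_per_g,
                 kj_per_kcal = kj_per_kcal, o2_kj_per_l = o2_kj_per_l,
                 molar_volume_l_per_mol = molar_volume_l_per_mol,
                 muscle_mass_fraction = muscle_mass_fraction,
                 fmr_kj_per_kg_day = fmr_kj_per_kg_day),
            class = "energy_equivalents")
}

#' One animal's molt mass record
#'
#' @param animal_id identifier
#' @param mass_pre,mass_post body mass in kg before and after the molt fast
#' @param days_ashore days between the two measurements (> 0)
#' @return list of class `seal_record`
#' @export
seal_record <- function(animal_id, mass_pre, mass_post, days_ashore) {
  if (!is.finite(mass_pre) || !is.finite(mass_post) || mass_pre <= 0 || mass_post <= 0)
    smt_stop("masses must be positive", "sealmito_invalid_input")
  if (!is.finite(days_ashore) || days_ashore <= 0)
    smt_stop("days_ashore must be > 0", "sealmito_invalid_input")
  if (mass_post > mass_pre)
    warning(sprintf("%s: mass_post > mass_pre (gained mass during a molt fast?)",
                    animal_id), call. = FALSE)
  structure(list(animal_id = as.character(animal_id), mass_pre = mass_pre,
                 mass_post = mass_post, days_ashore = days_ashore),
            class = "seal_record")
}

#' Daily mass loss and percent of initial mass
#'
#' @param rec a [seal_record()]
#' @return list: `daily_loss` (kg/day), `total_loss` (kg), `percent_loss`
#'   (% of initial mass)
#' @export
daily_mass_loss <- function(rec) {
  stopifnot(inherits(rec, "seal_record"))
  loss <- rec$mass_pre - rec$mass_post
  list(daily_loss = loss / rec$days_ashore,
       total_loss = loss,
       percent_loss = 100 * loss / rec$mass_pre)
}

#' Apportion daily mass loss into tissue components
#'
#' @param daily_loss kg lost per day (>= 0)
#' @param comp a [composition_model()]
#' @return named numeric: `pelage`, `water`, `ffm`, `fat` (kg/day; sums to
#'   `daily_loss` exactly)
#' @export
apportion <- function(daily_loss, comp = composition_model()) {
  stopifnot(inherits(comp, "composition_model"))
  if (!is.finite(daily_loss) || daily_loss < 0)
    smt_stop("daily_loss must be >= 0", "sealmito_invalid_input")
  c(pelage = daily_loss * comp$frac_pelage,
    water = daily_loss * comp$frac_water,
    ffm = daily_loss * comp$frac_ffm,
    fat = daily_loss * comp$frac_fat)
}

#' Daily energy expenditure from catabolized fat and fat-free mass
#'
#' Two unit paths are computed. The kcal path,
#' `dee_kcal = 1000 * (fat*9 + ffm*1)` with masses in kg/day, is canonical
#' for the kcal figure. The kJ path uses the direct kJ/g equivalents
#' (fat x 37.7 + ffm x 4.2, reported in MJ/day) and is canonical for the MJ
#' figures. The two differ by ~0.3% because 9 kcal/g is not exactly
#' 37.7/4.184.
#'
#' @param fat,ffm catabolized fat and fat-free mass, kg/day (>= 0)
#' @param eq an [energy_equivalents()]
#' @return list: `dee_kcal` (kcal/day), `dee_mj` (MJ/day, kJ path),
#'   `dee_mj_kcal_path` (MJ/day via kcal x 4.184), `fat_mj` (MJ/day from
#'   fat), `fat_fraction` (fat share of total energy; `NA` when total is 0)
#' @export
energy_expenditure <- function(fat, ffm, eq = energy_equivalents()) {
  stopifnot(inherits(eq, "energy_equivalents"))
  if (any(!is.finite(c(fat, ffm))) || fat < 0 || ffm < 0)
    smt_stop("fat and ffm must be >= 0", "sealmito_invalid_input")
  dee_kcal <- 1000 * (fat * eq$fat_kcal_per_g + ffm * eq$ffm_kcal_per_g)
  fat_mj <- fat * eq$fat_kj_per_g        # kg/day * kJ/g = MJ/day
  dee_mj <- fat_mj + ffm * eq$ffm_kj_per_g
  list(dee_kcal = dee_kcal,
       dee_mj = dee_mj,
       dee_mj_kcal_path = dee_kcal * eq$kj_per_kcal / 1000,
       fat_mj = fat_mj,
       fat_fraction = if (dee_mj > 0) fat_mj / dee_mj else NA_real_)
}

#' Skeletal muscle mass from body mass
#'
#' @param body_mass kg (> 0)
#' @param eq an [energy_equivalents()]
#' @return muscle mass, kg
#' @export
muscle_mass <- function(body_mass, eq = energy_equivalents()) {
  stopifnot(inherits(eq, "energy_equivalents"))
  if (!is.finite(body_mass) || body_mass <= 0)
    smt_stop("body_mass must be > 0", "sealmito_invalid_input")
  body_mass * eq$muscle_mass_fraction
}

#' Convert mass-specific flux to volume rate
#'
#' pmol O2 s-1 mg-1 is numerically umol O2 s-1 kg-1; times 60 s/min and the
#' molar volume (22.4 ul/umol at STP) gives ml O2 kg-1 min-1.
#'
#' @param flux pmol O2 s-1 mg-1 (>= 0)
#' @param eq an [energy_equivalents()]
#' @return ml O2 kg-1 min-1
#' @export
flux_to_mlo2 <- function(flux, eq = energy_equivalents()) {
  stopifnot(inherits(eq, "energy_equivalents"))
  if (any(!is.finite(flux)) || any(flux < 0))
    smt_stop("flux must be >= 0", "sealmito_invalid_input")
  flux * 60 * eq$molar_volume_l_per_mol / 1000
}

#' Inverse of [flux_to_mlo2()]
#'
#' @param mlo2 ml O2 kg-1 min-1
#' @param eq an [energy_equivalents()]
#' @return pmol O2 s-1 mg-1
#' @export
mlo2_to_flux <- function(mlo2, eq = energy_equivalents()) {
  stopifnot(inherits(eq, "energy_equivalents"))
  mlo2 * 1000 / (60 * eq$molar_volume_l_per_mol)
}

#' Whole-muscle leak respiratory capacity
#'
#' Extrapolates a mass-specific leak flux to the whole skeletal-muscle mass
#' and converts to daily energy via the oxygen equivalent: unrounded
#' ml O2 kg-1 min-1 x muscle kg x 1440 min/day -> l O2 day-1 x 19.7 kJ/l.
#'
#' @param muscle_kg skeletal muscle mass, kg (> 0)
#' @param leak_flux leak flux, pmol O2 s-1 mg-1 (>= 0)
#' @param eq an [energy_equivalents()]
#' @return MJ per day
#' @export
leak_capacity <- function(muscle_kg, leak_flux, eq = energy_equivalents()) {
  stopifnot(inherits(eq, "energy_equivalents"))
  if (!is.finite(muscle_kg) || muscle_kg <= 0)
    smt_stop("muscle_kg must be > 0", "sealmito_invalid_input")
  ml_per_kg_min <- flux_to_mlo2(leak_flux, eq)
  l_per_day <- ml_per_kg_min * muscle_kg * 1440 / 1000
  l_per_day * eq$o2_kj_per_l / 1000
}

#' Field metabolic rate from body mass
#'
#' @param body_mass kg (> 0)
#' @param eq an [energy_equivalents()]
#' @return MJ per day
#' @export
field_metabolic_rate <- function(body_mass, eq = energy_equivalents()) {
  stopifnot(inherits(eq, "energy_equivalents"))
  if (!is.finite(body_mass) || body_mass <= 0)
    smt_stop("body_mass must be > 0", "sealmito_invalid_input")
  body_mass * eq$fmr_kj_per_kg_day / 1000
}

#' Read a cohort CSV
#'
#' Columns: `animal_id,mass_pre_kg,mass_post_kg,days_ashore`.
#'
#' @param path CSV path
#' @return data.frame
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "mass_pre_kg", "mass_post_kg", "days_ashore")
  if (!all(need %in% names(df)))
    smt_stop(paste0(path, ": expected columns ", paste(need, collapse = ",")),
             "sealmito_io_error")
  df
}

#' Full energy budget for a molt cohort
#'
#' Per-animal rows plus a `cohort_mean` row in which every derived quantity
#' is computed from the cohort-mean inputs (the convention used for the
#' published figures: e.g. muscle mass and field metabolic rate scale from
#' the mean of pre- and post-molt body mass averaged over animals).
#'
#' @param cohort data.frame as from [read_cohort()]
#' @param comp a [composition_model()]
#' @param eq an [energy_equivalents()]
#' @param leak_flux optional mass-specific leak flux (pmol O2 s-1 mg-1) for
#'   the whole-muscle leak-capacity column; typically the lowest measured
#'   leak state
#' @return data.frame of class `energy_budget`
#' @export
energy_budget <- function(cohort, comp = composition_model(),
                          eq = energy_equivalents(), leak_flux = NULL) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    r <- cohort[i, ]
    budget_row(r$animal_id, r$mass_pre_kg, r$mass_post_kg, r$days_ashore,
               comp, eq, leak_flux)
  })
  mean_row <- budget_row("cohort_mean",
                         mean(cohort$mass_pre_kg), mean(cohort$mass_post_kg),
                         mean(cohort$days_ashore), comp, eq, leak_flux)
  out <- do.call(rbind, c(rows, list(mean_row)))
  class(out) <- c("energy_budget", "data.frame")
  out
}

budget_row <- function(id, pre, post, days, comp, eq, leak_flux) {
  rec <- seal_record(id, pre, post, days)
  dl <- daily_mass_loss(rec)
  ap <- apportion(dl$daily_loss, comp)
  en <- energy_expenditure(ap[["fat"]], ap[["ffm"]], eq)
  avg_mass <- (pre + post) / 2
  mm <- muscle_mass(avg_mass, eq)
  data.frame(
    animal_id = as.character(id), mass_pre_kg = pre, mass_post_kg = post,
    days_ashore = days, daily_loss_kg = dl$daily_loss,
    percent_loss = dl$percent_loss,
    pelage_kg_day = ap[["pelage"]], water_kg_day = ap[["water"]],
    ffm_kg_day = ap[["ffm"]], fat_kg_day = ap[["fat"]],
    dee_kcal_day = en$dee_kcal, dee_mj_day = en$dee_mj,
    fat_mj_day = en$fat_mj, fat_fraction = en$fat_fraction,
    avg_mass_kg = avg_mass, muscle_kg = mm,
    fmr_mj_day = field_metabolic_rate(avg_mass, eq),
    leak_capacity_mj_day = if (is.null(leak_flux)) NA_real_
                           else leak_capacity(mm, leak_flux, eq),
    stringsAsFactors = FALSE
  )
}
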