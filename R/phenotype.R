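# EWGSOP sarcopenia phenotyping from bioimpedance-derived muscle mass.

#' Skeletal muscle mass from bioimpedance (Janssen equation)
#'
#' Whole-body skeletal muscle mass in kg from single-frequency BIA:
#' \deqn{SMM = height_{cm}^2 / R \times 0.401 + sex \times 3.825
#'       - 0.071 \times age + 5.102}
#' with height in cm, resistance R in ohm, sex coded 1 for men and 0 for
#' women, and age in years.
#'
#' @param height_cm standing height in cm (> 0).
#' @param resistance_ohm BIA resistance in ohm (> 0).
#' @param sex_code 1 = male, 0 = female.
#' @param age_years age in years.
#' @return skeletal muscle mass in kg. A non-positive result is physically
#'   implausible and is returned with a warning.
#' @examples
#' janssen_smm(170, 500, 1, 78) # 26.567 kg
#' @export
janssen_smm <- function(height_cm, resistance_ohm, sex_code, age_years) {
  if (any(!is.na(resistance_ohm) & resistance_ohm <= 0))
    stopf("BIA resistance must be > 0 ohm")
  if (any(!is.na(height_cm) & height_cm <= 0))
    stopf("height must be > 0 cm")
  if (!all(is.na(sex_code) | sex_code %in% c(0, 1)))
    stopf("sex_code must be 1 (male) or 0 (female)")
  smm <- height_cm^2 / resistance_ohm * 0.401 + sex_code * 3.825 +
    age_years * (-0.071) + 5.102
  if (any(!is.na(smm) & smm <= 0))
    warnf("Janssen equation produced non-positive muscle mass; inputs implausible")
  smm
}

#' EWGSOP2 cutoff set
#'
#' Sex-specific diagnostic cutoffs: low grip strength below 27 kg (men) /
#' 16 kg (women); low skeletal muscle index below 8.87 (men) / 6.42
#' (women) kg/m^2; low physical performance below 0.8 m/s usual gait speed.
#'
#' @param grip_male,grip_female grip-strength cutoffs, kg.
#' @param smi_male,smi_female skeletal-muscle-index cutoffs, kg/m^2.
#' @param gait gait-speed cutoff, m/s (same for both sexes).
#' @return named list of class `ewgsop_cutoffs`.
#' @export
ewgsop_cutoffs <- function(grip_male = 27, grip_female = 16,
                           smi_male = 8.87, smi_female = 6.42,
                           gait = 0.8) {
  vals <- c(grip_male, grip_female, smi_male, smi_female, gait)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all cutoffs must be positive")
  structure(list(grip = c(male = grip_male, female = grip_female),
                 smi = c(male = smi_male, female = smi_female),
                 gait = gait),
            class = "ewgsop_cutoffs")
}

#' Classify sarcopenia status for a cohort
#'
#' Applies the EWGSOP decision rule: *confirmed* sarcopenia requires both low
#' grip strength and low muscle quantity (SMI below the sex-specific cutoff);
#' low gait speed additionally marks *severe* sarcopenia. Muscle mass is
#' computed with [janssen_smm()] and SMI as SMM divided by height (m)
#' squared. Samples missing any required measurement are left
#' `unclassified` with the reason recorded.
#'
#' @param cohort a cohort data frame (see [read_cohort()]).
#' @param cutoffs an [ewgsop_cutoffs()] set.
#' @return the cohort with columns `smm`, `smi`, `low_strength`, `low_mass`,
#'   `low_performance`, `severe`, and `status` filled in; unclassifiable rows
#'   get `status = "unclassified"` and the reason in `unclassified_reason`.
#' @export
classify_sarcopenia <- function(cohort, cutoffs = ewgsop_cutoffs()) {
  need <- c("sex", "age", "height_cm", "resistance_ohm", "grip_kg",
            "gait_m_s")
  out <- as.data.frame(cohort)
  sexi <- ifelse(out$sex == "male", 1, 0)

  has_all <- Reduce(`&`, lapply(need, function(cl) !is.na(out[[cl]])))
  reason <- rep(NA_character_, nrow(out))
  for (cl in rev(need)) reason[is.na(out[[cl]])] <- paste("missing", cl)

  smm <- rep(NA_real_, nrow(out))
  smm[has_all] <- janssen_smm(out$height_cm[has_all],
                              out$resistance_ohm[has_all],
                              sexi[has_all], out$age[has_all])
  smi <- smm / (out$height_cm / 100)^2

  grip_cut <- unname(cutoffs$grip[ifelse(sexi == 1, "male", "female")])
  smi_cut <- unname(cutoffs$smi[ifelse(sexi == 1, "male", "female")])

  low_strength <- out$grip_kg < grip_cut
  low_mass <- smi < smi_cut
  low_perf <- out$gait_m_s < cutoffs$gait

  status <- ifelse(low_strength & low_mass, "sarcopenic", "non_sarcopenic")
  status[!has_all] <- "unclassified"
  severe <- status == "sarcopenic" & low_perf

  out$smm <- smm
  out$smi <- smi
  out$low_strength <- ifelse(has_all, low_strength, NA)
  out$low_mass <- ifelse(has_all, low_mass, NA)
  out$low_performance <- ifelse(has_all, low_perf, NA)
  out$severe <- ifelse(has_all, severe, NA)
  out$status <- status
  out$unclassified_reason <- ifelse(has_all, NA_character_, reason)
  class(out) <- c("sarco_cohort", "data.frame")
  out
}
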