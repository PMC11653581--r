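# End-to-end PK arm: moment analysis of both routes, bioavailability
# decomposition against the group-mean IV AUC, and the per-animal flip-flop
# k_a fit with IV-derived disposition fixed. Also the strain-comparison
# summary table (mean +/- S.D. with unpaired t-tests).

#' Run the full PK pipeline on one study
#'
#' Per animal: IV moment analysis gives `k_e`, `CL_tot`, `Vd_ss`;
#' transdermal moment analysis gives `C_max`, `T_max`, transdermal AUC and
#' `CL_tot/F`; bioavailability `F` is each animal's dose-normalised
#' transdermal AUC over the group-mean dose-normalised IV AUC; `F_a` comes
#' from the patch residuals and `F_skin = F / F_a`; finally `k_a` is fit to
#' the transdermal profile with that animal's `F`, `k_e` and absolute volume
#' (`Vd_ss` x body weight) held fixed.
#'
#' @param study A `"rat_study"` (from [simulate_rat()]) or a list with
#'   `$profiles` and `$residuals` in the package's long formats.
#' @param n_terminal,method Passed to the moment analysis.
#' @param ... Passed to [fit_ka()] (weighting, scale, dialect).
#' @return Tibble of class `"pk_study"`, one row per animal, with the IV,
#'   transdermal, bioavailability and absorption-fit parameters.
#' @examples
#' study <- simulate_rat(rat_preset("wistar"), n_subjects = 5, seed = 2)
#' pk_study(study)
#' @export
pk_study <- function(study, n_terminal = 3, method = "linuplogdown", ...) {
  profiles <- as_tibble(study$profiles)
  iv <- nca_iv(profiles, n_terminal = n_terminal, method = method)
  td <- nca_td(profiles, n_terminal = n_terminal, method = method)

  dose_iv <- filter(profiles, .data$route == "iv_bolus")$dose[1]
  mean_auc_iv <- mean(iv$AUC_0_inf, na.rm = TRUE)
  bio <- bioavailability_table(td, study$residuals, mean_auc_iv, dose_iv)

  params <- iv %>%
    select("subject_id", k_e = "k_e", Vd_ss = "Vd_ss") %>%
    left_join(select(td, "subject_id", "body_weight_kg"),
              by = "subject_id") %>%
    left_join(select(bio, "subject_id", F_bio = "F"), by = "subject_id") %>%
    mutate(Vd = .data$Vd_ss * .data$body_weight_kg)

  ka <- fit_ka_cohort(profiles, select(params, "subject_id", "F_bio",
                                       "k_e", "Vd"), ...)

  out <- iv %>%
    select("subject_id", AUC_iv = "AUC_0_inf", "MRT", "k_e", "CL_tot",
           "Vd_ss") %>%
    left_join(select(td, "subject_id", "C_max", "T_max",
                     AUC_td = "AUC_0_inf", "CL_tot_over_F"),
              by = "subject_id") %>%
    left_join(bio, by = "subject_id") %>%
    left_join(select(ka, "subject_id", "k_a", "flip_flop",
                     "half_life_apparent"),
              by = "subject_id")
  class(out) <- c("pk_study", class(out))
  out
}

#' Strain-comparison parameter table
#'
#' Mean, standard deviation and unpaired t-test p-value for every shared PK
#' parameter of two per-animal tables — the layout of a two-strain summary
#' table, with bioavailability terms rendered as percentages. Welch's
#' unequal-variance t-test is the default; set `var_equal = TRUE` for
#' Student's.
#'
#' @param a,b Per-animal tibbles from [pk_study()].
#' @param labels Length-2 character vector naming the two groups.
#' @param var_equal Use the pooled-variance (Student) t-test.
#' @param alpha Significance flag threshold.
#' @return Tibble: `parameter`, per-group `mean`/`sd` columns, `p_value`,
#'   `significant`.
#' @export
pk_parameter_table <- function(a, b, labels = c("group_a", "group_b"),
                               var_equal = FALSE, alpha = 0.05) {
  pct <- c("F", "F_a", "F_skin")
  pars <- c("AUC_iv", "CL_tot", "k_e", "Vd_ss", "C_max", "T_max", "AUC_td",
            "CL_tot_over_F", "k_a", "F", "F_a", "F_skin")
  pars <- intersect(pars, intersect(names(a), names(b)))
  rows <- purrr::map(pars, function(p) {
    xa <- a[[p]] * if (p %in% pct) 100 else 1
    xb <- b[[p]] * if (p %in% pct) 100 else 1
    tt <- t.test(xa, xb, var.equal = var_equal)
    tibble(parameter = if (p %in% pct) paste0(p, "_pct") else p,
           mean_a = mean(xa), sd_a = sd(xa),
           mean_b = mean(xb), sd_b = sd(xb),
           p_value = tt$p.value, significant = tt$p.value < alpha)
  })
  out <- bind_rows(rows)
  names(out)[2:5] <- c(paste0("mean_", labels[1]), paste0("sd_", labels[1]),
                       paste0("mean_", labels[2]), paste0("sd_", labels[2]))
  out
}
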