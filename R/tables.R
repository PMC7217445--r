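#' Reference tables from the smallholder sheep survey
#'
#' Summary tables from a survey of 370 sheep-keeping smallholder
#' farmers in three districts of the northwest Ethiopian highlands
#' (117, 125 and 128 respondents), bundled so the ranking and reporting
#' tools can be exercised on real published summaries without any
#' external download.
#'
#' * `production_objective_ranks()`: proportion of respondents ranking
#'   each reason for keeping sheep 1st-4th.
#' * `selection_criteria_ranks(sex)`: the same for ram or ewe selection
#'   criteria; criteria not elicited for a sex are absent from its table.
#' * `flock_composition()`: mean and SD of flock counts per sheep
#'   category, by district and overall, with respondent counts in
#'   `attr(, "n_respondents")`.
#' * `sheep_gmnl_estimates(model)`: the published G-MNL coefficient
#'   estimates and standard errors for ram or ewe attribute part-worths
#'   (intercepts, fixed and random-mean coefficients, SDs of the random
#'   deviations and the scale-heterogeneity SD tau), with the model
#'   log-likelihood, null log-likelihood and retained observation count
#'   in attributes.
#'
#' @param sex,model `"ram"` or `"ewe"`.
#' @return A data frame (see above).
#' @name survey_tables
NULL

#' @rdname survey_tables
#' @export
production_objective_ranks <- function() {
  out <- data.frame(
    item = c("income_generation", "meat_source", "saving_asset",
             "manure_source", "sheep_skin", "wool_production"),
    rank1 = c(0.65, 0.32, 0.02, 0.00, 0.00, 0.00),
    rank2 = c(0.33, 0.52, 0.08, 0.07, 0.01, 0.00),
    rank3 = c(0.01, 0.14, 0.18, 0.45, 0.22, 0.01),
    rank4 = c(0.01, 0.03, 0.09, 0.44, 0.42, 0.03)
  )
  out
}

#' @rdname survey_tables
#' @export
selection_criteria_ranks <- function(sex = c("ram", "ewe")) {
  sex <- match.arg(sex)
  if (sex == "ram") {
    data.frame(
      item = c("body_size", "ear_size", "pedigree", "coat_color",
               "growth_rate", "sexual_maturity", "libido", "tail_type",
               "adaptation", "wool_yield", "horn_status"),
      rank1 = c(0.64, 0.03, 0.03, 0.25, 0.01, 0.00, 0.01, 0.03, 0.00,
                0.00, 0.00),
      rank2 = c(0.21, 0.05, 0.01, 0.44, 0.04, 0.02, 0.03, 0.14, 0.00,
                0.01, 0.02),
      rank3 = c(0.09, 0.13, 0.05, 0.16, 0.07, 0.02, 0.10, 0.18, 0.01,
                0.02, 0.02),
      rank4 = c(0.02, 0.19, 0.08, 0.08, 0.08, 0.10, 0.18, 0.17, 0.01,
                0.01, 0.10)
    )
  } else {
    data.frame(
      item = c("body_size", "litter_size", "lamb_survival", "lamb_growth",
               "lambing_interval", "ear_size", "pedigree", "coat_color",
               "growth_rate", "sexual_maturity", "tail_type",
               "adaptation", "wool_yield", "horn_status"),
      rank1 = c(0.63, 0.02, 0.00, 0.02, 0.02, 0.02, 0.05, 0.22, 0.01,
                0.00, 0.01, 0.00, 0.00, 0.00),
      rank2 = c(0.26, 0.02, 0.00, 0.04, 0.05, 0.04, 0.01, 0.41, 0.04,
                0.06, 0.06, 0.00, 0.01, 0.00),
      rank3 = c(0.05, 0.09, 0.01, 0.03, 0.13, 0.10, 0.03, 0.15, 0.08,
                0.19, 0.08, 0.02, 0.02, 0.01),
      rank4 = c(0.02, 0.12, 0.05, 0.08, 0.21, 0.07, 0.05, 0.06, 0.05,
                0.12, 0.11, 0.02, 0.02, 0.00)
    )
  }
}

#' @rdname survey_tables
#' @export
flock_composition <- function() {
  out <- data.frame(
    category = c("breeding_ewes", "breeding_rams", "ewe_lambs",
                 "ram_lambs", "lambs", "castrated", "total"),
    estie_mean = c(5.15, 0.52, 0.45, 0.62, 2.83, 0.07, 9.65),
    estie_sd = c(1.34, 0.57, 1.03, 0.94, 1.33, 0.31, 2.76),
    farta_mean = c(3.86, 0.46, 0.64, 0.79, 2.76, 0.03, 8.54),
    farta_sd = c(1.19, 0.50, 0.87, 0.92, 1.75, 0.18, 3.40),
    lay_gayient_mean = c(6.64, 0.45, 1.87, 0.68, 2.58, 0.14, 12.36),
    lay_gayient_sd = c(3.20, 0.60, 1.53, 1.15, 2.16, 0.68, 6.39),
    overall_mean = c(5.23, 0.48, 1.01, 0.70, 2.72, 0.08, 10.21),
    overall_sd = c(2.43, 0.56, 1.34, 1.01, 1.79, 0.45, 4.79)
  )
  attr(out, "n_respondents") <- c(estie = 117L, farta = 125L,
                                  lay_gayient = 128L, overall = 370L)
  out
}

#' @rdname survey_tables
#' @export
sheep_gmnl_estimates <- function(model = c("ram", "ewe")) {
  model <- match.arg(model)
  if (model == "ram") {
    out <- data.frame(
      term = c("asc_2", "asc_3", "asc_4",
               "coat_color", "growth_rate", "ear_size", "horn",
               "body_size", "tail_type",
               "sd_body_size", "sd_tail_type", "tau"),
      role = c(rep("intercept", 3),
               rep("fixed", 4), rep("random_mean", 2),
               rep("random_sd", 2), "scale"),
      estimate = c(0.2863, -0.9403, 0.9929,
                   0.3237, 0.2666, -0.1869, 0.2523,
                   0.5132, 0.8986,
                   0.001, 0.014, 0.004),
      se = c(0.117, 0.163, 0.152,
             0.039, 0.043, 0.060, 0.041,
             0.048, 0.051,
             0.072, 0.318, 0.130)
    )
    attr(out, "loglik") <- -1493.1
    attr(out, "loglik_null") <- -1864.1
    attr(out, "n_obs") <- 1473L
  } else {
    out <- data.frame(
      term = c("asc_2", "asc_3", "asc_4",
               "coat_color", "mothering_ability", "litter_size",
               "tail_type", "body_size", "growth_rate",
               "lambing_interval",
               "sd_body_size", "sd_growth_rate", "sd_lambing_interval",
               "tau"),
      role = c(rep("intercept", 3),
               rep("fixed", 4), rep("random_mean", 3),
               rep("random_sd", 3), "scale"),
      estimate = c(1.1342, 0.6060, 1.0351,
                   1.1517, 1.3056, 0.7737,
                   0.8547, 1.1287, 0.9618, 0.9645,
                   0.0055, 0.2086, 0.0745,
                   0.7565),
      se = c(0.251, 0.236, 0.241,
             0.312, 0.357, 0.327,
             0.240, 0.333, 0.254, 0.230,
             0.070, 0.244, 0.171,
             0.172)
    )
    attr(out, "loglik") <- -1376.3
    attr(out, "loglik_null") <- -1894.4
    attr(out, "n_obs") <- 1474L
  }
  out
}
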