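#' Published cohort demographics and clinical summary
#'
#' The printed demographic/clinical summary of the three-group coronary
#' atherosclerosis cohort (13 non-atherosclerotic controls, 38 CAS
#' patients with <50% stenosis, 32 ASCVD patients with 50-99% stenosis):
#' continuous variables as per-group mean and SD, categorical variables
#' as yes-counts per group. These printed rows are the input data for
#' the summary-statistic tests and for the defaults of the synthetic
#' clinical generator.
#'
#' @return list with elements `n` (named group sizes), `continuous`
#'   (data frame: variable, mean/sd per group), `categorical` (data
#'   frame: variable, yes-count per group).
#' @export
cohort_table <- function() {
  n <- c(NC = 13L, CAS = 38L, ASCVD = 32L)
  continuous <- data.frame(
    variable = c("age", "BMI", "systolic", "diastolic", "CK", "CKMB",
                 "LDH", "FBG", "UA", "AST", "ALT", "Cre", "WBC",
                 "neutrophils", "lymphocytes", "monocytes", "eosinophil",
                 "basophil", "TC", "TG", "HDL", "LDL", "FFA"),
    mean_NC = c(56.38, 23.78, 118.80, 74.77, 94.56, 16.14, 185.80, 6.41,
                324.10, 19.81, 28.17, 62.77, 5.94, 3.67, 1.66, 0.46,
                0.13, 0.04, 5.02, 1.35, 1.40, 2.60, 238.00),
    sd_NC = c(5.04, 2.98, 11.74, 7.80, 38.85, 8.47, 28.34, 1.06, 75.19,
              10.23, 6.11, 15.25, 1.73, 1.23, 0.41, 0.21, 0.14, 0.03,
              0.90, 0.48, 0.26, 0.57, 90.68),
    mean_CAS = c(56.50, 23.48, 127.00, 76.65, 72.87, 9.66, 177.70, 5.09,
                 379.30, 22.34, 27.84, 61.97, 6.27, 3.87, 1.76, 0.45,
                 0.16, 0.03, 4.40, 1.62, 1.31, 2.19, 315.50),
    sd_CAS = c(7.94, 3.21, 18.20, 10.20, 28.82, 5.14, 43.76, 0.94,
               121.40, 17.72, 12.22, 13.10, 1.54, 1.18, 0.49, 0.15,
               0.17, 0.01, 0.77, 0.91, 0.30, 0.61, 167.30),
    mean_ASCVD = c(60.03, 25.35, 133.10, 80.83, 103.5, 13.13, 176.40,
                   5.96, 384.40, 28.01, 30.06, 74.28, 6.48, 4.10, 1.74,
                   0.45, 0.15, 0.03, 4.22, 1.87, 1.10, 2.14, 445.10),
    sd_ASCVD = c(7.59, 3.63, 20.31, 8.20, 42.72, 6.71, 29.23, 2.05,
                 79.04, 18.53, 10.19, 17.55, 1.63, 1.30, 0.54, 0.14,
                 0.11, 0.01, 0.96, 0.65, 0.24, 0.67, 169.50),
    stringsAsFactors = FALSE)
  categorical <- data.frame(
    variable = c("male", "smoker", "hypertension", "hyperlipidemia",
                 "diabetes", "statins", "aspirin", "beta_blocker",
                 "ca_blocker", "clopidogrel"),
    yes_NC = c(6L, 3L, 2L, 2L, 0L, 0L, 0L, 0L, 0L, 2L),
    yes_CAS = c(20L, 13L, 15L, 14L, 5L, 12L, 7L, 5L, 7L, 9L),
    yes_ASCVD = c(23L, 18L, 22L, 21L, 4L, 19L, 18L, 14L, 13L, 10L),
    stringsAsFactors = FALSE)
  list(n = n, continuous = continuous, categorical = categorical)
}

#' Group x (yes, no) contingency table for one categorical cohort row
#'
#' @param variable one of the `categorical$variable` entries of
#'   [cohort_table()].
#' @return 3 x 2 integer matrix (groups x yes/no), ready for
#'   [chisq_test()].
#' @export
cohort_contingency <- function(variable) {
  tab <- cohort_table()
  row <- tab$categorical[tab$categorical$variable == variable, ]
  if (nrow(row) != 1L) stop("unknown categorical variable: ", variable)
  yes <- c(row$yes_NC, row$yes_CAS, row$yes_ASCVD)
  m <- cbind(yes = yes, no = tab$n - yes)
  rownames(m) <- names(tab$n)
  m
}

#' Summary-statistic ANOVA for one continuous cohort row
#'
#' @param variable one of the `continuous$variable` entries of
#'   [cohort_table()].
#' @return the [anova_from_summary()] result.
#' @export
cohort_anova <- function(variable) {
  tab <- cohort_table()
  row <- tab$continuous[tab$continuous$variable == variable, ]
  if (nrow(row) != 1L) stop("unknown continuous variable: ", variable)
  anova_from_summary(
    means = c(row$mean_NC, row$mean_CAS, row$mean_ASCVD),
    sds = c(row$sd_NC, row$sd_CAS, row$sd_ASCVD),
    ns = unname(cohort_table()$n))
}
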