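#' Study reference tables
#'
#' Printed summary values from the source cohort that parameterize the
#' synthetic-data generator: per-class quantifiable species counts and mean
#' class concentrations (nmol/mL) per metabolic group, mean protein
#' concentrations (nmol/L) per group, and the cohort group sizes. The five
#' groups are hypercholesterolemia (HC), hypertriglyceridemia (HT),
#' hyperlipidemia (HL), hyperglycemia (HG) and a normolipidemic reference
#' (NL). The NL column supplies unit-realistic baseline magnitudes; ratios of
#' the disease columns to NL supply default group effects.
#'
#' @return `lipid_class_reference()`: data.frame with `lipid_class`,
#'   `n_species` and one mean-concentration column per group.
#'   `protein_reference()`: data.frame with `protein` and per-group means.
#'   `cohort_group_sizes()`: named integer vector over the five groups.
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
lipid_class_reference <- function() {
  data.frame(
    lipid_class = c("CE", "CER", "DAG", "FFA", "HCER", "LPC", "LPE", "PC", "PE", "SM", "TAG"),
    n_species   = c(22L, 6L, 17L, 23L, 4L, 9L, 4L, 22L, 20L, 12L, 435L),
    HL = c(6293.02, 11.66, 112.60, 1631.17, 4.59, 1155.03, 6.01, 1935.99, 101.81, 643.17, 3225.76),
    HC = c(6582.15, 11.74, 66.47, 1422.70, 5.04, 1043.70, 4.84, 1943.40, 79.43, 750.77, 1651.70),
    HT = c(4652.47, 14.98, 91.61, 1541.25, 6.58, 834.88, 5.65, 1613.68, 76.98, 516.03, 3121.76),
    HG = c(3628.28, 9.97, 53.65, 1146.13, 4.96, 611.82, 4.74, 1333.21, 69.64, 498.27, 1464.90),
    NL = c(3902.51, 7.55, 43.65, 775.00, 3.93, 637.43, 5.67, 1565.61, 66.83, 473.00, 1272.10),
    stringsAsFactors = FALSE
  )
}

#' @rdname reference_tables
#' @export
protein_reference <- function() {
  data.frame(
    protein = c("apoA1", "AACT", "apoA2", "apoA4", "apoB", "apoC1", "apoC2",
                "apoC3", "apoD", "apoE", "apoM", "CETP", "HP", "LCAT",
                "apo(a)", "PLTP", "PON1", "SAA1", "SAA4", "TF"),
    HL = c(42083.17, 31373.50, 37812.64, 1975.83, 2135.44, 11107.72, 6016.09,
           15971.44, 2159.77, 1849.06, 910.14, 32.15, 22627.85, 104.62,
           66.42, 74.76, 1462.74, 1032.14, 2347.91, 12208.70),
    HC = c(56483.08, 34964.14, 41216.74, 2061.60, 2207.65, 13685.27, 5443.62,
           14438.28, 2370.71, 1912.59, 986.90, 46.06, 26019.40, 111.42,
           100.22, 88.63, 1774.69, 1190.87, 2320.39, 10557.58),
    HT = c(44540.11, 32233.06, 36878.18, 2212.38, 1760.61, 10828.05, 5535.84,
           15485.42, 1995.23, 1784.22, 819.74, 43.04, 30434.21, 106.36,
           54.40, 76.80, 1715.17, 866.73, 2015.95, 11204.71),
    HG = c(37341.74, 46986.16, 27421.17, 2146.20, 1360.11, 7486.51, 3590.02,
           9869.37, 2121.42, 1512.58, 684.93, 24.63, 37418.85, 81.85,
           110.40, 98.94, 1442.07, 1520.89, 2452.47, 8036.81),
    NL = c(43776.14, 27568.85, 39002.86, 1425.91, 1220.63, 8227.14, 2998.99,
           8056.58, 2322.35, 1149.86, 910.80, 33.36, 17136.29, 76.81,
           82.53, 76.33, 1644.84, 472.28, 1713.41, 1230.71),
    stringsAsFactors = FALSE
  )
}

#' @rdname reference_tables
#' @export
cohort_group_sizes <- function() {
  c(HC = 36L, HT = 32L, HL = 28L, HG = 29L, NL = 21L)
}

# Canonical group level order used throughout.
GROUP_LEVELS <- c("HC", "HT", "HL", "HG", "NL")
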