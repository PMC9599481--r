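# Shared fixture builders (all data generated in code).

# Tiny quant table built by hand.
toy_quant <- function(values = NULL) {
  v <- values %||% matrix(c(2, 4, NA, 1, 3, 5), nrow = 3,
                          dimnames = list(c("s1", "s2", "s3"),
                                          c("CE(18:2)", "apoB")))
  # layer inferred from the name: lipid grammar names vs protein symbols
  layer <- ifelse(grepl("^[A-Z]+\\(", colnames(v)), "lipid", "protein")
  meta <- data.frame(feature_id = colnames(v), layer = layer,
                     lipid_class = ifelse(layer == "lipid",
                                          sub("\\(.*$", "", colnames(v)), NA),
                     units = ifelse(layer == "lipid", "nmol/mL", "nmol/L"),
                     stringsAsFactors = FALSE)
  quant_table(v, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small two-group null config (no planted effects, no factors).
null_config <- function(seed = 1L, group_sizes = c(HL = 28, NL = 21),
                        n_species = c(CE = 10, TAG = 15, SM = 5),
                        n_proteins = 5, missing_rate = 0, cv = 0.15) {
  synthetic_config(group_sizes = group_sizes, n_species_per_class = n_species,
                   n_proteins = n_proteins, effect_table = NULL,
                   latent_factors = list(), cv_target = cv,
                   missing_rate = missing_rate, seed = seed)
}

# Cohort with a planted 2x shift on the CE class in HL.
shifted_config <- function(seed = 1L, shift = 2, classes = "CE", group = "HL") {
  synthetic_config(group_sizes = c(HL = 28, NL = 21),
                   n_species_per_class = c(CE = 10, TAG = 15, SM = 5),
                   n_proteins = 5,
                   effect_table = data.frame(target = classes, group = group,
                                             shift = shift),
                   latent_factors = list(), cv_target = 0.15,
                   missing_rate = 0, seed = seed)
}

# Deterministic separable 5-class data for classifier tests: informative
# features shift group means, noise features do not.
separable_matrix <- function(n_per_group = 20, n_inform = 4, n_noise = 12,
                             sep = 2.5, seed = 1) {
  groups <- c("HC", "HT", "HL", "HG", "NL")
  n <- n_per_group * length(groups)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * (n_inform + n_noise)), n)
    centers <- matrix(rnorm(length(groups) * n_inform, sd = sep),
                      length(groups), n_inform)
    for (g in seq_along(groups)) {
      rows <- seq_len(n_per_group) + (g - 1) * n_per_group
      X[rows, seq_len(n_inform)] <- X[rows, seq_len(n_inform)] +
        matrix(centers[g, ], n_per_group, n_inform, byrow = TRUE)
    }
    colnames(X) <- c(sprintf("inf%02d", seq_len(n_inform)),
                     sprintf("noise%02d", seq_len(n_noise)))
    rownames(X) <- sprintf("s%03d", seq_len(n))
    list(X = X, y = factor(rep(groups, each = n_per_group), levels = groups),
         informative = colnames(X)[seq_len(n_inform)])
  })
}
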