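# Synthetic cohort generator.
#
# Concentrations are lognormal around class-typical means (reference-table NL
# magnitudes), scaled by per-group multiplicative effects, with shared latent
# "particle number" factors inducing protein-lipid correlation blocks. The
# model: for feature i in sample s of group g,
#
#   X_is = b_i * shift_{i,g} * mix_is * eps_is
#   mix_is = (1 - sum_f w_if) + sum_f w_if F_fs
#   F_fs ~ group_scale_{f,g} * Lognormal(rel. sd sigma_f),  E[F] = group_scale
#   eps_is ~ Lognormal(rel. sd cv_target),  E[eps] = 1
#
# so cv_target maps to the log-scale sigma via sigma = sqrt(log(1 + CV^2)),
# loadings w are the share of a feature's mean carried by each factor, and the
# planted pair correlation is approximately
#   r_ij = cov_ij / sqrt(v_i v_j),  cov_ij = sum_f w_if w_jf Var(F_f),
#   v_i = sum_f w_if^2 Var(F_f) + cv^2 * (E mix_i)^2 (1 + ...).

#' Define a latent particle-number factor
#'
#' Both protein and lipid concentrations on a lipoprotein particle scale with
#' particle number, so features loading on a shared factor correlate. Loadings
#' are mean shares in `[0, 1]`; names refer to feature ids or to lipid class
#' codes (expanded to all members at generation time).
#'
#' @param name factor label, e.g. `"hdl_particles"`.
#' @param loading named nonnegative numeric vector of mean shares.
#' @param group_scale named positive multipliers of the factor's group mean
#'   (default 1 for every group).
#' @param sigma relative standard deviation of the factor across samples
#'   (default 0.3; with full loading and CV 0.15 this plants r ~ 0.8).
#' @param allow_missing silently ignore loading targets absent from the
#'   generated feature panel (used by the default factors so small custom
#'   panels still generate; user factors default to strict).
#' @return An object of class `lpn_factor`.
#' @export
latent_factor <- function(name, loading, group_scale = NULL, sigma = 0.3,
                          allow_missing = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(loading), !is.null(names(loading)),
            all(loading >= 0), is.numeric(sigma), sigma > 0)
  if (!is.null(group_scale)) stopifnot(all(group_scale > 0), !is.null(names(group_scale)))
  structure(list(name = name, loading = loading,
                 group_scale = group_scale, sigma = sigma,
                 allow_missing = isTRUE(allow_missing)),
            class = "lpn_factor")
}

#' Factor sigma that plants a target pair correlation
#'
#' For two features fully loaded (`w = 1`) on one factor with measurement CV
#' `cv`, the planted population correlation is `sigma^2 / (sigma^2 + cv^2)`
#' (to first order); this solves for sigma.
#' @param r target correlation in (0, 1).
#' @param cv measurement coefficient of variation.
#' @param w common loading share.
#' @export
factor_sigma_for_r <- function(r, cv, w = 1) {
  stopifnot(r > 0, r < 1, cv >= 0, w > 0, w <= 1)
  cv * sqrt(r / (1 - r)) / w
}

#' Default latent particle-number factors
#'
#' Two factors emulate the joint protein-lipid concentration structure of
#' lipoprotein pools: an apoB-particle factor (VLDL/LDL core lipids with apoB
#' and the exchangeable apoCs/apoE) and an HDL-particle factor (surface and
#' CE lipids with apoA1/apoA2/apoM/LCAT). Loadings are moderate mean shares;
#' with the default 15% measurement CV they plant protein-lipid correlations
#' of roughly 0.5-0.7 within the loaded blocks.
#' @export
default_latent_factors <- function() {
  list(
    latent_factor("apob_particles", allow_missing = TRUE,
                  c(TAG = 0.6, DAG = 0.5, CER = 0.4,
                    apoB = 0.5, apoC2 = 0.5, apoC3 = 0.5, apoE = 0.4),
                  sigma = 0.35),
    latent_factor("hdl_particles", allow_missing = TRUE,
                  c(CE = 0.5, SM = 0.5, LPC = 0.4, PC = 0.4,
                    apoA1 = 0.6, apoA2 = 0.5, apoM = 0.4, LCAT = 0.35),
                  sigma = 0.35))
}

#' Default group effect table from the study reference tables
#'
#' One multiplicative shift per (lipid class or protein, group): the ratio of
#' the group's printed mean concentration to the normolipidemic mean.
#' @return data.frame(target, group, shift); `target` is a lipid class code
#'   (applying to every species of the class) or a protein feature id.
#' @export
default_effect_table <- function() {
  lc <- lipid_class_reference(); pr <- protein_reference()
  grps <- setdiff(GROUP_LEVELS, "NL")
  rbind(
    do.call(rbind, lapply(grps, function(g)
      data.frame(target = lc$lipid_class, group = g,
                 shift = lc[[g]] / lc$NL, stringsAsFactors = FALSE))),
    do.call(rbind, lapply(grps, function(g)
      data.frame(target = pr$protein, group = g,
                 shift = pr[[g]] / pr$NL, stringsAsFactors = FALSE)))
  )
}

#' Configure a synthetic cohort
#'
#' Defaults reproduce the study's stated conditions: group sizes 36/32/28/29/21
#' (HC/HT/HL/HG/NL), the per-class quantifiable species census (574 species,
#' 11 classes), 20 proteins with reference-table baseline means, group shifts
#' equal to the printed class/protein mean ratios versus NL, 15% measurement
#' CV and 5% sporadic missingness.
#'
#' @param group_sizes named integer vector of samples per group (all >= 2).
#' @param n_species_per_class named integer vector, lipid class -> species
#'   count.
#' @param n_proteins number of protein features (first `n` reference proteins).
#' @param effect_table data.frame(target, group, shift) of multiplicative mean
#'   shifts (all > 0), or NULL for no planted effects.
#' @param latent_factors list of [latent_factor()] objects.
#' @param cv_target measurement CV, in (0, 1).
#' @param missing_rate MCAR cell blanking probability, in \[0, 0.3).
#' @param seed integer seed fixing the whole cohort.
#' @param reference reference group label.
#' @return An object of class `lpn_config`.
#' @export
synthetic_config <- function(group_sizes = cohort_group_sizes(),
                             n_species_per_class = NULL,
                             n_proteins = 20L,
                             effect_table = default_effect_table(),
                             latent_factors = default_latent_factors(),
                             cv_target = 0.15,
                             missing_rate = 0.05,
                             seed = 1L,
                             reference = "NL") {
  if (is.null(n_species_per_class)) {
    lc <- lipid_class_reference()
    n_species_per_class <- stats::setNames(lc$n_species, lc$lipid_class)
  }
  stopifnot(!is.null(names(group_sizes)), all(group_sizes >= 2L),
            !is.null(names(n_species_per_class)), all(n_species_per_class >= 0L),
            n_proteins >= 0L, length(seed) == 1L)
  if (!all(names(n_species_per_class) %in% LIPID_CLASSES))
    stop("unknown lipid class in n_species_per_class")
  if (!(cv_target > 0 && cv_target < 1) && cv_target != 0)
    stop("cv_target must be 0 or in (0,1)")
  if (!(missing_rate >= 0 && missing_rate < 0.3))
    stop("missing_rate must be in [0, 0.3)")
  if (!reference %in% names(group_sizes)) stop("reference group absent from group_sizes")
  if (!is.null(effect_table)) {
    stopifnot(all(c("target", "group", "shift") %in% names(effect_table)))
    if (any(effect_table$shift <= 0)) stop("all effect shifts must be > 0")
  }
  for (f in latent_factors) if (!inherits(f, "lpn_factor"))
    stop("latent_factors must be a list of latent_factor() objects")
  structure(list(group_sizes = group_sizes,
                 n_species_per_class = n_species_per_class,
                 n_proteins = as.integer(n_proteins),
                 effect_table = effect_table,
                 latent_factors = latent_factors,
                 cv_target = cv_target, missing_rate = missing_rate,
                 seed = as.integer(seed), reference = reference),
            class = "lpn_config")
}

# ---- feature panel ----------------------------------------------------------

# Deterministic species-name grids per class; sampled without replacement.
species_name_grid <- function(class) {
  single <- function(cl) {
    g <- expand.grid(c = 12:26, d = 0:6)
    g <- g[g$d <= pmax(1, (g$c - 12) %/% 2), ]
    sprintf("%s(%d:%d)", cl, g$c, g$d)
  }
  two_chain <- function(cl, ether = FALSE) {
    g <- expand.grid(c1 = seq(14, 22, 2), d1 = 0:4, c2 = seq(14, 22, 2), d2 = 0:6)
    g <- g[g$c1 <= g$c2, ]
    pre <- if (ether) "P-" else ""
    sprintf("%s(%s%d:%d/%d:%d)", cl, pre, g$c1, g$d1, g$c2, g$d2)
  }
  switch(class,
    PC = two_chain("PC"),
    PE = c(two_chain("PE"), two_chain("PE", ether = TRUE)),
    DAG = two_chain("DAG"),
    TAG = {
      g <- expand.grid(C = 40:60, D = 0:12, c = seq(12, 22, 2), d = 0:6)
      g <- g[g$d <= g$D & g$c <= g$C - 24, ]
      sprintf("TAG(%d:%d-FA%d:%d)", g$C, g$D, g$c, g$d)
    },
    single(class))
}

# Shared feature panel (names, baselines, metadata); deterministic in config.
build_feature_panel <- function(config) {
  lc <- lipid_class_reference()
  with_seed(sub_seed(config$seed, "panel"), {
    feats <- list()
    for (cl in names(config$n_species_per_class)) {
      n <- config$n_species_per_class[[cl]]
      if (n == 0L) next
      grid <- species_name_grid(cl)
      if (n > length(grid)) stop("class ", cl, " grid supports at most ", length(grid), " species")
      # even-carbon fatty acyls dominate serum; odd-chain species stay rare
      odd <- parse_lipid_name(grid)$total_carbons %% 2L == 1L
      nm <- sort(sample(grid, n, prob = ifelse(odd, 0.1, 1)))
      cm <- if (cl %in% lc$lipid_class) lc$NL[lc$lipid_class == cl] else 4.0
      w <- stats::rlnorm(n, 0, 1); w <- w / sum(w)
      feats[[cl]] <- data.frame(feature_id = nm, layer = "lipid", lipid_class = cl,
                                units = "nmol/mL", baseline = cm * w,
                                stringsAsFactors = FALSE)
    }
    pr <- protein_reference()
    if (config$n_proteins > 0L) {
      if (config$n_proteins <= nrow(pr)) {
        pnm <- pr$protein[seq_len(config$n_proteins)]
        pb <- pr$NL[seq_len(config$n_proteins)]
      } else {
        extra <- config$n_proteins - nrow(pr)
        pnm <- c(pr$protein, sprintf("prot%02d", seq_len(extra) + nrow(pr)))
        pb <- c(pr$NL, stats::rlnorm(extra, log(stats::median(pr$NL)), 0.5))
      }
      feats[["__protein__"]] <- data.frame(feature_id = pnm, layer = "protein",
                                           lipid_class = NA_character_,
                                           units = "nmol/L", baseline = pb,
                                           stringsAsFactors = FALSE)
    }
    do.call(rbind, c(feats, list(make.row.names = FALSE)))
  })
}

#' Feature ids a configuration will generate
#'
#' Useful for building latent factors or effect tables that reference specific
#' synthetic features before generating the cohort.
#' @param config a [synthetic_config()].
#' @export
synthetic_feature_names <- function(config) build_feature_panel(config)$feature_id

# Expand factor loadings (feature ids and/or class codes) to per-feature shares.
resolve_loadings <- function(factors, panel) {
  p <- nrow(panel)
  W <- matrix(0, p, length(factors),
              dimnames = list(panel$feature_id, vapply(factors, `[[`, "", "name")))
  for (j in seq_along(factors)) {
    ld <- factors[[j]]$loading
    lax <- isTRUE(factors[[j]]$allow_missing)
    for (k in seq_along(ld)) {
      nm <- names(ld)[k]
      if (nm %in% panel$feature_id) W[nm, j] <- W[nm, j] + ld[k]
      else if (nm %in% panel$lipid_class)
        W[panel$lipid_class %in% nm, j] <- W[panel$lipid_class %in% nm, j] + ld[k]
      else if (!lax)
        stop("factor '", factors[[j]]$name, "' loads on unknown target '", nm, "'")
    }
    has_lip <- any(W[panel$layer == "lipid", j] > 0)
    has_pro <- any(W[panel$layer == "protein", j] > 0)
    if (!has_lip || !has_pro) {
      if (lax) W[, j] <- 0   # inert factor on this panel
      else stop("factor '", factors[[j]]$name,
                "' must load on at least one lipid and one protein feature")
    }
  }
  if (any(rowSums(W) > 1 + 1e-12))
    stop("total latent-factor loading exceeds 1 for feature ",
         panel$feature_id[which(rowSums(W) > 1 + 1e-12)[1]])
  W
}

# Per-feature x group shift matrix from an effect table.
resolve_shifts <- function(effect_table, panel, groups) {
  S <- matrix(1, nrow(panel), length(groups),
              dimnames = list(panel$feature_id, groups))
  if (is.null(effect_table)) return(S)
  for (i in seq_len(nrow(effect_table))) {
    tgt <- effect_table$target[i]; g <- effect_table$group[i]
    if (!g %in% groups) next
    if (tgt %in% panel$feature_id) S[tgt, g] <- effect_table$shift[i]
    else if (tgt %in% panel$lipid_class)
      S[panel$lipid_class %in% tgt, g] <- effect_table$shift[i]
    else stop("effect target '", tgt, "' matches no feature or lipid class")
  }
  S
}

group_scale_of <- function(fac, group) {
  if (is.null(fac$group_scale)) 1 else (fac$group_scale[[group]] %||% 1)
}

# ---- generation -------------------------------------------------------------

#' Generate a synthetic cohort with ground truth
#'
#' @param config a [synthetic_config()].
#' @return list with `table` ([quant_table()]), `design` ([group_design()]),
#'   and `truth`: ground-truth lists of planted differential features (per
#'   group, up/down), planted strongly correlated protein-lipid pairs (per
#'   group, predicted `|r| >= 0.5`), and informative predictors. Deterministic
#'   under `config$seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "lpn_config"))
  panel <- build_feature_panel(config)
  groups <- names(config$group_sizes)
  W <- resolve_loadings(config$latent_factors, panel)
  S <- resolve_shifts(config$effect_table, panel, groups)
  sigmas <- vapply(config$latent_factors, `[[`, 0, "sigma")
  se <- sqrt(log(1 + config$cv_target^2))

  sample_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", g, seq_len(config$group_sizes[[g]]))))
  grp_of <- rep(groups, times = config$group_sizes)
  n <- length(sample_ids); p <- nrow(panel)

  vals <- with_seed(sub_seed(config$seed, "cohort"), {
    # factor draws per sample
    Fs <- matrix(1, n, max(1L, length(config$latent_factors)))
    for (j in seq_along(config$latent_factors)) {
      sl <- sqrt(log(1 + sigmas[j]^2))
      gs <- vapply(grp_of, function(g) group_scale_of(config$latent_factors[[j]], g), 0)
      Fs[, j] <- gs * stats::rlnorm(n, -sl^2 / 2, sl)
    }
    mix <- matrix(1 - rowSums(W), n, p, byrow = TRUE)
    if (length(config$latent_factors))
      mix <- mix + Fs[, seq_along(config$latent_factors), drop = FALSE] %*%
        t(W[, seq_along(config$latent_factors), drop = FALSE])
    mean_mat <- mix * t(S[, grp_of, drop = FALSE] * panel$baseline)
    eps <- matrix(stats::rlnorm(n * p, -se^2 / 2, se), n, p)
    v <- mean_mat * eps
    dimnames(v) <- list(sample_ids, panel$feature_id)
    v
  })

  table <- quant_table(vals, panel[, c("feature_id", "layer", "lipid_class", "units")])
  if (config$missing_rate > 0)
    table <- inject_missingness(table, config$missing_rate,
                                sub_seed(config$seed, "missing"))
  design <- group_design(sample_ids, grp_of, reference = config$reference)
  truth <- synthetic_truth(config, panel, W, S, sigmas)
  list(table = table, design = design, truth = truth)
}

# Expected mix mean per feature x group: (1 - sum w) + sum w * group_scale.
expected_mix <- function(config, W, groups) {
  M <- matrix(1 - rowSums(W), nrow(W), length(groups),
              dimnames = list(rownames(W), groups))
  for (j in seq_along(config$latent_factors)) {
    gs <- vapply(groups, function(g) group_scale_of(config$latent_factors[[j]], g), 0)
    M <- M + outer(W[, j], gs)
  }
  M
}

synthetic_truth <- function(config, panel, W, S, sigmas, r_threshold = 0.5) {
  groups <- names(config$group_sizes); ref <- config$reference
  EM <- expected_mix(config, W, groups)
  ratio <- (S / S[, ref]) * (EM / EM[, ref])   # effective mean ratio vs reference
  diff <- lapply(setdiff(groups, ref), function(g) {
    list(up = panel$feature_id[ratio[, g] > 1 + 1e-9],
         down = panel$feature_id[ratio[, g] < 1 - 1e-9])
  })
  names(diff) <- setdiff(groups, ref)

  cor_pairs <- lapply(groups, function(g) {
    if (!length(config$latent_factors)) return(
      data.frame(protein = character(), lipid = character(), r_pred = numeric()))
    gs2 <- vapply(seq_along(config$latent_factors), function(j)
      (group_scale_of(config$latent_factors[[j]], g) * sigmas[j])^2, 0)
    Vf <- sweep(W^2, 2, gs2, `*`)            # per-feature factor variance terms
    rel_var <- rowSums(Vf) / EM[, g]^2
    tot_var <- rel_var + config$cv_target^2 * (1 + rel_var)
    prot <- panel$feature_id[panel$layer == "protein"]
    lip <- panel$feature_id[panel$layer == "lipid"]
    Wg <- sweep(W, 2, sqrt(gs2), `*`)
    Cov <- Wg[prot, , drop = FALSE] %*% t(Wg[lip, , drop = FALSE]) /
      outer(EM[prot, g], EM[lip, g])
    R <- Cov / outer(sqrt(tot_var[prot]), sqrt(tot_var[lip]))
    idx <- which(abs(R) >= r_threshold, arr.ind = TRUE)
    data.frame(protein = prot[idx[, 1]], lipid = lip[idx[, 2]],
               r_pred = R[idx], stringsAsFactors = FALSE)
  })
  names(cor_pairs) <- groups

  informative <- unique(unlist(lapply(diff, function(d) c(d$up, d$down))))
  structure(list(differential_features = diff, correlated_pairs = cor_pairs,
                 informative_predictors = informative,
                 r_threshold = r_threshold),
            class = "lpn_truth")
}

#' Generate technical QC replicates of the feature panel
#'
#' Replicate injections of one pooled sample: baseline means plus pure
#' measurement noise at `cv_target`, no group effects or latent factors.
#' Feature panel and baselines match [generate_cohort()] under the same
#' config.
#' @param config a [synthetic_config()].
#' @param n_reps number of replicates (>= 3).
#' @export
generate_qc_replicates <- function(config, n_reps = 10L) {
  stopifnot(inherits(config, "lpn_config"))
  if (n_reps < 3L) stop("n_reps must be >= 3 to estimate a CV")
  panel <- build_feature_panel(config)
  se <- sqrt(log(1 + config$cv_target^2))
  vals <- with_seed(sub_seed(config$seed, "qc"), {
    eps <- matrix(stats::rlnorm(n_reps * nrow(panel), -se^2 / 2, se), n_reps)
    v <- eps * matrix(panel$baseline, n_reps, nrow(panel), byrow = TRUE)
    dimnames(v) <- list(sprintf("QC_%02d", seq_len(n_reps)), panel$feature_id)
    v
  })
  quant_table(vals, panel[, c("feature_id", "layer", "lipid_class", "units")])
}

#' Blank cells of a table completely at random
#'
#' Each cell is independently set to missing with probability `rate` (MCAR).
#' @param table a `lpn_quant`.
#' @param rate blanking probability in \[0, 1).
#' @param seed integer seed.
#' @export
inject_missingness <- function(table, rate, seed = 1L) {
  stopifnot(inherits(table, "lpn_quant"), is_fraction(rate), rate < 1)
  if (rate == 0) return(table)
  v <- table$values
  mask <- with_seed(seed, matrix(stats::runif(length(v)) < rate, nrow(v)))
  v[mask] <- NA_real_
  quant_table(v, table$feature_meta)
}
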