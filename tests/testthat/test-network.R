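make_corr_table <- function(n = 20, seed = 1) {
  withr::with_seed(seed, {
    prot <- matrix(rlnorm(n * 3), n, dimnames = list(NULL, c("apoB", "apoA1", "apoE")))
    lip <- matrix(rlnorm(n * 4), n,
                  dimnames = list(NULL, c("CE(18:2)", "TAG(52:2-FA16:0)",
                                          "SM(16:0)", "PC(16:0/18:1)")))
    lip[, 1] <- 2 * prot[, 1]  # exact linear dependence
    v <- cbind(lip, prot)
    rownames(v) <- sprintf("s%02d", seq_len(n))
    toy_quant(v)
  })
}

test_that("pairwise correlations: exact dependence, t-tail p, brute-force oracle", {
  tab <- make_corr_table()
  d <- group_design(rownames(tab$values), rep(c("HL", "NL"), each = 10))
  e <- pairwise_correlations(tab, d, "HL")
  expect_identical(nrow(e), 12L)  # 3 proteins x 4 lipids
  perfect <- e[e$protein == "apoB" & e$lipid == "CE(18:2)", ]
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  expect_lt(perfect$p, 1e-12)
  # documented pairing of thresholds: n = 36, r = 0.5 -> p just under 0.002
  expect_equal(correlation_pvalue(0.5, 36), 0.00187, tolerance = 0.002)
  expect_lt(correlation_pvalue(0.5, 36), 0.002)
  # brute-force deviation-product oracle
  hl <- group_samples(d, "HL")
  for (i in seq_len(nrow(e))) {
    x <- tab$values[hl, e$protein[i]]; y <- tab$values[hl, e$lipid[i]]
    r_brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(e$r[i], r_brute, tolerance = 1e-12)
    expect_equal(e$p[i], stats::cor.test(x, y)$p.value, tolerance = 1e-9)
  }
  expect_error(pairwise_correlations(tab, group_design(
    rownames(tab$values), rep(c("HL", "NL"), c(4, 16))), "HL"), "fewer than 5")
})

test_that("zero-variance features are excluded with a warning", {
  tab <- make_corr_table()
  tab$values[, "SM(16:0)"] <- 1
  d <- group_design(rownames(tab$values), rep(c("HL", "NL"), each = 10))
  expect_warning(e <- pairwise_correlations(tab, d, "HL"), "SM\\(16:0\\)")
  expect_false("SM(16:0)" %in% e$lipid)
})

test_that("dual filter applies strict thresholds and the endpoint rule", {
  edges <- data.frame(protein = "apoB",
                      lipid = c("CE(18:2)", "SM(16:0)", "PC(16:0/18:1)"),
                      group = "HL",
                      r = c(0.5, 0.8, 0.8), p = c(1e-5, 1e-5, 1e-5),
                      q = 1e-4, n = 30, stringsAsFactors = FALSE)
  diff <- data.frame(feature_id = c("CE(18:2)", "SM(16:0)", "PC(16:0/18:1)", "apoB"),
                     layer = c("lipid", "lipid", "lipid", "protein"), group = "HL",
                     log2_fc = 1, p = c(0.01, 0.01, 0.8, 0.8), q = 0.05,
                     direction = "up", stringsAsFactors = FALSE)
  net <- dual_filter(edges, diff)
  # |r| = 0.5 exactly is excluded (strict); non-dysregulated pair excluded
  expect_identical(net$edges$lipid, "SM(16:0)")
  # endpoint_rule = "both" additionally requires the protein
  expect_identical(nrow(dual_filter(edges, diff, endpoint_rule = "both")$edges), 0L)
  # protein-only dysregulation rescues edges under "either"
  diff2 <- diff; diff2$p[diff2$feature_id == "apoB"] <- 0.001
  expect_identical(nrow(dual_filter(edges, diff2, endpoint_rule = "either")$edges), 3L - 1L)
  expect_identical(nrow(dual_filter(edges, diff2, endpoint_rule = "lipid")$edges), 1L)
})

test_that("relaxing thresholds never removes edges (monotonicity)", {
  co <- generate_cohort(synthetic_config(
    group_sizes = c(HL = 20, NL = 10), n_species_per_class = c(CE = 8, TAG = 8),
    n_proteins = 4, effect_table = NULL, missing_rate = 0,
    latent_factors = list(latent_factor("f", c(TAG = 0.8, apoA1 = 0.8),
                                        group_scale = c(HL = 1.5, NL = 1))),
    seed = 3))
  diff <- differential_analysis(co$table, co$design)
  e <- pairwise_correlations(co$table, co$design, "HL")
  strict <- dual_filter(e, diff)
  loose <- dual_filter(e, diff, r_min = 0.3, p_corr_max = 0.05, p_diff_max = 0.2)
  key <- function(n) paste(n$edges$protein, n$edges$lipid)
  expect_true(all(key(strict) %in% key(loose)))
  expect_true(all(key(strict) %in% paste(e$protein, e$lipid)))
})

test_that("hub table ranks by lipid degree with alphabetical ties", {
  edges <- data.frame(protein = c(rep("apoE", 5), "apoB", "apoA1"),
                      lipid = c(sprintf("TAG(5%d:2-FA16:0)", 0:4),
                                "TAG(50:2-FA16:0)", "TAG(50:2-FA16:0)"),
                      group = "HL", r = 0.9, p = 1e-6, q = 1e-5, n = 30,
                      stringsAsFactors = FALSE)
  diff <- data.frame(feature_id = unique(c(edges$lipid, edges$protein)),
                     layer = "lipid", group = "HL", log2_fc = 1, p = 0.001,
                     q = 0.01, direction = "up", stringsAsFactors = FALSE)
  net <- dual_filter(edges, diff)
  hubs <- hub_table(net)
  expect_identical(hubs$protein, c("apoE", "apoA1", "apoB"))
  expect_identical(hubs$degree, c(5L, 1L, 1L))
  expect_identical(sum(hubs$degree), nrow(net$edges))  # bipartite handshake
  # empty network -> empty table
  empty <- dual_filter(edges[0, ], diff)
  expect_identical(nrow(hub_table(empty)), 0L)
})

test_that("export round-trips and types negative edges distinctly", {
  edges <- data.frame(protein = c("apoB", "apo(a)"),
                      lipid = c("TAG(52:2-FA16:0)", "CER(22:0)"), group = "HL",
                      r = c(0.8, -0.7), p = c(1e-5, 1e-4), q = c(1e-4, 1e-3),
                      n = 28, stringsAsFactors = FALSE)
  diff <- data.frame(feature_id = unique(c(edges$lipid, edges$protein)),
                     layer = "lipid", group = "HL", log2_fc = 1, p = 0.001,
                     q = 0.01, direction = "up", stringsAsFactors = FALSE)
  net <- dual_filter(edges, diff)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 2L)
  expect_true(any(grepl("corr_neg\tCER(22:0)", lines, fixed = TRUE)))
  # graphml round trip preserves edges and attributes
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml, "graphml")
  back <- back[order(back$protein), ]
  orig <- net$edges[order(net$edges$protein), ]
  expect_setequal(paste(back$protein, back$lipid), paste(orig$protein, orig$lipid))
  expect_equal(sort(back$r), sort(orig$r), tolerance = 1e-9)
  # empty network -> empty SIF body
  empty <- dual_filter(edges[0, ], diff)
  export_network(empty, sif, "sif")
  expect_identical(readLines(sif), character(0))
  expect_error(export_network(net, sif, "xml"), "should be one of")
})

test_that("hypergeometric ORA matches exact enumeration", {
  sets <- list(setA = sprintf("p%02d", 1:4), setB = sprintf("p%02d", 11:14))
  universe <- sprintf("p%02d", 1:20)
  query <- sprintf("p%02d", c(1:3, 15, 16))
  res <- ora_enrichment(query, sets, universe)
  pa <- res$p[res$set == "setA"]
  expect_equal(pa, 0.0320, tolerance = 5e-4)
  # independent oracle: direct enumeration of the hypergeometric mass
  enum_p <- function(N, K, k, ov) {
    sum(vapply(ov:min(K, k), function(x)
      choose(K, x) * choose(N - K, k - x), 0)) / choose(N, k)
  }
  expect_equal(pa, enum_p(20, 4, 5, 3), tolerance = 1e-12)
  # zero overlap -> p = 1
  expect_equal(res$p[res$set == "setB"], 1)
  # degenerate: query = set = universe
  res2 <- ora_enrichment(universe, list(all = universe), universe)
  expect_equal(res2$p, 1)
  expect_error(ora_enrichment(character(0), sets, universe), "query")
  expect_error(ora_enrichment(c(query, "zzz"), sets, universe), "subset")
  # randomized property check against enumeration, universes <= 30
  withr::with_seed(13, {
    for (i in 1:30) {
      N <- sample(5:30, 1); uni <- sprintf("u%02d", seq_len(N))
      K <- sample(N, 1); k <- sample(N, 1)
      st <- list(s = sample(uni, K))
      q <- sample(uni, k)
      mine <- ora_enrichment(q, st, uni)$p
      ov <- length(intersect(q, st$s))
      expect_equal(mine, enum_p(N, K, k, ov), tolerance = 1e-10)
    }
  })
})

test_that("GMT files round-trip", {
  sets <- list(pathA = c("apoB", "apoE"), pathB = c("apoA1", "apoA2", "LCAT"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, description = c("descA", "descB"))
  back <- read_gmt(path)
  expect_identical(back[["pathA"]], sets$pathA)
  expect_identical(back[["pathB"]], sets$pathB)
  expect_identical(attr(back, "description"), c("descA", "descB"))
})
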