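two_group_design <- function(n1, n2, g1 = "HL") {
  group_design(sprintf("s%02d", seq_len(n1 + n2)),
               rep(c(g1, "NL"), c(n1, n2)))
}

test_that("exact rank-sum enumeration matches hand values and wilcox.test", {
  d <- two_group_design(3, 3)
  p <- wilcoxon_vs_reference(
    stats::setNames(c(1, 2, 3, 4, 5, 6), d$sample_id), d, "HL")
  expect_equal(as.numeric(p), 0.10, tolerance = 1e-12)
  expect_true(attr(p, "exact"))
  # group identical to reference -> degenerate p = 1
  p1 <- wilcoxon_vs_reference(stats::setNames(rep(2, 6), d$sample_id), d, "HL")
  expect_equal(as.numeric(p1), 1)
  expect_true(attr(p1, "degenerate"))
  # oracle: wilcox.test exact branch on random untied draws
  withr::with_seed(42, {
    for (i in 1:50) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      x <- sample(100, n1 + n2)  # untied
      d2 <- two_group_design(n1, n2)
      mine <- wilcoxon_vs_reference(stats::setNames(x, d2$sample_id), d2, "HL")
      ref <- stats::wilcox.test(x[seq_len(n1)], x[-seq_len(n1)], exact = TRUE)$p.value
      expect_equal(as.numeric(mine), ref, tolerance = 1e-12)
    }
  })
})

test_that("exact and normal-approximation branches agree on moderate n", {
  withr::with_seed(7, {
    for (i in 1:20) {
      x <- rnorm(5); y <- rnorm(5)
      pe <- liponet:::ranksum_test(x, y, exact = TRUE)$p
      pa <- liponet:::ranksum_test(x, y, exact = FALSE)$p
      expect_lt(abs(pe - pa), 0.02)
    }
  })
})

test_that("Kruskal-Wallis and ANOVA match their base-R oracles", {
  withr::with_seed(11, {
    g <- factor(rep(paste0("G", 1:4), each = 8))
    d <- group_design(sprintf("s%02d", 1:32), as.character(g), reference = "G1")
    for (i in 1:20) {
      x <- stats::setNames(round(rnorm(32), 1), d$sample_id)  # some ties
      expect_equal(as.numeric(kruskal_wallis(x, d)),
                   stats::kruskal.test(x, g)$p.value, tolerance = 1e-10)
      expect_equal(as.numeric(anova_oneway(x, d)),
                   stats::oneway.test(x ~ g, var.equal = TRUE)$p.value,
                   tolerance = 1e-10)
    }
  })
  # strongly shifted group
  d5 <- two_group_design(10, 10)
  x <- stats::setNames(c(rnorm(10), rnorm(10) + 50), d5$sample_id)
  expect_lt(as.numeric(anova_oneway(x, d5)), 1e-6)
  # zero within-group variance everywhere -> flagged NA
  xc <- stats::setNames(rep(c(1, 2), each = 10), d5$sample_id)
  expect_true(is.na(anova_oneway(xc, d5)))
})

test_that("two-group KW equals the squared rank-sum z (algebraic identity)", {
  withr::with_seed(3, {
    for (i in 1:10) {
      n1 <- 8; n2 <- 6
      x <- round(rnorm(n1), 1); y <- round(rnorm(n2), 1)
      d <- two_group_design(n1, n2)
      v <- stats::setNames(c(x, y), d$sample_id)
      rt <- liponet:::ranksum_test(x, y, exact = FALSE)
      N <- n1 + n2
      r <- rank(c(x, y)); tab <- table(r)
      sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(tab^3 - tab) / (N * (N - 1))))
      z2 <- ((rt$statistic - n1 * n2 / 2) / sigma)^2
      kw_p <- as.numeric(kruskal_wallis(v, d))
      expect_equal(stats::pchisq(z2, 1, lower.tail = FALSE), kw_p, tolerance = 1e-10)
    }
  })
})

test_that("bh_fdr implements the step-up exactly", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, NaN)), "NA")
  # brute-force step-up definition: q_(i) = min_{j>=i} m p_(j)/j, capped at 1
  brute <- function(p) {
    m <- length(p); o <- order(p); q <- numeric(m)
    for (i in seq_len(m)) q[o[i]] <- min(1, min(m * sort(p)[i:m] / (i:m)))
    q
  }
  withr::with_seed(9, {
    for (i in 1:25) {
      p <- runif(sample(1:40, 1))
      q <- bh_fdr(p)
      expect_equal(q, brute(p), tolerance = 1e-12)
      expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-12))            # q >= p pointwise
      expect_true(all(diff(q[order(p)]) >= -1e-12))  # order-preserving
    }
  })
})

test_that("fold change is the log2 ratio of arithmetic means", {
  d <- two_group_design(3, 3)
  v <- stats::setNames(c(4, 4, 4, 2, 2, 2), d$sample_id)
  expect_equal(as.numeric(fold_change(v, d, "HL")), 1)
  expect_equal(as.numeric(fold_change(stats::setNames(rep(5, 6), d$sample_id), d, "HL")), 0)
  v0 <- stats::setNames(c(1, 2, 3, 0, 0, 0), d$sample_id)
  expect_true(is.na(fold_change(v0, d, "HL")))
})

test_that("volcano flags p <= 0.05 and keeps every row", {
  diff <- data.frame(feature_id = c("a", "b", "c"), group = "HL",
                     log2_fc = c(1, -1, 0), p = c(0.05, 0.051, 0.2),
                     q = c(0.1, 0.1, 0.2), direction = c("up", "ns", "ns"))
  vt <- volcano_table(diff)
  expect_equal(vt$significant, c(TRUE, FALSE, FALSE))
  expect_identical(nrow(vt), nrow(diff))
})

test_that("venn cells partition the significant features", {
  co <- generate_cohort(synthetic_config(
    group_sizes = c(HC = 12, HT = 12, HL = 12, HG = 12, NL = 12),
    n_species_per_class = c(CE = 6, TAG = 6), n_proteins = 2,
    effect_table = rbind(
      data.frame(target = "CE", group = c("HC", "HT", "HL", "HG"), shift = 3),
      data.frame(target = "TAG", group = "HL", shift = 3)),
    missing_rate = 0, seed = 17))
  diff <- differential_analysis(co$table, co$design)
  vs <- venn_sets(diff[diff$layer == "lipid", ], "up")
  all_feats <- unlist(vs$sets)
  expect_false(any(duplicated(all_feats)))  # disjoint partition
  expect_identical(sum(vs$counts), length(all_feats))
  # planted all-group shifts land in the 4-way cell
  four_way <- vs$sets[[which(vapply(strsplit(names(vs$sets), "+", fixed = TRUE),
                                    length, 0L) == 4)]]
  ce <- co$table$feature_meta$feature_id[co$table$feature_meta$lipid_class %in% "CE"]
  expect_gte(mean(ce %in% four_way), 0.8)
})

test_that("group-mean z-scores are centered and sign-faithful", {
  co <- generate_cohort(shifted_config(seed = 23))
  z <- group_mean_zscores(co$table, co$design)
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  ce <- co$table$feature_meta$feature_id[co$table$feature_meta$lipid_class %in% "CE"]
  expect_true(all(z[ce, "HL"] > 0))  # planted up-shift
  # constant feature -> all-zero row, flagged
  v <- cbind("apoB" = rep(3, 6), "apoE" = c(1, 1, 2, 2, 3, 3))
  rownames(v) <- sprintf("s%02d", 1:6)
  d <- two_group_design(3, 3)
  z2 <- group_mean_zscores(v, d)
  expect_true(all(z2["apoB", ] == 0))
  expect_identical(attr(z2, "flat_features"), "apoB")
})

test_that("hierarchical clustering merges nearest rows first", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  colnames(m) <- c("x", "y")
  hc <- hierarchical_cluster(m)
  expect_equal(sort(hc$row_hclust$merge[1, ]), c(-2, -1))  # identical rows first
  # 3-point collinear toy: nearest pair (0 and 1) merges before 5
  m2 <- cbind(v = c(p1 = 0, p2 = 1, p3 = 5), w = 0)
  hc2 <- hierarchical_cluster(m2)
  expect_equal(sort(hc2$row_hclust$merge[1, ]), c(-2, -1))
  # permutation invariance up to relabeling
  perm <- c(3, 1, 2)
  hc3 <- hierarchical_cluster(m2[perm, ])
  expect_identical(hc3$row_order, hc2$row_order)
})

test_that("differential_analysis respects q >= p and direction semantics", {
  co <- generate_cohort(shifted_config(seed = 29))
  diff <- differential_analysis(co$table, co$design)
  expect_true(all(diff$q >= diff$p - 1e-12))
  expect_true(all(diff$direction[diff$p > 0.05] == "ns"))
  expect_true(all(diff$direction[diff$p <= 0.05 & diff$log2_fc > 0] == "up"))
  ce <- co$table$feature_meta$feature_id[co$table$feature_meta$lipid_class %in% "CE"]
  expect_true(all(diff$direction[diff$feature_id %in% ce] == "up"))
})

test_that("class comparison reproduces the summary-table layout", {
  co <- generate_cohort(null_config(seed = 77))
  cc <- class_comparison(co$table, co$design)
  expect_setequal(unique(cc$kind), c("lipid_class", "protein"))
  expect_true(all(c("HL", "NL", "p_anova", "p_adj") %in% names(cc)))
  expect_true(all(cc$p_adj >= cc$p_anova - 1e-12))
})
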