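test_that("the default panel is the published 11-gene set and scores are means", {
  pan <- apl_stemness_panel()
  expect_identical(pan$gene_list,
                   c("SKAP2", "IL1RAP", "PLD1", "HOPX", "TRIM47", "MAP2K1",
                     "TNFSF4", "OLFML2A", "P2RY14", "NPTX2", "RALA"))
  # two-gene panel: log2(TPM+1) values 2 and 4 -> score 3
  B <- matrix(c(2^2 - 1, 2^4 - 1), nrow = 2,
              dimnames = list(c("SKAP2", "RALA"), "s1"))
  sc <- stemness_score(B, c("SKAP2", "RALA"))
  expect_equal(sc$score, 3)
  # all panel genes at TPM 0 -> score 0
  Z <- matrix(0, nrow = 11, ncol = 1, dimnames = list(pan$gene_list, "s1"))
  expect_equal(stemness_score(Z)$score, 0)
})

test_that("stemness score ignores gene order and non-panel genes, is monotone", {
  pan <- c("SKAP2", "RALA", "HOPX")
  set.seed(201)
  B <- matrix(rexp(8 * 3, 0.1), nrow = 8,
              dimnames = list(c(pan, sprintf("X%d", 1:5)), c("a", "b", "c")))
  s1 <- stemness_score(B, pan)
  s2 <- stemness_score(B[sample(nrow(B)), ], pan)
  expect_equal(s1$score, s2$score)
  s3 <- stemness_score(B[pan, ], pan)
  expect_equal(s1$score, s3$score)
  B2 <- B; B2["SKAP2", "a"] <- B2["SKAP2", "a"] + 10
  expect_gt(stemness_score(B2, pan)$score[1], s1$score[1])
  # missing panel genes warn with the count and are excluded
  expect_warning(sm <- stemness_score(B, c(pan, "GHOST1", "GHOST2")),
                 "2 of 5")
  expect_equal(sm$n_panel_genes_missing, rep(2L, 3))
  expect_equal(sm$score, s1$score)
  expect_error(stemness_score(B, c("GHOST1")), "no panel genes")
})

test_that("candidate selection separates quantity- and quality-driven sets", {
  mk_table <- function(genes, lfc, pct2, padj) {
    structure(tibble::tibble(
      gene = genes, log2_fold_change = lfc, pct_group1 = 0.9, pct_group2 = pct2,
      p_value = padj, p_adjusted = padj,
      passes_threshold = lfc > 0.58 & padj < 0.05),
      class = c("deg_table", "tbl_df", "tbl", "data.frame"))
  }
  # stem-exclusive gene: up vs branches with tiny outside detection, up vs HSPC
  svb <- mk_table(c("EXCL", "SHARED", "HK"), c(3, 3, 0), c(0.02, 0.6, 0.9),
                  c(1e-8, 1e-8, 0.9))
  svh <- mk_table(c("EXCL", "SHARED", "HK"), c(3, 0.1, 0), c(0.1, 0.5, 0.9),
                  c(1e-8, 0.8, 0.9))
  pool <- select_candidates(svb, svh, exclusivity = 0.1)
  expect_true("EXCL" %in% pool$quantity_driven)
  expect_false("SHARED" %in% pool$quantity_driven)  # detected outside stem-like
  expect_true("EXCL" %in% pool$quality_driven)
  expect_false("SHARED" %in% pool$quality_driven)   # equal in stem and HSPC
  expect_false("HK" %in% c(pool$quantity_driven, pool$quality_driven))
  expect_identical(pool$pool, pool$quality_driven)  # default combine mode
  pool_u <- select_candidates(svb, svh, combine = "union")
  expect_setequal(pool_u$pool, union(pool$quantity_driven, pool$quality_driven))
  empty <- mk_table("HK", 0, 0.9, 0.9)
  expect_error(select_candidates(empty, empty), "empty candidate pool")
})

test_that("top-decile labeling handles exact deciles, ties, and small n", {
  x <- setNames(seq(0.01, 0.20, by = 0.01), sprintf("s%02d", 1:20))
  lab <- label_top_decile(x)
  expect_equal(sum(lab$label), 2L)
  expect_setequal(lab$sample_id[lab$label == 1], c("s19", "s20"))
  # three-way tie spanning the boundary: all tied samples positive
  y <- setNames(c(1:17 / 100, 0.5, 0.5, 0.5), sprintf("t%02d", 1:20))
  lab2 <- label_top_decile(y)
  expect_equal(sum(lab2$label), 3L)
  expect_error(label_top_decile(x[1:5]), ">= 10")
  expect_error(label_top_decile(setNames(rep(0.3, 12), sprintf("u%02d", 1:12))),
               "identical")
})

test_that("LASSO finds a perfectly separating gene and is seed-deterministic", {
  set.seed(301)
  n <- 300; p <- 200
  y <- rep(c(0L, 1L), c(270, 30))
  X <- matrix(rnorm(n * p), nrow = p,
              dimnames = list(sprintf("G%03d", 1:p), sprintf("s%03d", 1:n)))
  X["G001", ] <- X["G001", ] + 5 * y
  fit <- fit_lasso_panel(X, y, seed = 1)
  expect_true("G001" %in% fit$selected_genes)
  fit2 <- fit_lasso_panel(X, y, seed = 1)
  expect_identical(fit$selected_genes, fit2$selected_genes)
  expect_identical(tidy(fit)$gene, fit$selected_genes)
  expect_equal(glance(fit)$n_genes, length(fit$selected_genes))
  expect_error(fit_lasso_panel(X, rep(0L, n)), "single class")
  Xz <- X; Xz["G002", ] <- 1
  expect_warning(fit_lasso_panel(Xz, y, seed = 1), "zero-variance")
})

test_that("log-rank equals the hand-computed toy-table value and survdiff", {
  # 6 subjects, times 1..6, all events, groups alternating A B A B A B
  # (A at times 1, 3, 5). Hand-derived per event time t (n at risk, n_A,
  # E contribution, V contribution):
  # t=1: 6,3 -> E 1/2,  V 1/4
  # t=2: 5,2 -> E 2/5,  V 6/25
  # t=3: 4,2 -> E 1/2,  V 1/4
  # t=4: 3,1 -> E 1/3,  V 2/9
  # t=5: 2,1 -> E 1/2,  V 1/4
  # t=6: 1,0 -> E 0,    V 0 (single subject at risk)
  # O_A = 3, E_A = 67/30, V = 1091/900,
  # chi-square = (3 - 67/30)^2 / (1091/900) = 529/1091
  toy <- tibble::tibble(time = 1:6, event = 1L)
  g <- rep(c(TRUE, FALSE), 3)
  lr <- logrank_test(toy, g)
  expect_equal(lr$chi_square, 529 / 1091, tolerance = 1e-12)
  expect_equal(sum(lr$groups$observed - lr$groups$expected), 0, tolerance = 1e-9)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(toy, g = g))
  expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-9)
  # identical groups give statistic 0
  dup <- tibble::tibble(time = rep(1:5, 2), event = 1L)
  lr0 <- logrank_test(dup, rep(c(TRUE, FALSE), each = 5))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_error(logrank_test(toy, rep(TRUE, 6)), "non-empty")
  expect_error(logrank_test(tibble::tibble(time = 1:6, event = 0L), g), "event")
})

test_that("log-rank matches the brute-force oracle on random small tables", {
  set.seed(401)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    tt <- tibble::tibble(time = sample(1:6, n, replace = TRUE),
                         event = rbinom(n, 1, 0.8))
    g <- rbinom(n, 1, 0.5) == 1
    if (length(unique(g)) < 2 || sum(tt$event) < 1) next
    lr <- logrank_test(tt, g)
    expect_equal(lr$chi_square, logrank_oracle(tt$time, tt$event, g),
                 tolerance = 1e-10)
  }
})

test_that("log-rank has power at a strong effect", {
  sc <- setNames(runif(200), sprintf("P%03d", 1:200))
  surv <- simulate_survival(sc, effect_beta = log(4), censor_rate = 0.1,
                            seed = 5)
  lr <- logrank_test(surv, surv$score > median(surv$score))
  expect_lt(lr$p_value, 0.05)
})

test_that("maxstat finds a planted step cutoff and handles degenerate ranges", {
  withr::with_seed(17, {
    n <- 200
    sc <- round(runif(n) * 20) / 20
    c0 <- 0.475
    surv <- simulate_survival(setNames(sc, sprintf("P%03d", 1:n)),
                              effect_beta = 0, baseline_rate = 0.1,
                              censor_rate = 0, seed = 23)
    surv$time <- rexp(n, 0.1 * ifelse(sc > c0, 4, 1))  # planted step
  })
  ms <- maxstat_cutoff(sc, surv)
  brackets <- c(max(sc[sc <= c0]), min(sc[sc > c0]))
  expect_gte(ms$cutoff, brackets[1] - 1e-12)
  expect_lte(ms$cutoff, brackets[2] + 1e-12)
  expect_gt(ms$max_standardized_statistic, 3)
  # single interior candidate reduces to that candidate
  s2 <- c(rep(0, 6), rep(1, 6))
  surv2 <- tibble::tibble(time = c(1:6, 7:12), event = 1L)
  ms2 <- maxstat_cutoff(s2, surv2, quantile_range = c(0.1, 0.9))
  expect_equal(ms2$cutoff, 0)
  expect_error(maxstat_cutoff(rep(1, 12), surv2), "constant")
  expect_error(maxstat_cutoff(s2, surv2, quantile_range = c(0.49, 0.51)),
               "no candidate")
})

test_that("null maxstat statistic sits inside the permutation reference", {
  withr::with_seed(31, {
    n <- 60
    sc <- runif(n)
    surv <- simulate_survival(setNames(sc, sprintf("P%02d", 1:n)),
                              effect_beta = 0, censor_rate = 0, seed = 37)
    ms <- maxstat_cutoff(sc, surv)
    perm <- vapply(1:99, function(i) {
      maxstat_cutoff(sample(sc), surv)$max_standardized_statistic
    }, 0)
    expect_gte(ms$max_standardized_statistic, quantile(perm, 0.025))
    expect_lte(ms$max_standardized_statistic, quantile(perm, 0.975))
  })
})

test_that("Kaplan-Meier steps match the closed form and handle censoring", {
  km <- km_curve(tibble::tibble(time = c(1, 2, 3, 4), event = 1L))
  expect_equal(km$estimate, c(0.75, 0.5, 0.25, 0))
  all_cens <- km_curve(tibble::tibble(time = c(1, 2, 3), event = 0L))
  expect_true(all(all_cens$estimate == 1))
  # estimate beyond the last event keeps the last value (step convention)
  km2 <- km_curve(tibble::tibble(time = c(1, 2, 10), event = c(1L, 1L, 0L)))
  expect_equal(km2$estimate[km2$time == 10], km2$estimate[km2$time == 2])
  expect_error(km_curve(tibble::tibble(time = -1, event = 1L)), "negative")
  expect_error(km_curve(tibble::tibble(time = numeric(), event = integer())),
               "empty")
  # Greenwood standard error against survfit
  sv <- survival::survfit(survival::Surv(c(1, 2, 3, 4), rep(1, 4)) ~ 1)
  expect_equal(km$std_error, sv$std.err * sv$surv, tolerance = 1e-12)
})

test_that("end-to-end: deconvolved stemness drives detectable survival risk", {
  prof <- make_population_profiles(n_genes = 600, markers_per_pop = 25,
                                   effect_size = 8, seed = 51)
  sc <- simulate_cells(prof, 60, seed = 52)
  sig <- suppressWarnings(build_signature(sc$matrix, downsample = 1e5, seed = 53))
  n <- 200
  P <- dirichlet_proportions(n, 9, alpha = c(1, rep(19 / 8, 8)), seed = 54)
  colnames(P) <- apl_populations()
  pb <- simulate_pseudobulk(prof, P, noise_sd = 0.1, seed = 55)
  dec <- svr_deconvolve(pb$bulk, sig)
  stem <- dec |> dplyr::filter(.data$population == "stem-like")
  # survival depends on the TRUE stem fraction; pipeline must detect it
  truth <- pb$truth |> dplyr::filter(.data$population == "stem-like")
  surv <- simulate_survival(setNames(truth$proportion, truth$sample_id),
                            effect_beta = log(4) / sd(truth$proportion),
                            censor_rate = 0.1, seed = 56)
  est <- stem$fraction[match(surv$sample_id, stem$sample_id)]
  ms <- maxstat_cutoff(est, surv)
  lr <- logrank_test(surv, est > ms$cutoff)
  expect_lt(lr$p_value, 0.05)
})
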