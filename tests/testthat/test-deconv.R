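sim_deconv_world <- function(n_genes = 800, markers = 30, effect = 8,
                             cells = 80, seed = 101) {
  prof <- make_population_profiles(n_genes = n_genes, markers_per_pop = markers,
                                   effect_size = effect, seed = seed)
  sc <- simulate_cells(prof, cells, seed = seed + 1)
  sig <- build_signature(sc$matrix, downsample = 1e5, seed = seed + 2) |>
    suppressWarnings()
  list(prof = prof, cells = sc, sig = sig)
}

test_that("signature recovers the planted marker structure", {
  w <- sim_deconv_world()
  sig <- w$sig
  expect_equal(ncol(sig$values), 9L)
  # marker recovery: at effect 8 nearly all planted markers are found
  planted <- unlist(w$prof$marker_map)
  expect_gte(nrow(sig$values), length(planted) * 0.9)
  found <- vapply(names(w$prof$marker_map), function(p) {
    mean(w$prof$marker_map[[p]] %in% sig$markers[[p]]) >= 0.9
  }, TRUE)
  expect_true(all(found))
  # signature column ~ generating profile on signature genes (CPM scale)
  cpm_prof <- sweep(w$prof$mean_matrix, 2, colSums(w$prof$mean_matrix), "/") * 1e6
  for (p in colnames(sig$values)) {
    expect_gte(cor(sig$values[, p], cpm_prof[rownames(sig$values), p]), 0.98)
  }
})

test_that("signature construction validates inputs", {
  w <- sim_deconv_world(cells = 25)
  expect_error(build_signature(w$cells$matrix, populations = c(apl_populations(),
                                                               "ghost")),
               "ghost")
  # keep all populations but only 10 cells each: trips the >= 20 rule
  meta <- w$cells$matrix$cell_meta
  keep <- unlist(lapply(split(meta$barcode, meta$label), head, 10))
  few <- gexp_subset_cells(w$cells$matrix, keep)
  expect_error(suppressWarnings(build_signature(few)), ">= 20 cells")
})

test_that("a pure mixture deconvolves to its own population", {
  w <- sim_deconv_world()
  P <- diag(9)[1:2, ]
  rownames(P) <- c("pure1", "pure2"); colnames(P) <- apl_populations()
  pb <- simulate_pseudobulk(w$prof, P, noise_sd = 0, seed = 5)
  dec <- svr_deconvolve(pb$bulk, w$sig)
  for (i in 1:2) {
    top <- dec |> dplyr::filter(.data$sample_id == rownames(P)[i]) |>
      dplyr::slice_max(.data$fraction, n = 1)
    expect_equal(top$population, apl_populations()[i])
    expect_gte(top$fraction, 0.99)
  }
})

test_that("SVR fractions agree with an NNLS oracle on noise-free mixtures", {
  w <- sim_deconv_world()
  P <- matrix(0, nrow = 3, ncol = 9,
              dimnames = list(c("m1", "m2", "m3"), apl_populations()))
  P["m1", 1:2] <- c(0.6, 0.4)
  P["m2", c(3, 7)] <- c(0.5, 0.5)
  P["m3", ] <- rep(1 / 9, 9)
  pb <- simulate_pseudobulk(w$prof, P, noise_sd = 0, seed = 6)
  dec <- svr_deconvolve(pb$bulk, w$sig)
  S <- w$sig$values
  for (s in rownames(P)) {
    y <- pb$bulk[rownames(S), s]
    nn <- pracma::lsqnonneg(S, y)$x
    nn <- nn / sum(nn)
    est <- dec |> dplyr::filter(.data$sample_id == s) |>
      dplyr::arrange(match(.data$population, colnames(S))) |> dplyr::pull(.data$fraction)
    expect_true(all(abs(est - nn) <= 0.02))
    expect_true(all(abs(est - P[s, colnames(S)]) <= 0.02))
  }
})

test_that("fractions are scale-invariant and sum to one", {
  w <- sim_deconv_world()
  P <- dirichlet_proportions(4, 9, seed = 7); colnames(P) <- apl_populations()
  pb <- simulate_pseudobulk(w$prof, P, noise_sd = 0.1, seed = 8)
  dec1 <- svr_deconvolve(pb$bulk, w$sig)
  dec2 <- svr_deconvolve(pb$bulk * 37.5, w$sig)
  expect_equal(dec1$fraction, dec2$fraction, tolerance = 1e-8)
  sums <- dec1 |> dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(s = sum(.data$fraction))
  expect_equal(sums$s, rep(1, 4), tolerance = 1e-9)
  expect_true(all(dec1$fraction >= 0))
  expect_true(all(dec1$chosen_nu %in% c(0.25, 0.5, 0.75)))
})

test_that("an absent population is estimated near zero", {
  w <- sim_deconv_world()
  P <- matrix(0, nrow = 3, ncol = 9,
              dimnames = list(sprintf("s%d", 1:3), apl_populations()))
  P[, 2:9] <- dirichlet_proportions(3, 8, seed = 9)  # stem-like truly 0
  pb <- simulate_pseudobulk(w$prof, P, noise_sd = 0.1, seed = 10)
  dec <- svr_deconvolve(pb$bulk, w$sig)
  stem <- dec$fraction[dec$population == "stem-like"]
  expect_true(all(stem <= 0.05))
})

test_that("deconvolution validates its inputs", {
  w <- sim_deconv_world()
  expect_error(svr_deconvolve(matrix(1, nrow = 10, ncol = 2,
                                     dimnames = list(letters[1:10], c("a", "b"))),
                              w$sig),
               "signature genes")
  const <- matrix(5, nrow = nrow(w$sig$values), ncol = 1,
                  dimnames = list(rownames(w$sig$values), "flat"))
  expect_error(svr_deconvolve(const, w$sig, min_shared_genes = 10), "constant|non-constant")
})

test_that("calibration recovers exact linear relations", {
  dec <- tibble::tibble(
    sample_id = rep(sprintf("s%d", 1:4), each = 2),
    population = rep(c("stem-like", "B"), 4),
    raw_coefficient = c(0.1, 0.5, 0.2, 0.4, 0.3, 0.3, 0.4, 0.2))
  obs_eq <- dec |> dplyr::transmute(.data$sample_id, .data$population,
                                    proportion = .data$raw_coefficient)
  cal <- calibrate(dec, obs_eq)
  expect_equal(cal$slope, c(1, 1), tolerance = 1e-10)
  expect_equal(cal$intercept, c(0, 0), tolerance = 1e-10)
  expect_equal(cal$pearson_r, c(1, 1), tolerance = 1e-10)
  obs_2x <- dec |> dplyr::transmute(.data$sample_id, .data$population,
                                    proportion = 2 * .data$raw_coefficient)
  cal2 <- calibrate(dec, obs_2x)
  expect_equal(cal2$slope, c(2, 2), tolerance = 1e-10)
  expect_error(calibrate(dec[1:4, ], obs_eq[1:4, ]), ">= 3")
})

test_that("predicted proportions pass through calibration and clip to [0, 1]", {
  w <- sim_deconv_world()
  P <- dirichlet_proportions(6, 9, seed = 11); colnames(P) <- apl_populations()
  pb <- simulate_pseudobulk(w$prof, P, noise_sd = 0, seed = 12)
  dec <- svr_deconvolve(pb$bulk, w$sig)
  # identity calibration: calibrated == raw coefficient (clipped)
  ident <- tibble::tibble(population = apl_populations(), slope = 1,
                          intercept = 0, pearson_r = 1, n_samples = 6L)
  class(ident) <- c("calibration_model", class(ident))
  pred <- predict_proportions(pb$bulk, w$sig, ident)
  expect_equal(pred$calibrated_proportion,
               pmin(1, pmax(0, pred$raw_coefficient)), tolerance = 1e-12)
  # a large negative intercept clips at zero
  neg <- ident; neg$intercept <- -10
  pred2 <- predict_proportions(pb$bulk, w$sig, neg)
  expect_true(all(pred2$calibrated_proportion == 0))
  bad <- ident; bad$population[1] <- "ghost"
  expect_error(predict_proportions(pb$bulk, w$sig, bad), "subset")
})

test_that("leave-one-out runs one fold per sample", {
  prof <- make_population_profiles(n_genes = 500, markers_per_pop = 20,
                                   effect_size = 8, seed = 13)
  ids <- sprintf("P%02d", 1:5)
  cells <- list(); bulks <- list()
  set.seed(77)
  for (i in seq_along(ids)) {
    # distinct composition per sample so bulk profiles and observed
    # proportions vary across the cohort
    n_per <- setNames(sample(15:60, 9, replace = TRUE), apl_populations())
    sc <- simulate_cells(prof, n_per, sample_id = ids[i], seed = 20 + i)
    cells[[ids[i]]] <- sc$matrix
    pr <- matrix(table(sc$truth$label)[apl_populations()] /
                   length(sc$truth$label), nrow = 1,
                 dimnames = list(ids[i], apl_populations()))
    bulks[[i]] <- simulate_pseudobulk(prof, pr, noise_sd = 0, seed = 30 + i)$bulk
  }
  bulk <- do.call(cbind, bulks)
  rep <- suppressWarnings(loo_validate(cells, bulk, downsample = 1e5, seed = 1))
  expect_equal(nrow(rep$folds), 5L)
  expect_setequal(rep$folds$sample_id, ids)
  expect_gte(rep$summary$median_r, 0.95)
  expect_error(loo_validate(cells[1:3], bulk[, 1:3]), ">= 4")
})
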