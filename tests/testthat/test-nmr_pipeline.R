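# NMR pipeline: binning/normalization, latent models versus base-R PCA,
# signature extraction, grid search, classification, blast classes.

make_spectra <- function(n = 8, ppm = seq(9.5, 0.5, by = -0.01), seed = 1) {
  amlmetab:::with_seed(seed, {
    X <- matrix(abs(rnorm(n * length(ppm), 1, 0.1)), n)
    rownames(X) <- sprintf("S%02d", 1:n)
    meta <- data.frame(patient = rownames(X),
                       status = rep(c("AML", "CTRL"), length.out = n),
                       age = 50 + seq_len(n), gender = "F",
                       blast_bm = NA, blast_pb = NA,
                       timepoint = "diagnosis", biofluid = "serum")
    spectral_matrix(X, ppm, meta)
  })
}

test_that("binning geometry, exclusions, and normalizations", {
  ppm <- seq(9.5, 0.5, by = -0.002)
  X <- matrix(0, 2, length(ppm))
  # peak at 1.33 ppm must land in bin [1.30, 1.34): floor((1.33-0.5)/0.04)=20
  X[1, ] <- amlmetab:::lorentz(ppm - 1.33, hw = 0.004)
  X[2, ] <- 1  # constant spectrum
  meta <- data.frame(patient = c("a", "b"), status = "AML", age = 60,
                     gender = "M", blast_bm = 50, blast_pb = 10,
                     timepoint = "diagnosis", biofluid = "serum")
  sm <- spectral_matrix(X, ppm, meta)
  binned <- preprocess_spectra(sm, bin_width = 0.04, exclude = list(),
                               normalization = "none")
  peak_bin <- which.max(binned$intensities[1, ])
  expect_equal(binned$ppm[peak_bin], 0.5 + (20 + 0.5) * 0.04)
  # constant spectrum: all bins equal; total_area sums to one
  expect_true(all(abs(binned$intensities[2, ] - 1) < 1e-12))
  ta <- preprocess_spectra(sm, normalization = "total_area",
                           exclude = list())
  expect_equal(unname(rowSums(ta$intensities)), c(1, 1))
  # idempotence of total_area
  ta2 <- preprocess_spectra(ta, bin_width = 0.04, exclude = list(),
                            normalization = "total_area")
  expect_equal(unname(rowSums(ta2$intensities)), c(1, 1))
  # water exclusion drops 4.5-5.0 ppm bins by default
  wa <- preprocess_spectra(sm, normalization = "none")
  expect_false(any(wa$ppm >= 4.5 & wa$ppm <= 5.0))
  # non-finite spectra are rejected with the offending sample id
  X_bad <- X; X_bad[2, 5] <- NA
  expect_error(preprocess_spectra(spectral_matrix(X_bad, ppm, meta)), "b")
})

test_that("pqn recovers a planted 2x dilution factor", {
  base <- make_spectra(n = 6, seed = 2)
  X <- base$intensities
  X[1, ] <- 2 * X[2, ]  # spectrum 1 is a 2x dilution twin of spectrum 2
  sm <- spectral_matrix(X, base$ppm, base$metadata)
  pq <- preprocess_spectra(sm, exclude = list(), normalization = "pqn")
  # after correction the twin spectra coincide
  expect_lt(max(abs(pq$intensities[1, ] - pq$intensities[2, ])), 1e-8)
})

test_that("PCA matches prcomp, loadings orthonormal, EV nonincreasing", {
  sm <- make_spectra(n = 12, seed = 3)
  fit <- fit_latent_model(sm, "PCA", n_components = 4, scaler = "none")
  L <- fit$loadings
  expect_lt(max(abs(crossprod(L) - diag(4))), 1e-8)
  expect_true(all(diff(fit$explained_variance) <= 1e-9))
  pr <- stats::prcomp(sm$intensities, center = TRUE, scale. = FALSE)
  # compare |scores| (sign is arbitrary)
  expect_lt(max(abs(abs(fit$scores) - abs(pr$x[, 1:4]))), 1e-6)
  # reconstruction error nonincreasing in n_components
  Xc <- scale(sm$intensities, center = TRUE, scale = FALSE)
  errs <- vapply(1:4, function(k) {
    f <- fit_latent_model(sm, "PCA", k, scaler = "none")
    sum((Xc - f$scores %*% t(f$loadings))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
  # collinear two-feature data: PC1 carries 100% of variance
  two <- cbind(1:10, 2 * (1:10))
  f2 <- fit_latent_model(two, "PCA", 1, scaler = "none")
  expect_equal(f2$explained_variance[1], 100, tolerance = 1e-9)
})

test_that("PLSDA separates separable classes; score identity holds", {
  amlmetab:::with_seed(4, {
    n <- 30
    X <- matrix(rnorm(n * 20), n)
    y <- rep(c("A", "B"), each = n / 2)
    X[y == "B", 1:3] <- X[y == "B", 1:3] + 4
    fit <- fit_latent_model(X, "PLSDA", 2, labels = y)
    # LV1 threshold separates the training classes perfectly
    lv1 <- fit$scores[, 1]
    thr <- mean(c(max(lv1[y == "A"]), min(lv1[y == "B"])))
    pred <- ifelse(lv1 > thr, "B", "A")
    if (mean(lv1[y == "B"]) < mean(lv1[y == "A"])) {
      pred <- ifelse(lv1 > thr, "A", "B")
      thr <- mean(c(max(lv1[y == "B"]), min(lv1[y == "A"])))
    }
    expect_true(mean(pred == y) %in% c(1))
    # score identity: scores = scaled(data) %*% loadings
    sc <- scale(X, fit$center, fit$scale)
    expect_lt(max(abs(sc %*% fit$loadings - fit$scores)), 1e-8)
    # sparsity: sPLSDA keeps the requested number of nonzero weights
    sp <- fit_latent_model(X, "sPLSDA", 2, labels = y, sparsity = 3)
    # projection loadings live in the span of the sparse weights: at most
    # 3 nonzero weight rows per component
    expect_lte(sum(rowSums(abs(sp$loadings)) > 1e-10), 6)
    expect_error(fit_latent_model(X, "PLSDA", 2, labels = rep("A", n)),
                 "two classes")
  })
})

test_that("signature extraction honors the SNR threshold", {
  w <- c(rep(0.001, 50), 0.9, rep(0.001, 49))
  noise <- 0.001 * stats::rnorm(100)
  fit <- structure(list(loadings = matrix(w + noise, 100,
                                          dimnames = list(sprintf("b%03d", 1:100), "C1"))),
                   class = "latent_model")
  top <- extract_signature_features(fit, 1, smoothing_window = 1,
                                    snr_threshold = 3)
  expect_equal(top$feature[1], "b051")
  all_feats <- extract_signature_features(fit, 1, smoothing_window = 1,
                                          snr_threshold = 0)
  expect_equal(nrow(all_feats), 100)
  # i.i.d. noise loadings at threshold 5: empty with high probability
  amlmetab:::with_seed(5, {
    empties <- vapply(1:20, function(i) {
      f <- structure(list(loadings = matrix(rnorm(200), 200,
                                            dimnames = list(NULL, "C1"))),
                     class = "latent_model")
      nrow(extract_signature_features(f, 1, smoothing_window = 5,
                                      snr_threshold = 5))
    }, numeric(1))
    expect_lt(mean(empties > 0), 0.25)
  })
  expect_error(extract_signature_features(fit, 1, smoothing_window = 500),
               "window")
})

test_that("grid search: determinism, singleton grids, superset dominance", {
  coh <- generate_biofluid_cohort(cohort_config(n_aml = 30, n_ctrl = 30,
                                                seed = 9))
  ser <- preprocess_spectra(coh$serum, normalization = "total_area")
  y <- ser$metadata$status
  single <- list(method = "PCA", n_components = 3L,
                 scaler = "unit_variance", classifier = "adaboost")
  g1 <- stochastic_grid_search(ser, y, grid = single, n_draws = 5,
                               k_folds = 3, seed = 2)
  expect_equal(nrow(g1$trace), 1)       # capped at grid size
  expect_equal(g1$best$method, "PCA")
  grid4 <- list(method = c("PCA", "PLSDA"), n_components = c(2L, 3L),
                scaler = "unit_variance", classifier = "adaboost")
  g4a <- stochastic_grid_search(ser, y, grid = grid4, n_draws = 4,
                                k_folds = 3, seed = 2)
  g4b <- stochastic_grid_search(ser, y, grid = grid4, n_draws = 4,
                                k_folds = 3, seed = 2)
  expect_identical(g4a$trace, g4b$trace)  # seeded determinism
  expect_equal(g4a$best$cv_mean, max(g4a$trace$cv_mean))
  # exhaustive superset >= exhaustive subset under the same fold policy
  sub <- stochastic_grid_search(ser, y,
                                grid = list(method = "PCA",
                                            n_components = c(2L, 3L),
                                            scaler = "unit_variance",
                                            classifier = "adaboost"),
                                n_draws = 2, k_folds = 3, seed = 2)
  expect_gte(g4a$best$cv_mean, sub$best$cv_mean)
  expect_error(stochastic_grid_search(ser, y, grid = list(), n_draws = 1),
               "empty grid")
})

test_that("cross-validated classification: signal, null, determinism", {
  coh <- generate_biofluid_cohort(cohort_config(n_aml = 60, n_ctrl = 60,
                                                seed = 10))
  ser <- preprocess_spectra(coh$serum, normalization = "total_area")
  fit <- fit_latent_model(ser, "PLSDA", 3, labels = ser$metadata$status)
  cv <- crossvalidated_classify(fit$scores, ser$metadata$status,
                                k_folds = 5, seed = 3,
                                metadata = ser$metadata)
  expect_gte(cv$winner_accuracy, 0.95)
  expect_true(cv$winner %in% c("adaboost", "svm"))
  # permuted labels -> chance
  y_perm <- amlmetab:::with_seed(11, sample(ser$metadata$status))
  cv0 <- crossvalidated_classify(fit$scores, y_perm, k_folds = 5, seed = 3)
  se <- sqrt(0.25 / nrow(fit$scores))
  expect_lt(abs(cv0$winner_accuracy - 0.5), 3 * se + 0.05)
  # deterministic fold split
  cv2 <- crossvalidated_classify(fit$scores, ser$metadata$status,
                                 k_folds = 5, seed = 3,
                                 metadata = ser$metadata)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_identical(cv$winner_accuracy, cv2$winner_accuracy)
})

test_that("blast classes partition correctly and order by planted shift", {
  cfg <- blast_class_config()
  # boundary: 49% belongs to 20-49, 50 to 50-74, 75 to >=75
  cls <- cut(c(49, 50, 74.9, 75), breaks = cfg$bm$breaks,
             labels = cfg$bm$labels, right = FALSE)
  expect_equal(as.character(cls), c("20-49", "50-74", "50-74", ">=75"))
  amlmetab:::with_seed(12, {
    n_aml <- 90; n_ctrl <- 60
    blast <- runif(n_aml, 20, 100)
    meta <- data.frame(status = c(rep("AML", n_aml), rep("CTRL", n_ctrl)),
                       blast_bm = c(blast, rep(NA, n_ctrl)))
    # CTRL scores as pseudo-class: D_KS ~ 0
    scores_null <- c(rnorm(n_aml), rnorm(n_ctrl))
    out0 <- blast_class_separation(scores_null, meta)
    expect_true(all(out0$D_KS < 0.35))
    # monotone location shift with blast class -> nondecreasing D_KS
    shift <- as.integer(cut(blast, cfg$bm$breaks, right = FALSE))
    scores <- c(rnorm(n_aml, mean = shift * 1.5), rnorm(n_ctrl))
    out <- blast_class_separation(scores, meta)
    expect_equal(out$class, cfg$bm$labels)
    expect_true(all(diff(out$D_KS) >= -1e-9))
  })
})
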