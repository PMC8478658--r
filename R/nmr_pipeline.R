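# Biofluid NMR pipeline: spectral container, binning/normalization,
# latent-variable models (PCA, PLS-DA, sparse PLS-DA), stochastic grid
# search, SNR-thresholded signature extraction, stratified cross-validated
# classification, and blast-class separation.

#' Construct a spectral matrix
#'
#' @param intensities sample x point (or bin) matrix, rownames = sample ids.
#' @param ppm numeric vector of ppm centers, strictly monotone descending.
#' @param metadata data.frame with one row per sample: `patient`, `status`
#'   (AML/CTRL), `age`, `gender`, `blast_bm`, `blast_pb`, `timepoint`,
#'   `biofluid` (a single biofluid per matrix).
#' @return `spectral_matrix` object.
#' @export
spectral_matrix <- function(intensities, ppm, metadata) {
  intensities <- as.matrix(intensities)
  if (length(ppm) != ncol(intensities))
    stop2("ppm length must match the number of columns")
  if (any(diff(ppm) >= 0)) stop2("ppm must be strictly decreasing")
  if (nrow(metadata) != nrow(intensities))
    stop2("metadata must have one row per sample")
  if ("biofluid" %in% names(metadata) &&
      length(unique(metadata$biofluid)) > 1L)
    stop2("one biofluid per spectral matrix")
  colnames(intensities) <- format(ppm, trim = TRUE)
  structure(list(intensities = intensities, ppm = ppm,
                 metadata = as.data.frame(metadata)),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("spectral_matrix: %d samples x %d points, %.2f-%.2f ppm (%s)\n",
              nrow(x$intensities), ncol(x$intensities), min(x$ppm),
              max(x$ppm),
              if ("biofluid" %in% names(x$metadata))
                x$metadata$biofluid[1] else "?"))
  invisible(x)
}

default_exclusions <- function(biofluid) {
  ex <- list(c(4.50, 5.00))                     # water
  if (identical(biofluid, "urine")) ex <- c(ex, list(c(5.5, 6.0)))  # urea
  ex
}

#' Preprocess spectra: bin, exclude, normalize
#'
#' Bins are mean intensities over left-closed windows
#' `[left, left + bin_width)` anchored at 0.5 ppm; excluded intervals are
#' dropped; negative bin values are clipped to zero; the chosen
#' normalization is applied per spectrum. Samples with non-finite intensity
#' values are rejected, and a QC filter removes samples with incomplete
#' core metadata (status/age/gender).
#'
#' Normalizations: `total_area` divides each spectrum by its summed
#' intensity; `pqn` (probabilistic quotient) divides by the median ratio of
#' the spectrum to the cohort median spectrum, the standard dilution
#' correction for urine.
#'
#' @param raw `spectral_matrix`.
#' @param bin_width bin width in ppm (default 0.04).
#' @param exclude list of `c(lo, hi)` ppm intervals; `NULL` uses the
#'   biofluid defaults (water 4.5-5.0; urine also urea 5.5-6.0).
#' @param normalization `"none"`, `"total_area"` or `"pqn"`.
#' @return Binned `spectral_matrix`.
#' @export
preprocess_spectra <- function(raw, bin_width = 0.04, exclude = NULL,
                               normalization = c("none", "total_area", "pqn")) {
  stopifnot(inherits(raw, "spectral_matrix"))
  normalization <- match.arg(normalization)
  if (bin_width <= 0) stop2("bin_width must be > 0")
  sample_ids <- rownames(raw$intensities)
  if (is.null(sample_ids)) {
    sample_ids <- if ("patient" %in% names(raw$metadata)) {
      as.character(raw$metadata$patient)
    } else as.character(seq_len(nrow(raw$intensities)))
  }
  bad <- rowSums(!is.finite(raw$intensities)) > 0
  if (any(bad))
    stop2("non-finite intensities in sample(s): %s",
          paste(sample_ids[bad], collapse = ", "))
  if (is.null(exclude)) {
    exclude <- default_exclusions(
      if ("biofluid" %in% names(raw$metadata)) raw$metadata$biofluid[1]
      else "serum")
  }
  origin <- 0.5
  idx <- floor((raw$ppm - origin) / bin_width)
  keep_pts <- raw$ppm >= origin
  bins <- sort(unique(idx[keep_pts]), decreasing = TRUE)
  centers <- origin + (bins + 0.5) * bin_width
  X <- vapply(bins, function(b) {
    cols <- which(idx == b & keep_pts)
    rowMeans(raw$intensities[, cols, drop = FALSE])
  }, numeric(nrow(raw$intensities)))
  X <- matrix(X, nrow = nrow(raw$intensities))
  excl <- rep(FALSE, length(centers))
  for (iv in exclude) {
    if (iv[1] < origin - bin_width || iv[2] > max(raw$ppm) + bin_width)
      stop2("exclusion interval [%g, %g] outside the spectral range",
            iv[1], iv[2])
    excl <- excl | (centers >= iv[1] & centers <= iv[2])
  }
  X <- X[, !excl, drop = FALSE]
  centers <- centers[!excl]
  X[X < 0] <- 0
  if (normalization == "total_area") {
    X <- X / rowSums(X)
  } else if (normalization == "pqn") {
    ref <- apply(X, 2, stats::median)
    usable <- ref > 0
    dil <- apply(X[, usable, drop = FALSE], 1,
                 function(s) stats::median(s / ref[usable]))
    dil[dil <= 0 | !is.finite(dil)] <- 1
    X <- X / dil
  }
  meta <- raw$metadata
  qc_ok <- !is.na(meta$status) & !is.na(meta$age) & !is.na(meta$gender)
  X <- X[qc_ok, , drop = FALSE]
  rownames(X) <- rownames(raw$intensities)[qc_ok]
  spectral_matrix(X, centers, meta[qc_ok, , drop = FALSE])
}

# ---- latent models --------------------------------------------------------

scale_spectra <- function(X, scaler) {
  center <- colMeans(X)
  scl <- if (scaler == "unit_variance") {
    s <- apply(X, 2, stats::sd); s[s == 0] <- 1; s
  } else rep(1, ncol(X))
  list(X = scale(X, center, scl), center = center, scale = scl)
}

#' Fit a latent-variable model (PCA, PLS-DA, sparse PLS-DA)
#'
#' PCA via singular value decomposition of the centered (and optionally
#' unit-variance scaled) matrix; loadings are orthonormal and
#' `scores = scaled(data) %*% loadings`. PLS-DA uses NIPALS against a
#' centered class-indicator matrix; the stored loadings are the projection
#' weights `W (P'W)^-1` so the same score identity holds. Sparse PLS-DA
#' zeroes all but the `sparsity[a]` largest-magnitude weights of component
#' `a` before computing scores and deflating.
#'
#' @param data `spectral_matrix` (typically preprocessed).
#' @param method `"PCA"`, `"PLSDA"` or `"sPLSDA"`.
#' @param n_components number of components (<= min(n - 1, bins)).
#' @param labels class vector, required for (s)PLS-DA.
#' @param sparsity integer keep-counts per component (sPLSDA only).
#' @param scaler `"unit_variance"` (default) or `"none"`.
#' @return `latent_model` with scores, loadings, explained variance (% of
#'   X variance), scaler info.
#' @export
fit_latent_model <- function(data, method = c("PCA", "PLSDA", "sPLSDA"),
                             n_components = 5L, labels = NULL,
                             sparsity = NULL,
                             scaler = c("unit_variance", "none")) {
  method <- match.arg(method)
  scaler <- match.arg(scaler)
  X <- if (inherits(data, "spectral_matrix")) data$intensities else
    as.matrix(data)
  if (n_components > min(nrow(X) - 1L, ncol(X)))
    stop2("n_components exceeds min(samples - 1, bins)")
  sc <- scale_spectra(X, scaler)
  Xc <- sc$X
  total_var <- sum(Xc^2)
  if (method == "PCA") {
    sv <- svd(Xc, nu = n_components, nv = n_components)
    loadings <- sv$v
    scores <- Xc %*% loadings
    expl <- 100 * sv$d[seq_len(n_components)]^2 / sum(sv$d^2)
  } else {
    if (is.null(labels)) stop2("labels required for %s", method)
    labels <- factor(labels)
    if (nlevels(labels) < 2) stop2("PLSDA needs at least two classes")
    Y <- stats::model.matrix(~ labels - 1)
    Yc <- scale(Y, scale = FALSE)
    if (method == "sPLSDA") {
      if (is.null(sparsity)) sparsity <- rep(ceiling(ncol(X) / 4), n_components)
      sparsity <- rep_len(sparsity, n_components)
    }
    Xd <- Xc; Yd <- Yc
    W <- matrix(0, ncol(X), n_components)
    P <- matrix(0, ncol(X), n_components)
    Tm <- matrix(0, nrow(X), n_components)
    expl <- numeric(n_components)
    for (a in seq_len(n_components)) {
      u <- Yd[, which.max(colSums(Yd^2))]
      for (it in 1:200) {
        w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
        if (method == "sPLSDA") {
          keep <- order(abs(w), decreasing = TRUE)[seq_len(min(sparsity[a], length(w)))]
          w[-keep] <- 0
          w <- w / sqrt(sum(w^2))
        }
        t_new <- Xd %*% w
        q <- crossprod(Yd, t_new) / sum(t_new^2)
        u_new <- Yd %*% q / sum(q^2)
        if (sum((u_new - u)^2) < 1e-12 * sum(u^2)) { u <- u_new; break }
        u <- u_new
      }
      t_a <- Xd %*% w
      p_a <- crossprod(Xd, t_a) / sum(t_a^2)
      q_a <- crossprod(Yd, t_a) / sum(t_a^2)
      Xd <- Xd - t_a %*% t(p_a)
      Yd <- Yd - t_a %*% t(q_a)
      W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
      expl[a] <- 100 * sum((t_a %*% t(p_a))^2) / total_var
    }
    loadings <- W %*% solve(crossprod(P, W))
    scores <- Xc %*% loadings
  }
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("C", seq_len(n_components))
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- colnames(scores)
  structure(list(method = method, scores = scores, loadings = loadings,
                 explained_variance = expl, scaler = scaler,
                 center = sc$center, scale = sc$scale,
                 sparsity = if (method == "sPLSDA") sparsity else NULL,
                 labels = labels),
            class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("latent_model (%s): %d components, EV%% = %s\n", x$method,
              ncol(x$scores),
              paste(sprintf("%.1f", x$explained_variance), collapse = ", ")))
  invisible(x)
}

#' Project new spectra onto a fitted latent model
#' @param model `latent_model`.
#' @param data `spectral_matrix` or matrix with the same bins.
#' @return score matrix.
#' @export
project_latent <- function(model, data) {
  X <- if (inherits(data, "spectral_matrix")) data$intensities else
    as.matrix(data)
  Xc <- scale(X, model$center, model$scale)
  Xc %*% model$loadings
}

# ---- signature extraction -------------------------------------------------

#' Extract SNR-thresholded signature features from a component
#'
#' The component's loading vector is smoothed with a centered moving
#' average; the noise level is the robust SD (median absolute deviation
#' scaled by 1.4826) of the smoothed vector; features whose
#' |smoothed weight| / noise clears the threshold are returned with their
#' signed smoothed weights.
#'
#' @param model `latent_model`.
#' @param component component index.
#' @param smoothing_window moving-average window in bins (default 5).
#' @param snr_threshold signal-to-noise threshold (default 3).
#' @return data.frame `feature`, `weight`, `snr`, sorted by |snr|.
#' @export
extract_signature_features <- function(model, component = 1L,
                                       smoothing_window = 5L,
                                       snr_threshold = 3) {
  stopifnot(inherits(model, "latent_model"))
  w <- model$loadings[, component]
  if (smoothing_window > length(w))
    stop2("smoothing window larger than the loading vector")
  if (smoothing_window > 1) {
    half <- floor(smoothing_window / 2)
    n <- length(w)
    sm <- vapply(seq_len(n), function(i) {
      mean(w[max(1, i - half):min(n, i + half)])
    }, numeric(1))
  } else sm <- w
  noise <- stats::mad(sm)
  if (noise == 0) noise <- stats::sd(sm)
  if (noise == 0 || !is.finite(noise)) noise <- 1e-12
  snr <- sm / noise
  sel <- abs(snr) >= snr_threshold
  out <- data.frame(feature = names(w)[sel], weight = sm[sel],
                    snr = snr[sel], stringsAsFactors = FALSE)
  out[order(-abs(out$snr)), , drop = FALSE]
}

# ---- stratified folds with gender/age balancing ---------------------------

# Class x gender stratification when every stratum holds >= k members,
# otherwise class-only ("when possible" policy); age enters as a secondary
# balancing key by ordering within strata before dealing.
nmr_fold_assignment <- function(labels, metadata, k_folds, seed) {
  key <- as.character(labels)
  if (!is.null(metadata) && "gender" %in% names(metadata)) {
    combo <- paste(key, metadata$gender, sep = ":")
    if (min(table(combo)) >= k_folds) key <- combo
  }
  fold <- integer(length(key))
  with_seed(derive_seed(seed, "nmrfolds"), {
    for (st in unique(key)) {
      idx <- which(key == st)
      if (!is.null(metadata) && "age" %in% names(metadata) &&
          !anyNA(metadata$age[idx])) {
        idx <- idx[order(metadata$age[idx] +
                           stats::runif(length(idx), 0, 1e-6))]
      } else {
        idx <- idx[sample.int(length(idx))]
      }
      start <- sample.int(k_folds, 1)
      fold[idx] <- ((seq_along(idx) + start - 2L) %% k_folds) + 1L
    }
  })
  fold
}

# ---- cross-validated classification --------------------------------------

#' Cross-validated classification on latent component scores
#'
#' Stratified k-fold accuracy for each requested classifier; the winner has
#' the highest mean accuracy (ties broken by lower SD, then by adaboost).
#'
#' @param scores sample x component score matrix.
#' @param labels class vector (>= 2 classes).
#' @param classifiers subset of `c("adaboost", "svm")`.
#' @param k_folds folds (default 5).
#' @param seed fold-split seed.
#' @param metadata optional metadata for gender/age stratification.
#' @return list with per-classifier `mean`, `sd`, `folds`, per-fold
#'   assignments, and `winner`.
#' @export
crossvalidated_classify <- function(scores, labels,
                                    classifiers = c("adaboost", "svm"),
                                    k_folds = 5L, seed = 1L,
                                    metadata = NULL) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop2("need at least two classes")
  fold <- nmr_fold_assignment(labels, metadata, k_folds, seed)
  for (f in seq_len(k_folds)) {
    if (length(unique(labels[fold != f])) < 2)
      stop2("a training fold contains one class; configuration rejected")
  }
  reports <- lapply(classifiers, function(kind) {
    accs <- numeric(k_folds)
    assign_log <- vector("list", k_folds)
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      fit <- fit_classifier(kind, scores[tr, , drop = FALSE],
                            droplevels(labels[tr]))
      pred <- predict(fit, scores[!tr, , drop = FALSE])
      accs[f] <- mean(as.character(pred) == as.character(labels[!tr]))
      assign_log[[f]] <- data.frame(sample = which(!tr),
                                    predicted = as.character(pred),
                                    truth = as.character(labels[!tr]))
    }
    list(classifier = kind, mean = mean(accs), sd = stats::sd(accs),
         folds = accs, assignments = do.call(rbind, assign_log))
  })
  names(reports) <- classifiers
  means <- vapply(reports, `[[`, numeric(1), "mean")
  sds <- vapply(reports, `[[`, numeric(1), "sd")
  ord <- order(-means, sds, classifiers != "adaboost")
  list(reports = reports, winner = classifiers[ord[1]],
       winner_accuracy = means[ord[1]], fold_assignment = fold)
}

# ---- stochastic grid search -----------------------------------------------

#' Stochastic grid search over preprocessing/model/classifier configurations
#'
#' The full parameter grid is the cross product of the supplied choices;
#' `n_draws` configurations are sampled uniformly without replacement
#' (capped at the grid size) and each is scored by stratified k-fold CV
#' accuracy with the latent model refit inside every training fold.
#'
#' @param data preprocessed `spectral_matrix`.
#' @param labels class vector.
#' @param grid named list of choice vectors: `method`, `n_components`,
#'   `scaler`, `classifier`.
#' @param n_draws number of sampled configurations.
#' @param k_folds CV folds.
#' @param seed seed controlling both sampling and fold splits.
#' @return list with `trace` (one row per sampled config, mean/sd CV
#'   accuracy), `best` (best row), `seed`, `n_draws`.
#' @export
stochastic_grid_search <- function(data, labels,
                                   grid = list(method = c("PCA", "PLSDA"),
                                               n_components = 2:6,
                                               scaler = c("unit_variance", "none"),
                                               classifier = c("adaboost", "svm")),
                                   n_draws = 10L, k_folds = 5L, seed = 1L) {
  if (n_draws < 1) stop2("n_draws must be >= 1")
  if (!length(grid) || any(lengths(grid) == 0)) stop2("empty grid")
  full <- expand.grid(grid, stringsAsFactors = FALSE)
  n_draws <- min(n_draws, nrow(full))
  picks <- with_seed(derive_seed(seed, "grid"),
                     sort(sample.int(nrow(full), n_draws)))
  labels <- factor(labels)
  meta <- if (inherits(data, "spectral_matrix")) data$metadata else NULL
  fold <- nmr_fold_assignment(labels, meta, k_folds, seed)
  X <- if (inherits(data, "spectral_matrix")) data$intensities else
    as.matrix(data)
  score_config <- function(cfg) {
    accs <- numeric(k_folds)
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2) return(c(NA, NA))
      lm_tr <- fit_latent_model(X[tr, , drop = FALSE], method = cfg$method,
                                n_components = cfg$n_components,
                                labels = if (cfg$method == "PCA") NULL else
                                  droplevels(labels[tr]),
                                scaler = cfg$scaler)
      s_tr <- lm_tr$scores
      s_te <- project_latent(lm_tr, X[!tr, , drop = FALSE])
      fit <- fit_classifier(cfg$classifier, s_tr, droplevels(labels[tr]))
      pred <- predict(fit, s_te)
      accs[f] <- mean(as.character(pred) == as.character(labels[!tr]))
    }
    c(mean(accs), stats::sd(accs))
  }
  trace <- full[picks, , drop = FALSE]
  res <- t(vapply(seq_len(nrow(trace)),
                  function(i) score_config(trace[i, ]), numeric(2)))
  trace$cv_mean <- res[, 1]
  trace$cv_sd <- res[, 2]
  rownames(trace) <- NULL
  best <- trace[order(-trace$cv_mean, trace$cv_sd), ][1, ]
  list(trace = trace, best = best, seed = seed, n_draws = n_draws)
}

# ---- blast-class separation -----------------------------------------------

#' Blast-percentage class configuration
#'
#' Bone-marrow classes 20-49, 50-74, >= 75 percent blasts; peripheral-blood
#' classes < 30, 30-69, >= 70 percent.
#' @return list of labeled breaks.
#' @export
blast_class_config <- function() {
  list(bm = list(breaks = c(20, 50, 75, Inf),
                 labels = c("20-49", "50-74", ">=75")),
       pb = list(breaks = c(-Inf, 30, 70, Inf),
                 labels = c("<30", "30-69", ">=70")))
}

#' Separation of blast-percentage classes from controls
#'
#' Partitions AML samples into blast classes and computes the two-sample KS
#' distance (and p-value) between each class's latent scores and the CTRL
#' score distribution. Empty classes are reported as absent.
#'
#' @param scores numeric vector of one latent component's scores.
#' @param metadata data.frame with `status` and `blast_bm` / `blast_pb`.
#' @param config [blast_class_config()].
#' @param compartment `"bm"` or `"pb"`.
#' @return data.frame `class`, `n`, `D_KS`, `p_value`.
#' @export
blast_class_separation <- function(scores, metadata,
                                   config = blast_class_config(),
                                   compartment = c("bm", "pb")) {
  compartment <- match.arg(compartment)
  cfg <- config[[compartment]]
  blast <- metadata[[paste0("blast_", compartment)]]
  if (is.null(blast)) stop2("metadata lacks blast_%s", compartment)
  ctrl <- scores[metadata$status == "CTRL"]
  if (!length(ctrl)) stop2("no CTRL samples")
  cls <- cut(blast, breaks = cfg$breaks, labels = cfg$labels, right = FALSE)
  out <- lapply(cfg$labels, function(lb) {
    idx <- which(metadata$status == "AML" & !is.na(cls) & cls == lb)
    if (!length(idx)) return(NULL)
    kd <- ks_distance(scores[idx], ctrl)
    data.frame(class = lb, n = length(idx), D_KS = kd$statistic,
               p_value = kd$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
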