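# Genomic-guided latent-component selection, serum+urine integration,
# hierarchical clustering, cluster-genotype association and the
# NPM1/cohesin subgroup enrichment analysis.

#' Score latent components by genomic signal
#'
#' Scores each serum and urine latent component by how well a classifier
#' trained on it discriminates the three genomic classes (NPM1-mut,
#' chromatin/spliceosome-mut, TP53-mut/aneuploid); components are ranked
#' jointly across both biofluids.
#'
#' Two scoring modes. `"solo"` (default): the selection score is the
#' component's own stratified-CV classification accuracy above the
#' majority-class rate -- a per-component classifier-derived score that
#' stays informative when several components carry overlapping signal.
#' `"permutation"`: a joint classifier is trained on all components and
#' each component is scored by the held-out accuracy drop when its values
#' are shuffled in the validation folds; sensitive only to components the
#' joint model actually relies on, so redundant components share (and can
#' all lose) credit.
#'
#' @param serum_model,urine_model fitted `latent_model`s whose score
#'   rownames are patient keys.
#' @param labels data.frame with `patient` and `molecular_class`; only the
#'   three genomic classes are used.
#' @param classifier `"adaboost"`, `"svm"` or `"rf"`.
#' @param mode `"solo"` or `"permutation"`.
#' @param k_folds CV folds (merged-fold fallback with a message when a
#'   class is smaller than `k_folds`).
#' @param seed seed for folds and permutations.
#' @param n_perm permutation repeats per component (permutation mode).
#' @return data.frame `component`, `biofluid`, `index`, `score`, sorted by
#'   decreasing score; attribute `cv_accuracy` (joint-model CV accuracy).
#' @export
score_components_by_genomic_signal <- function(serum_model, urine_model,
                                               labels,
                                               classifier = "adaboost",
                                               mode = c("solo", "permutation"),
                                               k_folds = 5L, seed = 1L,
                                               n_perm = 5L) {
  mode <- match.arg(mode)
  keep_classes <- c("NPM1", "chromatin_spliceosome", "TP53_aneuploid")
  lab <- labels[labels$molecular_class %in% keep_classes, , drop = FALSE]
  s_ids <- rownames(serum_model$scores)
  u_ids <- rownames(urine_model$scores)
  ids <- intersect(intersect(s_ids, u_ids), lab$patient)
  if (length(ids) < 2 * k_folds) stop2("too few labeled patients")
  X <- cbind(serum_model$scores[ids, , drop = FALSE],
             urine_model$scores[ids, , drop = FALSE])
  prov <- data.frame(
    component = c(paste0("serum_", colnames(serum_model$scores)),
                  paste0("urine_", colnames(urine_model$scores))),
    biofluid = c(rep("serum", ncol(serum_model$scores)),
                 rep("urine", ncol(urine_model$scores))),
    index = c(seq_len(ncol(serum_model$scores)),
              seq_len(ncol(urine_model$scores))),
    stringsAsFactors = FALSE)
  colnames(X) <- prov$component
  y <- factor(lab$molecular_class[match(ids, lab$patient)])
  if (min(table(y)) < k_folds) {
    k_folds <- max(2L, min(table(y)))
    message(sprintf("class smaller than k_folds: falling back to %d folds",
                    k_folds))
  }
  fold <- stratified_folds(y, k_folds, seed)
  base_acc <- numeric(k_folds)
  drops <- matrix(0, k_folds, ncol(X))
  with_seed(derive_seed(seed, "perm_imp"), {
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      fit <- fit_classifier(classifier, X[tr, , drop = FALSE],
                            droplevels(y[tr]))
      Xte <- X[!tr, , drop = FALSE]
      yte <- as.character(y[!tr])
      base_acc[f] <- mean(as.character(predict(fit, Xte)) == yte)
      if (mode == "permutation") {
        for (j in seq_len(ncol(X))) {
          d <- numeric(n_perm)
          for (r in seq_len(n_perm)) {
            Xp <- Xte
            Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
            d[r] <- base_acc[f] -
              mean(as.character(predict(fit, Xp)) == yte)
          }
          drops[f, j] <- mean(d)
        }
      } else {
        chance <- max(table(yte)) / length(yte)
        for (j in seq_len(ncol(X))) {
          fit_j <- fit_classifier(classifier, X[tr, j, drop = FALSE],
                                  droplevels(y[tr]))
          acc_j <- mean(as.character(predict(fit_j, Xte[, j, drop = FALSE])) ==
                          yte)
          drops[f, j] <- acc_j - chance
        }
      }
    }
  })
  prov$score <- colMeans(drops)
  out <- prov[order(-prov$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cv_accuracy") <- mean(base_acc)
  out
}

#' Integrate selected serum and urine components
#'
#' Inner-joins the two score matrices on the patient key, keeps the selected
#' components and standardizes every column (zero mean, unit variance) in
#' preparation for clustering.
#'
#' @param serum_scores,urine_scores score matrices with patient rownames.
#' @param selection character vector of selected component ids in the
#'   `serum_C1` / `urine_C2` naming of
#'   [score_components_by_genomic_signal()]; `NULL` keeps everything.
#' @return standardized matrix with attribute `provenance`.
#' @export
integrate_biofluid_components <- function(serum_scores, urine_scores,
                                          selection = NULL) {
  ids <- intersect(rownames(serum_scores), rownames(urine_scores))
  if (!length(ids)) stop2("no shared patients between biofluids")
  X <- cbind(serum_scores[ids, , drop = FALSE],
             urine_scores[ids, , drop = FALSE])
  colnames(X) <- c(paste0("serum_", colnames(serum_scores)),
                   paste0("urine_", colnames(urine_scores)))
  if (!is.null(selection)) {
    missing_sel <- setdiff(selection, colnames(X))
    if (length(missing_sel))
      stop2("unknown selected component(s): %s",
            paste(missing_sel, collapse = ", "))
    X <- X[, selection, drop = FALSE]
  }
  out <- standardize_columns(X)
  rownames(out) <- ids
  attr(out, "provenance") <- data.frame(
    column = colnames(X),
    biofluid = sub("_.*$", "", colnames(X)),
    stringsAsFactors = FALSE)
  out
}

#' Agglomerative hierarchical clustering cut to k clusters
#'
#' Deterministic dendrogram (ward/average/complete linkage over euclidean
#' or correlation distance) cut to `k`; cluster ids are relabeled by
#' decreasing size so the largest cluster is always 1.
#'
#' @param space sample x feature matrix (or `metabolite_table`, which is
#'   log-transformed and standardized first).
#' @param k number of clusters.
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @param distance `"euclidean"` or `"correlation"`.
#' @return list `cluster` (named integer vector), `k`, `linkage`,
#'   `distance`, `hclust`.
#' @export
hierarchical_cluster <- function(space, k = 3L,
                                 linkage = c("ward", "average", "complete"),
                                 distance = c("euclidean", "correlation")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  if (inherits(space, "metabolite_table")) {
    if (anyNA(space$intensities)) space <- impute_missing(space)
    space <- standardize_columns(log1p(space$intensities))
  }
  X <- as.matrix(space)
  if (k > nrow(X)) stop2("k exceeds the number of samples")
  d <- if (distance == "euclidean") stats::dist(X) else
    stats::as.dist(1 - stats::cor(t(X)))
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete")[linkage]
  hc <- stats::hclust(d, method = method)
  raw <- stats::cutree(hc, k = k)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- unname(relabel[as.character(raw)])
  names(cl) <- rownames(X)
  list(cluster = cl, k = k, linkage = linkage, distance = distance,
       hclust = hc)
}

#' Associate metabolic clusters with molecular classes
#'
#' Builds the cluster x class contingency table, tests it with the Monte
#' Carlo Fisher test, and reports each cluster's modal class and
#' enrichment fraction.
#'
#' @param assignment result of [hierarchical_cluster()].
#' @param labels data.frame `patient`, `molecular_class`.
#' @param B Monte Carlo resamples (default 1e6).
#' @param seed resampling seed.
#' @return list `table`, `test` (`aml_test`), `enrichment` data.frame.
#' @export
associate_clusters_with_molecular_classes <- function(assignment, labels,
                                                      B = 1e6, seed = 1L) {
  cl <- assignment$cluster
  cls <- labels$molecular_class[match(names(cl), labels$patient)]
  keep <- !is.na(cls)
  tab <- table(cluster = cl[keep], class = cls[keep])
  if (ncol(tab) < 2) {
    warn2("all samples share one molecular class; association untestable")
    return(list(table = tab,
                test = test_result(NA_real_, 1, "monte_carlo_fisher"),
                enrichment = NULL))
  }
  test <- monte_carlo_fisher(unclass(tab), B = B, seed = seed)
  enrich <- do.call(rbind, lapply(rownames(tab), function(cc) {
    row <- tab[cc, ]
    data.frame(cluster = cc, modal_class = names(which.max(row)),
               fraction = max(row) / sum(row), n = sum(row),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, test = test, enrichment = enrich)
}

#' Cohesin/DNA-damage enrichment between NPM1 metabolic subgroups
#'
#' Builds the 2x2 subgroup x flag table over NPM1-mut patients and applies
#' the exact two-sided Fisher test, reporting per-subgroup mutation
#' percentages.
#'
#' @param subgroup integer vector (1/2) of metabolic subgroup per NPM1-mut
#'   patient.
#' @param flag logical cohesin/DNA-damage co-mutation flag, same order.
#' @return list `table`, `test` (`aml_test`), `percent` (per subgroup).
#' @export
subgroup_enrichment_test <- function(subgroup, flag) {
  keep <- !is.na(subgroup) & !is.na(flag)
  subgroup <- subgroup[keep]; flag <- as.logical(flag[keep])
  if (length(unique(subgroup)) != 2L)
    stop2("need exactly 2 subgroups (got %d)", length(unique(subgroup)))
  tab <- table(factor(subgroup), factor(flag, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0)) stop2("a subgroup is empty")
  test <- if (length(unique(flag)) < 2) {
    test_result(NA_real_, 1, "fisher_exact_2x2")
  } else {
    exact_fisher_2x2(unclass(tab))
  }
  pct <- 100 * tab[, 1] / rowSums(tab)
  list(table = tab, test = test, percent = pct)
}

#' Rank cluster-discriminating features
#'
#' Kruskal-Wallis H across clusters per feature, Holm step-down Sidak
#' adjustment, ranking by adjusted p then by H (descending).
#'
#' @param data `metabolite_table` or sample x feature matrix.
#' @param assignment result of [hierarchical_cluster()] (or an integer
#'   vector of cluster ids named by sample).
#' @return data.frame `feature`, `H`, `p`, `adjusted_p`, ranked.
#' @export
rank_cluster_discriminating_metabolites <- function(data, assignment) {
  cl <- if (is.list(assignment)) assignment$cluster else assignment
  X <- if (inherits(data, "metabolite_table")) {
    if (anyNA(data$intensities)) data <- impute_missing(data)
    data$intensities
  } else as.matrix(data)
  if (!is.null(names(cl)) && !is.null(rownames(X))) {
    ids <- intersect(rownames(X), names(cl))
    X <- X[ids, , drop = FALSE]; cl <- cl[ids]
  }
  if (length(unique(cl)) < 2) stop2("need >= 2 clusters")
  if (min(table(cl)) < 2) stop2("degenerate cluster with < 2 samples")
  res <- lapply(colnames(X), function(m) {
    groups <- split(X[, m], cl)
    kt <- rank_tests(groups, "kruskal_wallis")
    data.frame(feature = m, H = kt$statistic, p = kt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- adjust_pvalues(out$p, "holm_sidak")
  out <- out[order(out$adjusted_p, -out$H), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split NPM1-mut patients into two metabolic subgroups
#'
#' Emulates the latent-space subgroup discovery: each candidate component
#' is cut into two groups (Ward hierarchical 2-cut on the single
#' component); the component with the largest between-group sum-of-squares
#' fraction (the most bimodal score distribution) defines the split.
#' Subgroup 1 is the group with the higher mean score on the winning
#' component when `orient_by` is `NULL`, otherwise the group with the
#' higher mean of the supplied per-patient marker value (e.g. a serum
#' choline + trimethylamine-N-oxide signature intensity).
#'
#' @param scores patient x component latent score matrix restricted to
#'   NPM1-mut patients (rownames = patient keys).
#' @param orient_by optional named numeric vector used to orient subgroup
#'   labels.
#' @return list `subgroup` (named 1/2 vector), `component` (winning
#'   component), `separation` (between-SS fraction).
#' @export
npm1_subgroup_split <- function(scores, orient_by = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 4) stop2("too few NPM1-mut patients to split")
  # exact optimal two-cluster partition of a 1-D score vector: scan all
  # sorted split points for the minimum within-group sum of squares
  cut_one <- function(v) {
    n <- length(v)
    ord <- order(v)
    vs <- v[ord]
    csum <- cumsum(vs); csq <- cumsum(vs^2)
    ss_tot <- csq[n] - csum[n]^2 / n
    # both groups must hold at least 15% of patients so a lone outlier
    # cannot masquerade as a subgroup
    min_size <- max(2L, ceiling(0.15 * n))
    best_i <- min_size; best_ss <- Inf
    for (i in min_size:(n - min_size)) {
      ss_l <- csq[i] - csum[i]^2 / i
      ss_r <- (csq[n] - csq[i]) - (csum[n] - csum[i])^2 / (n - i)
      if (ss_l + ss_r < best_ss) { best_ss <- ss_l + ss_r; best_i <- i }
    }
    g <- integer(n)
    g[ord] <- rep(1:2, c(best_i, n - best_i))
    sep <- if (ss_tot > 0) 1 - best_ss / ss_tot else 0
    list(g = g, sep = sep)
  }
  cuts <- apply(scores, 2, cut_one, simplify = FALSE)
  seps <- vapply(cuts, `[[`, numeric(1), "sep")
  best <- which.max(seps)
  g <- cuts[[best]]$g
  v <- scores[, best]
  ref <- if (is.null(orient_by)) v else orient_by[rownames(scores)]
  m1 <- mean(ref[g == 1]); m2 <- mean(ref[g == 2])
  sub <- if (m1 >= m2) g else 3L - g
  names(sub) <- rownames(scores)
  list(subgroup = sub, component = colnames(scores)[best],
       separation = unname(seps[best]))
}
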