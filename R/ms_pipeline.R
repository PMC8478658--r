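# Intracellular MS metabolomics: DNA normalization, half-minimum
# imputation, differential analysis with the |FC| >= 2 & q <= 0.05 rule,
# random-forest accuracy/importance, hypergeometric pathway
# over-representation and the 5-SD outlier rule.

#' Construct a metabolite table
#'
#' @param intensities sample x metabolite matrix (area-under-curve scale;
#'   `NA` allowed, negatives rejected), rownames = sample ids.
#' @param dna_content positive per-sample DNA content.
#' @param annotation data.frame `metabolite`, `superpathway`, `subpathway`.
#' @param groups per-sample group label (e.g. CD34_AML, CD34_CB).
#' @return `metabolite_table` object.
#' @export
metabolite_table <- function(intensities, dna_content = NULL,
                             annotation = NULL, groups = NULL) {
  intensities <- as.matrix(intensities)
  if (any(intensities < 0, na.rm = TRUE))
    stop2("intensities must be nonnegative")
  if (is.null(dna_content)) dna_content <- rep(1, nrow(intensities))
  if (is.null(groups)) groups <- rep("all", nrow(intensities))
  if (is.null(annotation)) {
    annotation <- data.frame(metabolite = colnames(intensities),
                             superpathway = "", subpathway = "",
                             stringsAsFactors = FALSE)
  }
  structure(list(intensities = intensities,
                 dna_content = as.numeric(dna_content),
                 annotation = annotation,
                 groups = as.character(groups)),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table: %d samples x %d metabolites (%.1f%% missing)\n",
              nrow(x$intensities), ncol(x$intensities),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Normalize intensities to DNA content
#'
#' Divides each sample's intensities by its DNA content; annotation and
#' missingness are untouched.
#'
#' @param table `metabolite_table` with DNA content for every sample.
#' @return normalized `metabolite_table` (DNA content reset to 1).
#' @export
normalize_to_dna <- function(table) {
  stopifnot(inherits(table, "metabolite_table"))
  bad <- which(!is.finite(table$dna_content) | table$dna_content <= 0)
  if (length(bad))
    stop2("nonpositive DNA content in sample(s): %s",
          paste(rownames(table$intensities)[bad], collapse = ", "))
  out <- table
  out$intensities <- table$intensities / table$dna_content
  out$dna_content <- rep(1, nrow(table$intensities))
  out
}

#' Impute missing values by the half-minimum rule
#'
#' Missing entries are replaced by half the observed per-metabolite
#' minimum, the standard practice for left-censored metabolomics panels.
#' Fully missing metabolites are dropped with a warning.
#'
#' @param table `metabolite_table`.
#' @param method currently only `"half_min"`.
#' @return imputed `metabolite_table`.
#' @export
impute_missing <- function(table, method = "half_min") {
  stopifnot(inherits(table, "metabolite_table"),
            identical(method, "half_min"))
  X <- table$intensities
  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na)) {
    warn2("dropping %d fully missing metabolite(s): %s", sum(all_na),
          paste(colnames(X)[all_na], collapse = ", "))
    X <- X[, !all_na, drop = FALSE]
    table$annotation <-
      table$annotation[!all_na, , drop = FALSE]
  }
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- min(X[, j], na.rm = TRUE) / 2
  }
  out <- table
  out$intensities <- X
  out
}

#' Differential metabolites between two groups
#'
#' Per-metabolite p-values (Welch t on log-transformed intensities, or
#' Kruskal-Wallis) with Benjamini-Hochberg q-values over the tested set;
#' fold change is the ratio of group means; flags follow the inclusive
#' `|FC| >= 2 and q <= 0.05` rule (`up` when FC >= 2, `down` when
#' FC <= 1/2).
#'
#' @param table `metabolite_table` (normalized/imputed).
#' @param group_a,group_b group labels present in `table$groups`; fold
#'   change is mean(group_a) / mean(group_b).
#' @param test `"welch"` or `"kruskal_wallis"`.
#' @param fc_threshold,q_threshold flag thresholds (defaults 2 and 0.05).
#' @return data.frame `metabolite`, `fold_change`, `p`, `q`, `flag`, with
#'   attribute `counts` = c(up =, down =).
#' @export
differential_metabolites <- function(table, group_a, group_b,
                                     test = c("welch", "kruskal_wallis"),
                                     fc_threshold = 2, q_threshold = 0.05) {
  stopifnot(inherits(table, "metabolite_table"))
  test <- match.arg(test)
  ia <- table$groups == group_a
  ib <- table$groups == group_b
  if (sum(ia) < 2 || sum(ib) < 2)
    stop2("both groups need >= 2 samples (got %d, %d)", sum(ia), sum(ib))
  X <- table$intensities
  res <- lapply(colnames(X), function(m) {
    xa <- X[ia, m]; xb <- X[ib, m]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2)
      return(data.frame(metabolite = m, fold_change = NA, p = NA))
    fc <- mean(xa) / mean(xb)
    p <- tryCatch({
      if (test == "welch") {
        welch_t_test(log1p(xa), log1p(xb))$p_value
      } else {
        rank_tests(list(xa, xb), "kruskal_wallis")$p_value
      }
    }, error = function(e) NA_real_)
    data.frame(metabolite = m, fold_change = fc, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  tested <- !is.na(out$p)
  out$q <- NA_real_
  out$q[tested] <- adjust_pvalues(out$p[tested], "bh")
  out$flag <- "none"
  up <- tested & out$fold_change >= fc_threshold & out$q <= q_threshold
  dn <- tested & out$fold_change <= 1 / fc_threshold & out$q <= q_threshold
  out$flag[up] <- "up"
  out$flag[dn] <- "down"
  attr(out, "counts") <- c(up = sum(up), down = sum(dn))
  rownames(out) <- NULL
  out
}

#' Random-forest classification assessment
#'
#' Out-of-bag accuracy of a seeded random forest on (optionally
#' log-transformed) metabolite intensities, plus mean-decrease-accuracy
#' importances (per-tree out-of-bag permutation of each metabolite).
#'
#' @param table `metabolite_table` (imputed) or plain matrix.
#' @param labels class vector (every class needs >= 2 samples).
#' @param n_trees number of trees (default 200).
#' @param seed forest seed.
#' @param log_transform log1p-transform intensities first (default TRUE).
#' @return list `accuracy` (OOB), `importance` (named, sorted decreasing),
#'   `forest`.
#' @export
random_forest_assessment <- function(table, labels, n_trees = 200L,
                                     seed = 1L, log_transform = TRUE) {
  X <- if (inherits(table, "metabolite_table")) table$intensities else
    as.matrix(table)
  if (anyNA(X)) stop2("impute missing values before random forest")
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop2("need >= 2 classes")
  if (min(table(labels)) < 2) stop2("a class has fewer than 2 samples")
  if (n_trees < 1) stop2("n_trees must be >= 1")
  if (log_transform) X <- log1p(X)
  forest <- fit_random_forest(X, labels, n_trees = n_trees, seed = seed)
  imp <- rf_importance(forest)
  list(accuracy = rf_oob_accuracy(forest),
       importance = sort(imp, decreasing = TRUE),
       forest = forest)
}

#' Pathway over-representation of flagged metabolites
#'
#' Hypergeometric upper-tail p for the overlap of the flagged set with each
#' pathway within the measured universe; BH q-values; impact = fraction of
#' the pathway hit.
#'
#' @param diff data.frame from [differential_metabolites()].
#' @param annotation named list pathway -> metabolite id vector (sets are
#'   restricted to the universe of tested metabolites).
#' @return data.frame `pathway`, `size`, `overlap`, `p`, `q`, `impact`.
#' @export
pathway_enrichment <- function(diff, annotation) {
  universe <- diff$metabolite[!is.na(diff$p)]
  if (!length(universe)) stop2("empty universe")
  flagged <- diff$metabolite[diff$flag != "none"]
  if (!length(flagged)) stop2("no flagged metabolites to test")
  out <- lapply(names(annotation), function(pw) {
    pset <- intersect(annotation[[pw]], universe)
    if (!length(pset)) return(NULL)
    ov <- length(intersect(pset, flagged))
    # P(X >= ov) for X ~ Hypergeom(universe, pathway, draws = |flagged|)
    p <- stats::phyper(ov - 1, length(pset),
                       length(universe) - length(pset),
                       length(flagged), lower.tail = FALSE)
    data.frame(pathway = pw, size = length(pset), overlap = ov, p = p,
               impact = ov / length(pset), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- adjust_pvalues(out$p, "bh")
  out[order(out$p), c("pathway", "size", "overlap", "p", "q", "impact")]
}

#' Five-SD outlier rule against a control population
#'
#' Flags values more than `n_sd` control standard deviations from the
#' control mean. Two-sided by default; the boundary itself is not an
#' outlier.
#'
#' @param values numeric vector to screen.
#' @param control reference sample (n >= 2, SD > 0).
#' @param n_sd threshold in control SDs (default 5).
#' @param direction `"two_sided"`, `"high"` or `"low"`.
#' @return logical vector of outlier flags.
#' @export
detect_outliers <- function(values, control, n_sd = 5,
                            direction = c("two_sided", "high", "low")) {
  direction <- match.arg(direction)
  control <- control[is.finite(control)]
  if (length(control) < 2) stop2("control needs n >= 2")
  s <- stats::sd(control)
  if (s == 0) stop2("control SD is zero")
  m <- mean(control)
  z <- (values - m) / s
  switch(direction,
         two_sided = abs(z) > n_sd,
         high = z > n_sd,
         low = z < -n_sd)
}
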