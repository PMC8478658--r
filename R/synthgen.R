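# Seeded synthetic cohorts with the statistical structure every downstream
# stage assumes: two-class biofluid NMR spectra with the packaged
# serum/urine effect directions, a clustered intracellular metabolome
# correlated with AML molecular classes, a cohesin/DNA-damage co-mutation
# flag enriched in one NPM1 subgroup, two-group expression tables with a
# designated downregulated gene set, and toy SBML models.

#' Cohort generator configuration
#'
#' @param n_aml,n_ctrl cohort sizes (defaults mirror the serum cohort sizes
#'   of 119 AML and 145 controls).
#' @param seed master seed; identical configs generate bit-identical output.
#' @param effect_scale nonnegative multiplier on all class effects; 0 makes
#'   the classes exchangeable (null calibration).
#' @param peak_jitter_ppm SD of the per-sample global chemical-shift jitter.
#' @param noise_sd SD of additive Gaussian noise per spectral point.
#' @param missing_rate fraction of missing values injected into MS tables.
#' @return `cohort_config` list.
#' @export
cohort_config <- function(n_aml = 119L, n_ctrl = 145L, seed = 1L,
                          effect_scale = 1, peak_jitter_ppm = 0.002,
                          noise_sd = 0.02, missing_rate = 0.1) {
  if (!is_count(n_aml) || !is_count(n_ctrl)) stop2("counts must be positive integers")
  if (!is_scalar(effect_scale) || effect_scale < 0)
    stop2("effect_scale must be a nonnegative scalar")
  if (missing_rate < 0 || missing_rate >= 1)
    stop2("missing_rate must lie in [0, 1)")
  structure(list(n_aml = as.integer(n_aml), n_ctrl = as.integer(n_ctrl),
                 seed = as.integer(seed), effect_scale = effect_scale,
                 peak_jitter_ppm = peak_jitter_ppm, noise_sd = noise_sd,
                 missing_rate = missing_rate),
            class = "cohort_config")
}

#' Packaged serum/urine effect list
#'
#' The 18 serum and urine metabolite alterations of AML versus controls
#' (direction up/down per biofluid) with field-standard chemical-shift
#' positions. Phenylalanine appears in both biofluids.
#'
#' @param magnitude fold-change magnitude applied to every effect (default
#'   1.5; the source reports directions and p-values, not effect sizes).
#' @return data.frame with columns `name`, `ppm`, `direction`, `magnitude`,
#'   `biofluid` (one row per peak position).
#' @export
aml_biofluid_effects <- function(magnitude = 1.5) {
  eff <- function(name, ppm, direction, biofluid) {
    data.frame(name = name, ppm = ppm, direction = direction,
               magnitude = magnitude, biofluid = biofluid,
               stringsAsFactors = FALSE)
  }
  rbind(
    eff("3-hydroxybutyrate", 1.20, "up", "serum"),
    eff("glycerol_of_lipids", 4.32, "up", "serum"),
    eff("glucose", 5.23, "up", "serum"),
    eff("glucose", 3.40, "up", "serum"),
    eff("glutamine", 2.45, "down", "serum"),
    eff("lactate", 1.33, "up", "serum"),
    eff("lactate", 4.11, "up", "serum"),
    eff("ldl1_vldl1", 0.88, "down", "serum"),
    eff("ldl2_vldl2", 1.28, "up", "serum"),
    eff("n_acetylglycoproteins", 2.04, "up", "serum"),
    eff("polyunsaturated_fatty_acids", 2.80, "up", "serum"),
    eff("pyruvate_succinate", 2.38, "up", "serum"),
    eff("threonine", 4.24, "down", "serum"),
    eff("valine", 1.04, "up", "serum"),
    eff("phenylalanine", 7.37, "up", "serum"),
    eff("phenylalanine", 7.37, "up", "urine"),
    eff("3-aminobutyrate", 2.30, "up", "urine"),
    eff("citrate", 2.54, "down", "urine"),
    eff("citrate", 2.66, "down", "urine"),
    eff("creatinine", 3.05, "down", "urine"),
    eff("creatinine", 4.06, "down", "urine"),
    eff("glycine", 3.56, "down", "urine"),
    eff("hippurate", 7.83, "down", "urine"),
    eff("hippurate", 3.97, "down", "urine"))
}

#' Molecular class labels and the NPM1/cohesin co-mutation flag
#'
#' Assigns each AML patient a molecular class (NPM1-mut,
#' chromatin/spliceosome-mut, TP53-mut/aneuploid, other), splits NPM1-mut
#' patients into two metabolic subgroups, and draws the cohesin/DNA-damage
#' co-mutation flag per subgroup with the documented default enrichment
#' rates (0.60 in subgroup 1 versus 0.091 in subgroup 2).
#'
#' @param patient_ids character vector of patient keys.
#' @param seed integer seed.
#' @param class_probs named probabilities over the four classes.
#' @param enrichment cohesin-flag Bernoulli rates for NPM1 subgroups 1 and 2.
#' @param subgroup1_frac fraction of NPM1-mut patients in subgroup 1.
#' @return data.frame `patient`, `molecular_class`, `npm1_subgroup` (NA
#'   outside NPM1), `cohesin_dd_mut` (logical, NA outside NPM1).
#' @export
generate_molecular_labeling <- function(patient_ids, seed = 1L,
                                        class_probs = c(NPM1 = 0.35,
                                          chromatin_spliceosome = 0.25,
                                          TP53_aneuploid = 0.2,
                                          other = 0.2),
                                        enrichment = c(0.60, 0.091),
                                        subgroup1_frac = 0.45) {
  n <- length(patient_ids)
  with_seed(derive_seed(seed, "labels"), {
    cls <- sample(names(class_probs), n, replace = TRUE, prob = class_probs)
    sub <- rep(NA_integer_, n)
    flag <- rep(NA, n)
    npm1 <- which(cls == "NPM1")
    sub[npm1] <- ifelse(stats::runif(length(npm1)) < subgroup1_frac, 1L, 2L)
    flag[npm1] <- stats::runif(length(npm1)) <
      ifelse(sub[npm1] == 1L, enrichment[1], enrichment[2])
    data.frame(patient = patient_ids, molecular_class = cls,
               npm1_subgroup = sub, cohesin_dd_mut = flag,
               stringsAsFactors = FALSE)
  })
}

# Lorentzian lineshape, unit height at the center, half-width hw (ppm).
lorentz <- function(delta, hw = 0.004) hw^2 / (delta^2 + hw^2)

# Deterministic biofluid background peak set (part of the stated world,
# independent of the cohort seed): 25 uninformative metabolite peaks.
background_peaks <- function(biofluid) {
  with_seed(derive_seed(20260909L, paste0("bg_", biofluid)), {
    data.frame(ppm = stats::runif(25, 0.6, 9.0),
               conc = stats::runif(25, 0.5, 2))
  })
}

# Positions used to plant molecular-class and NPM1-subgroup structure in
# serum (class markers) and urine.
class_marker_positions <- function(biofluid) {
  if (biofluid == "serum") {
    list(NPM1 = c(1.48, 3.25), chromatin_spliceosome = c(2.14, 3.77),
         TP53_aneuploid = c(0.72, 6.90))
  } else {
    list(NPM1 = c(1.92), chromatin_spliceosome = c(3.22),
         TP53_aneuploid = c(6.55))
  }
}

# Serum markers of NPM1 subgroup 1, all elevated: choline +
# trimethylamine-N-oxide, leucine, and the combined leucine + lysine
# envelope.
subgroup_marker_positions <- function() {
  c(choline_tmao = 3.21, leucine = 0.96, leucine_lysine = 1.70)
}

#' Generate paired serum and urine NMR cohorts
#'
#' Each spectrum is a flat baseline plus a sum of Lorentzian peaks (half
#' width 0.004 ppm), plus Gaussian noise and a per-sample global
#' chemical-shift jitter. Class-dependent peak concentrations follow
#' `control_mean * magnitude^(+/- effect_scale)` with the sign given by the
#' packaged effect direction. Serum and urine spectra of a patient share a
#' patient key; blast percentages are drawn for AML samples (bone marrow
#' blasts uniform on \[20, 100\] so all three blast classes are populated).
#'
#' When `labeling` is supplied, molecular-class marker peaks are planted per
#' class in both biofluids, and NPM1 subgroup 1 additionally receives
#' elevated serum choline + trimethylamine-N-oxide and leucine.
#'
#' @param config [cohort_config()].
#' @param effects effect table as from [aml_biofluid_effects()].
#' @param labeling optional data.frame from [generate_molecular_labeling()].
#' @return list with `serum`, `urine` (each a `spectral_matrix`) and
#'   `metadata` (one row per patient).
#' @export
generate_biofluid_cohort <- function(config = cohort_config(),
                                     effects = aml_biofluid_effects(),
                                     labeling = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!all(effects$biofluid %in% c("serum", "urine")))
    stop2("effect references a biofluid that is not generated")
  ppm_axis <- seq(9.5, 0.5, by = -0.002)
  if (any(effects$ppm < min(ppm_axis) | effects$ppm > max(ppm_axis)))
    stop2("effect ppm position outside the acquisition window")
  n <- config$n_aml + config$n_ctrl
  status <- c(rep("AML", config$n_aml), rep("CTRL", config$n_ctrl))
  with_seed(derive_seed(config$seed, "biofluid"), {
    patient <- sprintf("P%04d", seq_len(n))
    meta <- data.frame(
      patient = patient, status = status,
      age = round(ifelse(status == "AML", stats::runif(n, 18, 90),
                         stats::runif(n, 23, 75))),
      gender = sample(c("F", "M"), n, replace = TRUE),
      blast_bm = ifelse(status == "AML", stats::runif(n, 20, 100), NA),
      blast_pb = ifelse(status == "AML", stats::runif(n, 0, 100), NA),
      timepoint = ifelse(status == "AML" & stats::runif(n) < 0.25,
                         "relapse", "diagnosis"),
      stringsAsFactors = FALSE)
    make_fluid <- function(biofluid) {
      eff <- effects[effects$biofluid == biofluid, , drop = FALSE]
      bg <- background_peaks(biofluid)
      markers <- class_marker_positions(biofluid)
      X <- matrix(0, n, length(ppm_axis))
      jitter <- stats::rnorm(n, 0, config$peak_jitter_ppm)
      for (i in seq_len(n)) {
        centers <- c(eff$ppm, bg$ppm)
        eff_conc <- if (status[i] == "AML") {
          eff$magnitude^(config$effect_scale *
                           ifelse(eff$direction == "up", 1, -1))
        } else rep(1, nrow(eff))
        mean_conc <- c(eff_conc, bg$conc)
        if (!is.null(labeling) && status[i] == "AML") {
          lab <- labeling[labeling$patient == patient[i], ]
          if (nrow(lab) == 1 && lab$molecular_class %in% names(markers)) {
            mk <- markers[[lab$molecular_class]]
            centers <- c(centers, mk)
            mean_conc <- c(mean_conc,
                           rep(1.8^config$effect_scale, length(mk)))
          }
          if (biofluid == "serum" && nrow(lab) == 1 &&
              !is.na(lab$npm1_subgroup) && lab$npm1_subgroup == 1L) {
            sg <- subgroup_marker_positions()
            centers <- c(centers, sg)
            mean_conc <- c(mean_conc, rep(2^config$effect_scale, length(sg)))
          }
        }
        conc <- mean_conc * exp(stats::rnorm(length(centers), 0, 0.2))
        spec <- rep(0.01, length(ppm_axis))
        for (k in seq_along(centers)) {
          spec <- spec + conc[k] * lorentz(ppm_axis - centers[k] - jitter[i])
        }
        X[i, ] <- spec + stats::rnorm(length(ppm_axis), 0, config$noise_sd)
      }
      rownames(X) <- patient
      spectral_matrix(X, ppm_axis, cbind(meta, biofluid = biofluid))
    }
    list(serum = make_fluid("serum"), urine = make_fluid("urine"),
         metadata = meta)
  })
}

# The 15 cluster-discriminating metabolites (amino acids and derivatives,
# purine/pyrimidine intermediates, lipids) graded high/intermediate/low
# across the three clusters.
cluster_panel <- function() {
  data.frame(
    metabolite = c("tyrosine", "n_acetylalanine", "phenylalanine",
                   "tryptophan", "threonine", "lysine",
                   "hypoxanthine", "amp", "uridine",
                   "palmitoyl_sphingomyelin", "phosphatidylinositol",
                   "phosphatidylethanolamine", "phosphatidylcholine",
                   "cholesterol", "phosphatidylserine"),
    superpathway = c(rep("amino_acid", 6), rep("nucleotide", 3),
                     rep("lipid", 6)),
    stringsAsFactors = FALSE)
}

#' Generate a clustered intracellular metabolite table
#'
#' Log-normal area-under-curve intensities for `n_aml` leukemic samples over
#' a panel of 15 cluster-discriminating metabolites (graded
#' high/intermediate/low across clusters on the log scale) plus
#' uninformative background metabolites. When `class_assoc` labeling is
#' given, planted clusters are drawn conditioned on the molecular class so
#' cluster-genotype association is recoverable downstream. A DNA-content
#' column is emitted and missing values are injected at the configured rate.
#'
#' @param config [cohort_config()].
#' @param k_clusters number of planted clusters (default 3).
#' @param class_assoc optional labeling from [generate_molecular_labeling()].
#' @param shift log-scale separation between adjacent cluster grades for
#'   the 15-metabolite panel (default 3; calibrated once to the documented
#'   recovery targets).
#' @param n_secondary number of secondary discriminating metabolites
#'   carrying 40 percent of the panel shift (default 30): cluster
#'   differences in real profiles extend beyond the top-scoring panel.
#' @param n_background number of uninformative metabolites (default 30).
#' @return A `metabolite_table` with attribute `planted_cluster`.
#' @export
generate_intracellular_table <- function(config = cohort_config(),
                                         k_clusters = 3L,
                                         class_assoc = NULL,
                                         shift = 3,
                                         n_secondary = 30L,
                                         n_background = 30L) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is_count(k_clusters)) stop2("k_clusters must be >= 1")
  if (config$missing_rate >= 1) stop2("missing_rate must be < 1")
  n <- config$n_aml
  panel <- cluster_panel()
  with_seed(derive_seed(config$seed, "intracellular"), {
    ids <- if (!is.null(class_assoc)) {
      class_assoc$patient[seq_len(min(n, nrow(class_assoc)))]
    } else sprintf("P%04d", seq_len(n))
    n <- length(ids)
    if (is.null(class_assoc)) {
      cl <- sample.int(k_clusters, n, replace = TRUE)
    } else {
      probs <- list(NPM1 = c(0.75, 0.15, 0.10),
                    chromatin_spliceosome = c(0.125, 0.75, 0.125),
                    TP53_aneuploid = c(0.10, 0.15, 0.75),
                    other = c(1, 1, 1) / 3)
      cls <- class_assoc$molecular_class[match(ids, class_assoc$patient)]
      cl <- vapply(cls, function(cc) {
        p <- probs[[cc]]
        if (is.null(p) || k_clusters != 3L)
          p <- rep(1 / k_clusters, k_clusters)
        sample.int(k_clusters, 1, prob = p)
      }, integer(1))
    }
    # grades: cluster 1 high (+1), middle clusters 0, last low (-1)
    grade <- seq(1, -1, length.out = k_clusters)
    met_names <- c(panel$metabolite,
                   sprintf("sec_metab_%03d", seq_len(n_secondary)),
                   sprintf("bg_metab_%03d", seq_len(n_background)))
    base_log <- stats::runif(length(met_names), 12, 18)  # log AUC scale
    X <- matrix(stats::rnorm(n * length(met_names), 0, 0.5), n,
                dimnames = list(ids, met_names))
    X <- sweep(X, 2, base_log, "+")
    eff <- config$effect_scale * shift
    for (j in seq_len(nrow(panel))) {
      X[, j] <- X[, j] + eff * grade[cl]
    }
    for (j in seq_len(n_secondary)) {
      # secondary discriminating metabolites: weaker graded shifts with
      # alternating sign so no single direction dominates
      sgn <- if (j %% 2 == 0) 1 else -1
      X[, nrow(panel) + j] <- X[, nrow(panel) + j] +
        sgn * 0.4 * eff * grade[cl]
    }
    intens <- exp(X)
    dna <- exp(stats::rnorm(n, log(100), 0.3))
    if (config$missing_rate > 0) {
      # left-censored missingness: each metabolite's lowest values fall
      # below the detection limit, the mechanism half-minimum imputation
      # is designed for
      for (j in seq_len(ncol(intens))) {
        lod <- stats::quantile(intens[, j], config$missing_rate)
        intens[intens[, j] < lod, j] <- NA
      }
    }
    sec_paths <- rep_len(c("amino_acid", "nucleotide", "lipid"),
                         n_secondary)
    annotation <- data.frame(
      metabolite = met_names,
      superpathway = c(panel$superpathway, sec_paths,
                       rep("background", n_background)),
      subpathway = c(panel$superpathway, sec_paths,
                     rep("background", n_background)),
      stringsAsFactors = FALSE)
    tab <- metabolite_table(intens, dna_content = dna,
                            annotation = annotation,
                            groups = rep("AML", n))
    attr(tab, "planted_cluster") <- stats::setNames(cl, ids)
    tab
  })
}

#' Generate a two-group expression table with a planted downregulated set
#'
#' Log-normal expression for two groups; group B expression of the
#' designated gene set equals group A times `fold` (multiplicative noise on
#' both), all other genes exchangeable between groups.
#'
#' @param genes character vector of gene ids.
#' @param down_set subset of `genes` downregulated in group B.
#' @param n_per_group samples per group (default 20).
#' @param fold group-B/group-A ratio for the down set, in (0, 1)
#'   (default 0.25).
#' @param seed integer seed.
#' @return list with `expression` (gene x sample matrix) and `groups`.
#' @export
generate_expression_groups <- function(genes, down_set = character(0),
                                       n_per_group = 20L, fold = 0.25,
                                       seed = 1L) {
  if (!length(genes)) stop2("empty gene list")
  if (!all(down_set %in% genes)) stop2("down_set must be a subset of genes")
  if (fold <= 0 || fold > 1) stop2("fold must lie in (0, 1]")
  with_seed(derive_seed(seed, "expression"), {
    n <- 2L * n_per_group
    base <- stats::runif(length(genes), 4, 10)  # log2 expression level
    logx <- matrix(stats::rnorm(length(genes) * n, 0, 0.4),
                   length(genes), n,
                   dimnames = list(genes,
                                   c(sprintf("A%02d", seq_len(n_per_group)),
                                     sprintf("B%02d", seq_len(n_per_group)))))
    logx <- sweep(logx, 1, base, "+")
    groups <- rep(c("A", "B"), each = n_per_group)
    if (length(down_set)) {
      logx[down_set, groups == "B"] <-
        logx[down_set, groups == "B"] + log2(fold)
    }
    list(expression = 2^logx, groups = groups)
  })
}
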