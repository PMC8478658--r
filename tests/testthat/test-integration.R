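# Integration module: component selection, biofluid joining, clustering,
# cluster-genotype association, subgroup enrichment, feature ranking.

test_that("genomic-guided selection finds planted components and provenance", {
  amlmetab:::with_seed(9, {
    n <- 90
    cls <- rep(c("NPM1", "chromatin_spliceosome", "TP53_aneuploid"),
               each = n / 3)
    lab <- data.frame(patient = sprintf("P%04d", 1:n),
                      molecular_class = cls)
    # single informative serum component dominates
    sm1 <- fake_latent(genomic_score_fixture(n, cls, 1, 4))
    um1 <- fake_latent(genomic_score_fixture(n, cls, 0, 3))
    sel1 <- score_components_by_genomic_signal(sm1, um1, lab, seed = 2)
    expect_equal(sel1$component[1], "serum_C1")
    # pure-noise components score ~0
    noise_scores <- sel1$score[sel1$component != "serum_C1"]
    expect_true(all(abs(noise_scores) < 0.15))
    # 7 serum + 3 urine informative -> provenance counts recovered in top 10
    sm <- fake_latent(genomic_score_fixture(n, cls, 7, 3))
    um <- fake_latent(genomic_score_fixture(n, cls, 3, 3))
    sel <- score_components_by_genomic_signal(sm, um, lab, seed = 2)
    top10 <- sel[1:10, ]
    expect_equal(as.integer(table(top10$biofluid)[c("serum", "urine")]),
                 c(7L, 3L))
    expect_true(all(top10$index[top10$biofluid == "serum"] %in% 1:7))
    expect_true(all(top10$index[top10$biofluid == "urine"] %in% 1:3))
  })
})

test_that("biofluid integration joins on patients and standardizes", {
  s <- matrix(rnorm(20), 10, 2,
              dimnames = list(sprintf("P%02d", 1:10), c("C1", "C2")))
  u <- matrix(rnorm(16), 8, 2,
              dimnames = list(sprintf("P%02d", 3:10), c("C1", "C2")))
  X <- integrate_biofluid_components(s, u)
  expect_equal(rownames(X), sprintf("P%02d", 3:10))
  expect_true(all(abs(colMeans(X)) < 1e-10))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 1e-10))
  expect_equal(attr(X, "provenance")$biofluid,
               c("serum", "serum", "urine", "urine"))
  sel <- integrate_biofluid_components(s, u, selection = c("serum_C2",
                                                           "urine_C1"))
  expect_equal(colnames(sel), c("serum_C2", "urine_C1"))
  # disjoint patients -> error; single shared patient -> one row
  u_dis <- u; rownames(u_dis) <- sprintf("Q%02d", 1:8)
  expect_error(integrate_biofluid_components(s, u_dis), "no shared")
  u_one <- u[1, , drop = FALSE]; rownames(u_one) <- "P01"
  expect_equal(nrow(integrate_biofluid_components(s, u_one)), 1)
  expect_error(integrate_biofluid_components(s, u, selection = "serum_C9"),
               "unknown")
})

test_that("hierarchical clustering: blobs, k=1, permutation invariance", {
  amlmetab:::with_seed(10, {
    centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
    X <- do.call(rbind, lapply(1:3, function(k) {
      sweep(matrix(rnorm(40), 20, 2), 2, centers[k, ], "+")
    }))
    rownames(X) <- sprintf("S%02d", 1:60)
    truth <- rep(1:3, each = 20)
    hc <- hierarchical_cluster(X, k = 3)
    expect_equal(adjusted_rand_index(hc$cluster, truth), 1)
    expect_equal(unique(hierarchical_cluster(X, k = 1)$cluster), 1L)
    # sample-order permutation leaves the partition unchanged
    perm <- sample.int(60)
    hc_p <- hierarchical_cluster(X[perm, ], k = 3)
    expect_equal(adjusted_rand_index(hc_p$cluster[rownames(X)],
                                     hc$cluster), 1)
    # cluster ids are ordered by decreasing size
    hc_sz <- hierarchical_cluster(X[1:50, ], k = 3)
    sizes <- table(hc_sz$cluster)
    expect_true(all(diff(as.numeric(sizes)) <= 0))
    expect_error(hierarchical_cluster(X, k = 61), "exceeds")
  })
})

test_that("cluster-class association: extremes, calibration, 2x2 collapse", {
  patients <- sprintf("P%03d", 1:60)
  labels <- data.frame(patient = patients,
                       molecular_class = rep(c("NPM1", "TP53_aneuploid"),
                                             each = 30))
  perfect <- list(cluster = stats::setNames(rep(1:2, each = 30), patients))
  a_perf <- associate_clusters_with_molecular_classes(perfect, labels,
                                                      B = 1e4, seed = 1)
  expect_lt(a_perf$test$p_value, 2 / 1e4)   # ~1/(B+1), minimum attainable
  expect_equal(a_perf$enrichment$fraction, c(1, 1))
  # 2x2 collapse agrees with the exact Fisher oracle within MC error
  mixed <- list(cluster = stats::setNames(c(rep(1, 20), rep(2, 10),
                                            rep(1, 8), rep(2, 22)),
                                          patients))
  a_mix <- associate_clusters_with_molecular_classes(mixed, labels,
                                                     B = 2e5, seed = 2)
  exact <- exact_fisher_2x2(unclass(a_mix$table))$p_value
  se <- sqrt(exact * (1 - exact) / 2e5)
  expect_lt(abs(a_mix$test$p_value - exact), 3 * se)
  # degenerate single class: warning and p = 1
  labels1 <- labels; labels1$molecular_class <- "NPM1"
  expect_warning(a1 <- associate_clusters_with_molecular_classes(
    mixed, labels1, B = 1e3), "one molecular class")
  expect_equal(a1$test$p_value, 1)
})

test_that("association p-values are calibrated under random labels", {
  amlmetab:::with_seed(13, {
    patients <- sprintf("P%03d", 1:60)
    cl <- list(cluster = stats::setNames(rep(1:3, each = 20), patients))
    ps <- replicate(60, {
      labels <- data.frame(patient = patients,
                           molecular_class = sample(c("NPM1", "chrspl",
                                                      "TP53"), 60, TRUE))
      associate_clusters_with_molecular_classes(cl, labels, B = 2000,
                                                seed = sample.int(1e6, 1)
                                                )$test$p_value
    })
    # uniformity not rejected at the 1% level (Monte Carlo p-values are
    # discrete, so ties are expected and the KS p is conservative)
    expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  })
})

test_that("subgroup enrichment reproduces the worked 60.0%/9.1% table", {
  subgroup <- c(rep(1, 10), rep(2, 11))
  flag <- c(rep(TRUE, 6), rep(FALSE, 4), TRUE, rep(FALSE, 10))
  res <- subgroup_enrichment_test(subgroup, flag)
  expect_equal(unname(res$percent), c(60.0, 100 * 1 / 11), tolerance = 1e-9)
  expect_equal(res$test$p_value, 8372 / 352716, tolerance = 1e-9)
  expect_equal(round(res$test$p_value, 3), 0.024)
  # swapping subgroup order leaves p unchanged
  res_sw <- subgroup_enrichment_test(3 - subgroup, flag)
  expect_equal(res_sw$test$p_value, res$test$p_value)
  # constant flag: p = 1
  expect_equal(subgroup_enrichment_test(subgroup,
                                        rep(TRUE, 21))$test$p_value, 1)
  expect_error(subgroup_enrichment_test(rep(1, 10), rep(TRUE, 10)),
               "2 subgroups")
})

test_that("npm1 subgroup split recovers a planted bimodal component", {
  amlmetab:::with_seed(14, {
    n <- 40
    scores <- matrix(rnorm(n * 4), n,
                     dimnames = list(sprintf("P%02d", 1:n),
                                     paste0("C", 1:4)))
    truth <- rep(1:2, each = n / 2)
    scores[, 3] <- scores[, 3] + ifelse(truth == 1, 4, -4)
    sp <- npm1_subgroup_split(scores)
    expect_equal(sp$component, "C3")
    expect_equal(adjusted_rand_index(sp$subgroup, truth), 1)
    # orientation: subgroup 1 has the higher marker mean
    marker <- stats::setNames(ifelse(truth == 1, 10, 1) + rnorm(n, 0, 0.1),
                              rownames(scores))
    sp_or <- npm1_subgroup_split(scores, orient_by = marker)
    expect_true(mean(marker[sp_or$subgroup == 1]) >
                  mean(marker[sp_or$subgroup == 2]))
    expect_error(npm1_subgroup_split(scores[1:3, ]), "too few")
  })
})

test_that("cluster-discriminating ranking: planted feature first, monotone p", {
  amlmetab:::with_seed(15, {
    n <- 45
    X <- matrix(rnorm(n * 12), n,
                dimnames = list(sprintf("S%02d", 1:n),
                                sprintf("f%02d", 1:12)))
    cl <- stats::setNames(rep(1:3, each = 15), rownames(X))
    X[cl == 2, 5] <- X[cl == 2, 5] + 3  # one feature shifted in one cluster
    rk <- rank_cluster_discriminating_metabolites(X, cl)
    expect_equal(rk$feature[1], "f05")
    expect_true(all(rk$adjusted_p >= rk$p - 1e-12))
    # exchangeable features: no adjusted significance expected
    X0 <- matrix(rnorm(n * 12), n, dimnames = dimnames(X))
    rk0 <- rank_cluster_discriminating_metabolites(X0, cl)
    expect_equal(sum(rk0$adjusted_p <= 0.05), 0)
    expect_error(rank_cluster_discriminating_metabolites(
      X, stats::setNames(rep(1, n), rownames(X))), "2 clusters")
  })
})
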