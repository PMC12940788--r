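# Preprocessing, region comparisons, correlation map, Ward clustering,
# ARI, k selection, bootstrap stability, PCA, PD-L1/TLS scoring, IMP
# naming.

test_that("preprocessing applies log1p then standardization", {
  m <- cbind(a = c(0, exp(1) - 1, 3, 9), b = c(1, 2, 3, 4))
  rownames(m) <- paste0("P", 1:4)
  out <- preprocess_densities(m)
  expect_equal(unname(attr(out, "center")[1] + out[1:2, 1] *
                        attr(out, "scale")[1]), c(0, 1))
  expect_equal(unname(colMeans(out)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(out, 2, stats::var)), c(1, 1),
               tolerance = 1e-12)
})

test_that("constant features are scaled by 1 with a warning, not dropped", {
  m <- cbind(a = c(2, 2, 2), b = c(1, 5, 9))
  rownames(m) <- paste0("P", 1:3)
  expect_warning(out <- preprocess_densities(m), "constant")
  expect_true(all(is.finite(out)))
  expect_equal(unname(out[, "a"]), c(0, 0, 0))
})

test_that("patients missing too many cores are excluded, gaps imputed", {
  m <- matrix(stats::rlnorm(40), 4, 10,
              dimnames = list(paste0("P", 1:4), paste0("f", 1:10)))
  m[1, 1:6] <- NA          # 60% missing -> excluded
  m[2, 1] <- NA            # imputed
  out <- preprocess_densities(m)
  expect_equal(attr(out, "excluded"), "P1")
  expect_equal(nrow(out), 3)
  expect_false(anyNA(out))
})

test_that("identical central and peripheral columns yield p = 1", {
  co <- tiny_cohort(seed = 1, n = 10, include = "densities")
  d <- co$densities
  d[paste0(chs_markers(), "_peripheral")] <-
    d[paste0(chs_markers(), "_central")]
  res <- compare_regions(d)
  expect_true(all(res$p == 1))
  expect_true(all(res$direction == "none"))
})

test_that("region comparison statistic matches the hand signed-rank oracle", {
  central <- c(10, 22, 9, 41, 17, 30)
  peripheral <- c(14, 20, 15, 60, 18, 33)
  d <- data.frame(patient_id = paste0("P", 1:6), subtype = "G1")
  for (mk in chs_markers()) {
    d[[paste0(mk, "_central")]] <- central
    d[[paste0(mk, "_peripheral")]] <- peripheral
  }
  res <- compare_regions(d)
  expect_equal(res$statistic[1],
               oracle_signed_rank_stat(peripheral - central))
})

test_that("CD45 and companion markers are denser at the periphery (q < 0.05)", {
  co <- generate_cohort(generator_config(seed = 21), include = "densities")
  res <- compare_regions(co$densities)
  for (mk in c("CD45", "CD3", "CD4", "PD1", "CD141")) {
    row <- res[res$marker == mk, ]
    expect_equal(row$direction, "peripheral")
    expect_lt(row$q, 0.05)
  }
})

test_that("Spearman map honours monotone transforms and sign", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5)
  m <- cbind(a = x, b = 2 * x + 1, c = -x)
  cm <- correlation_map(m)
  expect_equal(cm$rho["a", "b"], 1)
  expect_equal(cm$rho["a", "c"], -1)
  expect_equal(diag(cm$rho), rep(1, 3), ignore_attr = TRUE)
})

test_that("tied vectors use midranks (direct computation oracle)", {
  x <- c(1, 2, 2, 3, 5)
  y <- c(2, 2, 4, 4, 7)
  cm <- correlation_map(cbind(a = x, b = y, c = stats::rnorm(5)))
  expect_equal(cm$rho["a", "b"], oracle_spearman_midrank(x, y),
               tolerance = 1e-12)
})

test_that("BH q-values are monotone in p-rank order and never below p", {
  co <- tiny_cohort(seed = 7, n = 40, include = "densities")
  cm <- correlation_map(co$densities)
  ut <- upper.tri(cm$p)
  p <- cm$p[ut]; q <- cm$q[ut]
  keep <- !is.na(p)
  ord <- order(p[keep])
  expect_true(all(diff(q[keep][ord]) >= -1e-12))
  expect_true(all(q[keep] >= p[keep] - 1e-12))
})

test_that("Ward clustering separates well-separated clouds and handles edges", {
  x <- blob_features(n_per = 15)
  wc <- ward_cluster(x, 3)
  expect_equal(adjusted_rand_index(wc$labels, attr(x, "truth")), 1)
  expect_equal(length(unique(ward_cluster(x, nrow(x))$labels)), nrow(x))
  expect_error(ward_cluster(x, nrow(x) + 1), "exceeds")
})

test_that("Ward merges match the exhaustive-agglomeration oracle", {
  for (s in 1:10) {
    set.seed(100 + s)
    x <- matrix(stats::rnorm(14), 7, 2)
    oracle <- oracle_ward_partitions(x)
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    for (k in 2:6)
      expect_equal(adjusted_rand_index(stats::cutree(hc, k),
                                       oracle[[as.character(k)]]), 1)
  }
})

test_that("ARI matches hand contingency value and pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 3), c(1, 1, 2, 3)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 3), c(2, 2, 3, 1)), 1)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
  set.seed(7)
  for (i in 1:8) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari_paircount(a, b),
                 tolerance = 1e-12)
  }
  if (requireNamespace("mclust", quietly = TRUE)) {
    set.seed(8)
    a <- sample(1:3, 30, TRUE); b <- sample(1:3, 30, TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("index vote finds k = 3 on three separated clusters", {
  x <- blob_features(n_per = 20)
  sel <- select_k(x, gap_B = 20)
  expect_equal(sel$k, 3)
})

test_that("a single Gaussian blob yields no cluster consensus; gap picks k_min", {
  # on structureless data most raw validity indices drift towards large
  # k; the gap statistic, built for the null case, nominates k_min, and
  # no k wins an absolute majority of the panel
  set.seed(31)
  x <- matrix(stats::rnorm(120), 60, 2)
  sel <- select_k(x, gap_B = 20)
  expect_equal(unname(sel$votes["gap"]), 2)
  expect_lt(max(table(sel$votes)), length(sel$votes) / 2 + 1)
})

test_that("default synthetic cohort clusters into three phenotypes", {
  co <- generate_cohort(generator_config(seed = 17), include = "densities")
  fit <- fit_immunophenotypes(co$densities)
  expect_equal(fit$k, 3)
  expect_gt(adjusted_rand_index(fit$imp, co$truth$patients$imp), 0.7)
})

test_that("bootstrap stability is 1 for perfectly separated clusters", {
  co <- tiny_cohort(seed = 2, n = 24, include = "densities")
  d <- co$densities
  # overwrite with three widely separated synthetic profiles
  f <- density_features()
  base <- matrix(stats::rlnorm(24 * 40, 2, 0.05), 24, 40)
  base[1:8, ] <- base[1:8, ] * 400
  base[9:16, ] <- base[9:16, ] * 20
  d[f] <- base
  bs <- bootstrap_stability(d, k = 3, B = 25, seed = 5)
  expect_equal(bs$mean_ari, 1)
  expect_length(bs$ari, 25)
})

test_that("B = 0 gives an empty ARI vector and undefined mean", {
  co <- tiny_cohort(seed = 2, n = 12, include = "densities")
  bs <- bootstrap_stability(co$densities, k = 3, B = 0)
  expect_length(bs$ari, 0)
  expect_true(is.na(bs$mean_ari))
})

test_that("structureless data is unstable while real structure is stable", {
  set.seed(41)
  f <- density_features()
  d <- data.frame(patient_id = sprintf("U%02d", 1:60), subtype = "G1")
  d[f] <- matrix(stats::runif(60 * 40, 0, 100), 60)
  d$pdl1_percent <- 0; d$tls_cd3 <- d$tls_cd20 <- d$tls_lamp3 <- FALSE
  unstructured <- bootstrap_stability(d, k = 3, B = 40, seed = 6)
  expect_lt(unstructured$mean_ari, 0.3)
  co <- generate_cohort(generator_config(seed = 18), include = "densities")
  structured <- bootstrap_stability(co$densities, k = 3, B = 40, seed = 6)
  expect_gt(structured$mean_ari, unstructured$mean_ari)
})

test_that("PCA matches the brute-force eigendecomposition on a toy matrix", {
  x <- matrix(c(1, 2, 0, 4, 3, 3, 7, 1, 2, 9, 4, 6), 4, 3)
  pc <- pca_contributions(x)
  ev <- eigen(stats::cov(x))
  expect_equal(pc$explained_variance, ev$values / sum(ev$values),
               tolerance = 1e-10)
  for (j in 1:3)
    expect_equal(abs(pc$loadings[, j]), abs(ev$vectors[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: dominant loading positive
  for (j in 1:3)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
})

test_that("collinear data puts all variance on the first component", {
  t <- stats::rnorm(20)
  x <- cbind(t, 2 * t, -t)
  pc <- pca_contributions(x)
  expect_equal(pc$explained_variance[1], 1, tolerance = 1e-12)
  expect_equal(sum(pc$explained_variance), 1, tolerance = 1e-12)
  expect_error(pca_contributions(x[1, , drop = FALSE]), "at least 2")
})

test_that("PD-L1 ordinal scoring follows the 1%/30% cut points", {
  expect_identical(score_pdl1(c(0, 0.5, 1, 29.9, 30, 100)),
                   c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_error(score_pdl1(-1), "0, 100")
  expect_error(score_pdl1(101), "0, 100")
})

test_that("TLS requires all three components", {
  expect_true(call_tls(TRUE, TRUE, TRUE))
  expect_false(call_tls(TRUE, TRUE, FALSE))
  expect_false(call_tls(FALSE, FALSE, FALSE))
  expect_equal(call_tls(c(TRUE, TRUE), c(TRUE, FALSE), c(TRUE, TRUE)),
               c(TRUE, FALSE))
})

test_that("clusters are named cold/hot/intermediate by total density", {
  co <- generate_cohort(generator_config(seed = 19), include = "densities")
  fit <- fit_immunophenotypes(co$densities, k = 3)
  tr <- co$truth$patients
  # permutation-correct naming: the dominant truth label in each named
  # group is the same phenotype
  for (imp in imp_levels()) {
    grp <- names(fit$imp)[fit$imp == imp]
    truth_mode <- names(which.max(table(tr$imp[match(grp,
                                                     tr$patient_id)])))
    expect_equal(truth_mode, imp)
  }
})

test_that("non-three cluster counts fall back to generic ordered names", {
  co <- tiny_cohort(seed = 5, n = 16, include = "densities")
  feat <- preprocess_densities(co$densities)
  wc <- ward_cluster(feat, 2)
  expect_warning(nm <- name_imps(wc$labels, co$densities), "generically")
  expect_setequal(unique(nm$imp), c("IMP1", "IMP2"))
  tot <- rowSums(density_matrix(co$densities), na.rm = TRUE)
  expect_lt(mean(tot[nm$imp == "IMP1"]), mean(tot[nm$imp == "IMP2"]))
})

test_that("assigned phenotypes recover the latent labels across seeds", {
  ari <- vapply(101:110, function(s) {
    co <- generate_cohort(generator_config(seed = s),
                          include = "densities")
    fit <- suppressWarnings(fit_immunophenotypes(co$densities))
    adjusted_rand_index(fit$imp, co$truth$patients$imp)
  }, numeric(1))
  expect_gte(mean(ari > 0.7), 0.9)
})
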