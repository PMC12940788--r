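# Generator: determinism, configuration validation, composition,
# ground-truth accounting, density structure, survival calibration.

test_that("fixed seed reproduces the cohort bit for bit", {
  a <- generate_cohort(generator_config(n_patients = 12, seed = 5))
  b <- generate_cohort(generator_config(n_patients = 12, seed = 5))
  expect_identical(a, b)
})

test_that("omitting a component leaves the other components' draws unchanged", {
  full <- generate_cohort(generator_config(n_patients = 15, seed = 2))
  surv_only <- generate_cohort(generator_config(n_patients = 15, seed = 2),
                               include = "survival")
  expect_identical(full$clinical$os_months, surv_only$clinical$os_months)
  expect_identical(full$truth$patients$imp, surv_only$truth$patients$imp)
  expect_null(surv_only$densities)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(generator_config(n_patients = 1), "n_patients")
  expect_error(generator_config(censoring_rate = 1.4), "censoring_rate")
  expect_error(generator_config(panel_size_mb = 0), "panel_size_mb")
  expect_error(generator_config(
    subtype_proportions = c(G1 = 0.5, G2 = 0.5, G3 = 0.2, DD = -0.2)),
    "subtype_proportions")
  expect_error(generator_config(
    subtype_survival_anchors = c(G1 = 1, G2 = .7, G3 = .4, DD = .1)),
    "anchors")
})

test_that("subtype composition follows the configured 28/37/24/10 mix", {
  counts <- table(factor(generate_cohort(generator_config(seed = 11),
                                         include = "survival")
                         $clinical$subtype, chs_subtypes()))
  expected <- c(28, 37, 24, 10)
  # within multinomial 99-draw variation (4 sd)
  sds <- sqrt(99 * (expected / 99) * (1 - expected / 99))
  expect_true(all(abs(counts - expected) <= 4 * sds))
})

test_that("forced phenotype assignment is honoured", {
  m <- matrix(c(0, 1, 0), 4, 3, byrow = TRUE,
              dimnames = list(chs_subtypes(), imp_levels()))
  co <- generate_cohort(generator_config(n_patients = 2,
                                         imp_given_subtype = m, seed = 1),
                        include = "survival")
  expect_equal(nrow(co$clinical), 2)
  expect_equal(co$truth$patients$imp, c("IMP2", "IMP2"))
})

test_that("injected record count = true variants + contaminants, per sample", {
  co <- tiny_cohort(seed = 3, n = 20)
  for (id in co$clinical$patient_id) {
    expect_equal(nrow(co$callers[[id]]$ts),
                 nrow(co$truth$variants[[id]]) +
                   nrow(co$truth$contaminants[[id]]))
    expect_setequal(variant_key(co$callers[[id]]$gatk),
                    c(variant_key(co$truth$variants[[id]]),
                      variant_key(co$truth$contaminants[[id]])))
  }
})

test_that("every pool-tagged contaminant shares its key with the pool set", {
  co <- tiny_cohort(seed = 4, n = 15)
  pool_keys <- variant_key(co$pool)
  for (id in co$clinical$patient_id) {
    cont <- co$truth$contaminants[[id]]
    expect_true(all(variant_key(cont[cont$stage == "pool", ]) %in%
                      pool_keys))
    expect_false(any(variant_key(cont[cont$stage != "pool", ]) %in%
                       pool_keys))
  }
})

test_that("retained-variant count distribution has median 4 (brute force)", {
  cfg <- generator_config()
  # brute-force the configured distribution: driver flags + NB background
  set.seed(99)
  M <- 2e5
  p <- cfg$gene_freqs
  nd <- rowSums(matrix(stats::rbinom(M * length(p), 1, rep(p, each = M)),
                       M))
  bg <- stats::rnbinom(M, size = cfg$final_variant_count_dist$size,
                       mu = cfg$final_variant_count_dist$mu)
  expect_equal(stats::median(nd + bg), 4)
  # a cohort draw agrees with the configured distribution
  co <- generate_cohort(generator_config(seed = 8))
  counts <- vapply(co$truth$variants, nrow, integer(1))
  expect_true(abs(stats::median(counts) - 4) <= 1)
})

test_that("a patient with no mutated genes and no contaminants yields empty sets", {
  pool <- data.frame(chrom = "1", pos = 1000L, ref = "A", alt = "C",
                     gene = "TP53", stringsAsFactors = FALSE)
  vc <- generate_variant_calls(character(), 0, pool,
                               generator_config(contaminants_per_class = 0))
  expect_equal(nrow(vc$ts), 0)
  expect_equal(nrow(vc$gatk), 0)
  expect_equal(nrow(vc$ir), 0)
})

test_that("cohort IDH1/2 frequency matches the configured 41% marginal", {
  f <- vapply(1:25, function(s) {
    tr <- generate_cohort(generator_config(seed = s),
                          include = "survival")$truth$patients
    mean(tr[, "IDH1"] | tr[, "IDH2"])
  }, numeric(1))
  expect_lt(abs(mean(f) - 0.41), 0.04)
})

# --- marker densities ------------------------------------------------------

test_that("density ordering IMP2 > IMP3 > IMP1 holds in every default draw", {
  for (s in 1:5) {
    co <- generate_cohort(generator_config(seed = s),
                          include = "densities")
    tot <- rowSums(density_matrix(co$densities), na.rm = TRUE)
    mt <- tapply(tot, co$truth$patients$imp, mean)
    expect_true(mt[["IMP2"]] > mt[["IMP3"]] &&
                  mt[["IMP3"]] > mt[["IMP1"]])
  }
})

test_that("zero noise variance collapses densities to phenotype means", {
  m <- matrix(c(1, 0, 0), 4, 3, byrow = TRUE,
              dimnames = list(chs_subtypes(), imp_levels()))
  cfg <- generator_config(n_patients = 3, density_noise_sd = 0,
                          core_dropout = 0, imp_given_subtype = m,
                          seed = 2)
  co <- generate_cohort(cfg, include = "densities")
  mu <- chsprofiler:::density_log_means("IMP1")
  for (f in names(mu))
    expect_equal(unname(co$densities[[f]]), rep(exp(mu[[f]]), 3),
                 tolerance = 1e-12)
})

test_that("cold-phenotype patients never express PD-L1 and never carry TLS", {
  co <- generate_cohort(generator_config(seed = 6), include = "densities")
  imp1 <- co$truth$patients$imp == "IMP1"
  expect_true(all(co$densities$pdl1_percent[imp1] == 0))
  expect_false(any(call_tls(co$densities$tls_cd3,
                            co$densities$tls_cd20,
                            co$densities$tls_lamp3)[imp1]))
})

test_that("complete TLS triads occur only in G2/G3/DD", {
  hits <- 0
  for (s in 1:4) {
    co <- generate_cohort(generator_config(seed = s),
                          include = "densities")
    tls <- call_tls(co$densities$tls_cd3, co$densities$tls_cd20,
                    co$densities$tls_lamp3)
    expect_false(any(tls[co$densities$subtype == "G1"]))
    hits <- hits + sum(tls)
  }
  expect_gt(hits, 0)
})

test_that("high PD-L1 expression concentrates in DD tumours", {
  co <- generate_cohort(generator_config(n_patients = 400, seed = 9),
                        include = "densities")
  high <- co$densities$pdl1_percent >= 30
  expect_gt(mean(co$densities$subtype[high] == "DD"), 0.5)
})

test_that("central CD68/CD163 TAM densities share a tight latent factor", {
  co <- generate_cohort(generator_config(n_patients = 3000, seed = 10),
                        include = "densities")
  rho <- stats::cor(co$densities$CD68_PGM1_central,
                    co$densities$CD163_central, method = "spearman",
                    use = "complete.obs")
  expect_gt(rho, 0.9)
})

test_that("cold phenotype keeps lymphocytes at the periphery", {
  co <- generate_cohort(generator_config(n_patients = 600, seed = 12),
                        include = "densities")
  imp1 <- co$truth$patients$imp == "IMP1"
  for (mk in c("CD45", "CD3", "CD4", "PD1", "CD141")) {
    expect_gt(mean(log(co$densities[[paste0(mk, "_peripheral")]][imp1]),
                   na.rm = TRUE),
              mean(log(co$densities[[paste0(mk, "_central")]][imp1]),
                   na.rm = TRUE))
  }
})

# --- survival --------------------------------------------------------------

test_that("an anchor of 0.5 calibrates to the closed-form hazard ln(2)/36", {
  cfg <- generator_config(
    true_log_hazards = c(imp2 = 0, imp3 = 0, idh1 = 0, size_per_cm = 0),
    subtype_survival_anchors = c(G1 = .5, G2 = .5, G3 = .5, DD = .5))
  g <- calibrate_baseline_hazards(cfg)
  expect_equal(unname(exp(g)), rep(log(2) / 36, 4), tolerance = 1e-6)
})

test_that("censoring_rate = 0 marks every patient as an event", {
  co <- generate_cohort(generator_config(censoring_rate = 0, seed = 3),
                        include = "survival")
  expect_true(all(co$clinical$os_event == 1))
  expect_equal(co$clinical$os_months, co$truth$patients$true_os_months)
})

test_that("true survival hits the subtype anchors in a large cohort", {
  co <- generate_cohort(generator_config(n_patients = 30000, seed = 13),
                        include = "survival")
  tr <- co$truth$patients
  anchors <- c(G1 = .913, G2 = .773, G3 = .407, DD = .114)
  for (s in chs_subtypes()) {
    emp <- mean(tr$true_os_months[tr$subtype == s] > 36)
    expect_lt(abs(emp - anchors[[s]]), 0.02)
  }
})

test_that("phenotype-stratum 5-year survival emerges near its anchors", {
  co <- generate_cohort(generator_config(n_patients = 30000, seed = 14),
                        include = "survival")
  tr <- co$truth$patients
  anchors <- c(IMP1 = .86, IMP2 = .29, IMP3 = .44)
  for (i in imp_levels()) {
    emp <- mean(tr$true_os_months[tr$imp == i] > 60)
    expect_lt(abs(emp - anchors[[i]]), 0.03)
  }
})
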