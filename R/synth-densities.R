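# Log-normal density model for the 20 IHC markers x 2 tumour regions.
# Structure emulated: a hot/intermediate/cold ordering of total density
# (IMP2 > IMP3 > IMP1); peripheral predominance of CD45/CD3/CD4/PD-1/CD141
# (strongest in the cold phenotype); a macrophage latent factor
# (CD14/CD68/CD163/HLA-DR/Gal-9/TIM-3), a T-cell factor (CD3/CD4/CD8/PD-1),
# and a tight M1/M2 TAM pairing of CD68 and CD163 in the central region.

density_model_params <- function() {
  base <- c(CD45 = 5.0, CD3 = 4.5, CD4 = 4.2, CD8 = 4.0, FOXP3 = 3.0,
            CD20 = 2.8, CD68_PGM1 = 5.5, CD68_KP1 = 5.8, CD163 = 5.8,
            CD14 = 5.8, CD80 = 2.8, HLADR = 6.0, CD1A = 2.5, CD141 = 3.5,
            LAMP3 = 2.3, PD1 = 4.0, TIM3 = 5.3, LAG3 = 2.5, GAL9 = 5.7)
  list(
    base = base,
    # phenotype mean shifts by compartment (log scale). The phenotypes
    # differ in direction, not just level: cold (IMP1) is globally
    # depleted, hot (IMP2) is myeloid/checkpoint-dominated, intermediate
    # (IMP3) is lymphoid-skewed with a near-baseline myeloid compartment;
    # total density still orders IMP2 > IMP3 > IMP1.
    lymphoid_markers = c("CD45", "CD3", "CD4", "CD8", "CD20", "FOXP3",
                         "CD141", "LAMP3", "CD1A"),
    imp_shift_lymphoid = c(IMP1 = -0.7, IMP2 = 0.4, IMP3 = 1.3),
    imp_shift_myeloid = c(IMP1 = -0.9, IMP2 = 1.3, IMP3 = -0.35),
    # markers that sit preferentially at the invasion front
    peripheral_markers = c("CD45", "CD3", "CD4", "PD1", "CD141"),
    peripheral_offset = 0.25,          # all phenotypes
    imp1_central_peripheral_extra = -1.0,  # cold: excluded from the core
    imp1_central_other = -0.3,
    imp2_central_markers = c("HLADR", "CD163", "GAL9", "PD1", "CD8"),
    imp2_central_extra = 0.5,
    macro_markers = c("CD14", "CD68_PGM1", "CD68_KP1", "CD163", "HLADR",
                      "GAL9", "TIM3"),
    macro_loading = 0.55,
    tcell_markers = c("CD3", "CD4", "CD8", "PD1"),
    tcell_loading = 0.50,
    tam_pair = c("CD68_PGM1_central", "CD163_central"),
    tam_pair_loading = 0.75,
    tam_pair_macro_loading = 0.30,
    tam_pair_resid_sd = 0.18)
}

# deterministic (marker, region) log-mean for one phenotype; the values
# zero-variance draws collapse to
density_log_means <- function(imp) {
  p <- density_model_params()
  feats <- setdiff(density_features(), c("PDL1_central", "PDL1_peripheral"))
  mk <- sub("_(central|peripheral)$", "", feats)
  rg <- sub("^.*_", "", feats)
  mu <- p$base[mk] + ifelse(mk %in% p$lymphoid_markers,
                            p$imp_shift_lymphoid[imp],
                            p$imp_shift_myeloid[imp])
  mu <- mu + ifelse(rg == "peripheral" & mk %in% p$peripheral_markers,
                    p$peripheral_offset, 0)
  if (imp == "IMP1") {
    mu <- mu + ifelse(rg == "central",
                      ifelse(mk %in% p$peripheral_markers,
                             p$imp1_central_peripheral_extra,
                             p$imp1_central_other), 0)
  }
  if (imp == "IMP2") {
    mu <- mu + ifelse(rg == "central" & mk %in% p$imp2_central_markers,
                      p$imp2_central_extra, 0)
  }
  names(mu) <- feats
  mu
}

#' Generate synthetic marker-density rows for assigned patients
#'
#' Draws per-patient immune marker densities (cells/mm2) for the 20 markers
#' in central and peripheral tumour regions from a log-normal model with
#' phenotype-specific means and a low-rank latent-factor covariance, plus
#' the PD-L1 percent-positive call and tertiary lymphoid structure (TLS)
#' component flags. Cold-phenotype (IMP1) patients never express PD-L1 and
#' never carry a complete TLS; jointly positive TLS components are
#' restricted to G2/G3/DD tumours; high PD-L1 concentrates in DD.
#'
#' @param truth data.frame with columns `patient_id`, `subtype`
#'   (`G1,G2,G3,DD`) and `imp` (`IMP1,IMP2,IMP3`).
#' @param config A [generator_config()].
#' @return A marker-density table: one row per patient with columns
#'   `patient_id`, `subtype`, the 40 `<marker>_<region>` densities,
#'   `pdl1_percent`, and logical `tls_cd3`, `tls_cd20`, `tls_lamp3`.
#'   Missing cores are `NA`.
#' @export
generate_marker_densities <- function(truth, config) {
  stopifnot(all(c("patient_id", "subtype", "imp") %in% names(truth)))
  p <- density_model_params()
  n <- nrow(truth)
  feats <- setdiff(density_features(), c("PDL1_central", "PDL1_peripheral"))
  mk <- sub("_(central|peripheral)$", "", feats)
  noisy <- config$density_noise_sd > 0

  mu <- t(vapply(truth$imp, density_log_means, numeric(length(feats))))
  logx <- mu
  if (noisy) {
    f_macro <- stats::rnorm(n)
    f_tcell <- stats::rnorm(n)
    f_pair <- stats::rnorm(n)
    load <- numeric(length(feats))
    load[mk %in% p$macro_markers] <- p$macro_loading
    load[feats %in% p$tam_pair] <- p$tam_pair_macro_loading
    logx <- logx + outer(f_macro, load)
    load_t <- ifelse(mk %in% p$tcell_markers, p$tcell_loading, 0)
    logx <- logx + outer(f_tcell, load_t)
    load_p <- ifelse(feats %in% p$tam_pair, p$tam_pair_loading, 0)
    logx <- logx + outer(f_pair, load_p)
    sds <- ifelse(feats %in% p$tam_pair, p$tam_pair_resid_sd,
                  config$density_noise_sd)
    logx <- logx + matrix(stats::rnorm(n * length(feats)), n) %*% diag(sds)
  }
  dens <- exp(logx)
  colnames(dens) <- feats

  # PD-L1 percent-positive: absent in IMP1, high values concentrated in DD
  pct <- numeric(n)
  for (i in seq_len(n)) {
    imp <- truth$imp[i]; dd <- truth$subtype[i] == "DD"
    pct[i] <- if (imp == "IMP1") 0
    else if (imp == "IMP2") {
      if (dd) stats::runif(1, 30, 80)
      else if (stats::runif(1) < 0.6) stats::runif(1, 1, 29) else 0
    } else {
      if (dd && stats::runif(1) < 0.4) stats::runif(1, 25, 60)
      else if (!dd && stats::runif(1) < 0.35) stats::runif(1, 1, 15) else 0
    }
  }
  pdl1_dens <- pct * 8 * if (noisy) exp(stats::rnorm(n, 0, 0.2)) else 1

  # TLS components: complete triads only in high-grade, never in IMP1
  tls <- matrix(FALSE, n, 3, dimnames = list(NULL, c("cd3", "cd20", "lamp3")))
  for (i in seq_len(n)) {
    imp <- truth$imp[i]; st <- truth$subtype[i]
    if (imp == "IMP1") next
    eligible <- st %in% c("G2", "G3", "DD")
    p_joint <- if (imp == "IMP2") 0.5 else 0.25
    if (eligible && stats::runif(1) < p_joint) {
      tls[i, ] <- TRUE
    } else {
      tls[i, ] <- stats::runif(3) < 0.25
      if (all(tls[i, ])) tls[i, "lamp3"] <- FALSE
    }
  }

  out <- data.frame(patient_id = truth$patient_id, subtype = truth$subtype,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(dens))
  out$PDL1_central <- pdl1_dens
  out$PDL1_peripheral <- pdl1_dens * if (noisy) exp(stats::rnorm(n, 0, 0.2)) else 1
  out$pdl1_percent <- pct
  out$tls_cd3 <- tls[, "cd3"]; out$tls_cd20 <- tls[, "cd20"]
  out$tls_lamp3 <- tls[, "lamp3"]

  if (config$core_dropout > 0) {
    fcols <- density_features()
    mask <- matrix(stats::runif(n * length(fcols)) < config$core_dropout,
                   n, length(fcols))
    for (j in seq_along(fcols)) out[[fcols[j]]][mask[, j]] <- NA_real_
  }
  out[, c("patient_id", "subtype", density_features(),
          "pdl1_percent", "tls_cd3", "tls_cd20", "tls_lamp3")]
}
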