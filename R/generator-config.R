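#' Configuration for the synthetic chondrosarcoma cohort generator
#'
#' Builds the full parameter set controlling [generate_cohort()]. Defaults
#' reproduce the statistical structure of a 99-patient chondrosarcoma
#' cohort: subtype composition 28 G1 / 37 G2 / 24 G3 / 10 dedifferentiated
#' (DD), combined IDH1/2 mutation frequency 41%, subtype 3-year overall
#' survival of 91.3/77.3/40.7/11.4%, immunophenotype 5-year overall
#' survival of 86/29/44% (IMP1/IMP2/IMP3), and a retained-variant count
#' distribution whose cohort median is 4 (median panel TMB 4/1.7 = 2.35
#' mut/Mb on the 1.7 Mb panel).
#'
#' Survival times are exponential under a proportional-hazards model. The
#' true log hazard ratios are `log(3.3)` for IMP2 membership and
#' `log(3.8)` for IDH1 mutation (IMP1 / wild-type reference), plus a
#' tumour-size effect; per-subtype baseline hazards are calibrated at
#' generation time so the true survival functions hit the subtype anchors
#' given the covariate mix (see [generate_survival()]).
#'
#' @param n_patients Number of patients (>= 2).
#' @param subtype_proportions Named probabilities over `G1,G2,G3,DD`;
#'   must sum to 1.
#' @param imp_given_subtype 4x3 matrix of P(IMP | subtype); rows
#'   `G1,G2,G3,DD`, columns `IMP1,IMP2,IMP3`; rows sum to 1.
#' @param gene_freqs Named cohort-marginal mutation probabilities per gene.
#' @param gene_subtype_weights Named list of length-4 relative enrichment
#'   vectors (subtype order `G1,G2,G3,DD`); within-subtype frequencies are
#'   renormalized so the cohort marginal equals `gene_freqs`.
#' @param idh1_imp_weights Length-3 relative enrichment of IDH1 across
#'   IMP1/IMP2/IMP3 within each subtype (marginal preserved).
#' @param true_log_hazards Named numeric: `imp2`, `imp3`, `idh1`,
#'   `size_per_cm` (per cm above 5 cm).
#' @param subtype_survival_anchors 3-year OS probability per subtype.
#' @param imp_survival_anchors 5-year OS probability per IMP (documentation
#'   of the emergent values; not used in calibration, which targets the
#'   subtype anchors).
#' @param censoring_rate Probability that a patient receives a finite
#'   censoring time (uniform on 6-120 months, independent of survival).
#' @param final_variant_count_dist List `size`, `mu` of the negative
#'   binomial background-variant count added to the driver-gene count;
#'   defaults calibrated so the cohort median total is 4.
#' @param contaminants_per_class Injected contaminant records per removal
#'   class per sample.
#' @param panel_size_mb Sequenced panel footprint in megabases.
#' @param core_dropout Probability that a single (marker, region) core
#'   measurement is missing (recorded `NA`, never zero-filled).
#' @param density_noise_sd Residual log-scale standard deviation of marker
#'   densities; 0 collapses draws to their (marker, region, IMP) means.
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#'
#' @return An object of class `generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(n_patients = 10, seed = 1)
#' cfg$n_patients
generator_config <- function(n_patients = 99,
                             subtype_proportions = c(G1 = 28, G2 = 37, G3 = 24, DD = 10) / 99,
                             imp_given_subtype = default_imp_given_subtype(),
                             gene_freqs = default_gene_freqs(),
                             gene_subtype_weights = default_gene_subtype_weights(),
                             idh1_imp_weights = c(IMP1 = 0.30, IMP2 = 1.30, IMP3 = 1.10),
                             true_log_hazards = c(imp2 = log(3.3), imp3 = log(2.6),
                                                  idh1 = log(3.8), size_per_cm = log(1.08)),
                             subtype_survival_anchors = c(G1 = 0.913, G2 = 0.773,
                                                          G3 = 0.407, DD = 0.114),
                             imp_survival_anchors = c(IMP1 = 0.86, IMP2 = 0.29, IMP3 = 0.44),
                             censoring_rate = 0.4,
                             final_variant_count_dist = list(size = 1.3, mu = 3.4),
                             contaminants_per_class = 2,
                             panel_size_mb = 1.7,
                             core_dropout = 0.02,
                             density_noise_sd = 0.5,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              subtype_proportions = subtype_proportions,
              imp_given_subtype = imp_given_subtype,
              gene_freqs = gene_freqs,
              gene_subtype_weights = gene_subtype_weights,
              idh1_imp_weights = idh1_imp_weights,
              true_log_hazards = true_log_hazards,
              subtype_survival_anchors = subtype_survival_anchors,
              imp_survival_anchors = imp_survival_anchors,
              censoring_rate = censoring_rate,
              final_variant_count_dist = final_variant_count_dist,
              contaminants_per_class = as.integer(contaminants_per_class),
              panel_size_mb = panel_size_mb,
              core_dropout = core_dropout,
              density_noise_sd = density_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stop_cfg <- function(field, msg)
    stop(sprintf("invalid generator configuration: field '%s' %s", field, msg),
         call. = FALSE)
  if (is.na(cfg$n_patients) || cfg$n_patients < 2L)
    stop_cfg("n_patients", "must be an integer >= 2")
  p <- cfg$subtype_proportions
  if (!identical(sort(names(p)), sort(chs_subtypes())))
    stop_cfg("subtype_proportions", "must be named G1,G2,G3,DD")
  if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-8)
    stop_cfg("subtype_proportions", "must be probabilities summing to 1")
  m <- cfg$imp_given_subtype
  if (!is.matrix(m) || nrow(m) != 4L || ncol(m) != 3L ||
      any(m < 0 | m > 1) || any(abs(rowSums(m) - 1) > 1e-8))
    stop_cfg("imp_given_subtype", "must be a 4x3 row-stochastic matrix")
  if (any(cfg$gene_freqs < 0 | cfg$gene_freqs > 1))
    stop_cfg("gene_freqs", "must lie in [0,1]")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate > 1)
    stop_cfg("censoring_rate", "must lie in [0,1]")
  a <- c(cfg$subtype_survival_anchors, cfg$imp_survival_anchors)
  if (any(a <= 0 | a >= 1))
    stop_cfg("survival_anchors", "must lie strictly inside (0,1)")
  if (cfg$panel_size_mb <= 0)
    stop_cfg("panel_size_mb", "must be > 0")
  d <- cfg$final_variant_count_dist
  if (!is.list(d) || is.null(d$size) || is.null(d$mu) || d$size <= 0 || d$mu < 0)
    stop_cfg("final_variant_count_dist", "must provide size > 0 and mu >= 0")
  if (cfg$contaminants_per_class < 0)
    stop_cfg("contaminants_per_class", "must be >= 0")
  if (cfg$core_dropout < 0 || cfg$core_dropout > 1)
    stop_cfg("core_dropout", "must lie in [0,1]")
  if (cfg$density_noise_sd < 0)
    stop_cfg("density_noise_sd", "must be >= 0")
  invisible(cfg)
}

#' @rdname generator_config
#' @export
default_imp_given_subtype <- function() {
  m <- rbind(G1 = c(0.75, 0.05, 0.20),
             G2 = c(0.36, 0.34, 0.30),
             G3 = c(0.25, 0.35, 0.40),
             DD = c(0.00, 0.70, 0.30))
  colnames(m) <- imp_levels()
  m
}

#' @rdname generator_config
#' @export
default_gene_freqs <- function() {
  c(IDH1 = 0.31, IDH2 = 0.10, TP53 = 0.16, RNF213 = 0.12, TAF1 = 0.11,
    MN1 = 0.10, UBR5 = 0.07, EPHA7 = 0.06, PTCH1 = 0.06, RB1 = 0.05,
    ATRX = 0.05, KMT2D = 0.05, ARID1A = 0.04, SETD2 = 0.04, NF1 = 0.04,
    EGFR = 0.03, PIK3CA = 0.03, BRAF = 0.02, KIT = 0.02)
}

#' @rdname generator_config
#' @export
default_gene_subtype_weights <- function() {
  list(IDH1 = c(0.50, 1.25, 1.40, 0.90),
       IDH2 = c(0.00, 0.50, 1.00, 4.00),
       TP53 = c(0.00, 0.70, 2.40, 1.20),
       PTCH1 = c(0.40, 0.80, 1.20, 2.00),
       RB1 = c(0.20, 0.80, 2.00, 1.50))
}

# categorical level sets shared across modules
chs_subtypes <- function() c("G1", "G2", "G3", "DD")
imp_levels <- function() c("IMP1", "IMP2", "IMP3")
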