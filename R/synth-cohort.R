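# Cohort-level generator: ties together subtype/phenotype assignment,
# gene mutation flags (with subtype enrichment and the IDH1-TP53/UBR5
# co-occurrence), marker densities, caller call sets, CNV events and
# survival outcomes, with a ground-truth ledger for every patient.

# within-subtype frequency of a gene, renormalized so the cohort marginal
# equals the configured frequency
gene_freq_by_subtype <- function(gene, config) {
  p_sub <- config$subtype_proportions[chs_subtypes()]
  w <- config$gene_subtype_weights[[gene]]
  if (is.null(w)) w <- rep(1, 4)
  f <- config$gene_freqs[[gene]] * w / sum(p_sub * w)
  pmin(f, 0.95)
}

# genes whose odds are tilted upward in IDH1 carriers (marginal preserved)
cooccurring_genes <- function() c(TP53 = 2.5, UBR5 = 2.5)

assign_gene_flags <- function(subtype, imp, config) {
  n <- length(subtype)
  genes <- names(config$gene_freqs)
  si <- match(subtype, chs_subtypes())
  flags <- matrix(0L, n, length(genes), dimnames = list(NULL, genes))

  f_si <- idh1_freq_matrix(config)
  flags[, "IDH1"] <- as.integer(
    stats::runif(n) < f_si[cbind(si, match(imp, imp_levels()))])

  co <- cooccurring_genes()
  p_idh1_s <- vapply(seq_len(4), function(s)
    sum(config$imp_given_subtype[s, ] * f_si[s, ]), numeric(1))
  p1_patient <- f_si[cbind(si, match(imp, imp_levels()))]
  for (g in setdiff(genes, "IDH1")) {
    f_s <- gene_freq_by_subtype(g, config)
    p <- f_s[si]
    if (g == "IDH2") {
      # IDH1/IDH2 hotspot mutations are mutually exclusive; condition on
      # IDH1 wild-type with the subtype marginal preserved, so the
      # combined IDH1/2 frequency is the sum of the configured marginals
      p <- ifelse(flags[, "IDH1"] == 1L, 0,
                  pmin(0.95, p / pmax(1 - p1_patient, 1e-6)))
    } else if (g %in% names(co)) {
      u <- co[[g]]
      den <- p_idh1_s[si] * u + (1 - p_idh1_s[si])
      p <- ifelse(flags[, "IDH1"] == 1L, pmin(0.95, p * u / den), p / den)
    }
    flags[, g] <- as.integer(stats::runif(n) < p)
  }
  flags
}

generate_cnv_table <- function(patient_id, subtype, config) {
  p_sub <- config$subtype_proportions[chs_subtypes()]
  w <- c(G1 = 0.5, G2 = 0.8, G3 = 2.0, DD = 1.5)
  f <- pmin(0.263 * w / sum(p_sub * w), 1)
  has <- stats::runif(length(subtype)) < f[subtype]
  rows <- lapply(which(has), function(i) {
    k <- 1 + stats::rpois(1, 5)
    data.frame(sample = patient_id[i],
               gene = sample(cnv_gene_pool(), k, replace = TRUE),
               type = sample(c("amp", "del"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(sample = character(), gene = character(),
                      type = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Generate a complete synthetic chondrosarcoma cohort
#'
#' Produces every input of the downstream pipeline with known ground
#' truth: the marker-density table, per-sample caller call sets in three
#' dialects plus the pool-of-normals set, the CNV event table, the
#' clinical/survival table, and a truth ledger (latent phenotype, mutated
#' genes, true variants, tagged contaminants, uncensored survival time).
#' Fixed seed gives bit-identical output.
#'
#' @param config A [generator_config()].
#' @param include Which study inputs to materialize (`densities`,
#'   `variants` - which also covers the pool and the CNV table - and
#'   `survival`). Patient assignment and clinical covariates are always
#'   generated. Each component consumes its own seeded random stream, so
#'   omitting one leaves the others' draws unchanged.
#' @return List with elements `densities`, `callers` (named per patient:
#'   list of `ts`, `gatk`, `ir`), `pool` (pool-of-normals records),
#'   `cnv`, `clinical`, and `truth`.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 4, seed = 7))
#' cohort$clinical[, c("patient_id", "subtype", "os_months", "os_event")]
generate_cohort <- function(config = generator_config(),
                            include = c("densities", "variants",
                                        "survival")) {
  validate_generator_config(config)
  include <- match.arg(include, several.ok = TRUE)
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 4)
  n <- config$n_patients
  id <- sprintf("P%03d", seq_len(n))

  subtype <- sample(chs_subtypes(), n, replace = TRUE,
                    prob = config$subtype_proportions[chs_subtypes()])
  imp <- vapply(subtype, function(s)
    sample(imp_levels(), 1,
           prob = config$imp_given_subtype[match(s, chs_subtypes()), ]),
    character(1), USE.NAMES = FALSE)

  flags <- assign_gene_flags(subtype, imp, config)

  sdp <- size_dist_params()
  size_cm <- stats::rlnorm(n, sdp$meanlog[subtype], sdp$sdlog)
  age <- pmin(pmax(round(stats::rnorm(n, 55, 14)), 18), 90)
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.55, 0.45))
  site <- sample(c("axial", "extremity"), n, replace = TRUE,
                 prob = c(0.4, 0.6))
  margins <- sample(c("R0", "R1"), n, replace = TRUE, prob = c(0.8, 0.2))

  deamination <- stats::runif(n, 0, 9.5)

  truth_tbl <- data.frame(patient_id = id, subtype = subtype, imp = imp,
                          stringsAsFactors = FALSE)

  densities <- NULL
  if ("densities" %in% include) {
    set.seed(stage_seed[1])
    densities <- generate_marker_densities(truth_tbl, config)
  }

  callers <- NULL; truth_variants <- NULL; contaminants <- NULL
  pool_sites <- NULL; cnv <- NULL; pool_rec <- NULL
  prelim_tmb <- rep(NA_real_, n)
  if ("variants" %in% include) {
    set.seed(stage_seed[2])
    pool_sites <- make_pool_sites()
    d <- config$final_variant_count_dist
    bg <- stats::rnbinom(n, size = d$size, mu = d$mu)
    callers <- vector("list", n); names(callers) <- id
    truth_variants <- vector("list", n); names(truth_variants) <- id
    contaminants <- vector("list", n); names(contaminants) <- id
    for (i in seq_len(n)) {
      mg <- names(which(flags[i, ] == 1L))
      vc <- generate_variant_calls(mg, length(mg) + bg[i], pool_sites,
                                   config)
      callers[[i]] <- vc[c("ts", "gatk", "ir")]
      truth_variants[[i]] <- vc$truth
      contaminants[[i]] <- vc$contaminants
    }
    cnv <- generate_cnv_table(id, subtype, config)
    prelim_tmb <- vapply(callers, function(cc) nrow(cc$ir), numeric(1)) /
      config$panel_size_mb
  }

  surv <- data.frame(os_months = NA_real_, os_event = NA_integer_,
                     dfs_months = NA_real_, dfs_event = NA_integer_,
                     true_os_months = NA_real_)[rep(1, n), ]
  if ("survival" %in% include) {
    set.seed(stage_seed[3])
    covar <- data.frame(subtype = subtype, imp = imp,
                        idh1 = flags[, "IDH1"], size_cm = size_cm)
    surv <- generate_survival(covar, config)
  }

  clinical <- data.frame(patient_id = id, age = age, sex = sex,
                         size_cm = size_cm, site = site, margins = margins,
                         subtype = subtype,
                         os_months = surv$os_months, os_event = surv$os_event,
                         dfs_months = surv$dfs_months,
                         dfs_event = surv$dfs_event,
                         deamination_score = deamination,
                         prelim_tmb = prelim_tmb,
                         stringsAsFactors = FALSE)

  pool_rec <- empty_variant_records()[0, ]
  if (!is.null(pool_sites) && nrow(pool_sites) > 0) {
    pool_rec <- cbind(pool_sites[, c("chrom", "pos", "ref", "alt")],
                      vclass = "SNP", dp = 500, af = 0.5, tlod = NA_real_,
                      sb_fwd = 100, sb_rev = 100, gene = pool_sites$gene,
                      impact = NA_character_, clnsig = NA_character_,
                      sift = NA_character_, polyphen = NA_character_,
                      am_class = NA_character_, dbsnp = NA_character_,
                      kg_af = NA_real_, caller = "POOL",
                      stringsAsFactors = FALSE)
  }

  truth <- list(patients = cbind(truth_tbl,
                                 true_os_months = surv$true_os_months,
                                 flags),
                mutated_genes = apply(flags, 1, function(r)
                  names(which(r == 1L)), simplify = FALSE) |>
                  stats::setNames(id),
                variants = truth_variants,
                contaminants = contaminants)

  list(densities = densities, callers = callers, pool = pool_rec,
       cnv = cnv, clinical = clinical, truth = truth, config = config)
}

#' Write a synthetic cohort to plain-text study files
#'
#' Writes `densities.csv` (long format: patient, marker, region, density,
#' PD-L1 percent, TLS flags), per-sample caller VCFs
#' `<sample>.<caller>.vcf`, `pool.vcf`, `cnv.csv`, `clinical.csv` and
#' `truth.json` under `dir`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  d <- cohort$densities
  long <- do.call(rbind, lapply(density_features(), function(f) {
    marker <- sub("_(central|peripheral)$", "", f)
    region <- sub("^.*_", "", f)
    data.frame(patient_id = d$patient_id, marker = marker, region = region,
               density_per_mm2 = d[[f]], pdl1_percent = d$pdl1_percent,
               tls_cd3 = d$tls_cd3, tls_cd20 = d$tls_cd20,
               tls_lamp3 = d$tls_lamp3, stringsAsFactors = FALSE)
  }))
  p <- file.path(dir, "densities.csv")
  utils::write.csv(long, p, row.names = FALSE); paths <- c(paths, p)

  for (id in names(cohort$callers)) {
    for (cl in c("ts", "gatk", "ir")) {
      p <- file.path(dir, sprintf("%s.%s.vcf", id, toupper(cl)))
      write_caller_vcf(cohort$callers[[id]][[cl]], p, sample_id = id)
      paths <- c(paths, p)
    }
  }
  p <- file.path(dir, "pool.vcf")
  write_caller_vcf(cohort$pool, p, sample_id = "POOL")
  paths <- c(paths, p)

  p <- file.path(dir, "cnv.csv")
  utils::write.csv(cohort$cnv, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "clinical.csv")
  utils::write.csv(cohort$clinical, p, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(dir, "truth.json")
  truth <- cohort$truth
  jsonlite::write_json(
    list(patients = truth$patients,
         mutated_genes = truth$mutated_genes,
         contaminant_keys = lapply(truth$contaminants, function(x)
           if (nrow(x)) data.frame(key = variant_key(x), stage = x$stage)
           else data.frame(key = character(), stage = character()))),
    p, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
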