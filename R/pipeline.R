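# End-to-end orchestration: simulate -> immunophenotypes -> variant
# cascade -> cohort statistics -> survival -> immunograms, with a run
# manifest (seeds, output paths, file digests) for reproducibility.

pipeline_stages <- function() {
  c("simulate", "cluster", "variants", "stats", "survive", "immunogram")
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic
#' cohort and writes each stage's outputs under `out_dir`. Rerunning
#' with the same configuration reproduces identical file digests.
#'
#' @param config A [generator_config()] for the simulated study inputs.
#' @param out_dir Output directory.
#' @param stages Subset of `simulate`, `cluster`, `variants`, `stats`,
#'   `survive`, `immunogram`. Later stages require the earlier ones in
#'   the same run; a missing dependency aborts with the stage name.
#' @param thresholds Cascade thresholds before per-sample policy
#'   adjustment.
#' @param bootstrap_B Bootstrap iterations for cluster stability.
#' @return The run manifest: package version, seed, per-stage output
#'   paths and md5 digests.
#' @export
run_pipeline <- function(config = generator_config(), out_dir,
                         stages = pipeline_stages(),
                         thresholds = cascade_thresholds(),
                         bootstrap_B = 100) {
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  need <- function(stage, dep, obj) {
    if (is.null(obj))
      stop("stage '", stage, "' requires output of disabled stage '",
           dep, "'")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "chsprofiler",
                   version = as.character(utils::packageVersion("chsprofiler")),
                   seed = config$seed, stages = list())
  paths <- character()
  cohort <- NULL; fit <- NULL; profiles <- NULL; mm <- NULL; tmb <- NULL

  if ("simulate" %in% stages) {
    cohort <- generate_cohort(config)
    p <- write_cohort(cohort, file.path(out_dir, "inputs"))
    manifest$stages$simulate <- p; paths <- c(paths, p)
  }

  if ("cluster" %in% stages) {
    need("cluster", "simulate", cohort)
    fit <- fit_immunophenotypes(cohort$densities, B = bootstrap_B,
                                seed = config$seed)
    p1 <- file.path(out_dir, "imp_assignments.csv")
    utils::write.csv(data.frame(patient_id = names(fit$imp),
                                cluster = fit$labels, imp = fit$imp),
                     p1, row.names = FALSE)
    p2 <- file.path(out_dir, "stability.json")
    jsonlite::write_json(list(k = fit$k, B = bootstrap_B,
                              mean_ari = fit$stability$mean_ari,
                              votes = as.list(fit$votes)),
                         p2, auto_unbox = TRUE, digits = NA)
    cm <- correlation_map(cohort$densities)
    p3 <- file.path(out_dir, "correlation_map.csv")
    utils::write.csv(cm$rho, p3)
    pc <- pca_contributions(fit$features)
    p4 <- file.path(out_dir, "pca_loadings.csv")
    utils::write.csv(pc$loadings[, 1:5], p4)
    p5 <- file.path(out_dir, "region_comparisons.csv")
    utils::write.csv(compare_regions(cohort$densities), p5,
                     row.names = FALSE)
    manifest$stages$cluster <- c(p1, p2, p3, p4, p5)
    paths <- c(paths, manifest$stages$cluster)
  }

  if ("variants" %in% stages) {
    need("variants", "simulate", cohort)
    ids <- cohort$clinical$patient_id
    profiles <- lapply(seq_along(ids), function(i) {
      th <- apply_deamination_policy(
        list(deamination_score = cohort$clinical$deamination_score[i],
             prelim_tmb = cohort$clinical$prelim_tmb[i]), thresholds)
      cc <- cohort$callers[[ids[i]]]
      run_cascade(cc$ts, cc$gatk, cc$ir, cohort$pool, th,
                  config$panel_size_mb)
    })
    names(profiles) <- ids
    tmb <- vapply(profiles, `[[`, numeric(1), "tmb")
    p1 <- file.path(out_dir, "tmb.csv")
    utils::write.csv(data.frame(sample = ids,
                                n_final = vapply(profiles, function(p)
                                  nrow(p$final), integer(1)),
                                tmb = tmb), p1, row.names = FALSE)
    led <- do.call(rbind, lapply(ids, function(id)
      if (nrow(profiles[[id]]$ledger))
        cbind(sample = id, profiles[[id]]$ledger)))
    p2 <- file.path(out_dir, "removal_ledger.tsv")
    utils::write.table(led, p2, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    vdir <- file.path(out_dir, "final_variants")
    dir.create(vdir, showWarnings = FALSE)
    p3 <- vapply(ids, function(id) {
      fp <- file.path(vdir, paste0(id, ".final.vcf"))
      write_caller_vcf(profiles[[id]]$final, fp, sample_id = id)
      fp
    }, character(1))
    manifest$stages$variants <- c(p1, p2, unname(p3))
    paths <- c(paths, manifest$stages$variants)
  }

  if ("stats" %in% stages) {
    need("stats", "variants", profiles)
    mm <- mutation_matrix(profiles, cohort$cnv,
                          patients = cohort$clinical$patient_id)
    p1 <- file.path(out_dir, "oncoprint.tsv")
    utils::write.table(t(attr(mm, "classes")), p1, sep = "\t",
                       quote = FALSE)
    gst <- gene_subtype_test(mm, cohort$clinical$subtype)
    p2 <- file.path(out_dir, "gene_subtype_tests.csv")
    utils::write.csv(gst, p2, row.names = FALSE)
    p3 <- file.path(out_dir, "cooccurrence.csv")
    utils::write.csv(cooccurrence(mm), p3, row.names = FALSE)
    pd <- pathway_deregulation(mm, strata = list(
      subtype = cohort$clinical$subtype, imp = fit$imp))
    p4 <- file.path(out_dir, "pathway_summary.csv")
    utils::write.csv(pd$overall, p4, row.names = FALSE)
    p5 <- file.path(out_dir, "cnv_summary.json")
    cs <- summarize_cnv(cohort$cnv, cohort$clinical)
    jsonlite::write_json(list(n_events = cs$n_events,
                              fraction_patients = cs$fraction_patients),
                         p5, auto_unbox = TRUE, digits = NA)
    manifest$stages$stats <- c(p1, p2, p3, p4, p5)
    paths <- c(paths, manifest$stages$stats)
  }

  if ("survive" %in% stages) {
    need("survive", "variants", profiles)
    need("survive", "cluster", fit)
    cl <- cohort$clinical
    cl$imp <- fit$imp[cl$patient_id]
    gm <- mm
    if (is.null(gm)) gm <- mutation_matrix(profiles, cohort$cnv,
                                           patients = cl$patient_id)
    km <- do.call(rbind, lapply(split(seq_len(nrow(cl)), cl$imp),
                                function(ix) {
      k <- km_estimate(cl$os_months[ix], cl$os_event[ix])
      data.frame(imp = cl$imp[ix[1]], time = k$time, surv = k$surv)
    }))
    p1 <- file.path(out_dir, "km_curves.csv")
    utils::write.csv(km, p1, row.names = FALSE)
    us <- univariate_screen(cl$os_months, cl$os_event, gm)
    p2 <- file.path(out_dir, "cox_univariate.csv")
    utils::write.csv(us, p2, row.names = FALSE)
    X <- build_covariates(cl, gene_flags = gm, tmb = tmb)
    ls <- lasso_cox(cl$os_months, cl$os_event, X, seed = config$seed)
    p3 <- file.path(out_dir, "lasso_path.csv")
    utils::write.csv(ls$path, p3, row.names = FALSE)
    p4 <- file.path(out_dir, "final_model.json")
    fm <- if (is.null(ls$refit)) list(selected = list()) else
      list(selected = ls$selected,
           hr = as.list(ls$refit$hr),
           ci_lower = as.list(stats::setNames(ls$refit$ci_lower,
                                              ls$selected)),
           ci_upper = as.list(stats::setNames(ls$refit$ci_upper,
                                              ls$selected)),
           p = as.list(stats::setNames(ls$refit$p, ls$selected)),
           lambda_1se = ls$lambda_1se)
    jsonlite::write_json(fm, p4, auto_unbox = TRUE, digits = NA)
    manifest$stages$survive <- c(p1, p2, p3, p4)
    paths <- c(paths, manifest$stages$survive)
  }

  if ("immunogram" %in% stages) {
    need("immunogram", "variants", profiles)
    need("immunogram", "cluster", fit)
    gm <- mm
    if (is.null(gm)) gm <- mutation_matrix(profiles, cohort$cnv,
                                           patients = cohort$clinical$patient_id)
    ig <- build_immunograms(cohort$densities, gm, tmb)
    p1 <- file.path(out_dir, "immunograms.csv")
    utils::write.csv(ig, p1, row.names = FALSE)
    p2 <- file.path(out_dir, "imp_profiles.csv")
    utils::write.csv(summarize_by_imp(ig, fit$imp), p2, row.names = FALSE)
    manifest$stages$immunogram <- c(p1, p2)
    paths <- c(paths, manifest$stages$immunogram)
  }

  manifest$digests <- as.list(tools::md5sum(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Validate pipeline input files
#'
#' Schema checks for the CSV/VCF study inputs. Violations are collected
#' and reported, not thrown; an unreadable file is fatal.
#'
#' @param paths Named list with any of `densities`, `clinical`, `cnv`
#'   (CSV paths) and `vcf` (character vector of VCF paths).
#' @return data.frame `file`, `where`, `issue` (zero rows when clean).
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  note <- function(file, where, issue)
    issues[[length(issues) + 1]] <<- data.frame(
      file = file, where = where, issue = issue, stringsAsFactors = FALSE)

  if (!is.null(paths$densities)) {
    d <- utils::read.csv(paths$densities)
    bad <- which(!is.na(d$density_per_mm2) & d$density_per_mm2 < 0)
    for (i in bad) note(paths$densities, paste0("row ", i),
                        "negative density")
    if (!all(c("patient_id", "marker", "region") %in% names(d)))
      note(paths$densities, "header", "missing required columns")
  }
  if (!is.null(paths$clinical)) {
    cl <- utils::read.csv(paths$clinical)
    for (col in c("os_months", "dfs_months")) {
      bad <- which(!is.na(cl[[col]]) & cl[[col]] <= 0)
      for (i in bad) note(paths$clinical, paste0("row ", i),
                          paste0("non-positive ", col))
    }
    for (col in c("os_event", "dfs_event")) {
      bad <- which(!cl[[col]] %in% c(0, 1))
      for (i in bad) note(paths$clinical, paste0("row ", i),
                          paste0(col, " not in {0,1}"))
    }
  }
  if (!is.null(paths$cnv)) {
    cn <- utils::read.csv(paths$cnv)
    bad <- which(!cn$type %in% c("amp", "del"))
    for (i in bad) note(paths$cnv, paste0("row ", i), "type not amp/del")
  }
  for (vp in paths$vcf) {
    rec <- parse_caller_vcf(vp, dialect = "GATK")
    bad <- which(!is.na(rec$af) & (rec$af < 0 | rec$af > 1))
    for (i in bad) note(vp, variant_key(rec[i, , drop = FALSE]),
                        "AF outside [0,1]")
    bad <- which(rec$pos < 1)
    for (i in bad) note(vp, variant_key(rec[i, , drop = FALSE]),
                        "non-positive position")
  }
  if (length(issues) == 0)
    return(data.frame(file = character(), where = character(),
                      issue = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
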