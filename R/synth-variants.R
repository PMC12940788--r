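# Synthetic caller output: per-sample call sets in three caller dialects
# (TS, GATK, IR) plus a pool-of-normals set. True somatic variants pass
# every cascade threshold; each injected contaminant is built to fail at
# exactly one tagged stage. No read-level simulation: this emulates caller
# OUTPUT, not sequencing.

variant_columns <- function() {
  c("chrom", "pos", "ref", "alt", "vclass", "dp", "af", "tlod",
    "sb_fwd", "sb_rev", "gene", "impact", "clnsig", "sift", "polyphen",
    "am_class", "dbsnp", "kg_af", "caller")
}

empty_variant_records <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), vclass = character(), dp = numeric(),
             af = numeric(), tlod = numeric(), sb_fwd = numeric(),
             sb_rev = numeric(), gene = character(), impact = character(),
             clnsig = character(), sift = character(), polyphen = character(),
             am_class = character(), dbsnp = character(), kg_af = numeric(),
             caller = character(), stringsAsFactors = FALSE)
}

#' Variant identity key
#'
#' Canonical `(chrom, pos, ref, alt)` key used to match records across
#' caller sets, the pool of normals, and the removal ledger.
#'
#' @param records A variant record data.frame.
#' @return Character vector of keys.
#' @export
variant_key <- function(records) {
  if (nrow(records) == 0) return(character())
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

rand_bases <- function(n, len = 1) {
  if (len == 1) return(sample(c("A", "C", "G", "T"), n, replace = TRUE))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n)
  apply(m, 1, paste, collapse = "")
}

# substitute each base by one of the three others, uniformly
mutate_base <- function(b) {
  bases <- c("A", "C", "G", "T")
  k <- sample.int(3, length(b), replace = TRUE)
  bases[(match(b, bases) - 1L + k) %% 4L + 1L]
}

# draw loci within panel genes; guarantees unique keys within the draw
draw_loci <- function(genes) {
  pg <- panel_genes()
  idx <- match(genes, pg$gene)
  pos <- pg$start[idx] + floor(stats::runif(length(genes)) *
                               (pg$end[idx] - pg$start[idx]))
  data.frame(gene = genes, chrom = pg$chrom[idx], pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

# annotations that survive the pathogenicity rules; exercises both the
# SIFT+PolyPhen route and the AlphaMissense-only route
pathogenic_annotations <- function(n) {
  route_a <- stats::runif(n) < 0.7
  data.frame(
    impact = sample(c("MODERATE", "HIGH"), n, TRUE, prob = c(0.7, 0.3)),
    clnsig = sample(c("pathogenic", "uncertain_significance", NA),
                    n, TRUE, prob = c(0.3, 0.4, 0.3)),
    sift = ifelse(route_a, "deleterious", NA),
    polyphen = ifelse(route_a, "damaging", NA),
    am_class = ifelse(route_a,
                      sample(c("pathogenic", "ambiguous"), n, TRUE),
                      "pathogenic"),
    dbsnp = ifelse(stats::runif(n) < 0.3,
                   sprintf("rs%d", sample.int(2e8, n)), NA),
    kg_af = ifelse(stats::runif(n) < 0.2, stats::runif(n, 0, 0.04), NA),
    stringsAsFactors = FALSE)
}

# quality fields passing every threshold; strand support >= 2 per strand
passing_quality <- function(n, vclass) {
  dp <- ifelse(vclass == "INDEL", round(stats::runif(n, 80, 400)),
               round(stats::runif(n, 200, 1500)))
  af <- ifelse(vclass == "INDEL", stats::runif(n, 0.36, 0.54),
               stats::runif(n, 0.12, 0.65))
  alt_reads <- pmax(round(dp * af), 6)
  sb_fwd <- 2 + floor(stats::runif(n) * (alt_reads - 3))
  data.frame(dp = dp, af = af, tlod = stats::runif(n, 20, 200),
             sb_fwd = sb_fwd, sb_rev = alt_reads - sb_fwd)
}

make_true_variants <- function(mutated_genes, total_count,
                               background_genes = panel_genes()$gene) {
  n_extra <- max(0L, total_count - length(mutated_genes))
  genes <- c(mutated_genes,
             sample(background_genes, n_extra, replace = TRUE))
  n <- length(genes)
  if (n == 0) return(empty_variant_records())
  vclass <- sample(c("SNP", "MNP", "INDEL"), n, TRUE,
                   prob = c(0.88, 0.04, 0.08))
  loci <- draw_loci(genes)
  ref <- rand_bases(n)
  alt <- mutate_base(ref)
  mnp <- vclass == "MNP"
  if (any(mnp)) {
    second <- rand_bases(sum(mnp))
    ref[mnp] <- paste0(ref[mnp], second)
    alt[mnp] <- paste0(alt[mnp], mutate_base(second))
  }
  ins <- vclass == "INDEL" & stats::runif(n) < 0.5
  del <- vclass == "INDEL" & !ins
  if (any(ins)) alt[ins] <- paste0(ref[ins], rand_bases(sum(ins), 2))
  if (any(del)) {
    ref[del] <- paste0(ref[del], rand_bases(sum(del), 2))
    alt[del] <- substr(ref[del], 1, 1)
  }
  cbind(loci[, c("chrom", "pos")], ref = ref, alt = alt, vclass = vclass,
        passing_quality(n, vclass), gene = loci$gene,
        pathogenic_annotations(n))
}

# contaminant records for a given removal-stage tag
make_contaminants <- function(stage, n, pool_sites) {
  if (n == 0) return(NULL)
  if (stage == "pool") {
    site <- pool_sites[sample.int(nrow(pool_sites), n), , drop = FALSE]
    rec <- cbind(site[, c("chrom", "pos", "ref", "alt")],
                 vclass = "SNP", passing_quality(n, rep("SNP", n)),
                 gene = site$gene, pathogenic_annotations(n))
    rec$af <- stats::runif(n, 0.4, 0.6)  # germline-like fraction
    rownames(rec) <- NULL
    return(rec)
  }
  genes <- sample(panel_genes()$gene, n, replace = TRUE)
  loci <- draw_loci(genes)
  vclass <- rep(if (stage == "gatk_indel") "INDEL" else "SNP", n)
  ref <- rand_bases(n); alt <- mutate_base(ref)
  if (stage == "gatk_indel") ref <- paste0(ref, rand_bases(n, 2))
  rec <- cbind(loci[, c("chrom", "pos")], ref = ref, alt = alt,
               vclass = vclass, passing_quality(n, vclass),
               gene = genes, pathogenic_annotations(n))
  switch(stage,
    gatk_snv = {  # rotate which quality threshold fails
      mode <- sample.int(3, n, replace = TRUE)
      rec$dp[mode == 1] <- sample(5:14, sum(mode == 1), replace = TRUE)
      rec$af[mode == 2] <- stats::runif(sum(mode == 2), 0.001, 0.014)
      rec$tlod[mode == 3] <- stats::runif(sum(mode == 3), 0, 13.9)
    },
    gatk_indel = {  # depth fine, allele fraction outside the 0.35-0.55 window
      rec$dp <- round(stats::runif(n, 80, 300))
      low <- stats::runif(n) < 0.5
      rec$af <- ifelse(low, stats::runif(n, 0.06, 0.30),
                       stats::runif(n, 0.60, 0.90))
    },
    impact_benign = {
      rec$impact <- "LOW"; rec$clnsig <- "benign"
    },
    kg_common = {
      rec$kg_af <- stats::runif(n, 0.06, 0.5)
      rec$dbsnp <- sprintf("rs%d", sample.int(2e8, n))
    },
    read_support = {
      one <- stats::runif(n) < 0.5
      rec$sb_fwd <- ifelse(one, 1, 2); rec$sb_rev <- ifelse(one, 9, 2)
    },
    stop("unknown contaminant stage: ", stage))
  rownames(rec) <- NULL
  rec
}

contaminant_stages <- function() {
  c("gatk_snv", "gatk_indel", "pool", "impact_benign", "kg_common",
    "read_support")
}

# shared germline/artifact sites forming the cohort pool of normals
make_pool_sites <- function(n_sites = 30) {
  genes <- sample(panel_genes()$gene, n_sites, replace = TRUE)
  loci <- draw_loci(genes)
  ref <- rand_bases(n_sites)
  alt <- vapply(ref, function(b) {
    repeat { a <- rand_bases(1); if (a != b) return(a) }
  }, character(1))
  data.frame(loci[, c("chrom", "pos")], ref = ref, alt = alt,
             gene = genes, stringsAsFactors = FALSE)
}

#' Generate per-sample caller sets with tagged contaminants
#'
#' Builds the three caller-dialect call sets for one patient. Every true
#' somatic variant appears in the TS and GATK sets with fields passing all
#' cascade thresholds (and in IR with probability 1/2); each contaminant
#' class is injected into TS and GATK so that it is removed at exactly its
#' tagged cascade stage (`gatk_snv`, `gatk_indel`, `pool`, `impact_benign`,
#' `kg_common`, `read_support`); `pool`-tagged records share their key with
#' the pool-of-normals set.
#'
#' @param mutated_genes Character vector of the patient's true mutated
#'   genes (each receives at least one variant).
#' @param total_count Total true somatic variant count for the sample.
#' @param pool_sites Cohort pool-of-normals site table from the generator.
#' @param config A [generator_config()].
#' @return List with data.frames `ts`, `gatk`, `ir` (caller column set
#'   accordingly; TS and IR records carry no TLOD), `truth` (true variant
#'   records) and `contaminants` (records plus `stage` tag).
#' @export
generate_variant_calls <- function(mutated_genes, total_count, pool_sites,
                                   config) {
  # passenger variants live outside the modelled driver genes so that
  # the configured gene_freqs stay the exact per-gene cohort mutation
  # probabilities after the cascade
  bg <- setdiff(panel_genes()$gene, names(config$gene_freqs))
  truth <- make_true_variants(mutated_genes, total_count, bg)
  ncls <- config$contaminants_per_class
  cont <- do.call(rbind, lapply(contaminant_stages(), function(st) {
    rec <- make_contaminants(st, ncls, pool_sites)
    if (!is.null(rec)) rec$stage <- st
    rec
  }))
  if (is.null(cont)) cont <- cbind(empty_variant_records()[0, 1:18],
                                   stage = character())

  # de-duplicate colliding keys; non-pool records must not hit pool sites
  truth$stage <- rep(NA_character_, nrow(truth))
  all_rec <- rbind(truth, cont)
  truth$stage <- NULL
  if (nrow(all_rec) > 0) {
    pk <- paste(pool_sites$chrom, pool_sites$pos, sep = ":")
    repeat {
      keys <- paste(all_rec$chrom, all_rec$pos, sep = ":")
      bad <- duplicated(keys) |
        (keys %in% pk & (is.na(all_rec$stage) | all_rec$stage != "pool"))
      if (!any(bad)) break
      all_rec$pos[bad] <- all_rec$pos[bad] + sample(1000, sum(bad))
    }
  }
  truth <- all_rec[is.na(all_rec$stage), setdiff(names(all_rec), "stage"),
                   drop = FALSE]
  cont <- all_rec[!is.na(all_rec$stage), , drop = FALSE]

  as_caller <- function(rec, caller) {
    if (nrow(rec) == 0) { out <- empty_variant_records(); return(out) }
    out <- rec[, setdiff(names(rec), "stage"), drop = FALSE]
    out$caller <- caller
    if (caller != "GATK") out$tlod <- NA_real_
    rownames(out) <- NULL
    out[, variant_columns()]
  }
  both <- rbind(truth, cont[, names(truth), drop = FALSE])
  in_ir <- if (nrow(truth) > 0) stats::runif(nrow(truth)) < 0.5 else logical()
  list(ts = as_caller(both, "TS"),
       gatk = as_caller(both, "GATK"),
       ir = as_caller(truth[in_ir, , drop = FALSE], "IR"),
       truth = as_caller(truth, "GATK"),
       contaminants = cbind(as_caller(cont[, names(truth), drop = FALSE],
                                      "GATK"),
                            stage = cont$stage))
}
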