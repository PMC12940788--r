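# The staged somatic-variant consensus cascade. Stage order:
#   1. GATK-branch quality thresholds (SNP/MNP: DP >= 15, AF >= 0.015,
#      TLOD >= 14; INDEL: DP >= 70, 0.35 <= AF <= 0.55; inclusive)
#   2. caller merge: (TS intersect GATK) union IR
#   3. pool-of-normals subtraction
#   4. post-filtration: AF >= 0.05 (policy-adjustable) and DP >= 50
#   5. annotation-based pathogenicity rules
# Every removal is ledgered with the stage that caused it; the TS branch
# applies no per-variant thresholds of its own (its run-level QC criteria
# are sample-admission checks, not record filters).

#' Default cascade thresholds
#'
#' All numeric thresholds of the filtration cascade by name, so each can
#' be overridden. `stricter_gatk_af` is the SNP/MNP allele-fraction floor
#' substituted by the deamination policy; its printed source value (0.75)
#' is retained as the default but is configurable because it is far above
#' the usual somatic range.
#'
#' @param gatk_snv_dp,gatk_snv_af,gatk_snv_tlod SNP/MNP thresholds.
#' @param gatk_indel_dp,gatk_indel_af_min,gatk_indel_af_max INDEL rules.
#' @param post_af,post_dp Post-filtration floors.
#' @param kg_af_max Maximum population (1000 Genomes) allele frequency.
#' @param min_total_reads,min_strand_reads Read-support floors.
#' @param ir_af Ion Reporter minimum allele fraction.
#' @param stricter_ir_af,stricter_gatk_af Values substituted under the
#'   deamination policy.
#' @param annotation_profile Named annotation-filter profile flag.
#' @return Named list of thresholds (class `cascade_thresholds`).
#' @export
cascade_thresholds <- function(gatk_snv_dp = 15, gatk_snv_af = 0.015,
                               gatk_snv_tlod = 14, gatk_indel_dp = 70,
                               gatk_indel_af_min = 0.35,
                               gatk_indel_af_max = 0.55,
                               post_af = 0.05, post_dp = 50,
                               kg_af_max = 0.05, min_total_reads = 5,
                               min_strand_reads = 2, ir_af = 0.05,
                               stricter_ir_af = 0.1,
                               stricter_gatk_af = 0.75,
                               annotation_profile = "Oncomine Extended") {
  structure(list(gatk_snv_dp = gatk_snv_dp, gatk_snv_af = gatk_snv_af,
                 gatk_snv_tlod = gatk_snv_tlod, gatk_indel_dp = gatk_indel_dp,
                 gatk_indel_af_min = gatk_indel_af_min,
                 gatk_indel_af_max = gatk_indel_af_max, post_af = post_af,
                 post_dp = post_dp, kg_af_max = kg_af_max,
                 min_total_reads = min_total_reads,
                 min_strand_reads = min_strand_reads, ir_af = ir_af,
                 stricter_ir_af = stricter_ir_af,
                 stricter_gatk_af = stricter_gatk_af,
                 annotation_profile = annotation_profile),
            class = "cascade_thresholds")
}

#' Adjust thresholds for FFPE deamination / preliminary TMB
#'
#' Samples with a deamination score below 10 are analysed under the
#' default thresholds. A score in 10-25 and/or a preliminary (caller
#' software) TMB in 11-50 mut/Mb triggers the stricter policy: the IR and
#' post-filtration allele-fraction floors rise from 0.05 to 0.1, the GATK
#' SNP/MNP floor is replaced by `stricter_gatk_af`, and the annotation
#' profile switches from "Oncomine Extended" to "Oncomine Variants".
#' Scores above 25 disqualify the sample.
#'
#' @param meta List or data.frame row with `deamination_score` and
#'   `prelim_tmb`.
#' @param thresholds A [cascade_thresholds()].
#' @return Adjusted thresholds; attribute `"policy"` records
#'   `"standard"`, `"stricter"` or `"rejected"`.
#' @export
apply_deamination_policy <- function(meta,
                                     thresholds = cascade_thresholds()) {
  score <- meta$deamination_score
  tmb <- meta$prelim_tmb
  if (score < 0) stop("deamination score must be >= 0")
  if (score > 25) {
    attr(thresholds, "policy") <- "rejected"
    return(thresholds)
  }
  strict <- (score >= 10 && score <= 25) ||
    (!is.null(tmb) && !is.na(tmb) && tmb >= 11 && tmb <= 50)
  if (strict) {
    thresholds$ir_af <- thresholds$stricter_ir_af
    thresholds$post_af <- thresholds$stricter_ir_af
    thresholds$gatk_snv_af <- thresholds$stricter_gatk_af
    thresholds$annotation_profile <- "Oncomine Variants"
  }
  attr(thresholds, "policy") <- if (strict) "stricter" else "standard"
  thresholds
}

filter_result <- function(records, removed, reason) {
  if (nrow(removed) > 0) removed$reason <- reason[seq_len(nrow(removed))]
  else removed$reason <- character()
  list(records = records, removed = removed)
}

#' GATK-branch quality filtering
#'
#' SNP/MNP records are kept iff `DP >= 15`, `AF >= 0.015` and
#' `TLOD >= 14`; INDELs iff `DP >= 70` and `0.35 <= AF <= 0.55`
#' (boundaries inclusive). SNP/MNP records missing TLOD are rejected with
#' reason `missing_quality_field`.
#'
#' @param records GATK-provenance variant records.
#' @param thresholds A [cascade_thresholds()].
#' @return List with `records` (survivors) and `removed` (with `reason`
#'   column: `gatk_snv`, `gatk_indel`, or `missing_quality_field`).
#' @export
filter_gatk_branch <- function(records, thresholds = cascade_thresholds()) {
  th <- thresholds
  if (nrow(records) == 0)
    return(filter_result(records, records, character()))
  is_indel <- records$vclass == "INDEL"
  missing_q <- !is_indel & (is.na(records$tlod) | is.na(records$dp) |
                            is.na(records$af))
  keep_snv <- !is_indel & !missing_q &
    records$dp >= th$gatk_snv_dp & records$af >= th$gatk_snv_af &
    records$tlod >= th$gatk_snv_tlod
  keep_indel <- is_indel & !is.na(records$dp) & !is.na(records$af) &
    records$dp >= th$gatk_indel_dp &
    records$af >= th$gatk_indel_af_min & records$af <= th$gatk_indel_af_max
  keep <- keep_snv | keep_indel
  reason <- ifelse(missing_q, "missing_quality_field",
                   ifelse(is_indel, "gatk_indel", "gatk_snv"))
  filter_result(records[keep, , drop = FALSE],
                records[!keep, , drop = FALSE], reason[!keep])
}

#' Merge the three caller sets
#'
#' The merged set is `(keys(TS) intersect keys(GATK)) union keys(IR)`
#' on the canonical `(chrom, pos, ref, alt)` key. A merged record unions
#' caller provenance; field values follow the precedence GATK > TS > IR.
#'
#' @param ts,gatk,ir Normalized variant record data.frames.
#' @return List with `records` (merged) and `removed` (records excluded
#'   by the intersection rule, reason `merge`).
#' @export
merge_callers <- function(ts, gatk, ir) {
  kt <- variant_key(ts); kg <- variant_key(gatk); ki <- variant_key(ir)
  merged_keys <- union(intersect(kt, kg), ki)
  all_rec <- rbind(gatk, ts, ir)        # precedence order
  all_keys <- variant_key(all_rec)
  # same (chrom,pos,ref) must not disagree across callers after
  # normalization: detect two keys sharing chrom:pos:alt with differing ref
  cpa <- paste(all_rec$chrom, all_rec$pos, all_rec$alt, sep = ":")
  for (d in unique(cpa[duplicated(cpa)])) {
    refs <- unique(all_rec$ref[cpa == d])
    if (length(refs) > 1)
      stop("conflicting REF alleles at ", d, " after normalization: ",
           paste(refs, collapse = "/"))
  }
  first <- !duplicated(all_keys)
  out <- all_rec[first & all_keys %in% merged_keys, , drop = FALSE]
  ok <- variant_key(out)
  out$caller <- vapply(ok, function(k)
    paste(c("TS", "GATK", "IR")[c(k %in% kt, k %in% kg, k %in% ki)],
          collapse = ","), character(1), USE.NAMES = FALSE)
  dropped <- all_rec[first & !(all_keys %in% merged_keys), , drop = FALSE]
  filter_result(out, dropped, rep("merge", nrow(dropped)))
}

#' Subtract the pool of normals
#'
#' Removes records whose key occurs in the healthy-tissue pool call set
#' (likely germline variants or recurrent artifacts).
#'
#' @param records Variant records.
#' @param pool_keys Character vector of pool keys ([variant_key()]), or a
#'   pool record data.frame.
#' @return List with `records` and `removed` (reason `pool`).
#' @export
subtract_pool <- function(records, pool_keys) {
  if (is.data.frame(pool_keys)) pool_keys <- variant_key(pool_keys)
  hit <- variant_key(records) %in% pool_keys
  filter_result(records[!hit, , drop = FALSE],
                records[hit, , drop = FALSE], rep("pool", sum(hit)))
}

#' Post-filtration on allele fraction and depth
#'
#' Keeps records with `AF >= post_af` (0.05 by default, raised to 0.1 by
#' the deamination policy) and `DP >= 50`; records missing either field
#' are rejected.
#'
#' @inheritParams filter_gatk_branch
#' @return List with `records` and `removed` (reason `post_filter` or
#'   `missing_quality_field`).
#' @export
post_filter <- function(records, thresholds = cascade_thresholds()) {
  if (nrow(records) == 0)
    return(filter_result(records, records, character()))
  missing_q <- is.na(records$af) | is.na(records$dp)
  keep <- !missing_q & records$af >= thresholds$post_af &
    records$dp >= thresholds$post_dp
  reason <- ifelse(missing_q, "missing_quality_field", "post_filter")
  filter_result(records[keep, , drop = FALSE],
                records[!keep, , drop = FALSE], reason[!keep])
}

#' Annotation-based pathogenicity filtering
#'
#' Applies, in order: (1) remove records with `LOW` impact and a benign
#' ClinVar class; (2) keep only records classified deleterious by SIFT
#' and damaging by PolyPhen-2, or pathogenic by AlphaMissense (records
#' with all three predictors absent are removed as `predictor`); (3)
#' remove records with 1000 Genomes AF > 0.05 (`kg_common`); (4) remove
#' records with fewer than 5 supporting reads in total or fewer than 2 on
#' either strand (`read_support`).
#'
#' @inheritParams filter_gatk_branch
#' @return List with `records` and `removed` (reasons `impact_benign`,
#'   `predictor`, `kg_common`, `read_support`).
#' @export
pathogenicity_filter <- function(records, thresholds = cascade_thresholds()) {
  th <- thresholds
  if (nrow(records) == 0)
    return(filter_result(records, records, character()))
  low_benign <- !is.na(records$impact) & records$impact == "LOW" &
    !is.na(records$clnsig) & records$clnsig == "benign"
  sift_del <- !is.na(records$sift) & records$sift == "deleterious"
  poly_dam <- !is.na(records$polyphen) & records$polyphen == "damaging"
  am_path <- !is.na(records$am_class) & records$am_class == "pathogenic"
  predicted <- (sift_del & poly_dam) | am_path
  kg_hit <- !is.na(records$kg_af) & records$kg_af > th$kg_af_max
  total <- records$sb_fwd + records$sb_rev
  weak <- is.na(total) | total < th$min_total_reads |
    pmin(records$sb_fwd, records$sb_rev) < th$min_strand_reads
  reason <- rep(NA_character_, nrow(records))
  reason[weak] <- "read_support"
  reason[kg_hit] <- "kg_common"
  reason[!predicted] <- "predictor"
  reason[low_benign] <- "impact_benign"   # rule order: first match wins
  keep <- is.na(reason)
  filter_result(records[keep, , drop = FALSE],
                records[!keep, , drop = FALSE], reason[!keep])
}

#' Panel tumor mutational burden
#'
#' TMB in mutations per megabase: the number of final retained variants
#' (CNVs excluded) divided by the panel footprint (1.7 Mb by default).
#'
#' @param final_records Final variant records (or a count).
#' @param panel_size_mb Panel size in megabases; must be > 0.
#' @return Numeric TMB in mut/Mb.
#' @export
#' @examples
#' compute_tmb(17)        # 10 mut/Mb on the 1.7 Mb panel
compute_tmb <- function(final_records, panel_size_mb = 1.7) {
  if (panel_size_mb <= 0) stop("panel_size_mb must be > 0")
  n <- if (is.data.frame(final_records)) nrow(final_records)
       else as.numeric(final_records)
  n / panel_size_mb
}

#' Run the full per-sample cascade
#'
#' Applies the stages in order (GATK-branch filter, caller merge, pool
#' subtraction, post-filtration, pathogenicity rules) and assembles the
#' removal ledger: every input key is either retained or attributed to
#' exactly one removal stage (the first that discarded it).
#'
#' @param ts,gatk,ir Caller record sets for one sample.
#' @param pool_keys Pool-of-normals keys or records.
#' @param thresholds A [cascade_thresholds()], possibly policy-adjusted
#'   via [apply_deamination_policy()].
#' @param panel_size_mb Panel size for TMB.
#' @return List with `final` (records), `tmb`, `gene_flags` (named 0/1
#'   per mutated gene), and `ledger` (data.frame `key`, `stage`).
#' @export
run_cascade <- function(ts, gatk, ir, pool_keys = character(),
                        thresholds = cascade_thresholds(),
                        panel_size_mb = 1.7) {
  if (identical(attr(thresholds, "policy"), "rejected"))
    stop("sample disqualified by deamination score; no cascade run")
  ledger <- data.frame(key = character(), stage = character(),
                       stringsAsFactors = FALSE)
  note <- function(step, stage_override = NULL) {
    if (nrow(step$removed) > 0) {
      st <- if (is.null(stage_override)) step$removed$reason
            else stage_override
      ledger <<- rbind(ledger, data.frame(key = variant_key(step$removed),
                                          stage = st,
                                          stringsAsFactors = FALSE))
    }
    step$records
  }
  gf <- filter_gatk_branch(gatk, thresholds)
  gatk_kept <- note(gf)
  gatk_reason <- stats::setNames(gf$removed$reason,
                                 variant_key(gf$removed))

  mg <- merge_callers(ts, gatk_kept, ir)
  # TS/IR copies of records the GATK branch discarded inherit that reason
  if (nrow(mg$removed) > 0) {
    k <- variant_key(mg$removed)
    mg$removed$reason <- ifelse(k %in% names(gatk_reason),
                                gatk_reason[k], "merge")
    # drop keys already ledgered by the GATK step itself
    dup <- k %in% ledger$key
    mg$removed <- mg$removed[!dup, , drop = FALSE]
  }
  merged <- note(mg)

  pooled <- note(subtract_pool(merged, pool_keys))
  posted <- note(post_filter(pooled, thresholds))
  final <- note(pathogenicity_filter(posted, thresholds))

  genes <- sort(unique(final$gene[!is.na(final$gene)]))
  gene_flags <- stats::setNames(rep(1L, length(genes)), genes)
  list(final = final, tmb = compute_tmb(final, panel_size_mb),
       gene_flags = gene_flags, ledger = ledger)
}

#' Summarize copy-number events across the cohort
#'
#' @param cnv_table data.frame with `sample`, `gene`, `type`
#'   (`amp`/`del`).
#' @param cohort data.frame with `patient_id` and `subtype` covering all
#'   samples in `cnv_table`.
#' @return List with `by_subtype` (event counts per subtype and type),
#'   `n_events`, and `fraction_patients` with at least one event.
#' @export
summarize_cnv <- function(cnv_table, cohort) {
  unknown <- setdiff(cnv_table$sample, cohort$patient_id)
  if (length(unknown) > 0)
    stop("unknown sample id(s) in CNV table: ",
         paste(unknown, collapse = ", "))
  sub <- cohort$subtype[match(cnv_table$sample, cohort$patient_id)]
  by_subtype <- as.data.frame(table(subtype = factor(sub, chs_subtypes()),
                                    type = factor(cnv_table$type,
                                                  c("amp", "del"))),
                              responseName = "n_events")
  list(by_subtype = by_subtype,
       n_events = nrow(cnv_table),
       fraction_patients = length(unique(cnv_table$sample)) /
         nrow(cohort))
}
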