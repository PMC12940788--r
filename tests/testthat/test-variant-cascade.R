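# The filtration cascade: per-stage rules at their inclusive boundaries,
# the deamination policy, caller-merge set algebra, pool subtraction,
# pathogenicity rule order, TMB, ground-truth separation and the ledger
# partition invariant.

test_that("GATK SNP/MNP thresholds are inclusive", {
  kept <- make_record(dp = 15, af = 0.015, tlod = 14)
  out <- filter_gatk_branch(kept)
  expect_equal(nrow(out$records), 1)
  for (bad in list(make_record(dp = 14, af = 0.9, tlod = 100),
                   make_record(dp = 500, af = 0.0149, tlod = 100),
                   make_record(dp = 500, af = 0.9, tlod = 13.9))) {
    out <- filter_gatk_branch(bad)
    expect_equal(nrow(out$records), 0)
    expect_equal(out$removed$reason, "gatk_snv")
  }
})

test_that("GATK INDEL window is 0.35-0.55 at depth >= 70", {
  kept <- make_record(vclass = "INDEL", ref = "CAT", alt = "C",
                      dp = 70, af = 0.35, tlod = NA)
  expect_equal(nrow(filter_gatk_branch(kept)$records), 1)
  kept$af <- 0.55
  expect_equal(nrow(filter_gatk_branch(kept)$records), 1)
  kept$af <- 0.56
  out <- filter_gatk_branch(kept)
  expect_equal(out$removed$reason, "gatk_indel")
  kept$af <- 0.45; kept$dp <- 69
  expect_equal(filter_gatk_branch(kept)$removed$reason, "gatk_indel")
})

test_that("SNVs without TLOD are rejected as missing_quality_field", {
  rec <- make_record(tlod = NA)
  out <- filter_gatk_branch(rec)
  expect_equal(out$removed$reason, "missing_quality_field")
})

test_that("deamination policy adjusts thresholds exactly when triggered", {
  base <- cascade_thresholds()
  unchanged <- apply_deamination_policy(
    list(deamination_score = 9, prelim_tmb = 5), base)
  expect_equal(unchanged$post_af, 0.05)
  expect_equal(unchanged$gatk_snv_af, 0.015)
  expect_equal(attr(unchanged, "policy"), "standard")

  strict <- apply_deamination_policy(
    list(deamination_score = 12, prelim_tmb = 5), base)
  expect_equal(strict$ir_af, 0.1)
  expect_equal(strict$post_af, 0.1)
  expect_equal(strict$gatk_snv_af, 0.75)
  expect_equal(strict$annotation_profile, "Oncomine Variants")
  expect_equal(attr(strict, "policy"), "stricter")

  tmb_trig <- apply_deamination_policy(
    list(deamination_score = 0, prelim_tmb = 20), base)
  expect_equal(attr(tmb_trig, "policy"), "stricter")

  rej <- apply_deamination_policy(
    list(deamination_score = 26, prelim_tmb = 2), base)
  expect_equal(attr(rej, "policy"), "rejected")
  expect_error(run_cascade(empty_variant_records(),
                           empty_variant_records(),
                           empty_variant_records(), character(), rej),
               "disqualified")
})

test_that("caller merge implements (TS n GATK) u IR over all patterns", {
  recs <- lapply(1:7, function(i)
    make_record(chrom = "1", pos = 1000L + i, caller = "TS"))
  # membership patterns: bits TS, GATK, IR
  patterns <- expand.grid(ts = c(TRUE, FALSE), gatk = c(TRUE, FALSE),
                          ir = c(TRUE, FALSE))
  patterns <- patterns[rowSums(patterns) > 0, ]
  ts <- do.call(rbind, recs[which(patterns$ts)])
  gatk <- do.call(rbind, recs[which(patterns$gatk)])
  ir <- do.call(rbind, recs[which(patterns$ir)])
  out <- merge_callers(ts, gatk, ir)
  got <- variant_key(out$records)
  for (i in seq_len(nrow(patterns))) {
    expected_in <- (patterns$ts[i] && patterns$gatk[i]) || patterns$ir[i]
    expect_equal(variant_key(recs[[i]]) %in% got, expected_in)
  }
  # provenance unions the callers that reported the variant
  both <- which(patterns$ts & patterns$gatk & patterns$ir)[1]
  expect_equal(out$records$caller[got == variant_key(recs[[both]])],
               "TS,GATK,IR")
  expect_true(all(out$removed$reason == "merge"))
})

test_that("conflicting REF alleles at one locus abort the merge", {
  ts <- make_record(chrom = "1", pos = 500L, ref = "A", alt = "G")
  gatk <- make_record(chrom = "1", pos = 500L, ref = "C", alt = "G")
  expect_error(merge_callers(ts, gatk, empty_variant_records()),
               "conflicting REF")
})

test_that("pool subtraction removes exactly the shared keys", {
  a <- make_record(chrom = "1", pos = 100L)
  b <- make_record(chrom = "2", pos = 200L)
  out <- subtract_pool(rbind(a, b), variant_key(a))
  expect_equal(variant_key(out$records), variant_key(b))
  expect_equal(out$removed$reason, "pool")
  expect_equal(nrow(subtract_pool(rbind(a, b), character())$removed), 0)
})

test_that("post-filtration floors are inclusive", {
  expect_equal(nrow(post_filter(make_record(af = 0.05, dp = 50))$records),
               1)
  expect_equal(post_filter(make_record(af = 0.049, dp = 500))
               $removed$reason, "post_filter")
  expect_equal(post_filter(make_record(af = 0.5, dp = 49))
               $removed$reason, "post_filter")
  # policy-adjusted floor
  th <- apply_deamination_policy(list(deamination_score = 12,
                                      prelim_tmb = 1))
  expect_equal(post_filter(make_record(af = 0.07, dp = 500), th)
               $removed$reason, "post_filter")
})

test_that("pathogenicity rules fire in order with the documented reasons", {
  # LOW impact + benign ClinVar removed first, regardless of predictors
  r <- make_record(impact = "LOW", clnsig = "benign", kg_af = 0.5)
  expect_equal(pathogenicity_filter(r)$removed$reason, "impact_benign")
  # predictor gate: SIFT+PolyPhen route and AlphaMissense route
  keep_a <- make_record(sift = "deleterious", polyphen = "damaging",
                        am_class = "benign")
  keep_b <- make_record(sift = NA, polyphen = NA, am_class = "pathogenic")
  expect_equal(nrow(pathogenicity_filter(keep_a)$records), 1)
  expect_equal(nrow(pathogenicity_filter(keep_b)$records), 1)
  drop_half <- make_record(sift = "deleterious", polyphen = "benign",
                           am_class = "benign")
  expect_equal(pathogenicity_filter(drop_half)$removed$reason,
               "predictor")
  all_absent <- make_record(sift = NA, polyphen = NA, am_class = NA)
  expect_equal(pathogenicity_filter(all_absent)$removed$reason,
               "predictor")
  # population frequency
  common <- make_record(kg_af = 0.06)
  expect_equal(pathogenicity_filter(common)$removed$reason, "kg_common")
  expect_equal(nrow(pathogenicity_filter(make_record(kg_af = 0.05))
                    $records), 1)
  # read support: < 5 total or < 2 on either strand
  expect_equal(pathogenicity_filter(make_record(sb_fwd = 1, sb_rev = 10))
               $removed$reason, "read_support")
  expect_equal(pathogenicity_filter(make_record(sb_fwd = 2, sb_rev = 2))
               $removed$reason, "read_support")
  expect_equal(nrow(pathogenicity_filter(make_record(sb_fwd = 2,
                                                     sb_rev = 3))
                    $records), 1)
})

test_that("TMB is count over panel size with exact values", {
  expect_equal(compute_tmb(empty_variant_records()), 0)
  expect_equal(compute_tmb(17), 10)
  expect_equal(compute_tmb(4), 4 / 1.7)
  expect_equal(compute_tmb(10, panel_size_mb = 2), 5)
  expect_error(compute_tmb(3, panel_size_mb = 0), "> 0")
  # linearity
  co <- tiny_cohort(seed = 9, n = 4)
  id <- co$clinical$patient_id[1]
  n <- nrow(co$truth$variants[[id]])
  expect_equal(compute_tmb(2 * n), 2 * compute_tmb(n))
})

test_that("cascade separates ground truth perfectly with a partitioned ledger", {
  co <- tiny_cohort(seed = 10, n = 25)
  for (id in co$clinical$patient_id) {
    cc <- co$callers[[id]]
    res <- run_cascade(cc$ts, cc$gatk, cc$ir, co$pool)
    truth_keys <- variant_key(co$truth$variants[[id]])
    cont <- co$truth$contaminants[[id]]
    expect_setequal(variant_key(res$final), truth_keys)
    # each contaminant removed at exactly its tagged stage
    led <- stats::setNames(res$ledger$stage, res$ledger$key)
    expect_equal(unname(led[variant_key(cont)]), cont$stage)
    # ledger partitions input minus final
    input_keys <- unique(c(variant_key(cc$ts), variant_key(cc$gatk),
                           variant_key(cc$ir)))
    expect_setequal(c(variant_key(res$final), res$ledger$key), input_keys)
    expect_false(any(duplicated(res$ledger$key)))
  }
})

test_that("cascade output is insensitive to input record order", {
  co <- tiny_cohort(seed = 11, n = 5)
  id <- co$clinical$patient_id[2]
  cc <- co$callers[[id]]
  res1 <- run_cascade(cc$ts, cc$gatk, cc$ir, co$pool)
  set.seed(1)
  perm <- function(x) x[sample(nrow(x)), , drop = FALSE]
  res2 <- run_cascade(perm(cc$ts), perm(cc$gatk), perm(cc$ir), co$pool)
  expect_setequal(variant_key(res1$final), variant_key(res2$final))
  expect_equal(res1$tmb, res2$tmb)
})

test_that("each stage output is a subset of its input", {
  co <- tiny_cohort(seed = 12, n = 5)
  id <- co$clinical$patient_id[1]
  cc <- co$callers[[id]]
  g <- filter_gatk_branch(cc$gatk)
  expect_true(all(variant_key(g$records) %in% variant_key(cc$gatk)))
  m <- merge_callers(cc$ts, g$records, cc$ir)
  expect_true(all(variant_key(m$records) %in%
                    c(variant_key(cc$ts), variant_key(cc$ir))))
  p <- subtract_pool(m$records, co$pool)
  expect_true(all(variant_key(p$records) %in% variant_key(m$records)))
  q <- post_filter(p$records)
  expect_true(all(variant_key(q$records) %in% variant_key(p$records)))
  f <- pathogenicity_filter(q$records)
  expect_true(all(variant_key(f$records) %in% variant_key(q$records)))
})

test_that("CNV summaries count events and affected patients", {
  cohort <- data.frame(patient_id = paste0("P", 1:4),
                       subtype = c("G1", "G2", "G3", "DD"))
  empty <- data.frame(sample = character(), gene = character(),
                      type = character())
  s0 <- summarize_cnv(empty, cohort)
  expect_equal(s0$n_events, 0)
  expect_equal(s0$fraction_patients, 0)
  one <- data.frame(sample = "P2", gene = "RB1", type = "del")
  s1 <- summarize_cnv(one, cohort)
  expect_equal(s1$fraction_patients, 0.25)
  expect_equal(s1$by_subtype$n_events[s1$by_subtype$subtype == "G2" &
                                        s1$by_subtype$type == "del"], 1)
  expect_error(summarize_cnv(data.frame(sample = "NOPE", gene = "X",
                                        type = "amp"), cohort),
               "unknown sample")
})

test_that("synthetic CNV fractions match a truth-ledger recount", {
  co <- tiny_cohort(seed = 13, n = 40)
  s <- summarize_cnv(co$cnv, co$clinical)
  expect_equal(s$n_events, nrow(co$cnv))
  expect_equal(s$fraction_patients,
               length(unique(co$cnv$sample)) / 40)
})
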