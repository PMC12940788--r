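# Shared in-code fixtures for the test suite.

# one variant record with fields that pass every cascade stage; override
# any field via ...
make_record <- function(chrom = "2", pos = 209110000L, ref = "C",
                        alt = "T", vclass = "SNP", dp = 500, af = 0.3,
                        tlod = 80, sb_fwd = 60, sb_rev = 60,
                        gene = "IDH1", impact = "MODERATE",
                        clnsig = "pathogenic", sift = "deleterious",
                        polyphen = "damaging", am_class = "pathogenic",
                        dbsnp = NA_character_, kg_af = NA_real_,
                        caller = "GATK") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vclass = vclass, dp = dp, af = af, tlod = tlod,
             sb_fwd = sb_fwd, sb_rev = sb_rev, gene = gene,
             impact = impact, clnsig = clnsig, sift = sift,
             polyphen = polyphen, am_class = am_class, dbsnp = dbsnp,
             kg_af = kg_af, caller = caller, stringsAsFactors = FALSE)
}

make_records <- function(...) do.call(rbind, list(...))

# small default-structure cohort for fast tests
tiny_cohort <- function(seed = 1, n = 30, ...) {
  generate_cohort(generator_config(n_patients = n, seed = seed), ...)
}

# density table with exactly three spherical groups, for clustering tests
blob_features <- function(n_per = 20, centers = rbind(c(0, 0), c(8, 0),
                                                      c(0, 8)),
                          sd = 0.5, seed = 42) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(stats::rnorm(n_per, centers[i, 1], sd),
          stats::rnorm(n_per, centers[i, 2], sd))))
  rownames(x) <- sprintf("S%02d", seq_len(nrow(x)))
  attr(x, "truth") <- rep(seq_len(nrow(centers)), each = n_per)
  x
}
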