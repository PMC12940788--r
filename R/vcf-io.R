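# VCF 4.2 interchange for the three caller dialects and the pool set.
# Quality and annotation values travel in INFO keys DP, AF, TLOD, SB_FWD,
# SB_REV, IMPACT, CLNSIG, SIFT, POLYPHEN, AM_CLASS, DBSNP, KG_AF, GENE,
# VCLASS; absent values are omitted from INFO (never written as zero).

vcf_info_keys <- function() {
  data.frame(
    key = c("DP", "AF", "TLOD", "SB_FWD", "SB_REV", "GENE", "VCLASS",
            "IMPACT", "CLNSIG", "SIFT", "POLYPHEN", "AM_CLASS", "DBSNP",
            "KG_AF"),
    col = c("dp", "af", "tlod", "sb_fwd", "sb_rev", "gene", "vclass",
            "impact", "clnsig", "sift", "polyphen", "am_class", "dbsnp",
            "kg_af"),
    type = c("Integer", "Float", "Float", "Integer", "Integer", "String",
             "String", "String", "String", "String", "String", "String",
             "String", "Float"),
    stringsAsFactors = FALSE)
}

#' Write variant records as a VCF 4.2 file
#'
#' @param records Variant record data.frame (canonical column set used
#'   throughout the cascade).
#' @param path Output file path.
#' @param sample_id Sample name recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_caller_vcf <- function(records, path, sample_id = "SAMPLE") {
  keys <- vcf_info_keys()
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##sample=%s", sample_id),
           sprintf(
             '##INFO=<ID=%s,Number=1,Type=%s,Description="%s">',
             keys$key, keys$type, keys$key),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    parts <- character()
    for (j in seq_len(nrow(keys))) {
      v <- records[[keys$col[j]]][i]
      if (is.null(v) || is.na(v)) next
      if (is.numeric(v)) v <- format(v, digits = 15, scientific = FALSE)
      parts <- c(parts, paste0(keys$key[j], "=", v))
    }
    id <- records$dbsnp[i]
    lines[i] <- paste(records$chrom[i], records$pos[i],
                      if (is.na(id)) "." else id,
                      records$ref[i], records$alt[i], ".", "PASS",
                      if (length(parts)) paste(parts, collapse = ";") else ".",
                      sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Parse a caller VCF into variant records
#'
#' Reads a VCF 4.2 file produced by one of the three caller dialects (or
#' the pool of normals) into the canonical variant record table.
#' Multi-allelic sites are split into one record per alternate allele;
#' INFO keys missing from a record become `NA`, never zero.
#'
#' @param path VCF file path.
#' @param dialect One of `"TS"`, `"GATK"`, `"IR"`, `"POOL"`; recorded as
#'   the record's caller provenance.
#' @return Variant record data.frame.
#' @export
parse_caller_vcf <- function(path, dialect = c("TS", "GATK", "IR", "POOL")) {
  dialect <- match.arg(dialect)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (is.null(dim(fm)))                      # single-record files
    fm <- matrix(fm, nrow = 1, dimnames = list(NULL, names(fm)))
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_variant_records())
  keys <- vcf_info_keys()
  info <- lapply(seq_len(nrow(keys)), function(j)
    vcfR::extract.info(v, element = keys$key[j]))
  names(info) <- keys$col

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    pick <- function(col, k) {
      x <- info[[col]][i]
      if (is.null(x) || is.na(x)) return(NA_character_)
      vals <- strsplit(x, ",", fixed = TRUE)[[1]]
      if (length(vals) == length(alts)) vals[k] else vals[1]
    }
    do.call(rbind, lapply(seq_along(alts), function(k) {
      data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                 ref = fix$REF[i], alt = alts[k],
                 vclass = pick("vclass", k),
                 dp = as.numeric(pick("dp", k)),
                 af = as.numeric(pick("af", k)),
                 tlod = as.numeric(pick("tlod", k)),
                 sb_fwd = as.numeric(pick("sb_fwd", k)),
                 sb_rev = as.numeric(pick("sb_rev", k)),
                 gene = pick("gene", k), impact = pick("impact", k),
                 clnsig = pick("clnsig", k), sift = pick("sift", k),
                 polyphen = pick("polyphen", k),
                 am_class = pick("am_class", k),
                 dbsnp = pick("dbsnp", k),
                 kg_af = as.numeric(pick("kg_af", k)),
                 caller = dialect, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, variant_columns()]
}

#' Normalize variant records by trimming and left-alignment
#'
#' Trims bases shared by REF and ALT (suffix first, then prefix, keeping
#' at least one base of each allele) and, when a reference fetcher is
#' supplied, shifts insertions/deletions to their leftmost equivalent
#' position so every record carries its canonical `(chrom, pos, ref,
#' alt)` key.
#'
#' @param records Variant record data.frame.
#' @param ref_fetch `NULL`, or `function(chrom, start, end)` returning the
#'   reference bases of the closed 1-based interval. Required for
#'   left-shifting; trimming alone needs no reference.
#' @return The records with canonical coordinates and alleles.
#' @export
normalize_left_align <- function(records, ref_fetch = NULL) {
  if (nrow(records) == 0) return(records)
  for (i in seq_len(nrow(records))) {
    pos <- records$pos[i]; ref <- records$ref[i]; alt <- records$alt[i]
    if (!is.null(ref_fetch)) {
      seen <- ref_fetch(records$chrom[i], pos, pos + nchar(ref) - 1L)
      if (!identical(toupper(seen), toupper(ref)))
        stop(sprintf("reference mismatch at %s:%d (expected %s, context %s)",
                     records$chrom[i], pos, ref, seen))
    }
    last_ch <- function(x) substr(x, nchar(x), nchar(x))
    if (is.null(ref_fetch)) {
      # without reference context only trims that keep both alleles
      # non-empty are safe
      while (nchar(ref) > 1 && nchar(alt) > 1 &&
             last_ch(ref) == last_ch(alt)) {
        ref <- substr(ref, 1, nchar(ref) - 1L)
        alt <- substr(alt, 1, nchar(alt) - 1L)
      }
    } else {
      # trim trailing shared base; when an allele empties, extend both
      # one reference base to the left (leftmost equivalent position)
      repeat {
        if (nchar(ref) > 0 && nchar(alt) > 0 &&
            last_ch(ref) == last_ch(alt)) {
          ref <- substr(ref, 1, nchar(ref) - 1L)
          alt <- substr(alt, 1, nchar(alt) - 1L)
        } else if (nchar(ref) == 0 || nchar(alt) == 0) {
          if (pos <= 1L) stop(sprintf(
            "cannot left-extend variant at %s:%d past contig start",
            records$chrom[i], records$pos[i]))
          prev <- toupper(ref_fetch(records$chrom[i], pos - 1L, pos - 1L))
          ref <- paste0(prev, ref); alt <- paste0(prev, alt)
          pos <- pos - 1L
        } else break
      }
    }
    # trim leading shared bases (keep at least one of each allele)
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1L
    }
    records$pos[i] <- pos; records$ref[i] <- ref; records$alt[i] <- alt
  }
  records
}
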