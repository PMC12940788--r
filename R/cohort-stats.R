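# Cohort association statistics on the mutation matrix: gene-by-subtype
# Fisher exact tests, Kruskal-Wallis TMB comparisons, pairwise mutation
# co-occurrence, and pathway deregulation summaries against a curated
# gene-to-pathway map.

#' Build the patient-by-gene mutation matrix
#'
#' A gene counts as mutated in a patient if any retained SNV/INDEL from
#' the cascade falls in it, or if the patient carries a CNV event in it.
#'
#' @param profiles Named list (per patient) of [run_cascade()] results,
#'   or a named list of gene-flag vectors.
#' @param cnv_table Optional CNV event table (`sample`, `gene`, `type`).
#' @param patients Optional character vector fixing row order.
#' @return Integer matrix patients x genes with 0/1 flags; attribute
#'   `"classes"` holds the variant-class annotation (`snv`, `cnv` or
#'   `snv;cnv`) for oncoprint-style output.
#' @export
mutation_matrix <- function(profiles, cnv_table = NULL, patients = NULL) {
  flags <- lapply(profiles, function(p)
    if (is.list(p) && !is.null(p$gene_flags)) p$gene_flags else p)
  if (is.null(patients)) patients <- names(flags)
  genes <- sort(unique(c(unlist(lapply(flags, names)),
                         if (!is.null(cnv_table)) cnv_table$gene)))
  m <- matrix(0L, length(patients), length(genes),
              dimnames = list(patients, genes))
  cls <- matrix("", length(patients), length(genes),
                dimnames = list(patients, genes))
  for (id in patients) {
    g <- names(flags[[id]])[flags[[id]] == 1L]
    m[id, g] <- 1L; cls[id, g] <- "snv"
  }
  if (!is.null(cnv_table) && nrow(cnv_table) > 0) {
    for (i in seq_len(nrow(cnv_table))) {
      id <- cnv_table$sample[i]; g <- cnv_table$gene[i]
      if (!id %in% patients) next
      m[id, g] <- 1L
      cls[id, g] <- if (cls[id, g] == "") "cnv"
                    else if (grepl("cnv", cls[id, g])) cls[id, g]
                    else "snv;cnv"
    }
  }
  attr(m, "classes") <- cls
  m
}

#' Gene-by-subtype association tests
#'
#' For each gene mutated in at least `min_mutated` patients, a Fisher
#' exact test on the gene x subtype contingency table (exact network
#' enumeration), with Benjamini-Hochberg correction across tested genes.
#'
#' @param matrix Patient-by-gene 0/1 matrix.
#' @param subtypes Subtype per patient (matrix row order).
#' @param min_mutated Prevalence floor for testing a gene.
#' @return data.frame `gene`, `n_mutated`, `p`, `fdr`, sorted by `p`.
#' @export
gene_subtype_test <- function(matrix, subtypes, min_mutated = 3) {
  if (length(unique(subtypes)) < 2)
    stop("at least 2 subtypes required")
  counts <- colSums(matrix)
  test_genes <- names(counts)[counts >= min_mutated]
  skipped <- names(counts)[counts == 0]
  if (length(skipped))
    message("gene(s) mutated in 0 patients skipped: ",
            paste(skipped, collapse = ", "))
  rows <- lapply(test_genes, function(g) {
    tab <- table(factor(matrix[, g], levels = c(0, 1)), subtypes)
    data.frame(gene = g, n_mutated = counts[[g]],
               p = stats::fisher.test(tab, workspace = 2e7)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(), n_mutated = integer(),
                      p = numeric(), fdr = numeric()))
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Kruskal-Wallis comparison of TMB between groups
#'
#' Rank-based H statistic with tie correction and chi-square p-value on
#' k-1 degrees of freedom.
#'
#' @param tmb_values Numeric TMB per patient.
#' @param groups Group label per patient (>= 2 non-empty groups).
#' @return List with `statistic`, `df`, `p`.
#' @export
tmb_by_group <- function(tmb_values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("at least 2 non-empty groups required")
  kt <- stats::kruskal.test(tmb_values, groups)
  if (is.nan(kt$statistic)) {  # all values tied
    return(list(statistic = 0, df = unname(kt$parameter), p = 1))
  }
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Pairwise mutation co-occurrence / mutual exclusivity
#'
#' For every pair of genes each mutated at least once, a 2x2 Fisher exact
#' test; the odds ratio direction flags the pair as co-occurring (OR > 1)
#' or exclusive (OR < 1), with BH-adjusted q alongside the raw p.
#'
#' @param matrix Patient-by-gene 0/1 matrix.
#' @return data.frame `gene_a`, `gene_b`, `odds_ratio`, `p`, `q`,
#'   `direction`.
#' @export
cooccurrence <- function(matrix) {
  genes <- colnames(matrix)[colSums(matrix) >= 1]
  if (length(genes) < 2) stop("need >= 2 genes with >= 1 mutation")
  pairs <- utils::combn(genes, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tab <- table(factor(matrix[, a], c(0, 1)), factor(matrix[, b], c(0, 1)))
    ft <- stats::fisher.test(tab)
    or <- unname(ft$estimate)
    data.frame(gene_a = a, gene_b = b, odds_ratio = or, p = ft$p.value,
               direction = if (is.na(or)) NA_character_
                           else if (or > 1) "co-occurring"
                           else if (or < 1) "exclusive" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), c("gene_a", "gene_b", "odds_ratio", "p", "q",
                      "direction")]
}

#' Read the curated gene-to-pathway map
#'
#' The map ships as an editable CSV (`gene`, `pathway`); each gene maps
#' to at most one primary pathway.
#'
#' @param path CSV path; defaults to the map installed with the package.
#' @return data.frame `gene`, `pathway`.
#' @export
read_pathway_map <- function(path = system.file("extdata",
                                                "pathway_map.csv",
                                                package = "chsprofiler")) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(map$gene))
    stop("pathway map assigns multiple pathways to: ",
         paste(unique(map$gene[duplicated(map$gene)]), collapse = ", "))
  map
}

#' Pathway deregulation by stratum
#'
#' A patient counts as deregulated for a pathway iff any gene mapped to
#' it is altered. Percentages are reported overall and per stratum;
#' altered genes absent from the map are returned in `unmapped`.
#'
#' @param matrix Patient-by-gene 0/1 matrix.
#' @param map Pathway map ([read_pathway_map()]).
#' @param strata Optional named list of per-patient stratum labels (e.g.
#'   `list(subtype = ..., imp = ...)`), each in matrix row order.
#' @return List with `overall` (data.frame `pathway`, `n`, `percent`),
#'   `by_stratum` (one data.frame per stratum variable) and `unmapped`.
#' @export
pathway_deregulation <- function(matrix, map = read_pathway_map(),
                                 strata = NULL) {
  if (nrow(map) == 0) stop("pathway map is empty")
  unmapped <- setdiff(colnames(matrix)[colSums(matrix) > 0], map$gene)
  pws <- sort(unique(map$pathway))
  hit <- vapply(pws, function(pw) {
    genes <- intersect(map$gene[map$pathway == pw], colnames(matrix))
    if (length(genes) == 0) return(rep(FALSE, nrow(matrix)))
    rowSums(matrix[, genes, drop = FALSE]) > 0
  }, logical(nrow(matrix)))
  overall <- data.frame(pathway = pws, n = colSums(hit),
                        percent = 100 * colMeans(hit),
                        row.names = NULL)
  by_stratum <- lapply(strata, function(s)
    do.call(rbind, lapply(unique(s), function(lv)
      data.frame(stratum = lv, pathway = pws,
                 percent = 100 * colMeans(hit[s == lv, , drop = FALSE]),
                 row.names = NULL))))
  list(overall = overall, by_stratum = by_stratum, unmapped = unmapped)
}
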