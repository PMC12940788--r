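# Per-patient immunogram: six axes in [0,1] combining immune-suppressive
# cell density, IDH1 status, TMB status, PD-L1 presence, remaining-marker
# density and immune-checkpoint density. Density axes are cohort
# min-max-normalized means; status axes are binary.

immunogram_axis_markers <- function() {
  list(suppressive = c("FOXP3", "CD163", "CD68_KP1"),
       icp = c("TIM3", "LAG3", "GAL9", "PD1"))
}

#' Build per-patient immunograms
#'
#' Axis definitions: `a1` mean density of immune-suppressive cell
#' markers (FOXP3, CD163, CD68 clone KP1; both regions), min-max
#' normalized across the cohort; `a2` 1 iff IDH1 mutated; `a3` 1 iff TMB
#' above the cohort median; `a4` 1 iff the PD-L1 ordinal score is at
#' least 1 (any expression); `a5` normalized mean of all remaining
#' density markers in both regions (PD-L1 densities excluded - axis 4
#' carries PD-L1); `a6` normalized mean immune-checkpoint density
#' (TIM-3, LAG-3, Gal-9, PD-1).
#'
#' @param densities Marker-density table.
#' @param gene_flags Patient-by-gene 0/1 matrix (needs an `IDH1`
#'   column; patients without a row count as wild-type).
#' @param tmb Named numeric TMB per patient.
#' @return data.frame `patient_id`, `a1`..`a6`.
#' @export
build_immunograms <- function(densities, gene_flags, tmb) {
  ids <- densities$patient_id
  missing_tmb <- setdiff(ids, names(tmb))
  if (length(missing_tmb) > 0)
    stop("patient(s) missing from TMB input: ",
         paste(missing_tmb, collapse = ", "))
  ax <- immunogram_axis_markers()
  feats <- function(markers)
    as.vector(outer(markers, tumor_regions(), paste, sep = "_"))
  rest <- setdiff(chs_markers(), c(ax$suppressive, ax$icp, "PDL1"))
  mean_density <- function(markers) {
    m <- as.matrix(densities[, feats(markers), drop = FALSE])
    rowMeans(m, na.rm = TRUE)
  }
  minmax <- function(x) {
    r <- range(x, na.rm = TRUE)
    if (r[1] == r[2]) return(rep(0, length(x)))
    (x - r[1]) / (r[2] - r[1])
  }
  idh1 <- if ("IDH1" %in% colnames(gene_flags))
    gene_flags[match(ids, rownames(gene_flags)), "IDH1"] else 0L
  idh1[is.na(idh1)] <- 0L
  data.frame(
    patient_id = ids,
    a1 = minmax(mean_density(ax$suppressive)),
    a2 = as.integer(idh1 == 1L),
    a3 = as.integer(tmb[ids] > stats::median(tmb[ids])),
    a4 = as.integer(score_pdl1(densities$pdl1_percent) >= 1L),
    a5 = minmax(mean_density(rest)),
    a6 = minmax(mean_density(ax$icp)),
    stringsAsFactors = FALSE)
}

#' Mean immunogram profile per immunophenotype
#'
#' @param immunograms Output of [build_immunograms()].
#' @param labels Named IMP assignment per patient (must cover all
#'   patients in `immunograms`).
#' @return data.frame: one row per IMP with the arithmetic mean of each
#'   axis; empty groups yield `NA` means.
#' @export
summarize_by_imp <- function(immunograms, labels) {
  uncovered <- setdiff(immunograms$patient_id, names(labels))
  if (length(uncovered) > 0)
    stop("label(s) missing for: ", paste(uncovered, collapse = ", "))
  lv <- sort(unique(c(labels[immunograms$patient_id], imp_levels())))
  rows <- lapply(lv, function(g) {
    sel <- labels[immunograms$patient_id] == g
    axes <- immunograms[sel, paste0("a", 1:6), drop = FALSE]
    data.frame(imp = g, n = sum(sel),
               t(if (sum(sel) > 0) colMeans(axes)
                 else stats::setNames(rep(NA_real_, 6), paste0("a", 1:6))))
  })
  do.call(rbind, rows)
}
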