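# Density preprocessing and the cohort-level descriptive analyses that
# precede clustering: paired central-vs-peripheral comparisons and the
# marker-marker Spearman correlation map.

#' Extract the 40-feature density matrix from a marker-density table
#'
#' @param table Marker-density table (see [generate_marker_densities()]).
#' @return Numeric matrix, patients x 40 features, patient ids as
#'   rownames.
#' @export
density_matrix <- function(table) {
  m <- as.matrix(table[, density_features()])
  rownames(m) <- table$patient_id
  m
}

#' Preprocess densities for clustering
#'
#' Each feature is transformed `log(1 + x)` and standardized to zero mean
#' and unit variance. Patients missing more than `max_missing` of their
#' features are excluded; remaining missing values are imputed with the
#' feature median (on the log scale). Location/scale parameters are
#' stored in attributes so bootstrap resamples can be re-preprocessed the
#' same way.
#'
#' @param table Marker-density table or a raw non-negative matrix.
#' @param max_missing Maximum tolerated fraction of missing features per
#'   patient (default 0.25).
#' @return Standardized numeric matrix with attributes `center`, `scale`
#'   and `excluded` (ids of dropped patients). All-constant features get
#'   scale 1 with a warning.
#' @export
preprocess_densities <- function(table, max_missing = 0.25) {
  m <- if (is.matrix(table)) table else density_matrix(table)
  if (any(m < 0, na.rm = TRUE)) stop("densities must be non-negative")
  frac_missing <- rowMeans(is.na(m))
  excluded <- rownames(m)[frac_missing > max_missing]
  m <- m[frac_missing <= max_missing, , drop = FALSE]
  lx <- log1p(m)
  for (j in seq_len(ncol(lx))) {
    nas <- is.na(lx[, j])
    if (any(nas)) lx[nas, j] <- stats::median(lx[, j], na.rm = TRUE)
  }
  ctr <- colMeans(lx)
  scl <- apply(lx, 2, stats::sd)
  if (any(scl == 0 | is.na(scl))) {
    warning("constant feature(s) scaled by 1: ",
            paste(colnames(lx)[scl == 0 | is.na(scl)], collapse = ", "))
    scl[scl == 0 | is.na(scl)] <- 1
  }
  out <- sweep(sweep(lx, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "excluded") <- excluded
  out
}

#' Paired central-versus-peripheral region comparisons
#'
#' For each marker, a two-sided Wilcoxon signed-rank test on patients
#' with both regions measured, with Benjamini-Hochberg correction across
#' markers. Direction reports which region has the larger median density.
#'
#' @param table Marker-density table.
#' @return data.frame with `marker`, `n`, `statistic`, `p`, `q`,
#'   `direction` (`peripheral`, `central` or `none`). Markers with fewer
#'   than 2 complete pairs are skipped with a message.
#' @export
compare_regions <- function(table) {
  markers <- chs_markers()
  rows <- lapply(markers, function(mk) {
    x <- table[[paste0(mk, "_central")]]
    y <- table[[paste0(mk, "_peripheral")]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) {
      message("marker ", mk, " skipped: fewer than 2 complete pairs")
      return(NULL)
    }
    x <- x[ok]; y <- y[ok]
    d <- y - x
    if (all(d == 0)) {
      stat <- 0; p <- 1
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(y, x, paired = TRUE, exact = FALSE,
                           correct = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    dir <- if (stats::median(d) > 0) "peripheral"
           else if (stats::median(d) < 0) "central" else "none"
    data.frame(marker = mk, n = sum(ok), statistic = stat, p = p,
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("marker", "n", "statistic", "p", "q", "direction")]
}

#' Spearman correlation map of density features
#'
#' Pairwise Spearman rank correlations (average ranks on ties) across the
#' 40 density features, with two-sided p-values from the t approximation
#' and Benjamini-Hochberg q-values computed over the strict upper
#' triangle. Constant features yield `NA` correlations.
#'
#' @param table Marker-density table or numeric matrix.
#' @return List with matrices `rho`, `p`, `q` (symmetric; unit diagonal
#'   for `rho`).
#' @export
correlation_map <- function(table) {
  m <- if (is.matrix(table)) table else density_matrix(table)
  nf <- ncol(m)
  rho <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  n_pair <- crossprod(!is.na(m))
  tstat <- rho * sqrt((n_pair - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = pmax(n_pair - 2, 1),
                     lower.tail = FALSE)
  p[n_pair < 3] <- NA
  diag(p) <- NA
  p[abs(rho) >= 1 - 1e-12] <- 0       # perfect monotone association
  p[is.na(rho)] <- NA
  diag(rho) <- 1
  ut <- upper.tri(p)
  q <- matrix(NA_real_, nf, nf, dimnames = dimnames(p))
  q[ut] <- stats::p.adjust(p[ut], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  list(rho = rho, p = p, q = q)
}
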