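# Immunophenotype discovery: Ward-D2 hierarchical clustering of the
# preprocessed density features, chance-corrected agreement (ARI),
# bootstrap stability of the clustering solution, PCA marker
# contributions, and the density-ordering rule that names clusters
# cold / hot / intermediate.

#' Ward-D2 hierarchical clustering
#'
#' Agglomerative clustering on Euclidean distances with Ward's D2
#' criterion (squared-distance Lance-Williams update), cut at `k`
#' clusters.
#'
#' @param features Preprocessed numeric matrix (patients x features).
#' @param k Number of clusters (`2 <= k <= n`).
#' @return List with `labels` (integer vector named by rownames),
#'   `hclust` (the merge tree) and `k`.
#' @export
ward_cluster <- function(features, k) {
  n <- nrow(features)
  if (k > n) stop("k (", k, ") exceeds the number of patients (", n, ")")
  if (anyNA(features)) stop("features must not contain missing values")
  hc <- stats::hclust(stats::dist(features), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  list(labels = labels, hclust = hc, k = as.integer(k))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table:
#' `ARI = (sum_ij C(n_ij,2) - E) / (M - E)` with `E` and `M` from the
#' marginals. Equals 1 iff the partitions are identical up to label
#' permutation.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Numeric ARI (at most 1).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(labels_a))
  expected <- a * b / n2
  maximum <- (a + b) / 2
  if (maximum == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}

#' Bootstrap stability of a clustering solution
#'
#' For each of `B` iterations, patients are resampled with replacement,
#' preprocessing and Ward-D2 clustering are re-run at fixed `k` on the
#' resample, and the resample's labels are compared with the original
#' labels by the adjusted Rand index, restricted to the distinct
#' resampled patients (first occurrence of each duplicate).
#'
#' @param table Marker-density table (raw densities; preprocessing is
#'   recomputed per resample).
#' @param k Number of clusters.
#' @param B Bootstrap iterations (the reference protocol uses 1000).
#' @param seed Integer seed for reproducibility.
#' @param original Optional precomputed original labels.
#' @return List with `ari` (numeric vector, one value per completed
#'   iteration), `mean_ari` (`NA` if no iterations completed) and
#'   `skipped` (iterations with fewer than `k` distinct patients).
#' @export
bootstrap_stability <- function(table, k, B = 1000, seed = 1,
                                original = NULL) {
  feat <- preprocess_densities(table)
  if (is.null(original)) original <- ward_cluster(feat, k)$labels
  n <- nrow(feat)
  raw <- density_matrix(table)
  raw <- raw[setdiff(rownames(raw), attr(feat, "excluded")), , drop = FALSE]
  set.seed(seed)
  ari <- numeric(0); skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    first <- !duplicated(idx)
    if (sum(first) < k) { skipped <- skipped + 1L; next }
    bf <- preprocess_densities(raw[idx, , drop = FALSE])
    bl <- ward_cluster(bf, k)$labels
    ari <- c(ari, adjusted_rand_index(bl[first], original[idx[first]]))
  }
  if (skipped > 0)
    message(skipped, " bootstrap iteration(s) skipped: fewer than k ",
            "distinct patients")
  list(ari = ari, mean_ari = if (length(ari)) mean(ari) else NA_real_,
       skipped = skipped, B = B, k = k)
}

#' PCA contributions of the density features
#'
#' Principal components of the preprocessed matrix: orthonormal loadings
#' (sign convention: the largest-magnitude loading of each component is
#' positive) and explained-variance fractions summing to 1.
#'
#' @param features Preprocessed numeric matrix.
#' @return List with `loadings` (features x components),
#'   `explained_variance` (fractions), `scores`.
#' @export
pca_contributions <- function(features) {
  if (nrow(features) < 2) stop("PCA needs at least 2 patients")
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  list(loadings = loadings,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2),
       scores = scores)
}

#' Ordinal PD-L1 score
#'
#' 0 (no expression, below 1% positive cells), 1 (low, 1 to below 30%),
#' 2 (high, 30% or more).
#'
#' @param percent_positive Percent of positive cells in `[0, 100]`.
#' @return Integer score(s) in `{0, 1, 2}`.
#' @export
score_pdl1 <- function(percent_positive) {
  if (any(is.na(percent_positive)) ||
      any(percent_positive < 0 | percent_positive > 100))
    stop("percent_positive must lie in [0, 100]")
  ifelse(percent_positive < 1, 0L,
         ifelse(percent_positive < 30, 1L, 2L))
}

#' Tertiary lymphoid structure call
#'
#' TLS presence requires positive expression of all three components:
#' CD3 (T cells), CD20 (B cells) and LAMP3 (dendritic cells).
#'
#' @param cd3_pos,cd20_pos,lamp3_pos Logical component flags.
#' @return Logical TLS call.
#' @export
call_tls <- function(cd3_pos, cd20_pos, lamp3_pos) {
  cd3_pos & cd20_pos & lamp3_pos
}

#' Name clusters by total immune density
#'
#' Clusters are ranked by their mean total (summed over all markers and
#' regions) raw density: lowest becomes IMP1 ("cold"), highest IMP2
#' ("hot"), middle IMP3 ("intermediate"). With `k != 3` clusters are
#' named IMP1..IMPk by the same ordering, with a warning. Ties are broken
#' by cluster index.
#'
#' @param labels Integer cluster labels (from [ward_cluster()]).
#' @param table Marker-density table covering the labelled patients.
#' @return List with `imp` (character vector of IMP names per patient)
#'   and `mapping` (cluster id to IMP name).
#' @export
name_imps <- function(labels, table) {
  raw <- density_matrix(table)
  raw <- raw[names(labels), , drop = FALSE]
  total <- rowSums(raw, na.rm = TRUE)
  cl <- sort(unique(labels))
  mean_total <- vapply(cl, function(c) mean(total[labels == c]), numeric(1))
  k <- length(cl)
  ord <- order(mean_total, cl)   # ascending density, ties by cluster index
  imp_names <- if (k == 3) {
    nm <- character(3)
    nm[ord[1]] <- "IMP1"; nm[ord[3]] <- "IMP2"; nm[ord[2]] <- "IMP3"
    nm
  } else {
    warning("k = ", k, " clusters; naming generically IMP1..IMP", k,
            " by increasing density")
    nm <- character(k); nm[ord] <- paste0("IMP", seq_len(k)); nm
  }
  mapping <- stats::setNames(imp_names, cl)
  list(imp = unname(mapping[as.character(labels)]) |>
         stats::setNames(names(labels)),
       mapping = mapping)
}

#' Fit the immunophenotype model end to end
#'
#' Convenience wrapper: preprocess densities, select the cluster number
#' by the validity-index vote (unless `k` is given), cluster with
#' Ward-D2, name the clusters by density ordering, and optionally assess
#' bootstrap stability.
#'
#' @param table Marker-density table.
#' @param k Cluster number; `NULL` to select via [select_k()].
#' @param B Bootstrap iterations for stability (0 to skip).
#' @param seed Seed for the bootstrap.
#' @param ... Passed to [select_k()].
#' @return List with `imp` (named assignments), `labels`, `k`, `votes`
#'   (if selected), `hclust`, `mapping`, `stability`, `features`.
#' @export
fit_immunophenotypes <- function(table, k = NULL, B = 0, seed = 1, ...) {
  feat <- preprocess_densities(table)
  votes <- NULL
  if (is.null(k)) {
    sel <- select_k(feat, ...)
    k <- sel$k; votes <- sel$votes
  }
  wc <- ward_cluster(feat, k)
  nm <- name_imps(wc$labels, table)
  stability <- if (B > 0) bootstrap_stability(table, k, B = B, seed = seed,
                                              original = wc$labels)
  list(imp = nm$imp, labels = wc$labels, k = k, votes = votes,
       hclust = wc$hclust, mapping = nm$mapping, stability = stability,
       features = feat)
}
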