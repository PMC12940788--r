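# Ensemble cluster-number selection: a fixed panel of nine internal
# validity indices, each nominating one k over the candidate range for
# the Ward-D2 hierarchy; the returned k is the majority vote (ties
# toward smaller k). The panel preserves the ensemble-vote semantics of
# large index collections at tractable cost.

within_ss <- function(x, labels) {
  sum(vapply(unique(labels), function(c) {
    xi <- x[labels == c, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
}

cluster_centroids <- function(x, labels) {
  cl <- sort(unique(labels))
  t(vapply(cl, function(c) colMeans(x[labels == c, , drop = FALSE]),
           numeric(ncol(x))))
}

index_calinski_harabasz <- function(x, dmat, labels) {
  n <- nrow(x); k <- length(unique(labels))
  w <- within_ss(x, labels)
  tot <- sum(sweep(x, 2, colMeans(x))^2)
  ((tot - w) / (k - 1)) / (w / (n - k))
}

index_silhouette <- function(x, dmat, labels) {
  mean(cluster::silhouette(labels, dmatrix = dmat)[, "sil_width"])
}

index_davies_bouldin <- function(x, dmat, labels) {
  cl <- sort(unique(labels)); k <- length(cl)
  cent <- cluster_centroids(x, labels)
  s <- vapply(seq_len(k), function(i) {
    xi <- x[labels == cl[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cent[i, ])^2)))
  }, numeric(1))
  m <- as.matrix(stats::dist(cent))
  mean(vapply(seq_len(k), function(i)
    max(((s[i] + s[-i]) / m[i, -i])), numeric(1)))
}

index_dunn <- function(x, dmat, labels) {
  cl <- sort(unique(labels))
  same <- outer(labels, labels, "==")
  diam <- max(dmat[same & upper.tri(dmat)])
  sep <- min(dmat[!same & upper.tri(dmat)])
  sep / diam
}

index_c <- function(x, dmat, labels) {
  ut <- upper.tri(dmat)
  d <- dmat[ut]
  within <- outer(labels, labels, "==")[ut]
  nw <- sum(within)
  s <- sum(d[within])
  ds <- sort(d)
  smin <- sum(ds[seq_len(nw)])
  smax <- sum(ds[seq(length(ds) - nw + 1, length(ds))])
  (s - smin) / (smax - smin)
}

index_mcclain_rao <- function(x, dmat, labels) {
  ut <- upper.tri(dmat)
  d <- dmat[ut]
  within <- outer(labels, labels, "==")[ut]
  mean(d[within]) / mean(d[!within])
}

index_point_biserial <- function(x, dmat, labels) {
  ut <- upper.tri(dmat)
  d <- dmat[ut]
  within <- outer(labels, labels, "==")[ut]
  nw <- sum(within); nb <- sum(!within); nt <- length(d)
  (mean(d[!within]) - mean(d[within])) *
    sqrt(nw * nb / nt^2) / stats::sd(d)
}

index_hartigan_w <- function(x, labels) within_ss(x, labels)

# Gap statistic with uniform reference over the observed feature ranges
gap_statistic <- function(x, labels_by_k, k_range, B = 50) {
  logw <- vapply(k_range, function(k)
    log(within_ss(x, labels_by_k[[as.character(k)]])), numeric(1))
  rng_lo <- apply(x, 2, min); rng_hi <- apply(x, 2, max)
  logw_ref <- matrix(NA_real_, B, length(k_range))
  for (b in seq_len(B)) {
    xb <- sapply(seq_len(ncol(x)), function(j)
      stats::runif(nrow(x), rng_lo[j], rng_hi[j]))
    hb <- stats::hclust(stats::dist(xb), method = "ward.D2")
    for (i in seq_along(k_range))
      logw_ref[b, i] <- log(within_ss(xb, stats::cutree(hb, k_range[i])))
  }
  gap <- colMeans(logw_ref) - logw
  se <- apply(logw_ref, 2, stats::sd) * sqrt(1 + 1 / B)
  list(gap = gap, se = se)
}

#' Select the cluster number by validity-index vote
#'
#' Cuts the Ward-D2 hierarchy at each candidate `k` and lets each of nine
#' internal validity indices (Calinski-Harabasz, mean silhouette,
#' Davies-Bouldin, Dunn, C-index, McClain-Rao, point-biserial, gap
#' statistic with uniform reference, Hartigan) nominate one k. The
#' returned k is the majority vote; ties are broken toward smaller k.
#'
#' @param features Preprocessed numeric matrix.
#' @param k_min,k_max Candidate range (`k_max < n`).
#' @param gap_B Reference datasets for the gap statistic.
#' @param gap_seed Seed for the gap reference draws (global RNG state is
#'   restored afterwards).
#' @return List with `k` (selected), `votes` (named integer, one
#'   nomination per index) and `values` (matrix of index values by k).
#' @export
select_k <- function(features, k_min = 2, k_max = 8, gap_B = 50,
                     gap_seed = 1) {
  n <- nrow(features)
  if (k_max >= n) stop("k_max must be smaller than the number of patients")
  hc <- stats::hclust(stats::dist(features), method = "ward.D2")
  k_range <- seq(k_min, k_max)
  labels_by_k <- stats::setNames(
    lapply(c(k_range, k_max + 1), function(k) stats::cutree(hc, k)),
    c(k_range, k_max + 1))
  dmat <- as.matrix(stats::dist(features))

  maximize <- c(calinski_harabasz = TRUE, silhouette = TRUE,
                davies_bouldin = FALSE, dunn = TRUE, c_index = FALSE,
                mcclain_rao = FALSE, point_biserial = TRUE)
  fns <- list(calinski_harabasz = index_calinski_harabasz,
              silhouette = index_silhouette,
              davies_bouldin = index_davies_bouldin,
              dunn = index_dunn, c_index = index_c,
              mcclain_rao = index_mcclain_rao,
              point_biserial = index_point_biserial)
  values <- matrix(NA_real_, length(k_range), length(fns) + 2,
                   dimnames = list(k_range, c(names(fns), "gap", "hartigan")))
  for (i in seq_along(k_range)) {
    lab <- labels_by_k[[as.character(k_range[i])]]
    for (nm in names(fns))
      values[i, nm] <- tryCatch(fns[[nm]](features, dmat, lab),
                                error = function(e) NA_real_)
  }

  votes <- integer(0)
  for (nm in names(fns)) {
    v <- values[, nm]
    if (all(is.na(v))) next
    votes[nm] <- k_range[if (maximize[nm]) which.max(v) else which.min(v)]
  }

  # gap: smallest k with Gap(k) >= Gap(k+1) - se(k+1); needs k_max+1
  rs <- get0(".Random.seed", envir = globalenv())
  set.seed(gap_seed)
  gp <- gap_statistic(features, labels_by_k, c(k_range, k_max + 1), gap_B)
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
  values[, "gap"] <- gp$gap[seq_along(k_range)]
  ok <- which(gp$gap[seq_along(k_range)] >=
                gp$gap[seq_along(k_range) + 1] - gp$se[seq_along(k_range) + 1])
  votes["gap"] <- if (length(ok)) k_range[min(ok)] else k_max

  # Hartigan: smallest k with H(k) <= 10, else largest drop in H
  w <- vapply(c(k_range, k_max + 1), function(k)
    within_ss(features, labels_by_k[[as.character(k)]]), numeric(1))
  h <- (w[seq_along(k_range)] / w[seq_along(k_range) + 1] - 1) *
    (n - k_range - 1)
  values[, "hartigan"] <- h
  small <- which(h <= 10)
  votes["hartigan"] <- if (length(small)) k_range[min(small)]
  else k_range[which.max(-diff(c(h, h[length(h)])))]

  if (length(votes) == 0)
    stop("all validity indices undefined; cannot select k")
  tab <- table(factor(votes, levels = k_range))
  k_sel <- as.integer(names(tab)[which.max(tab)])  # ties -> smaller k
  list(k = k_sel, votes = votes, values = values)
}
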