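# Survival modelling: Kaplan-Meier product-limit curves, log-rank tests,
# Efron-tie Cox regression, a univariate gene screen with FDR, and
# LASSO-penalized Cox selection (10-fold cross-validation, one-standard-
# error lambda) with an unpenalized refit for interpretable hazard
# ratios and confidence intervals.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with the survival curve, the median survival
#' time (earliest time with S <= 0.5; `NA` if never reached) and S(t) at
#' query times.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event flags (1 = event observed).
#' @param query_times Optional times at which to evaluate S(t).
#' @return List with `time`, `surv`, `n_risk`, `n_event`, `median`,
#'   and `surv_at` (named by `query_times`).
#' @export
km_estimate <- function(times, events, query_times = NULL) {
  if (any(times <= 0)) stop("survival times must be > 0")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  step_t <- fit$time; step_s <- fit$surv
  med <- if (any(step_s <= 0.5)) min(step_t[step_s <= 0.5]) else NA_real_
  surv_at <- NULL
  if (!is.null(query_times)) {
    surv_at <- vapply(query_times, function(t) {
      if (t < min(step_t)) return(1)
      step_s[max(which(step_t <= t))]
    }, numeric(1))
    names(surv_at) <- query_times
  }
  list(time = step_t, surv = step_s, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med, surv_at = surv_at)
}

#' Log-rank test between survival groups
#'
#' Observed-minus-expected statistic over event times with hypergeometric
#' variance, chi-square on k-1 degrees of freedom. With no events in any
#' group the statistic is 0 and p = 1.
#'
#' @param times,events Survival outcome.
#' @param groups Group label per subject (>= 2 groups).
#' @return List with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("at least 2 groups required")
  if (sum(events) == 0) return(list(statistic = 0,
                                    df = nlevels(groups) - 1, p = 1))
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Efron-tie-corrected partial-likelihood maximization by Newton
#' iterations (convergence tolerance 1e-9, at most 50 iterations), with
#' Wald confidence intervals `exp(beta +/- 1.96 se)`. Monotone-likelihood
#' (perfect separation) coefficients are flagged and capped at |beta| =
#' 15 with a warning.
#'
#' @param times,events Survival outcome.
#' @param x Covariate matrix or data.frame (no constant columns).
#' @return List (`cox_fit`) with `coef`, `hr`, `se`, `ci_lower`,
#'   `ci_upper`, `p`, `loglik`, `separation_flagged`, and the underlying
#'   `coxph` model.
#' @export
cox_fit <- function(times, events, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(x)[const], collapse = ", "))
  if (sum(events) < 1) stop("at least one event required")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      # re-reported below as an explicit separation flag
      if (grepl("coefficient may be infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients)
  se <- sqrt(diag(as.matrix(fit$var)))
  flagged <- abs(beta) > 15 | se > 1e3
  if (any(flagged)) {
    warning("monotone likelihood suspected for: ",
            paste(colnames(x)[flagged], collapse = ", "),
            "; coefficient(s) capped")
    beta[flagged] <- sign(beta[flagged]) * 15
  }
  z <- beta / se
  list(coef = stats::setNames(beta, colnames(x)),
       hr = stats::setNames(exp(beta), colnames(x)),
       se = stats::setNames(se, colnames(x)),
       ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       loglik = fit$loglik[length(fit$loglik)],
       separation_flagged = stats::setNames(flagged, colnames(x)),
       model = fit)
}

#' Univariate Cox screen over gene mutation flags
#'
#' One single-covariate Cox fit per gene mutated in at least
#' `min_mutated` patients, with Benjamini-Hochberg FDR across tested
#' genes.
#'
#' @param times,events Survival outcome.
#' @param gene_flags Patient-by-gene 0/1 matrix.
#' @param min_mutated Prevalence floor.
#' @return data.frame `gene`, `n_mutated`, `hr`, `ci_lower`, `ci_upper`,
#'   `p`, `fdr`, sorted by p.
#' @export
univariate_screen <- function(times, events, gene_flags, min_mutated = 3) {
  counts <- colSums(gene_flags)
  variable <- apply(gene_flags, 2, function(v) stats::sd(v) > 0)
  genes <- colnames(gene_flags)[counts >= min_mutated & variable &
                                  counts < nrow(gene_flags)]
  if (length(genes) == 0) {
    message("no gene passes the prevalence floor")
    return(data.frame(gene = character(), n_mutated = integer(),
                      hr = numeric(), ci_lower = numeric(),
                      ci_upper = numeric(), p = numeric(), fdr = numeric()))
  }
  rows <- lapply(genes, function(g) {
    f <- suppressWarnings(
      cox_fit(times, events, gene_flags[, g, drop = FALSE]))
    data.frame(gene = g, n_mutated = counts[[g]], hr = unname(f$hr),
               ci_lower = unname(f$ci_lower),
               ci_upper = unname(f$ci_upper), p = unname(f$p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

# fold assignment stratified by event status, seeded and balanced
stratified_folds <- function(events, nfolds, seed) {
  set.seed(seed)
  foldid <- integer(length(events))
  for (e in unique(events)) {
    idx <- sample(which(events == e))
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  foldid
}

#' LASSO-penalized Cox selection with cross-validation
#'
#' L1-penalized partial-likelihood maximization over a 100-step
#' log-spaced lambda path, with per-fold cross-validated partial-
#' likelihood deviance (Verweij-van Houwelingen form, as implemented by
#' `glmnet`), fold assignment stratified by event status. The selected
#' lambda is the largest whose CV error is within one standard error of
#' the minimum (the sparsest such model); covariates with nonzero
#' coefficients there form the selected set, and reported hazard ratios
#' and confidence intervals come from an unpenalized [cox_fit()] refit on
#' that set. Covariates are standardized internally for the penalty;
#' coefficients are reported on the original scale.
#'
#' @param times,events Survival outcome.
#' @param x Covariate matrix (columns named).
#' @param nfolds Cross-validation folds (reduced with a warning if there
#'   are fewer events).
#' @param seed Seed for fold assignment.
#' @param lambda Optional fixed lambda path.
#' @return List (`lasso_cox`) with `selected`, `refit` (a [cox_fit()] or
#'   `NULL` if nothing selected), `lambda_min`, `lambda_1se`, `path`
#'   (data.frame `lambda`, `nzero`, `cvm`, `cvsd`), `coef_1se`
#'   (penalized coefficients at lambda_1se), `foldid`.
#' @export
lasso_cox <- function(times, events, x, nfolds = 10, seed = 1,
                      lambda = NULL) {
  x <- as.matrix(x)
  n_events <- sum(events)
  if (n_events < nfolds) {
    warning("fewer events (", n_events, ") than folds; reducing to ",
            max(3, n_events), " folds")
    nfolds <- max(3, n_events)
  }
  foldid <- stratified_folds(events, nfolds, seed)
  y <- survival::Surv(times, events)
  cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                          nlambda = 100, lambda = lambda,
                          standardize = TRUE)
  cf <- as.matrix(stats::coef(cv, s = "lambda.1se"))[, 1]
  selected <- names(cf)[cf != 0]
  refit <- if (length(selected) > 0)
    cox_fit(times, events, x[, selected, drop = FALSE])
  list(selected = selected, refit = refit,
       lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
       path = data.frame(lambda = cv$lambda, nzero = cv$nzero,
                         cvm = cv$cvm, cvsd = cv$cvsd),
       coef_1se = cf, foldid = foldid, cv = cv)
}

#' Build the multivariate covariate matrix from a cohort table
#'
#' Reference-coded design matrix combining clinical covariates (age,
#' tumour size, sex, site, margins; references: female, axial, R0),
#' histological subtype (reference G1), immunophenotype (reference
#' IMP1), TMB, and gene mutation flags for genes above the prevalence
#' floor.
#'
#' @param cohort data.frame with the clinical columns plus `imp`.
#' @param gene_flags Optional patient-by-gene 0/1 matrix (row order
#'   matching `cohort`).
#' @param tmb Optional numeric TMB per patient.
#' @param min_mutated Prevalence floor for gene columns.
#' @return Numeric covariate matrix.
#' @export
build_covariates <- function(cohort, gene_flags = NULL, tmb = NULL,
                             min_mutated = 3) {
  out <- cbind(age = cohort$age, size_cm = cohort$size_cm,
               sex_M = as.integer(cohort$sex == "M"),
               site_extremity = as.integer(cohort$site == "extremity"),
               margins_R1 = as.integer(cohort$margins == "R1"),
               subtype_G2 = as.integer(cohort$subtype == "G2"),
               subtype_G3 = as.integer(cohort$subtype == "G3"),
               subtype_DD = as.integer(cohort$subtype == "DD"),
               IMP2 = as.integer(cohort$imp == "IMP2"),
               IMP3 = as.integer(cohort$imp == "IMP3"))
  if (!is.null(tmb)) out <- cbind(out, tmb = tmb)
  if (!is.null(gene_flags)) {
    keep <- colSums(gene_flags) >= min_mutated &
      colSums(gene_flags) < nrow(gene_flags)
    out <- cbind(out, gene_flags[, keep, drop = FALSE])
  }
  rownames(out) <- cohort$patient_id
  out
}
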