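# Elastic-net Cox survival analysis: penalized fit, prognostic index,
# median risk stratification, log-rank testing.

#' Elastic-net Cox configuration
#'
#' @param shrinkage penalty weight (glmnet's lambda); `NULL` selects it by
#'   3-fold cross-validated partial likelihood over a logarithmic path.
#' @param l1Ratio relative weight of the L1 versus L2 penalty, in `[0, 1]`
#'   (0 = ridge, 1 = lasso); default 0.5.
#' @return Configuration list of class `"CoxConfig"`.
#' @export
coxConfig <- function(shrinkage = NULL, l1Ratio = 0.5) {
  if (!is.null(shrinkage) && shrinkage < 0) stopf("shrinkage must be >= 0")
  if (l1Ratio < 0 || l1Ratio > 1) stopf("l1Ratio must lie in [0, 1]")
  structure(list(shrinkage = shrinkage, l1Ratio = l1Ratio),
            class = "CoxConfig")
}

check_survival <- function(surv) {
  if (!all(c("sample_id", "time", "event") %in% colnames(surv)))
    stopf("survival data needs columns 'sample_id', 'time', 'event'")
  if (any(surv$time < 0)) stopf("survival times must be >= 0")
  if (!all(surv$event %in% c(0, 1))) stopf("event must be 0 (censored) or 1")
  if (anyDuplicated(surv$sample_id)) stopf("duplicate sample ids in survival data")
  surv
}

#' Fit a penalized Cox proportional hazards model
#'
#' Maximizes the elastic-net-penalized Cox partial likelihood over the
#' omics features. Multi-feature inputs use glmnet; a single-feature input
#' falls back to an unpenalized (or ridge-penalized) `coxph` fit, since
#' the coordinate-descent path needs at least two covariates.
#'
#' @param Y numeric matrix, rows = samples with survival data (rownames =
#'   sample ids).
#' @param surv data.frame with columns `sample_id`, `time`, `event`
#'   (1 = event observed, 0 = censored).
#' @param cfg a [coxConfig()].
#' @param seed seed for the cross-validated penalty selection.
#' @return Named coefficient vector (length = `ncol(Y)`).
#' @export
coxFit <- function(Y, surv, cfg = coxConfig(), seed = 1L) {
  Y <- as.matrix(Y)
  surv <- check_survival(surv)
  ids <- intersect(rownames(Y), as.character(surv$sample_id))
  if (length(ids) < 3L) stopf("need at least 3 samples with survival data")
  Y <- Y[ids, , drop = FALSE]
  sv <- surv[match(ids, surv$sample_id), ]
  if (sum(sv$event) < 2L) stopf("need at least 2 observed events")
  yy <- survival::Surv(sv$time, sv$event)
  if (ncol(Y) < 2L) {
    pen <- cfg$shrinkage %||% 0
    fit <- if (pen > 0)
      survival::coxph(yy ~ survival::ridge(Y[, 1L], theta = pen))
    else survival::coxph(yy ~ Y[, 1L])
    beta <- stats::setNames(unname(stats::coef(fit))[1L], colnames(Y))
    return(beta)
  }
  # drop constant features: they carry no partial-likelihood information
  keep <- apply(Y, 2L, function(x) stats::sd(x) > 0)
  beta <- stats::setNames(numeric(ncol(Y)), colnames(Y))
  if (sum(keep) < 2L) return(beta)
  Yk <- Y[, keep, drop = FALSE]
  if (is.null(cfg$shrinkage)) {
    cvfit <- with_local_seed(sub_seed(seed, "coxcv"),
      glmnet::cv.glmnet(Yk, yy, family = "cox", alpha = cfg$l1Ratio,
                        nfolds = 3L))
    lam <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    lam <- cfg$shrinkage
    fit <- glmnet::glmnet(Yk, yy, family = "cox", alpha = cfg$l1Ratio)
  }
  beta[keep] <- as.numeric(stats::coef(fit, s = lam))
  beta
}

#' Prognostic index
#'
#' The linear predictor `PI = Y %*% beta` of a fitted Cox model; higher
#' scores indicate higher risk.
#'
#' @param beta coefficient vector of length q.
#' @param Y_test numeric matrix (samples x q).
#' @return Named numeric vector of risk scores.
#' @export
prognosticIndex <- function(beta, Y_test) {
  Y_test <- as.matrix(Y_test)
  if (ncol(Y_test) != length(beta))
    stopf("matrix has %d features but beta has length %d",
          ncol(Y_test), length(beta))
  drop(Y_test %*% beta)
}

#' Median split into low- and high-risk groups
#'
#' Ranks the scores and assigns the lower half (ties at the median broken
#' toward low risk by stable sample order) to the low-risk group; group
#' sizes differ by at most one.
#'
#' @param scores numeric vector of prognostic scores (names = sample ids).
#' @return List with character (or integer) vectors `low` and `high`.
#' @export
medianRiskSplit <- function(scores) {
  n <- length(scores)
  if (n < 2L) stopf("need at least 2 samples to split")
  if (length(unique(scores)) == 1L)
    warnf("all scores identical; balanced split by stable sample order")
  ids <- names(scores) %||% seq_along(scores)
  ord <- order(scores)                      # stable: ties keep input order
  n_low <- ceiling(n / 2)
  list(low = ids[ord[seq_len(n_low)]], high = ids[ord[(n_low + 1L):n]])
}

#' Two-group log-rank test p-value
#'
#' Standard chi-squared log-rank comparison of the survival curves of the
#' two risk groups.
#'
#' @param groups list with elements `low` and `high` holding sample ids,
#'   as returned by [medianRiskSplit()].
#' @param surv data.frame with `sample_id`, `time`, `event`.
#' @return p-value in (0, 1].
#' @export
logrankPvalue <- function(groups, surv) {
  surv <- check_survival(surv)
  if (length(groups$low) == 0L || length(groups$high) == 0L)
    stopf("both risk groups must be non-empty")
  ids <- c(groups$low, groups$high)
  missing_ids <- setdiff(ids, surv$sample_id)
  if (length(missing_ids))
    stopf("no survival data for: %s",
          paste(utils::head(missing_ids, 5L), collapse = ", "))
  sv <- surv[match(ids, surv$sample_id), ]
  if (sum(sv$event) < 1L) stopf("need at least one observed event")
  grp <- factor(rep(c("low", "high"), c(length(groups$low), length(groups$high))))
  sd <- tryCatch(survival::survdiff(survival::Surv(sv$time, sv$event) ~ grp),
                 error = function(e) NULL)
  # degenerate tables (zero log-rank variance, e.g. all events at one time
  # in one group at full risk) carry no discriminating information
  if (is.null(sd)) return(1)
  as.numeric(1 - stats::pchisq(sd$chisq, df = 1L))
}

#' End-to-end survival evaluation of a completed matrix
#'
#' Convenience wrapper reproducing the prognostic protocol: split samples
#' 80/20, fit the elastic-net Cox model on the training portion of the
#' completed matrix, compute the prognostic index on the test portion,
#' median-split into risk groups and compare them by log-rank test.
#'
#' @param cm a [CompletedMatrix-class].
#' @param surv survival data.frame (`sample_id`, `time`, `event`).
#' @param cfg a [coxConfig()].
#' @param trainFraction fraction used to fit the Cox model, default 0.8.
#' @param seed seed for the split and penalty selection.
#' @return List with `beta`, `pi` (test-set scores), `groups`, `p`.
#' @export
survivalEvaluation <- function(cm, surv, cfg = coxConfig(),
                               trainFraction = 0.8, seed = 1L) {
  stopifnot(is(cm, "CompletedMatrix"))
  surv <- check_survival(surv)
  ids <- intersect(sampleIds(cm), as.character(surv$sample_id))
  n <- length(ids)
  if (n < 10L) stopf("need at least 10 samples with survival data")
  n_train <- as.integer(round_half_up(trainFraction * n))
  tr <- with_local_seed(sub_seed(seed, "survsplit"), sample(ids, n_train))
  te <- setdiff(ids, tr)
  X <- exprValues(cm)
  beta <- coxFit(X[tr, , drop = FALSE], surv, cfg, seed = seed)
  pi_te <- prognosticIndex(beta, X[te, , drop = FALSE])
  names(pi_te) <- te
  groups <- medianRiskSplit(pi_te)
  list(beta = beta, pi = pi_te, groups = groups,
       p = logrankPvalue(groups, surv))
}
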