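# Multivariate association of transformed feature abundances with clinical
# variables: arcsin-sqrt variance stabilization, abundance/prevalence
# feature filtering, component-wise L2-boosting covariate selection, a
# linear model with forced confounders (age, sex, smoking) and a twin-pair
# random intercept, and Benjamini-Hochberg FDR across the whole run.

#' Arcsin-square-root transform for proportions
#'
#' The variance-stabilizing transform \code{asin(sqrt(x))}, mapping [0, 1]
#' monotonically onto [0, pi/2]. Inputs outside [0, 1] by more than 1e-12
#' are rejected; tiny numerical overshoot is clamped.
#'
#' @param x proportions in [0, 1] (vectorized).
#' @return transformed values.
#' @export
arcsin_sqrt <- function(x) {
  if (any(is.na(x)) || any(x < -1e-12) || any(x > 1 + 1e-12))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  asin(sqrt(pmin(pmax(x, 0), 1)))
}

#' Filter features by abundance and prevalence
#'
#' Keeps features whose relative abundance strictly exceeds
#' \code{min_abundance} in strictly more than a \code{min_prevalence}
#' fraction of samples; emits a warning when nothing survives.
#'
#' @param table samples-by-features matrix-like (abundance or function table).
#' @param min_abundance strict abundance cutoff (default 0.001).
#' @param min_prevalence strict prevalence-fraction cutoff (default 0.1).
#' @return the filtered table (same class), possibly with zero columns.
#' @export
filter_features <- function(table, min_abundance = 0.001,
                            min_prevalence = 0.1) {
  assert_number(min_abundance, "min_abundance", 0, 1)
  assert_number(min_prevalence, "min_prevalence", 0, 1)
  m <- as.matrix(table)
  frac <- colMeans(m > min_abundance)
  keep <- frac > min_prevalence
  if (!any(keep)) warning("no features pass the abundance/prevalence filter")
  out <- m[, keep, drop = FALSE]
  if (inherits(table, "abundance_table"))
    return(abundance_table(out, rank = attr(table, "rank")))
  if (inherits(table, "function_table")) return(function_table(out))
  out
}

#' Association analysis configuration
#'
#' @param covariates_forced confounders always included in every model
#'   (default age, sex, smoking).
#' @param random_effect metadata column used as the random-intercept
#'   grouping factor (default \code{pair_id}, the twin pair).
#' @param n_iterations,learning_rate,selection_frequency_threshold
#'   boosting hyperparameters: number of boosting steps, shrinkage per step,
#'   and the fraction of steps in which a candidate must be chosen to count
#'   as selected.
#' @param min_abundance,min_prevalence feature filter thresholds.
#' @param q_threshold BH q-value cutoff used for reporting significance.
#' @param variables candidate clinical variables; default all of
#'   \code{\link{clinical_variables}} present in the metadata.
#' @return a list of class \code{association_config}.
#' @export
association_config <- function(covariates_forced = c("age", "sex", "smoking"),
                               random_effect = "pair_id",
                               n_iterations = 1000,
                               learning_rate = 0.01,
                               selection_frequency_threshold = 0.05,
                               min_abundance = 0.001,
                               min_prevalence = 0.1,
                               q_threshold = 0.2,
                               variables = NULL) {
  assert_number(n_iterations, "n_iterations", lower = 1, integer = TRUE)
  assert_number(learning_rate, "learning_rate", lower = 1e-6, upper = 1)
  assert_number(selection_frequency_threshold,
                "selection_frequency_threshold", 0, 1)
  assert_number(min_abundance, "min_abundance", 0, 1)
  assert_number(min_prevalence, "min_prevalence", 0, 1)
  assert_number(q_threshold, "q_threshold", 0, 1)
  structure(list(covariates_forced = covariates_forced,
                 random_effect = random_effect,
                 n_iterations = as.integer(n_iterations),
                 learning_rate = learning_rate,
                 selection_frequency_threshold = selection_frequency_threshold,
                 min_abundance = min_abundance,
                 min_prevalence = min_prevalence,
                 q_threshold = q_threshold,
                 variables = variables),
            class = "association_config")
}

#' Component-wise L2-boosting covariate selection
#'
#' Gradient boosting with univariate linear base learners: at each step the
#' standardized candidate giving the largest residual sum-of-squares
#' reduction is fit to the current residual and added with shrinkage
#' \code{learning_rate}. A candidate is selected when it is chosen in at
#' least \code{selection_frequency_threshold} of the steps. Zero-variance
#' candidates are excluded up front with a warning. The procedure is
#' deterministic; ties are broken by candidate order.
#'
#' @param y numeric response (a transformed feature), no missing values.
#' @param candidates numeric matrix or data frame of candidate covariates
#'   (rows = samples), no missing values, n >= 10.
#' @param config an \code{\link{association_config}} (boosting fields used).
#' @return character vector of selected candidate names (possibly empty),
#'   with the per-candidate selection frequencies as an attribute.
#' @export
select_covariates <- function(y, candidates, config = association_config()) {
  X <- as.matrix(candidates)
  if (ncol(X) == 0)
    return(structure(character(), frequencies = numeric()))
  if (anyNA(y) || anyNA(X))
    stop("boosting requires complete cases", call. = FALSE)
  if (length(y) < 10)
    stop("boosting requires n >= 10 samples", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance candidate(s) excluded: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(X) == 0)
    return(structure(character(), frequencies = numeric()))
  Xs <- scale(X)
  r <- y - mean(y)
  n <- length(y)
  counts <- integer(ncol(Xs))
  names(counts) <- colnames(Xs)
  xx <- rep(n - 1, ncol(Xs))  # crossprod of each standardized column
  for (it in seq_len(config$n_iterations)) {
    b <- as.vector(crossprod(Xs, r)) / xx
    gain <- b^2 * xx
    j <- which.max(gain)
    counts[j] <- counts[j] + 1L
    r <- r - config$learning_rate * b[j] * Xs[, j]
  }
  freq <- counts / config$n_iterations
  structure(names(freq)[freq >= config$selection_frequency_threshold],
            frequencies = freq)
}

#' Fit one feature's linear model with a twin-pair random intercept
#'
#' Fits \code{y ~ covariates + (1 | group)} by REML (lme4); when the
#' random-intercept variance is estimated at zero (singular fit) or the
#' mixed fit fails, falls back to ordinary least squares with a warning.
#' Fixed-effect p-values are Wald tests (normal reference for the mixed
#' model, t for OLS). Perfectly collinear columns are dropped with a
#' warning; rows with missing values are dropped listwise.
#'
#' @param y numeric response.
#' @param X data frame of covariates (numeric or factor).
#' @param groups grouping factor for the random intercept (e.g. pair id).
#' @return list with \code{coefficients} (data frame: term, coefficient, se,
#'   p),
#'   \code{n} (samples used), \code{method} ("lmm" or "ols") and
#'   \code{dropped} (aliased columns removed).
#' @export
fit_feature_model <- function(y, X, groups) {
  X <- as.data.frame(X)
  ok <- stats::complete.cases(X) & !is.na(y) & !is.na(groups)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; groups <- factor(groups[ok])
  dropped <- character()
  # drop constant and aliased columns
  for (col in names(X)) {
    v <- X[[col]]
    if ((is.numeric(v) && stats::sd(v) == 0) ||
        (is.factor(v) && nlevels(droplevels(v)) < 2)) {
      X[[col]] <- NULL
      dropped <- c(dropped, col)
    }
  }
  if (ncol(X)) {
    mm <- stats::model.matrix(~., data = X)
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      aliased <- colnames(mm)[qr_mm$pivot[-seq_len(qr_mm$rank)]]
      # map aliased model-matrix columns back to covariates via the assign
      # attribute and drop covariates all of whose columns are aliased
      term_of <- attr(mm, "assign")
      orig <- names(X)
      to_drop <- vapply(seq_along(orig), function(ti) {
        cols_of <- colnames(mm)[term_of == ti]
        length(cols_of) > 0 && all(cols_of %in% aliased)
      }, logical(1))
      X[orig[to_drop]] <- NULL
      dropped <- c(dropped, orig[to_drop])
      mm <- stats::model.matrix(~., data = X)
      if (qr(mm)$rank < ncol(mm))
        stop("design matrix singular after dropping aliased columns",
             call. = FALSE)
    }
  }
  if (length(dropped))
    warning("dropped collinear/constant covariate(s): ",
            paste(unique(dropped), collapse = ", "))
  if (length(y) <= ncol(stats::model.matrix(~., data = X)) + 1)
    stop("too few samples for the number of parameters", call. = FALSE)
  if (stats::sd(y) == 0) {
    # constant response: every slope is exactly zero, nothing to test
    terms <- setdiff(colnames(stats::model.matrix(~., data = X)),
                     "(Intercept)")
    return(list(coefficients = data.frame(term = terms, coefficient = 0,
                                          se = NA_real_, p = 1,
                                          stringsAsFactors = FALSE),
                n = length(y), method = "constant", dropped = unique(dropped)))
  }
  dat <- data.frame(.y = y, X, .g = groups, check.names = FALSE)
  rhs <- if (ncol(X)) paste(sprintf("`%s`", names(X)), collapse = " + ")
         else "1"
  fit <- NULL
  method <- "lmm"
  if (nlevels(groups) >= 2) {
    fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .g)"))
    fit <- tryCatch(
      suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-6)) fit <- NULL
  }
  if (is.null(fit)) {
    if (nlevels(groups) >= 2)
      warning("random-intercept variance 0 or mixed fit failed; ",
              "falling back to ordinary least squares")
    method <- "ols"
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), coefficient = sm[, 1],
                        se = sm[, 2], p = sm[, 4], row.names = NULL,
                        stringsAsFactors = FALSE)
  } else {
    sm <- summary(fit)$coefficients
    z <- sm[, "t value"]
    coefs <- data.frame(term = rownames(sm), coefficient = sm[, "Estimate"],
                        se = sm[, "Std. Error"],
                        p = 2 * stats::pnorm(-abs(z)), row.names = NULL,
                        stringsAsFactors = FALSE)
  }
  coefs$term <- gsub("`", "", coefs$term)
  list(coefficients = coefs[coefs$term != "(Intercept)", , drop = FALSE],
       n = length(y), method = method, dropped = unique(dropped))
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up adjusted p-values: \code{q_(i) = min_{j >= i} p_(j) * m / j},
#' capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the original order.
#' @export
fdr_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Run the full association analysis
#'
#' For every feature passing the abundance/prevalence filter: arcsin-sqrt
#' transform, boosting-based selection over the candidate clinical
#' variables, then a linear model of the transformed abundance on the
#' selected variables plus the forced confounders with a twin-pair random
#' intercept. Only the selected clinical variables are reported; BH FDR is
#' applied across all (feature, variable) tests of the run as one family.
#' Samples with missing candidate values are dropped per model, not
#' globally.
#'
#' @param features an \code{\link{abundance_table}} or
#'   \code{\link{function_table}}.
#' @param metadata a \code{\link{metadata_table}} covering the samples.
#' @param config an \code{\link{association_config}}.
#' @return data frame with columns \code{feature}, \code{variable},
#'   \code{coefficient} (on the transformed scale), \code{p}, \code{q},
#'   \code{n}; ordered by q then p.
#' @export
run_association <- function(features, metadata,
                            config = association_config()) {
  md <- as.data.frame(metadata)
  shared <- intersect(rownames(features), md$sample_id)
  if (length(shared) < 10)
    stop("need >= 10 samples shared between features and metadata",
         call. = FALSE)
  shared <- sort(shared)
  m <- as.matrix(features)[shared, , drop = FALSE]
  md <- md[match(shared, md$sample_id), ]
  m <- as.matrix(filter_features(m, config$min_abundance,
                                 config$min_prevalence))
  if (ncol(m) == 0)
    stop("no features pass the abundance/prevalence filter", call. = FALSE)
  vars <- config$variables %||% intersect(clinical_variables(), names(md))
  vars <- setdiff(vars, config$covariates_forced)
  if (!length(vars)) stop("no candidate clinical variables", call. = FALSE)
  forced <- intersect(config$covariates_forced, names(md))
  groups <- md[[config$random_effect]]
  cand <- md[, vars, drop = FALSE]
  rows <- list()
  for (feat in colnames(m)) {
    y <- arcsin_sqrt(m[, feat])
    cc <- stats::complete.cases(cand)
    sel <- select_covariates(y[cc], cand[cc, , drop = FALSE], config)
    if (!length(sel)) next
    X <- md[, c(sel, forced), drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(fit_feature_model(y, X, groups)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- fit$coefficients
    cf <- cf[cf$term %in% sel, , drop = FALSE]
    if (!nrow(cf)) next
    rows[[feat]] <- data.frame(feature = feat, variable = cf$term,
                               coefficient = cf$coefficient, p = cf$p,
                               n = fit$n, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(feature = character(), variable = character(),
                      coefficient = numeric(), p = numeric(), q = numeric(),
                      n = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- fdr_bh(out$p)
  out <- out[order(out$q, out$p), c("feature", "variable", "coefficient",
                                    "p", "q", "n")]
  rownames(out) <- NULL
  out
}
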