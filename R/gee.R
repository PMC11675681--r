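#' Logistic regression by generalized estimating equations
#'
#' Fits a marginal logistic model to clustered binary data (segments nested
#' in subjects) by the usual GEE iteration: Fisher scoring on the estimating
#' equations `sum_i D_i' V_i^{-1} (y_i - mu_i) = 0`, with a working
#' correlation `R(alpha)` re-estimated from Pearson residuals by moment
#' equations at every step, and the robust (sandwich) covariance for
#' inference. Estimates of the regression coefficients are consistent even
#' under a misspecified working correlation, which is why the sandwich
#' standard errors are reported rather than the model-based ones.
#'
#' Covariates with zero variance in the analysed rows are excluded from the
#' design (their coefficient is reported as `NA`). Rows with missing values
#' in the response or covariates are dropped and counted.
#'
#' @param data a data frame (one row per segment).
#' @param response name of a binary 0/1 column.
#' @param covariates character vector of covariate column names.
#' @param cluster name of the cluster (subject id) column.
#' @param corstr working correlation structure: `"exchangeable"` (default),
#'   `"independence"`, or `"ar1"` (adjacent segments within a subject).
#' @param maxit,tol scoring iteration controls.
#' @return An object of class `gee_fit`: coefficients, robust `se`, `z`, `p`,
#'   `alpha` (working-correlation parameter), `phi` (dispersion),
#'   `n_clusters`, `n_obs`, `n_dropped`, `aic` (independence
#'   quasi-likelihood AIC), `qic`, `vcov` (robust), `fitted`, plus bookkeeping
#'   (`response`, `covariates`, `excluded`, `corstr`, `converged`).
#' @export
fit_gee <- function(data, response, covariates, cluster,
                    corstr = c("exchangeable", "independence", "ar1"),
                    maxit = 50, tol = 1e-8) {
  corstr <- match.arg(corstr)
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  if (anyDuplicated(covariates)) stop("duplicate covariates", call. = FALSE)
  miss <- setdiff(c(response, covariates, cluster), names(data))
  if (length(miss)) {
    stop("columns not in data: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  y <- data[[response]]
  keep <- stats::complete.cases(data[c(response, covariates)])
  n_dropped <- sum(!keep)
  y <- as.numeric(y[keep])
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1", call. = FALSE)
  id <- as.character(data[[cluster]][keep])
  if (length(unique(y)) < 2L) {
    stop("degenerate response: only one class present", call. = FALSE)
  }
  if (length(unique(id)) < 2L) {
    stop("need at least 2 clusters", call. = FALSE)
  }
  xm <- as.matrix(data[keep, covariates, drop = FALSE])
  storage.mode(xm) <- "double"
  sds <- apply(xm, 2, stats::sd)
  excluded <- covariates[sds == 0 | !is.finite(sds)]
  used <- setdiff(covariates, excluded)
  if (!length(used)) stop("no usable covariates", call. = FALSE)
  X <- cbind("(Intercept)" = 1, xm[, used, drop = FALSE])
  # drop aliased (exactly collinear) columns, as glm() would report NA
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep_cols <- sort(qx$pivot[seq_len(qx$rank)])
    aliased <- setdiff(colnames(X), colnames(X)[keep_cols])
    excluded <- c(excluded, aliased)
    used <- setdiff(used, aliased)
    if (!length(used)) stop("no usable covariates", call. = FALSE)
    X <- X[, keep_cols, drop = FALSE]
  }

  ord <- order(id)                       # cluster-contiguous rows
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  id <- id[ord]
  cl <- split(seq_along(y), id)
  p <- ncol(X)
  nobs <- length(y)

  # start from the independence (ordinary logistic) fit
  beta <- tryCatch(
    suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial())$coefficients),
    error = function(e) rep(0, p))
  if (anyNA(beta)) beta <- ifelse(is.na(beta), 0, beta)

  alpha <- 0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    w <- sqrt(mu * (1 - mu))
    res <- (y - mu) / w                  # Pearson residuals
    phi <- sum(res^2) / (nobs - p)
    alpha <- estimate_alpha(res, cl, corstr, phi, p)

    lhs <- matrix(0, p, p)
    rhs <- numeric(p)
    for (idx in cl) {
      U <- X[idx, , drop = FALSE] * w[idx]
      ri <- res[idx]
      RU <- apply_rinv(U, corstr, alpha)
      lhs <- lhs + crossprod(RU, U)
      rhs <- rhs + drop(crossprod(RU, ri))
    }
    step <- tryCatch(solve(lhs, rhs), error = function(e) {
      stop("GEE scoring step failed (singular system); check for separation",
           call. = FALSE)
    })
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (any(!is.finite(beta)) || max(abs(beta)) > 1e4) {
    stop("GEE did not converge (diverging coefficients; possible separation)",
         call. = FALSE)
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  w <- sqrt(mu * (1 - mu))
  res <- (y - mu) / w
  phi <- sum(res^2) / (nobs - p)
  bread <- matrix(0, p, p)
  meat <- matrix(0, p, p)
  indep_info <- matrix(0, p, p)
  for (idx in cl) {
    U <- X[idx, , drop = FALSE] * w[idx]
    RU <- apply_rinv(U, corstr, alpha)
    bread <- bread + crossprod(RU, U)
    g <- drop(crossprod(RU, res[idx]))
    meat <- meat + tcrossprod(g)
    indep_info <- indep_info + crossprod(U)
  }
  binv <- solve(bread)
  vcov <- binv %*% meat %*% binv
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  pvals <- 2 * stats::pnorm(-abs(z))

  # binomial quasi-log-likelihood at the fitted means
  ql <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  aic <- -2 * ql + 2 * p
  qic <- -2 * ql + 2 * sum(diag(indep_info %*% vcov))  # Pan's trace penalty

  coef_full <- stats::setNames(rep(NA_real_, length(covariates) + 1L),
                               c("(Intercept)", covariates))
  coef_full[colnames(X)] <- beta
  structure(
    list(coefficients = beta, coef_full = coef_full, se = stats::setNames(se,
         colnames(X)), z = stats::setNames(z, colnames(X)),
         p = stats::setNames(pvals, colnames(X)),
         alpha = alpha, phi = phi, vcov = vcov,
         n_clusters = length(cl), n_obs = nobs, n_dropped = n_dropped,
         aic = aic, qic = qic, fitted = mu,
         response = response, covariates = used, excluded = excluded,
         cluster = cluster, corstr = corstr, converged = converged),
    class = "gee_fit"
  )
}

# Moment estimators of the working-correlation parameter.
estimate_alpha <- function(res, cl, corstr, phi, p) {
  if (corstr == "independence") return(0)
  num <- 0
  den <- 0
  for (idx in cl) {
    ri <- res[idx]
    ni <- length(ri)
    if (ni < 2L) next
    if (corstr == "exchangeable") {
      num <- num + (sum(ri)^2 - sum(ri^2)) / 2
      den <- den + ni * (ni - 1) / 2
    } else {                             # ar1: lag-1 products
      num <- num + sum(ri[-ni] * ri[-1])
      den <- den + ni - 1
    }
  }
  den <- den - p
  if (den <= 0 || phi <= 0) return(0)
  a <- num / (den * phi)
  nmax <- max(lengths(cl))
  lo <- if (corstr == "exchangeable") -1 / (nmax - 1) + 1e-6 else -0.95
  min(max(a, lo), 0.95)
}

# Apply R(alpha)^{-1} to the columns of a cluster block (closed forms; no
# ni x ni inversion).
apply_rinv <- function(U, corstr, alpha) {
  ni <- nrow(U)
  if (corstr == "independence" || alpha == 0 || ni == 1L) return(U)
  if (corstr == "exchangeable") {
    cs <- colSums(U)
    f <- alpha / (1 + (ni - 1) * alpha)
    return((U - matrix(cs * f, ni, ncol(U), byrow = TRUE)) / (1 - alpha))
  }
  # AR1 tridiagonal inverse
  out <- U * (1 + alpha^2)
  out[1, ] <- U[1, ]
  out[ni, ] <- U[ni, ]
  out[-ni, ] <- out[-ni, ] - alpha * U[-1, , drop = FALSE]
  out[-1, ] <- out[-1, ] - alpha * U[-ni, , drop = FALSE]
  out / (1 - alpha^2)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE logistic fit: %s ~ %s\n", x$response,
              paste(x$covariates, collapse = " + ")))
  cat(sprintf("clusters: %d, observations: %d, corstr: %s, alpha = %.3f\n",
              x$n_clusters, x$n_obs, x$corstr, x$alpha))
  tab <- data.frame(coef = x$coefficients, se = x$se, z = x$z, p = x$p)
  print(round(tab, 4))
  cat(sprintf("AIC (independence QL): %.2f  QIC: %.2f\n", x$aic, x$qic))
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' Predicted class probabilities from a GEE fit
#'
#' Applies the fitted marginal logistic model to new segments:
#' `p = plogis(intercept + sum beta * x)`.
#'
#' @param object a [fit_gee()] result.
#' @param newdata data frame containing all retained covariates.
#' @param type `"response"` (probability) or `"link"` (linear predictor).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.gee_fit <- function(object, newdata, type = c("response", "link"),
                            ...) {
  type <- match.arg(type)
  miss <- setdiff(object$covariates, names(newdata))
  if (length(miss)) {
    stop("newdata lacks covariates: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(1, as.matrix(newdata[object$covariates]))
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' Backward covariate elimination for a GEE model
#'
#' Starting from the full model, repeatedly refits with each single covariate
#' removed and accepts the removal that most lowers the selection criterion;
#' stops when no removal improves it (the intercept is never dropped). The
#' criterion is either the AIC of the independence binomial
#' quasi-likelihood at the GEE estimates (`"aic"`, the default) or the
#' correlation-adjusted QIC (`"qic"`).
#'
#' @inheritParams fit_gee
#' @param criterion `"aic"` or `"qic"`.
#' @return The final `gee_fit`, with a `selection_trace` data frame recording
#'   each accepted drop and the criterion value after it (non-increasing by
#'   construction).
#' @export
backward_select <- function(data, response, covariates, cluster,
                            corstr = c("exchangeable", "independence", "ar1"),
                            criterion = c("aic", "qic"), ...) {
  corstr <- match.arg(corstr)
  criterion <- match.arg(criterion)
  crit <- function(f) if (criterion == "aic") f$aic else f$qic
  current <- fit_gee(data, response, covariates, cluster, corstr, ...)
  trace <- data.frame(dropped = "<full model>", criterion = crit(current),
                      stringsAsFactors = FALSE)
  active <- current$covariates
  while (length(active) > 1L) {
    fits <- lapply(active, function(v) {
      tryCatch(fit_gee(data, response, setdiff(active, v), cluster, corstr,
                       ...),
               error = function(e) NULL)
    })
    vals <- vapply(fits, function(f) if (is.null(f)) Inf else crit(f),
                   numeric(1))
    best <- which.min(vals)
    if (vals[best] >= crit(current)) break
    current <- fits[[best]]
    trace <- rbind(trace, data.frame(dropped = active[best],
                                     criterion = vals[best],
                                     stringsAsFactors = FALSE))
    active <- current$covariates
  }
  current$selection_trace <- trace
  current$criterion <- criterion
  current
}

#' Stratified subject-level train/test split
#'
#' Groups subjects into strata of similar sleep-stage composition
#' (k-medoids on each subject's certain-stage share vector) and randomly
#' assigns about `train_frac` of the subjects of every stratum to the
#' training set. Whole subjects — never individual segments — move to one
#' side, preserving within-subject correlation and independence between the
#' sets.
#'
#' @param table a segment table (see [segment_table()]) with a `subject_id`
#'   column and `certain_*` label columns.
#' @param train_frac target share of subjects in training (default 0.7).
#' @param n_strata number of composition strata (default 4; reduced
#'   automatically when there are few subjects).
#' @param seed integer seed for the random assignment.
#' @return List with `train_subjects`, `test_subjects`, `strata` (named
#'   vector subject -> stratum), `achieved_train_fraction` (share of
#'   segments, not subjects, in training).
#' @export
stratified_subject_split <- function(table, train_frac = 0.7, n_strata = 4,
                                     seed = 1) {
  stopifnot(is.data.frame(table), "subject_id" %in% names(table))
  subjects <- unique(table$subject_id)
  if (length(subjects) < 3L) stop("need at least 3 subjects", call. = FALSE)
  lab_cols <- grep("^certain_", names(table), value = TRUE)
  shares <- t(vapply(subjects, function(s) {
    rows <- table$subject_id == s
    colMeans(table[rows, lab_cols, drop = FALSE])
  }, numeric(length(lab_cols))))
  k <- min(n_strata, max(1L, floor(length(subjects) / 2)))
  strata <- if (k > 1L) {
    cluster::pam(shares, k = k, cluster.only = TRUE)
  } else {
    rep(1L, length(subjects))
  }
  names(strata) <- subjects
  set.seed(seed)
  train <- character(0)
  for (g in unique(strata)) {
    members <- subjects[strata == g]
    n_tr <- round(train_frac * length(members))
    if (length(members) >= 2L) {
      n_tr <- min(max(n_tr, 1L), length(members) - 1L)
    }
    train <- c(train, sample(members, n_tr))
  }
  test <- setdiff(subjects, train)
  list(train_subjects = sort(train), test_subjects = sort(test),
       strata = strata,
       achieved_train_fraction = mean(table$subject_id %in% train))
}
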