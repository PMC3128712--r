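# Maximum-likelihood logistic regression by iteratively re-weighted least
# squares, and the nested likelihood-ratio test built on it. Written out
# rather than delegated so that convergence, separation and rank problems
# surface exactly as the scan needs them to (glm is used as an independent
# cross-check in the test suite).

# numerically stable log(1 + exp(z))
.log1pexp <- function(z) {
  pmax(z, 0) + log1p(exp(-abs(z)))
}

.bernoulli_ll <- function(y, eta) {
  sum(y * eta - .log1pexp(eta))
}

#' Fit a logistic regression by IRLS
#'
#' @param design a `design_matrix` (from [dosage_design()] /
#'   [genotype_design()]) or a plain numeric matrix that already contains an
#'   intercept column.
#' @param y binary response vector (0/1), one entry per design row.
#' @param tol convergence tolerance on the relative change of the
#'   log-likelihood (default 1e-10).
#' @param max_iter iteration cap (default 100).
#' @return a `logistic_fit`: `coef` (log-odds scale), `loglik` (Bernoulli
#'   log-likelihood at the estimates), `n_par`, `n`, `converged`,
#'   `iterations`, `separation` (flag: the fit drifted towards a perfectly
#'   separating solution and is reported as non-converged), `labels`.
#' @details Perfect separation is surfaced, never masked: such fits carry
#'   `converged = FALSE` and `separation = TRUE`. A rank-deficient design is
#'   an error naming the collinear columns.
#' @export
fit_logistic <- function(design, y, tol = 1e-10, max_iter = 100L) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must match nrow(design)")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (nrow(X) <= ncol(X)) stop("need more samples than parameters")
  const <- apply(X, 2L, function(v) diff(range(v)) == 0)
  if (any(const[-1L])) {
    stop("constant covariate column(s): ",
         paste(colnames(X)[-1L][const[-1L]], collapse = ", "))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dep, collapse = ", "))
  }

  beta <- numeric(ncol(X))
  ll <- .bernoulli_ll(y, drop(X %*% beta))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    fit <- lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    ll_new <- .bernoulli_ll(y, drop(X %*% beta_new))
    # step-halve if the proposed step decreases the likelihood
    halvings <- 0L
    while (ll_new < ll && halvings < 20L) {
      beta_new <- (beta + beta_new) / 2
      ll_new <- .bernoulli_ll(y, drop(X %*% beta_new))
      halvings <- halvings + 1L
    }
    delta <- abs(ll_new - ll) / (abs(ll_new) + 1e-8)
    beta <- beta_new
    ll <- ll_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- plogis(drop(X %*% beta))
  separation <- any(mu < 1e-10 | mu > 1 - 1e-10) && max(abs(beta)) > 10
  if (separation) converged <- FALSE
  structure(list(coef = stats::setNames(beta, colnames(X)),
                 loglik = ll, n_par = ncol(X), n = nrow(X),
                 converged = converged, iterations = iter,
                 separation = separation, labels = colnames(X)),
            class = "logistic_fit")
}

#' Likelihood-ratio test of nested logistic fits
#'
#' @param base,full converged `logistic_fit` objects; the base model's
#'   covariates must be a subset of the full model's, fitted on the same
#'   samples.
#' @return an `lrt_result`: `statistic` (twice the log-likelihood
#'   difference), `df` (parameter-count difference), `p` (chi-square upper
#'   tail; 1 when `df == 0`).
#' @export
lrt <- function(base, full) {
  stopifnot(inherits(base, "logistic_fit"), inherits(full, "logistic_fit"))
  if (!base$converged || !full$converged) {
    stop("both fits must have converged (separation or iteration cap hit)")
  }
  if (base$n != full$n) stop("fits use different sample sets; not nested")
  if (!all(base$labels %in% full$labels)) {
    stop("models are not nested: base covariates not contained in full")
  }
  stat <- 2 * (full$loglik - base$loglik)
  if (stat < -1e-6) {
    stop("negative LR statistic (", format(stat),
         "): optimization of the full model failed")
  }
  stat <- max(stat, 0)
  df <- full$n_par - base$n_par
  p <- if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p,
                 ll_base = base$loglik, ll_full = full$loglik),
            class = "lrt_result")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit:", x$n_par, "parameters, n =", x$n,
      "| logLik =", format(x$loglik, digits = 6),
      "|", if (x$converged) "converged" else
        if (x$separation) "NOT converged (separation)" else "NOT converged",
      "in", x$iterations, "iterations\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("LR test: statistic =", format(x$statistic, digits = 5),
      " df =", x$df, " p =", format.pval(x$p, digits = 3), "\n")
  invisible(x)
}
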