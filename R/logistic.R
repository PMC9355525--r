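#' @title Optimized DSP + INR + ALP logistic model
#' @description The optimized risk model combines three covariates — DSP
#'   pattern membership (0/1), INR at onset and ALP at onset (U/L) — through a
#'   logistic regression.  The published linear predictor is
#'   \deqn{score = 1.347 \cdot DSP + 8.363 \cdot INR + 0.004 \cdot ALP,}
#'   shipped verbatim and without an intercept: it is a risk score whose
#'   ranking (hence AUROC) is intercept-invariant.  For probability outputs
#'   (Brier score, calibration) the intercept is calibrated so that the mean
#'   predicted probability matches a supplied prevalence.  Note the published
#'   coefficients are not the logs of the published odds ratios
#'   (log 11.8 = 2.468 vs 8.363 for INR; log 3.906 = 1.363 vs 1.347 for DSP);
#'   both sets are reported as printed and no reconciliation is attempted.
#'   The module also contains a self-contained maximum-likelihood logistic
#'   fitter (IRLS) and likelihood-ratio-based forward selection so that the
#'   same model can be regenerated on any cohort.
#' @name logistic_model
NULL

#' The published coefficients of the optimized model
#' @return List with \code{beta_dsp}, \code{beta_inr}, \code{beta_alp}
#'   (per U/L) and \code{intercept} (NA: not published).
#' @export
published_coefficients <- function() {
  list(beta_dsp = 1.347, beta_inr = 8.363, beta_alp = 0.004,
       intercept = NA_real_)
}

#' Linear predictor of the optimized model
#'
#' @param dsp 0/1 indicator of DSP pattern membership.
#' @param inr INR at DILI onset (> 0).
#' @param alp ALP at DILI onset, U/L (> 0).
#' @param coef Coefficient list as from \code{\link{published_coefficients}};
#'   an NA intercept contributes 0.
#' @return Numeric score(s); vectorised.
#' @export
linear_predictor <- function(dsp, inr, alp, coef = published_coefficients()) {
  if (any(!is.finite(dsp)) || any(!is.finite(inr)) || any(!is.finite(alp))) {
    stop("non-finite covariate value")
  }
  icpt <- if (is.na(coef$intercept)) 0 else coef$intercept
  icpt + coef$beta_dsp * dsp + coef$beta_inr * inr + coef$beta_alp * alp
}

#' Inverse-logit link
#' @param score Finite linear-predictor value(s).
#' @return Probability in (0, 1).
#' @export
predict_prob <- function(score) {
  if (any(!is.finite(score))) stop("non-finite score")
  stats::plogis(score)
}

log_likelihood <- function(eta, y) {
  # numerically stable Bernoulli log-likelihood: sum y*eta - log(1+exp(eta))
  sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
}

#' Maximum-likelihood logistic regression via IRLS
#'
#' Newton/Fisher scoring on the Bernoulli log-likelihood with canonical link.
#' Convergence is declared when every component of the score equation is
#' below \code{1e-8} or the parameter step is below \code{1e-10}.  Wald
#' standard errors come from the inverse observed information.
#'
#' @param X Numeric covariate matrix (n x p), without intercept column.
#' @param y Binary outcome vector (0/1) of length n, both classes present.
#' @param add_intercept Prepend an intercept column (default TRUE).
#' @param max_iter Iteration cap (default 100).
#' @return List of class \code{"logistic_fit"}: \code{coef}, \code{se},
#'   \code{vcov}, \code{loglik}, \code{or} (odds ratios), \code{or_ci}
#'   (Wald 95\% CIs), \code{p_wald}, \code{fitted}, \code{converged},
#'   \code{iterations}, \code{n}.
#' @export
fit_logistic <- function(X, y, add_intercept = TRUE, max_iter = 100L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  if (any(!is.finite(X))) stop("non-finite covariate values in X")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (sum(y) == 0 || sum(y) == length(y)) stop("y must contain both classes")
  if (ncol(X) > 0) {
    const <- apply(X, 2, function(col) diff(range(col)) == 0)
    if (any(const)) {
      stop("constant covariate(s): ",
           paste(colnames(X)[const], collapse = ", "))
    }
  }
  if (add_intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  p <- ncol(X)
  if (length(y) <= p) stop("need more observations than parameters")
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) {
      stop("singular information matrix: covariates may be collinear")
    })
    beta <- beta + step
    if (max(abs(score)) < 1e-8 || max(abs(step)) < 1e-10) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (max(abs(beta)) > 25) {
    worst <- colnames(X)[which.max(abs(beta))]
    stop("apparent complete separation (diverging coefficient for ",
         worst, ")")
  }
  if (!converged) stop("IRLS failed to converge in ", max_iter, " iterations")
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X * (mu * (1 - mu)), X)
  vc <- solve(info)
  se <- sqrt(diag(vc))
  names(beta) <- names(se) <- colnames(X)
  z <- beta / se
  ci <- cbind(lo = exp(beta - 1.959963984540054 * se),
              hi = exp(beta + 1.959963984540054 * se))
  structure(list(coef = beta, se = se, vcov = vc,
                 loglik = log_likelihood(eta, y),
                 or = exp(beta), or_ci = ci,
                 p_wald = 2 * stats::pnorm(-abs(z)),
                 fitted = mu, converged = converged, iterations = iter,
                 n = length(y)),
            class = "logistic_fit")
}

#' Univariate logistic screening
#'
#' Fits one single-covariate logistic model per candidate and keeps those
#' with Wald p below \code{alpha}.
#'
#' @param X Named covariate matrix.
#' @param y Binary outcomes.
#' @param alpha Screening level (default 0.05).
#' @return Data frame (variable, coef, p) with a logical \code{keep} column.
#' @export
univariate_screen <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  res <- lapply(colnames(X), function(v) {
    fit <- fit_logistic(X[, v, drop = FALSE], y)
    data.frame(variable = v, coef = unname(fit$coef[v]),
               p = unname(fit$p_wald[v]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$keep <- out$p < alpha
  out
}

#' Forward selection by likelihood-ratio tests
#'
#' Starting from the intercept-only model, repeatedly adds the candidate with
#' the smallest likelihood-ratio p value (2 x delta log-likelihood against
#' chi-square with 1 df) as long as that p is below \code{alpha_in}.  Ties
#' are broken by candidate name order so the path is deterministic.
#'
#' @param X Named candidate covariate matrix (typically pre-screened with
#'   \code{\link{univariate_screen}}).
#' @param y Binary outcomes.
#' @param alpha_in Entry level (default 0.05).
#' @return List of class \code{"forward_fit"}: \code{fit} (the final
#'   \code{\link{fit_logistic}} result), \code{selected} (variables in entry
#'   order) and \code{path} (data frame of variable, LR statistic, p and
#'   model log-likelihood at each entry step).
#' @export
forward_lr_select <- function(X, y, alpha_in = 0.05) {
  X <- as.matrix(X)
  candidates <- sort(colnames(X))
  selected <- character(0)
  current <- fit_logistic(X[, selected, drop = FALSE], y)
  path <- data.frame(variable = character(), lr_stat = numeric(),
                     p = numeric(), loglik = numeric(),
                     stringsAsFactors = FALSE)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    trial <- lapply(remaining, function(v) {
      fit <- tryCatch(fit_logistic(X[, c(selected, v), drop = FALSE], y),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      lr <- 2 * (fit$loglik - current$loglik)
      list(variable = v, lr = lr,
           p = stats::pchisq(lr, df = 1, lower.tail = FALSE), fit = fit)
    })
    trial <- Filter(Negate(is.null), trial)
    if (length(trial) == 0) break
    ps <- vapply(trial, `[[`, 0, "p")
    best <- trial[[which.min(ps)]]   # candidates sorted: which.min is the
    if (best$p >= alpha_in) break    # name-order tie-break
    selected <- c(selected, best$variable)
    current <- best$fit
    path <- rbind(path, data.frame(variable = best$variable,
                                   lr_stat = best$lr, p = best$p,
                                   loglik = current$loglik,
                                   stringsAsFactors = FALSE))
  }
  structure(list(fit = current, selected = selected, path = path),
            class = "forward_fit")
}

#' Calibrate the intercept of a risk score to a target prevalence
#'
#' Finds c such that \code{mean(plogis(c + score)) == prevalence}, turning an
#' intercept-free risk score into predicted probabilities with the right
#' overall event rate.  AUROC is unaffected; Brier scores become meaningful.
#'
#' @param score Linear-predictor values for a cohort.
#' @param prevalence Target mean predicted probability in (0, 1); default is
#'   the discovery-cohort acute-liver-failure rate 28/604.
#' @return The calibrated intercept (a scalar).
#' @export
calibrate_intercept <- function(score, prevalence = 28 / 604) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  f <- function(c) mean(stats::plogis(c + score)) - prevalence
  stats::uniroot(f, lower = -50 - max(score), upper = 50 - min(score),
                 tol = 1e-12)$root
}
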