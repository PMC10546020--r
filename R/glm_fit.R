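# Generalized linear models for the three physiological responses:
# beta/logit for IPARf, gamma/log for biomass, gaussian/identity for RUE.
# The linear predictor is built from an intercept, the candidate VI, GDD
# and their interaction (the VI x GDD slope/intercept shift seen across
# growth stages); the RUE response uses intercept + period-averaged VI.

glm_terms_default <- function(family) {
  if (family == "gaussian") c("intercept", "vi")
  else c("intercept", "vi", "gdd", "vi_gdd")
}

build_design <- function(terms, vi = NULL, gdd = NULL, n = NULL) {
  cols <- list()
  if ("intercept" %in% terms) cols$intercept <- rep(1, n)
  if ("vi" %in% terms) {
    if (is.null(vi)) stop("missing predictor: vi", call. = FALSE)
    cols$vi <- vi
  }
  if ("gdd" %in% terms) {
    if (is.null(gdd)) stop("missing predictor: gdd", call. = FALSE)
    cols$gdd <- gdd
  }
  if ("vi_gdd" %in% terms) {
    if (is.null(vi) || is.null(gdd)) {
      stop("missing predictor for vi_gdd interaction", call. = FALSE)
    }
    cols$vi_gdd <- vi * gdd
  }
  unknown <- setdiff(terms, c("intercept", "vi", "gdd", "vi_gdd"))
  if (length(unknown)) {
    stop(sprintf("unknown term(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(cbind, cols)
}

beta_negll <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  mu <- clamp(stats::plogis(eta), 1e-12, 1 - 1e-12)
  phi <- exp(par[p + 1L])
  -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

# Analytic score of the negative beta log-likelihood in (beta, log phi);
# standard beta-regression score with the logit mean link.
beta_grad_negll <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  mu <- clamp(stats::plogis(eta), 1e-12, 1 - 1e-12)
  phi <- exp(par[p + 1L])
  ystar <- stats::qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  d_beta <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  d_phi <- sum(mu * (ystar - mustar) + log(1 - y) -
                 digamma((1 - mu) * phi) + digamma(phi))
  -c(d_beta, d_phi * phi)
}

fit_beta_logit <- function(X, y) {
  p <- ncol(X)
  if (any(y <= 0 | y >= 1)) {
    bad <- which(y <= 0 | y >= 1)
    stop(sprintf("beta response must lie in (0, 1); invalid rows: %s",
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  # standardize the non-intercept columns so the optimizer works on
  # comparably scaled parameters, then map the fit back
  centers <- rep(0, p); scales <- rep(1, p)
  Z <- X
  for (j in seq_len(p)) {
    if (stats::sd(X[, j]) > 0) {
      centers[j] <- mean(X[, j])
      scales[j] <- stats::sd(X[, j])
      Z[, j] <- (X[, j] - centers[j]) / scales[j]
    }
  }
  b0 <- tryCatch(stats::coef(stats::lm.fit(Z, stats::qlogis(y))),
                 error = function(e) rep(0, p))
  b0[!is.finite(b0)] <- 0
  mu0 <- clamp(mean(y), 0.05, 0.95)
  phi0 <- max(mu0 * (1 - mu0) / max(stats::var(y), 1e-6) - 1, 2)
  fit <- stats::optim(c(b0, log(phi0)), beta_negll, beta_grad_negll,
                      X = Z, y = y, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  if (fit$convergence != 0L) {
    nm <- stats::optim(fit$par, beta_negll, X = Z, y = y,
                       method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    fit <- stats::optim(nm$par, beta_negll, beta_grad_negll, X = Z, y = y,
                        method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
  }
  # back-transform: eta = sum bz_j (x_j - m_j) / s_j + intercept terms
  bz <- fit$par[seq_len(p)]
  coefs <- bz / scales
  const_idx <- which(scales == 1 & centers == 0 &
                       apply(X, 2, function(c) all(c == c[1L])))
  if (length(const_idx)) {
    coefs[const_idx[1L]] <- bz[const_idx[1L]] -
      sum((bz * centers / scales)[-const_idx[1L]])
  }
  par_orig <- c(coefs, fit$par[p + 1L])
  # observed information in the well-conditioned standardized space,
  # mapped back through the linear reparametrization beta_x = T beta_z
  Hz <- stats::optimHess(fit$par, beta_negll, beta_grad_negll, X = Z, y = y)
  vcz <- tryCatch(solve(Hz), error = function(e) NULL)
  vc <- NULL
  if (!is.null(vcz)) {
    Tm <- diag(1 / scales)
    if (length(const_idx)) {
      i0 <- const_idx[1L]
      Tm[i0, ] <- -centers / scales
      Tm[i0, i0] <- 1
    }
    vc <- Tm %*% vcz[seq_len(p), seq_len(p), drop = FALSE] %*% t(Tm)
  }
  names(coefs) <- colnames(X)
  list(coefficients = coefs,
       dispersion = unname(exp(fit$par[p + 1L])),
       loglik = -beta_negll(par_orig, X, y),
       vcov = vc,
       converged = fit$convergence == 0L)
}

fit_gamma_log <- function(X, y) {
  if (any(y <= 0)) {
    bad <- which(y <= 0)
    stop(sprintf("gamma response must be > 0; invalid rows: %s",
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  dat <- data.frame(.y = y)
  fit <- stats::glm(.y ~ X - 1, family = stats::Gamma(link = "log"),
                    data = dat)
  mu <- fit$fitted.values
  shape <- MASS::gamma.shape(fit)$alpha
  ll <- sum(stats::dgamma(y, shape = shape, rate = shape / mu, log = TRUE))
  # expected information for the log link scales as shape^-1
  XtWX <- crossprod(X)            # W = 1 for gamma/log at the MLE scale
  vc <- tryCatch(solve(XtWX) / shape, error = function(e) NULL)
  coefs <- unname(fit$coefficients)
  names(coefs) <- colnames(X)
  list(coefficients = coefs, dispersion = shape, loglik = ll,
       vcov = vc, converged = isTRUE(fit$converged))
}

fit_gaussian_identity <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n                     # ML estimate
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  vc <- tryCatch(chol2inv(chol(crossprod(X))) * sigma2 * n / (n - ncol(X)),
                 error = function(e) NULL)
  coefs <- fit$coefficients
  names(coefs) <- colnames(X)
  list(coefficients = coefs, dispersion = sigma2, loglik = ll,
       vcov = vc, converged = TRUE)
}

#' Fit a physiological GLM
#'
#' Maximum-likelihood fit of one response under its distributional
#' family: `"beta"` with a logit link (IPARf, open (0,1) response),
#' `"gamma"` with a log link (biomass, positive response) or
#' `"gaussian"` with the identity link (RUE; equivalent to ordinary
#' linear regression). The beta fit maximizes the exact beta
#' log-likelihood over the mean coefficients and the precision phi; the
#' gamma fit pairs the usual IRLS coefficient estimates with the ML
#' shape alpha.
#'
#' @param y response vector.
#' @param vi candidate vegetation-index values (same length as `y`), or
#'   `NULL` when the term set omits it.
#' @param gdd growing degree days at the observation (same length), or
#'   `NULL`.
#' @param family `"beta"`, `"gamma"` or `"gaussian"`.
#' @param terms subset of `c("intercept", "vi", "gdd", "vi_gdd")`.
#'   Defaults to all four for beta/gamma and `intercept + vi` for
#'   gaussian.
#' @param predictor_vi name tag carried into score tables.
#' @return object of class `cotton_glm`: coefficients, `dispersion`
#'   (phi, alpha or sigma^2), `loglik`, `n`, `vcov` for the mean
#'   coefficients and a `converged` flag.
#' @export
fit_glm <- function(y, vi = NULL, gdd = NULL,
                    family = c("beta", "gamma", "gaussian"),
                    terms = NULL, predictor_vi = NA_character_) {
  family <- match.arg(family)
  if (is.null(terms)) terms <- glm_terms_default(family)
  ok <- is.finite(y) & (if (is.null(vi)) TRUE else is.finite(vi)) &
    (if (is.null(gdd)) TRUE else is.finite(gdd))
  n_dropped <- sum(!ok)
  y <- y[ok]
  if (!is.null(vi)) vi <- vi[ok]
  if (!is.null(gdd)) gdd <- gdd[ok]
  n <- length(y)
  X <- build_design(terms, vi = vi, gdd = gdd, n = n)
  if (n <= ncol(X) + 1L) {
    stop(sprintf("too few observations (n = %d) for %d terms", n, ncol(X)),
         call. = FALSE)
  }
  res <- switch(family,
    beta = fit_beta_logit(X, y),
    gamma = fit_gamma_log(X, y),
    gaussian = fit_gaussian_identity(X, y))
  structure(c(res, list(family = family,
                        link = c(beta = "logit", gamma = "log",
                                 gaussian = "identity")[[family]],
                        terms = terms, n = n, n_dropped = n_dropped,
                        predictor_vi = predictor_vi)),
            class = "cotton_glm")
}

#' @export
print.cotton_glm <- function(x, ...) {
  cat(sprintf("cotton_glm: %s/%s, n = %d%s\n", x$family, x$link, x$n,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$coefficients, 6))
  cat(sprintf("dispersion = %.4f, logLik = %.3f\n", x$dispersion, x$loglik))
  invisible(x)
}

#' Predict on the response scale
#'
#' Applies the model's inverse link to the linear predictor built from
#' the supplied predictors: beta predictions lie in (0,1), gamma
#' predictions are positive.
#'
#' @param model a `cotton_glm` fit.
#' @param vi,gdd predictor vectors as required by the model's terms.
#' @return predictions in response units.
#' @export
predict_response <- function(model, vi = NULL, gdd = NULL) {
  if (!inherits(model, "cotton_glm")) stop("not a cotton_glm", call. = FALSE)
  if (!model$converged) {
    warning("predicting from a non-converged model", call. = FALSE)
  }
  n <- max(length(vi), length(gdd), 1L)
  X <- build_design(model$terms, vi = vi, gdd = gdd, n = n)
  eta <- drop(X %*% model$coefficients)
  switch(model$family,
    beta = stats::plogis(eta),
    gamma = exp(eta),
    gaussian = eta)
}
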