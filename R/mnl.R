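# Internal: assemble the estimation arrays from filtered choice data.
# Rows must contain no opt-out alternatives.
model_arrays <- function(data) {
  stopifnot(inherits(data, "choice_data"))
  if (any(data$is_opt_out == 1L)) {
    stop("dataset still contains opt-out rows; apply drop_opt_outs() first",
         call. = FALSE)
  }
  attrs <- choice_attributes(data)$name
  x <- as.matrix(data[, attrs, drop = FALSE])
  storage.mode(x) <- "double"
  key <- situation_key(data)
  sit <- match(key, unique(key))
  resp <- match(data$respondent_id, unique(data$respondent_id))
  sit_resp <- resp[!duplicated(sit)]
  alt_levels <- sort(unique(data$alternative_id))
  list(x = x, attrs = attrs,
       sit = sit, n_sit = max(sit),
       sit_resp = sit_resp, n_resp = max(resp),
       alt = match(data$alternative_id, alt_levels),
       alt_levels = alt_levels,
       n_alt = length(alt_levels),
       chosen = as.integer(data$chosen))
}

# Conditional logit negative log-likelihood and analytic gradient.
# theta = c(beta[K], asc_free[n_alt - 1]); ASC of the first alternative
# position is the zero reference.
mnl_nll <- function(theta, arr, use_asc) {
  k <- ncol(arr$x)
  beta <- theta[seq_len(k)]
  asc <- if (use_asc) c(0, theta[k + seq_len(arr$n_alt - 1L)]) else
    rep(0, arr$n_alt)
  u <- (if (k) drop(arr$x %*% beta) else 0) + asc[arr$alt]
  mx <- tapply(u, arr$sit, max)[arr$sit]
  eu <- exp(u - mx)
  denom <- rowsum(eu, arr$sit)
  p <- eu / denom[arr$sit]
  ll <- sum(log(p[arr$chosen == 1L]))
  resid <- arr$chosen - p
  g_beta <- drop(crossprod(arr$x, resid))
  grad <- if (use_asc) {
    c(g_beta, rowsum(resid, arr$alt)[-1L])
  } else {
    g_beta
  }
  list(nll = -ll, grad = -grad, p = p)
}

# Analytic observed information of the conditional logit:
# I = Z' diag(p) Z - sum_s (Z_s' p_s)(Z_s' p_s)' with Z = [X, ASC dummies].
mnl_information <- function(theta, arr, use_asc) {
  p <- as.vector(mnl_nll(theta, arr, use_asc)$p)
  z <- arr$x
  if (use_asc) {
    dummies <- outer(arr$alt, seq_len(arr$n_alt)[-1L], "==") + 0
    colnames(dummies) <- paste0("asc_", arr$alt_levels[-1L])
    z <- cbind(z, dummies)
  }
  crossprod(sqrt(p) * z) - crossprod(rowsum(p * z, arr$sit))
}

#' Fit a conditional (multinomial) logit model
#'
#' Maximum-likelihood conditional logit on effect-coded attributes with
#' alternative-specific constants by choice-set position (the first
#' position is the zero reference). The log-likelihood is globally
#' concave; BFGS with the analytic gradient is run to a gradient
#' max-norm below `1e-6` and standard errors come from the inverse
#' observed Hessian. The null model for pseudo-R-squared is the
#' ASC-only fit (see [null_loglik()]).
#'
#' @param data a validated, opt-out-filtered [choice_data()] object.
#' @param use_asc include alternative-specific constants (default
#'   `TRUE`; `FALSE` gives a pure attribute model, useful for
#'   closed-form checks).
#' @param start optional initial coefficient vector.
#' @return An object of class `mnl_fit`: coefficients (attributes, then
#'   `asc_2 ...`), `se`, `vcov`, `loglik`, `loglik_null`, `rho2`,
#'   `n_obs` (choice situations), `n_respondents`, `grad_norm`,
#'   `convergence`.
#' @examples
#' plan <- sheep_design("ram")
#' truth <- preset_truth("ram_table6")
#' dat <- drop_opt_outs(simulate_choices(plan, truth, 200, seed = 7))
#' fit <- fit_mnl(dat)
#' coef(fit)["tail_type"]
#' @export
fit_mnl <- function(data, use_asc = TRUE, start = NULL) {
  arr <- model_arrays(data)
  k <- ncol(arr$x)
  npar <- k + if (use_asc) arr$n_alt - 1L else 0L
  theta0 <- if (is.null(start)) rep(0, npar) else start
  stopifnot(length(theta0) == npar)

  fn <- function(th) mnl_nll(th, arr, use_asc)$nll
  gr <- function(th) mnl_nll(th, arr, use_asc)$grad
  opt <- optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = 1000L, reltol = 1e-12))
  # Newton polish with the analytic Hessian (the log-likelihood is
  # concave) until the gradient max-norm target is met
  theta <- opt$par
  for (i in 1:25) {
    g <- gr(theta)
    if (max(abs(g)) < 1e-8) break
    h <- mnl_information(theta, arr, use_asc)
    step <- tryCatch(solve(h, g), error = function(e) g)
    cand <- theta - step
    halvings <- 0L
    while (halvings < 12L &&
           (!all(is.finite(cand)) || !is.finite(fn(cand)) ||
              fn(cand) > fn(theta))) {
      step <- step / 2
      cand <- theta - step
      halvings <- halvings + 1L
    }
    if (halvings >= 12L) break
    theta <- cand
  }
  if (any(abs(theta[seq_len(k)]) > 15)) {
    worst <- arr$attrs[which.max(abs(theta[seq_len(k)]))]
    stop("non-finite or separated likelihood: attribute '", worst,
         "' diverges; check for complete separation", call. = FALSE)
  }
  names(theta) <- c(arr$attrs,
                    if (use_asc) paste0("asc_", arr$alt_levels[-1L]))
  hess <- mnl_information(theta, arr, use_asc)
  vcov <- tryCatch(solve(hess), error = function(e) MASS::ginv(hess))
  dimnames(vcov) <- list(names(theta), names(theta))
  ll <- -fn(theta)
  ll0 <- null_loglik(data)
  structure(list(
    coefficients = theta,
    beta = theta[seq_len(k)],
    asc = c(0, if (use_asc) theta[k + seq_len(arr$n_alt - 1L)] else
      rep(0, arr$n_alt - 1L)),
    se = setNames(sqrt(pmax(diag(vcov), 0)), names(theta)),
    vcov = vcov,
    loglik = ll,
    loglik_null = ll0,
    rho2 = mcfadden_rho2(ll, ll0),
    n_obs = arr$n_sit,
    n_respondents = arr$n_resp,
    use_asc = use_asc,
    grad_norm = max(abs(gr(theta))),
    convergence = opt$convergence
  ), class = "mnl_fit")
}

#' Null (ASC-only) log-likelihood
#'
#' Maximized log-likelihood of the conditional logit with no attribute
#' effects, only alternative-specific constants. This is the reference
#' model of the McFadden pseudo-R-squared: with choices spread
#' uniformly it equals `-(situations) * log(alternatives)`, and it is
#' never below that bound.
#'
#' @inheritParams fit_mnl
#' @return The maximized null log-likelihood (scalar).
#' @export
null_loglik <- function(data) {
  arr <- model_arrays(data)
  arr$x <- arr$x[, 0, drop = FALSE]  # strip attributes
  arr$attrs <- character(0)
  npar <- arr$n_alt - 1L
  fn <- function(th) mnl_nll(th, arr, TRUE)$nll
  gr <- function(th) mnl_nll(th, arr, TRUE)$grad
  opt <- optim(rep(0, npar), fn, gr, method = "BFGS",
               control = list(maxit = 1000L, reltol = 1e-14))
  -opt$value
}

#' Closed-form conditional logit choice probabilities
#'
#' Per-row choice probabilities implied by coefficients `beta` and
#' alternative-specific constants, without any simulation. Useful as an
#' analytic oracle for the simulator and the degenerate (no
#' heterogeneity) cases of the G-MNL probability.
#'
#' @param data an opt-out-filtered [choice_data()] object.
#' @param beta named attribute coefficient vector.
#' @param asc alternative-specific constants (full vector, first 0);
#'   default all zero.
#' @return Numeric vector of probabilities, one per row of `data`;
#'   sums to 1 within each situation.
#' @export
mnl_probabilities <- function(data, beta, asc = NULL) {
  arr <- model_arrays(data)
  if (is.null(asc)) asc <- rep(0, arr$n_alt)
  beta <- beta[arr$attrs]
  u <- drop(arr$x %*% beta) + asc[arr$alt]
  mx <- tapply(u, arr$sit, max)[arr$sit]
  eu <- exp(u - mx)
  drop(eu / rowsum(eu, arr$sit)[arr$sit])
}

#' @export
print.mnl_fit <- function(x, ...) {
  cat("Conditional logit fit: ", x$n_obs, " situations, ",
      x$n_respondents, " respondents\n", sep = "")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  cat("log-likelihood ", round(x$loglik, 2), " (null ",
      round(x$loglik_null, 2), "), McFadden rho2 ",
      round(x$rho2, 3), "\n", sep = "")
  invisible(x)
}

#' @export
coef.mnl_fit <- function(object, ...) object$coefficients

#' @export
vcov.mnl_fit <- function(object, ...) object$vcov

#' @export
logLik.mnl_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' @export
summary.mnl_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  out <- data.frame(term = names(object$coefficients),
                    estimate = unname(object$coefficients),
                    se = unname(object$se),
                    z = unname(z),
                    p_value = unname(2 * pnorm(-abs(z))))
  rownames(out) <- NULL
  out
}
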