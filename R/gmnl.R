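#' Simulated G-MNL choice probability (reference implementation)
#'
#' Per-respondent simulated probability of the observed choice
#' sequence: for each draw `d` the coefficient vector is
#' `sigma_d * beta + gamma * eta_d + (1 - gamma) * sigma_d * eta_d`
#' with `sigma_d = exp(-tau^2/2 + tau * eps0_d)` and
#' `eta_d = eta_sd * z_d`; conditional logit probabilities are
#' multiplied across the respondent's situations and averaged over
#' draws. With `tau = 0` and all `eta_sd = 0` this collapses exactly to
#' the closed-form conditional logit for any number of draws. This is
#' the plain-R reference used to verify the compiled estimation kernel;
#' utilities are max-subtracted so probabilities never overflow.
#'
#' @param data an opt-out-filtered [choice_data()] object.
#' @param beta named attribute coefficient vector (means).
#' @param asc full ASC vector (first element 0); default all zero.
#' @param eta_sd named SDs of the random deviations (subset of the
#'   attributes); names define which attributes are random.
#' @param tau scale-heterogeneity SD.
#' @param gamma mixing parameter, 0 by default.
#' @param draws a [make_draws()] object with one taste dimension per
#'   random attribute.
#' @return Named vector of per-respondent simulated probabilities.
#' @export
gmnl_probability <- function(data, beta, asc = NULL, eta_sd = numeric(0),
                             tau = 0, gamma = 0, draws = NULL) {
  arr <- model_arrays(data)
  k <- ncol(arr$x)
  if (is.null(asc)) asc <- rep(0, arr$n_alt)
  beta <- beta[arr$attrs]
  random <- names(eta_sd)
  if (!all(random %in% arr$attrs)) {
    stop("'eta_sd' names must be attributes", call. = FALSE)
  }
  if (is.null(draws)) draws <- make_draws(1L, length(random))
  if (draws$K != length(random)) {
    stop("draw set has ", draws$K, " taste dimensions but ",
         length(random), " random attributes were given", call. = FALSE)
  }
  D <- draws$D
  sigma <- exp(-tau^2 / 2 + tau * draws$eps0)
  # K x D coefficient matrix across draws
  cf <- matrix(beta, k, D) * rep(sigma, each = k)
  for (r in seq_along(random)) {
    kk <- match(random[r], arr$attrs)
    cf[kk, ] <- cf[kk, ] +
      (gamma + (1 - gamma) * sigma) * eta_sd[r] * draws$eta[, r]
  }
  u <- arr$x %*% cf + asc[arr$alt]  # rows x D
  split_idx <- split(seq_len(nrow(u)), arr$sit)
  logp <- matrix(0, arr$n_resp, D)
  for (s in seq_along(split_idx)) {
    ii <- split_idx[[s]]
    us <- u[ii, , drop = FALSE]
    mx <- apply(us, 2L, max)
    lse <- mx + log(colSums(exp(sweep(us, 2L, mx))))
    ch <- ii[arr$chosen[ii] == 1L]
    n <- arr$sit_resp[s]
    logp[n, ] <- logp[n, ] + u[ch, ] - lse
  }
  p <- rowMeans(exp(logp))
  names(p) <- unique(data$respondent_id)
  p
}

#' Fit the generalized multinomial logit by maximum simulated likelihood
#'
#' Estimates mean part-worths, alternative-specific constants, the SDs
#' of normally distributed person-level taste deviations on the chosen
#' random attributes, and the scale-heterogeneity SD `tau`
#' (respondent scale `exp(-tau^2/2 + tau * e0)`, normalized so its mean
#' is 1 and the means keep their conditional-logit interpretation).
#' The mixing parameter `gamma` is held fixed (0 by default, the
#' conventional restriction). The simulated log-likelihood uses common
#' draws across respondents (Halton by default) and is maximized by
#' BFGS with the analytic gradient; deviation SDs and `tau` are
#' estimated unconstrained (the likelihood is symmetric in their signs)
#' and reported as absolute values. Standard errors come from the
#' finite-difference Hessian of the simulated log-likelihood. Refitting
#' with the same seed and draws reproduces the estimates exactly.
#'
#' @param data a validated, opt-out-filtered [choice_data()] object.
#' @param random character vector of attributes with random
#'   coefficients (may be empty).
#' @param D number of draws (default 500).
#' @param scheme draw scheme, `"halton"` (default) or `"pseudo"`.
#' @param gamma fixed mixing value in `[0, 1]`.
#' @param seed integer seed for the draws.
#' @param estimate_scale estimate `tau` (default `TRUE`); when `FALSE`
#'   the scale is fixed at 1 (`tau = 0`) and the model is a mixed
#'   logit, or plain conditional logit if `random` is empty.
#' @param start optional named start values (full parameter vector).
#' @return An object of class `gmnl_fit` with `coefficients` (full
#'   vector: attribute means, ASCs, `sd_*`, `tau`), `beta`, `asc`,
#'   `eta_sd`, `tau`, `se`, `vcov`, `loglik`, `loglik_null`, `rho2`,
#'   `n_obs`, `boundary` flags, draw metadata and convergence info.
#' @examples
#' \donttest{
#' plan <- sheep_design("ewe")
#' truth <- preset_truth("ewe_table6")
#' dat <- drop_opt_outs(simulate_choices(plan, truth, 300, seed = 11))
#' fit <- fit_gmnl(dat, random = c("body_size", "growth_rate",
#'                                 "lambing_interval"), D = 200, seed = 1)
#' fit$tau
#' }
#' @export
fit_gmnl <- function(data, random = character(0), D = 500L,
                     scheme = c("halton", "pseudo"), gamma = 0,
                     seed = 1L, estimate_scale = TRUE, start = NULL) {
  scheme <- match.arg(scheme)
  if (gamma < 0 || gamma > 1) stop("'gamma' must be in [0, 1]",
                                   call. = FALSE)
  arr <- model_arrays(data)
  k <- ncol(arr$x)
  if (!all(random %in% arr$attrs)) {
    stop("'random' must name attributes of the dataset", call. = FALSE)
  }
  random <- arr$attrs[arr$attrs %in% random]  # attribute order
  is_random <- arr$attrs %in% random
  kr <- length(random)

  draws <- make_draws(D, kr, scheme = scheme, seed = seed)
  h <- matrix(0, nrow = D, ncol = k)
  if (kr) h[, which(is_random)] <- draws$eta

  par_names <- c(arr$attrs, paste0("asc_", arr$alt_levels[-1L]),
                 if (kr) paste0("sd_", random),
                 if (estimate_scale) "tau")
  npar <- length(par_names)

  if (is.null(start)) {
    init <- fit_mnl(data)
    theta0 <- c(init$beta, init$coefficients[k + seq_len(arr$n_alt - 1L)],
                rep(0.1, kr), if (estimate_scale) 0.1)
  } else {
    theta0 <- start
  }
  stopifnot(length(theta0) == npar)

  kernel <- function(th, want_grad) {
    gmnl_loglik_cpp(th, arr$x, arr$alt, arr$sit - 1L, arr$sit_resp - 1L,
                    arr$chosen, h, draws$eps0, is_random, arr$n_alt,
                    gamma, estimate_scale, 0, want_grad)
  }
  fn <- function(th) -kernel(th, FALSE)$loglik
  gr <- function(th) -kernel(th, TRUE)$grad

  opt <- optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = 1000L, reltol = 1e-12))
  for (i in 1:3) {
    if (max(abs(gr(opt$par))) < 1e-4) break
    opt <- optim(opt$par, fn, gr, method = "BFGS",
                 control = list(maxit = 1000L, reltol = 1e-12))
  }
  grad_norm <- max(abs(gr(opt$par)))
  if (opt$convergence != 0 && grad_norm > 1e-2) {
    stop("G-MNL estimation did not converge (gradient max-norm ",
         signif(grad_norm, 3), "); best log-likelihood ",
         signif(-opt$value, 8), call. = FALSE)
  }
  theta <- setNames(opt$par, par_names)

  hess <- optimHess(theta, fn, gr)
  vcov <- tryCatch(solve(hess), error = function(e) {
    warning("Hessian is singular; using pseudo-inverse standard errors",
            call. = FALSE)
    MASS::ginv(hess)
  })
  dimnames(vcov) <- list(par_names, par_names)
  se <- setNames(sqrt(pmax(diag(vcov), 0)), par_names)

  # report deviation SDs and tau on the natural (nonnegative) scale
  theta_rep <- theta
  if (kr) theta_rep[paste0("sd_", random)] <-
    abs(theta_rep[paste0("sd_", random)])
  if (estimate_scale) theta_rep["tau"] <- abs(theta_rep["tau"])

  eta_sd <- if (kr) theta_rep[paste0("sd_", random)] else numeric(0)
  if (kr) names(eta_sd) <- random
  tau <- if (estimate_scale) unname(theta_rep["tau"]) else 0
  boundary <- c(eta_sd < 1e-3, if (estimate_scale) c(tau = tau < 1e-3))

  ll <- -opt$value
  ll0 <- null_loglik(data)
  structure(list(
    coefficients = theta_rep,
    beta = theta_rep[seq_len(k)],
    asc = c(0, unname(theta_rep[k + seq_len(arr$n_alt - 1L)])),
    eta_sd = eta_sd,
    tau = tau,
    random = random,
    gamma = gamma,
    se = se,
    vcov = vcov,
    loglik = ll,
    loglik_null = ll0,
    rho2 = mcfadden_rho2(ll, ll0),
    n_obs = arr$n_sit,
    n_respondents = arr$n_resp,
    D = as.integer(D),
    scheme = scheme,
    seed = as.integer(seed),
    boundary = boundary,
    grad_norm = grad_norm,
    convergence = opt$convergence
  ), class = "gmnl_fit")
}

#' @export
print.gmnl_fit <- function(x, ...) {
  cat("G-MNL fit (gamma = ", x$gamma, ", ", x$D, " ", x$scheme,
      " draws): ", x$n_obs, " situations, ", x$n_respondents,
      " respondents\n", sep = "")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  if (any(x$boundary)) {
    cat("  note: ", paste(names(x$boundary)[x$boundary], collapse = ", "),
        " at the zero boundary\n", sep = "")
  }
  cat("simulated log-likelihood ", round(x$loglik, 2), " (null ",
      round(x$loglik_null, 2), "), McFadden rho2 ", round(x$rho2, 3),
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.gmnl_fit <- function(object, ...) object$coefficients

#' @export
vcov.gmnl_fit <- function(object, ...) object$vcov

#' @export
logLik.gmnl_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' @export
summary.gmnl_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  out <- data.frame(term = names(object$coefficients),
                    estimate = unname(object$coefficients),
                    se = unname(object$se),
                    z = unname(z),
                    p_value = unname(2 * pnorm(-abs(z))))
  rownames(out) <- NULL
  out
}

#' McFadden pseudo-R-squared
#'
#' `1 - loglik / loglik_null`, the likelihood-ratio index of a choice
#' model against its ASC-only null; values of 0.2-0.4 are conventional
#' indicators of a very good fit.
#'
#' @param loglik maximized model log-likelihood (negative).
#' @param loglik_null maximized null log-likelihood (negative).
#' @return The pseudo-R-squared (scalar).
#' @examples
#' mcfadden_rho2(-1493.1, -1864.1)  # about 0.20
#' @export
mcfadden_rho2 <- function(loglik, loglik_null) {
  if (loglik > 0) stop("'loglik' must be nonpositive", call. = FALSE)
  if (loglik_null >= 0) stop("'loglik_null' must be negative",
                             call. = FALSE)
  1 - loglik / loglik_null
}

#' Wald odds ratios of attribute part-worths
#'
#' For effect-coded two-level attributes `exp(beta)` is the
#' multiplicative change in choice odds between the two levels, with
#' Wald confidence bounds `exp(beta +/- z * se)` on the log-odds scale.
#'
#' @param fit an `mnl_fit` or `gmnl_fit`, or a data frame with columns
#'   `term`, `estimate`, `se`.
#' @param level confidence level (default 0.95).
#' @return A data frame with `term`, `estimate`, `se`, `odds_ratio`,
#'   `lower`, `upper`.
#' @examples
#' odds_ratios(data.frame(term = "tail_type", estimate = 0.8986,
#'                        se = 0.051))
#' @export
odds_ratios <- function(fit, level = 0.95) {
  UseMethod("odds_ratios")
}

or_from_table <- function(tab, level) {
  z <- qnorm(1 - (1 - level) / 2)
  if (any(is.na(tab$se))) {
    warning("missing standard errors: confidence bounds omitted for ",
            paste(tab$term[is.na(tab$se)], collapse = ", "), call. = FALSE)
  }
  data.frame(term = tab$term,
             estimate = tab$estimate,
             se = tab$se,
             odds_ratio = exp(tab$estimate),
             lower = exp(tab$estimate - z * tab$se),
             upper = exp(tab$estimate + z * tab$se))
}

#' @export
odds_ratios.data.frame <- function(fit, level = 0.95) {
  stopifnot(all(c("term", "estimate") %in% names(fit)))
  if (is.null(fit$se)) fit$se <- NA_real_
  or_from_table(fit, level)
}

#' @export
odds_ratios.mnl_fit <- function(fit, level = 0.95) {
  keep <- names(fit$beta)
  or_from_table(data.frame(term = keep,
                           estimate = unname(fit$beta),
                           se = unname(fit$se[keep])), level)
}

#' @export
odds_ratios.gmnl_fit <- function(fit, level = 0.95) {
  keep <- names(fit$beta)
  or_from_table(data.frame(term = keep,
                           estimate = unname(fit$beta),
                           se = unname(fit$se[keep])), level)
}
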