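test_that("single-draw scale shifts coefficients by exp(-tau^2/2)", {
  dat <- quick_mnl_data(25, seed = 33)
  beta <- ram_mnl_truth()$beta
  asc <- c(0, 0.3, -0.9, 1.0)
  tau <- 0.8
  # one draw with eta = 0, eps0 = 0: sigma = exp(-tau^2/2) exactly
  d1 <- structure(list(eta = matrix(0, 1, 0), eps0 = 0, D = 1L, K = 0L,
                       scheme = "pseudo", seed = 1L), class = "draw_set")
  p_sim <- gmnl_probability(dat, beta, asc, tau = tau, draws = d1)
  pm <- mnl_probabilities(dat, beta * exp(-tau^2 / 2), asc)
  ch <- dat$chosen == 1
  p_ref <- exp(tapply(log(pm[ch]), dat$respondent_id[ch], sum))
  expect_equal(unname(p_sim), as.vector(p_ref[names(p_sim)]),
               tolerance = 1e-12)
})

test_that("mixed-logit probability matches numerical integration", {
  # one random attribute, 2 alternatives, 1 situation per respondent
  attrs <- tiny_attrs(1)
  rows <- data.frame(
    respondent_id = rep(1:2, each = 2),
    situation_id = 1L,
    alternative_id = rep(1:2, 2),
    chosen = c(1L, 0L, 0L, 1L),
    is_opt_out = 0L,
    a1 = rep(c(1L, -1L), 2)
  )
  dat <- choice_data(rows, attrs)
  beta <- c(a1 = 0.5)
  s <- 0.9
  draws <- make_draws(1e5, 1, "halton")
  p_sim <- gmnl_probability(dat, beta, eta_sd = c(a1 = s), tau = 0,
                            draws = draws)
  # P(choose +1) = E[plogis(2(beta + s z))] over z ~ N(0,1)
  p_int <- stats::integrate(function(z) {
    plogis(2 * (beta + s * z)) * dnorm(z)
  }, -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(unname(p_sim[1]), p_int, tolerance = 1e-3)
  expect_equal(unname(p_sim[2]), 1 - p_int, tolerance = 1e-3)
})

test_that("the compiled kernel reproduces the R reference likelihood", {
  dat <- quick_mnl_data(40, seed = 34)
  arr <- flockchoice:::model_arrays(dat)
  random <- c("body_size", "tail_type")
  is_random <- arr$attrs %in% random
  draws <- make_draws(40, 2, "halton")
  h <- matrix(0, 40, ncol(arr$x))
  h[, which(is_random)] <- draws$eta
  npar <- ncol(arr$x) + arr$n_alt - 1 + 2 + 1
  theta <- seq(-0.3, 0.6, length.out = npar)
  out <- flockchoice:::gmnl_loglik_cpp(
    theta, arr$x, arr$alt, arr$sit - 1L, arr$sit_resp - 1L, arr$chosen,
    h, draws$eps0, is_random, arr$n_alt, 0, TRUE, 0, TRUE)
  k <- ncol(arr$x)
  p_ref <- gmnl_probability(
    dat, setNames(theta[1:k], arr$attrs),
    asc = c(0, theta[k + 1:(arr$n_alt - 1)]),
    eta_sd = setNames(theta[k + arr$n_alt - 1 + 1:2], random),
    tau = theta[npar], draws = draws)
  expect_equal(out$loglik, sum(log(p_ref)), tolerance = 1e-10)

  # analytic gradient against central differences
  f <- function(th) flockchoice:::gmnl_loglik_cpp(
    th, arr$x, arr$alt, arr$sit - 1L, arr$sit_resp - 1L, arr$chosen,
    h, draws$eps0, is_random, arr$n_alt, 0, TRUE, 0, FALSE)$loglik
  fd <- fd_gradient(f, theta)
  expect_lt(max(abs(out$grad - fd)), 1e-5)
})

test_that("simulated likelihood is invariant to permuting draws", {
  dat <- quick_mnl_data(30, seed = 35)
  beta <- ram_mnl_truth()$beta
  asc <- c(0, 0.3, -0.9, 1.0)
  draws <- make_draws(100, 1, "halton")
  perm <- sample(100)
  shuffled <- draws
  shuffled$eta <- draws$eta[perm, , drop = FALSE]
  shuffled$eps0 <- draws$eps0[perm]
  p1 <- gmnl_probability(dat, beta, asc,
                         eta_sd = c(tail_type = 0.5), tau = 0.4,
                         draws = draws)
  p2 <- gmnl_probability(dat, beta, asc,
                         eta_sd = c(tail_type = 0.5), tau = 0.4,
                         draws = shuffled)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("simulation noise at the likelihood shrinks as draws grow", {
  dat <- quick_mnl_data(60, seed = 36)
  beta <- ram_mnl_truth()$beta
  asc <- c(0, 0.3, -0.9, 1.0)
  ll <- function(D) {
    sum(log(gmnl_probability(dat, beta, asc,
                             eta_sd = c(body_size = 0.4, tail_type = 0.6),
                             tau = 0.5, draws = make_draws(D, 2, "halton"))))
  }
  ref <- ll(20000)
  expect_lt(abs(ll(2000) - ref), abs(ll(100) - ref))
})

test_that("G-MNL with no heterogeneity collapses to the MNL fit", {
  dat <- quick_mnl_data(150, seed = 37)
  mnl <- fit_mnl(dat)
  gm <- fit_gmnl(dat, random = character(0), D = 10,
                 estimate_scale = FALSE, seed = 1)
  expect_equal(coef(gm)[names(coef(mnl))], coef(mnl), tolerance = 1e-6)
  expect_equal(gm$loglik, mnl$loglik, tolerance = 1e-8)
  expect_equal(gm$rho2, mnl$rho2, tolerance = 1e-6)
})

test_that("same-seed refits are exactly reproducible", {
  dat <- quick_mnl_data(60, seed = 38)
  f1 <- fit_gmnl(dat, random = "tail_type", D = 50, seed = 5)
  f2 <- fit_gmnl(dat, random = "tail_type", D = 50, seed = 5)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("McFadden rho2 reproduces the published model fits", {
  ram <- sheep_gmnl_estimates("ram")
  ewe <- sheep_gmnl_estimates("ewe")
  rho_ram <- mcfadden_rho2(attr(ram, "loglik"), attr(ram, "loglik_null"))
  rho_ewe <- mcfadden_rho2(attr(ewe, "loglik"), attr(ewe, "loglik_null"))
  expect_equal(round(rho_ram, 2), 0.20)
  expect_equal(round(rho_ewe, 2), 0.27)
  expect_lt(abs(rho_ram - 0.199), 5e-4)
  expect_lt(abs(rho_ewe - 0.273), 5e-4)
  expect_equal(mcfadden_rho2(-100, -100), 0)
  expect_error(mcfadden_rho2(10, -100), "nonpositive")
  expect_error(mcfadden_rho2(-10, 100), "negative")
})

test_that("odds ratios and Wald bounds follow the log-odds scale", {
  or1 <- odds_ratios(data.frame(term = "tail_type", estimate = 0.8986,
                                se = 0.051))
  expect_equal(round(or1$odds_ratio, 2), 2.46)
  expect_equal(round(or1$lower, 2), 2.22)
  expect_equal(round(or1$upper, 2), 2.71)

  or2 <- odds_ratios(data.frame(term = "mothering_ability",
                                estimate = 1.3056, se = 0.357))
  expect_equal(round(or2$odds_ratio, 2), 3.69)
  expect_equal(round(or2$lower, 2), 1.83)
  expect_lt(abs(or2$upper - 7.42), 0.015)

  # zero effect: OR 1 with bounds symmetric on the log scale
  or0 <- odds_ratios(data.frame(term = "x", estimate = 0, se = 0.2))
  expect_equal(or0$odds_ratio, 1)
  expect_equal(or0$lower * or0$upper, 1, tolerance = 1e-12)

  expect_warning(
    orna <- odds_ratios(data.frame(term = "x", estimate = 0.5)),
    "missing standard errors")
  expect_equal(orna$odds_ratio, exp(0.5))
  expect_true(is.na(orna$lower))
})

test_that("odds ratios from a fit cover exactly the attribute means", {
  dat <- quick_mnl_data(100, seed = 39)
  fit <- fit_mnl(dat)
  ors <- odds_ratios(fit)
  expect_setequal(ors$term, choice_attributes(dat)$name)
  expect_equal(ors$odds_ratio, exp(ors$estimate))
})
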