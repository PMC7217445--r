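test_that("analytic gradient matches finite differences", {
  dat <- quick_mnl_data(60, seed = 4)
  arr <- flockchoice:::model_arrays(dat)
  theta <- seq(-0.4, 0.5, length.out = ncol(arr$x) + arr$n_alt - 1)
  f <- function(th) flockchoice:::mnl_nll(th, arr, TRUE)$nll
  g <- flockchoice:::mnl_nll(theta, arr, TRUE)$grad
  fd <- fd_gradient(f, theta)
  expect_lt(max(abs(g - fd)) / max(1, max(abs(fd))), 1e-5)
})

test_that("binary logit on one attribute matches the closed form", {
  # 2 alternatives with codes +1 and -1: P(+1) = plogis(2 beta), so
  # beta-hat = qlogis(share) / 2 on the aggregated shares
  attrs <- tiny_attrs(1)
  set.seed(77)
  n <- 400
  rows <- data.frame(
    respondent_id = rep(seq_len(n), each = 2),
    situation_id = 1L,
    alternative_id = rep(1:2, n),
    chosen = 0L,
    is_opt_out = 0L,
    a1 = rep(c(1L, -1L), n)
  )
  beta_true <- 0.7
  pick <- runif(n) < plogis(2 * beta_true)
  rows$chosen <- as.integer((rows$alternative_id == 1) == rep(pick, each = 2))
  dat <- choice_data(rows, attrs)
  fit <- fit_mnl(dat, use_asc = FALSE)
  share <- mean(pick)
  expect_equal(unname(coef(fit)), qlogis(share) / 2, tolerance = 1e-6)
})

test_that("MNL recovers its own data-generating parameters", {
  truth <- ram_mnl_truth()
  dat <- quick_mnl_data(2000, seed = 12)
  fit <- fit_mnl(dat)
  target <- c(truth$beta, setNames(truth$asc[-1], paste0("asc_", 2:4)))
  z <- (coef(fit)[names(target)] - target) / fit$se[names(target)]
  expect_true(all(abs(z) < 3))
  expect_lt(fit$grad_norm, 1e-6)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("uniform-random choices give estimates near zero", {
  plan <- sheep_design("ram")
  attrs <- ram_attributes()
  truth <- true_preferences(attrs,
                            beta = setNames(rep(0, 6), attrs$name))
  dat <- drop_opt_outs(simulate_choices(plan, truth, 1500, seed = 14))
  fit <- fit_mnl(dat)
  expect_true(all(abs(coef(fit) / fit$se) < 3))
})

test_that("null log-likelihood equals the multinomial-share optimum", {
  dat <- quick_mnl_data(200, seed = 15)
  ll0 <- null_loglik(dat)
  # with a common alternative set the ASC-only optimum has closed form
  counts <- table(dat$alternative_id[dat$chosen == 1])
  s <- sum(counts)
  expect_equal(ll0, sum(counts * log(counts / s)), tolerance = 1e-8)
  expect_gte(ll0, -s * log(4))

  # uniform spread attains the -S log(J) bound
  rows <- do.call(rbind, lapply(1:4, function(r) {
    data.frame(respondent_id = r, situation_id = 1L,
               alternative_id = 1:4, chosen = as.integer(1:4 == r),
               is_opt_out = 0L, a1 = c(1L, -1L, 1L, -1L))
  }))
  uni <- choice_data(rows, tiny_attrs(1))
  expect_equal(null_loglik(uni), -4 * log(4), tolerance = 1e-8)
})

test_that("negating an attribute's codes flips its estimate exactly", {
  dat <- quick_mnl_data(250, seed = 16)
  fit <- fit_mnl(dat)
  df <- as.data.frame(dat)
  df$coat_color <- -df$coat_color
  flipped <- fit_mnl(choice_data(df, choice_attributes(dat)))
  expect_equal(unname(coef(flipped)["coat_color"]),
               -unname(coef(fit)["coat_color"]), tolerance = 1e-6)
  others <- setdiff(names(coef(fit)), "coat_color")
  expect_equal(coef(flipped)[others], coef(fit)[others], tolerance = 1e-6)
})

test_that("estimates agree with an independent conditional-logit fit", {
  skip_if_not_installed("survival")
  library(survival)
  dat <- quick_mnl_data(250, seed = 18)
  fit <- fit_mnl(dat)
  df <- as.data.frame(dat)
  df$sit <- paste(df$respondent_id, df$situation_id)
  df$pos2 <- as.integer(df$alternative_id == 2)
  df$pos3 <- as.integer(df$alternative_id == 3)
  df$pos4 <- as.integer(df$alternative_id == 4)
  ref <- survival::clogit(
    chosen ~ body_size + coat_color + growth_rate + ear_size + horn +
      tail_type + pos2 + pos3 + pos4 + survival::strata(sit),
    data = df)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$loglik), unname(ref$loglik[2]), tolerance = 1e-6)
})

test_that("the optimum is unique across random restarts", {
  dat <- quick_mnl_data(100, seed = 19)
  base <- fit_mnl(dat)
  set.seed(20)
  for (r in 1:10) {
    start <- runif(length(coef(base)), -1, 1)
    refit <- fit_mnl(dat, start = start)
    expect_equal(coef(refit), coef(base), tolerance = 1e-6)
  }
})

test_that("separation is reported with the offending attribute", {
  # choices perfectly aligned with tail_type
  dat <- quick_mnl_data(80, seed = 22)
  df <- as.data.frame(dat)
  key <- paste(df$respondent_id, df$situation_id)
  df$chosen <- 0L
  for (kk in unique(key)) {
    rows <- which(key == kk)
    df$chosen[rows[which.max(df$tail_type[rows] * 2 +
                               df$alternative_id[rows] * 1e-3)]] <- 1L
  }
  sep <- choice_data(df, choice_attributes(dat))
  expect_error(fit_mnl(sep), "separation|diverges")
})
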