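.halton_primes <- c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L,
                    37L, 41L, 43L)

halton_radical_inverse <- function(idx, base) {
  r <- numeric(length(idx))
  f <- 1
  while (any(idx > 0L)) {
    f <- f / base
    r <- r + f * (idx %% base)
    idx <- idx %/% base
  }
  r
}

#' Draws for simulated likelihood and simulation
#'
#' Generates the `D` draws of the random taste deviations (one
#' dimension per random coefficient) and of the scalar driving the
#' respondent scale. The Halton scheme uses one prime base per
#' dimension with the first 100 points discarded, mapped through the
#' standard-normal quantile; the pseudo scheme draws seeded standard
#' normals. Halton sequences are deterministic, so the seed matters
#' only for the pseudo scheme (it is stored for provenance either way).
#'
#' @param D number of draws (>= 1).
#' @param K number of taste dimensions.
#' @param scheme `"halton"` or `"pseudo"`.
#' @param seed integer seed.
#' @return An object of class `draw_set`: list with `eta` (`D x K`
#'   matrix of standard-normal draws), `eps0` (length-`D` vector),
#'   `D`, `K`, `scheme`, `seed`.
#' @examples
#' d <- make_draws(500, 2, "halton", seed = 1)
#' round(colMeans(d$eta), 2)
#' @export
make_draws <- function(D, K, scheme = c("halton", "pseudo"), seed = 1L) {
  scheme <- match.arg(scheme)
  if (D < 1L) stop("'D' must be at least 1", call. = FALSE)
  if (K + 1L > length(.halton_primes)) {
    stop("at most ", length(.halton_primes) - 1L,
         " taste dimensions are supported (available prime bases)",
         call. = FALSE)
  }
  if (scheme == "halton") {
    idx <- seq.int(101L, length.out = D)  # discard the first 100 points
    eta <- vapply(seq_len(max(K, 1L)), function(k) {
      qnorm(halton_radical_inverse(idx, .halton_primes[k]))
    }, numeric(D))
    eta <- matrix(eta, nrow = D)[, seq_len(K), drop = FALSE]
    eps0 <- qnorm(halton_radical_inverse(idx, .halton_primes[K + 1L]))
  } else {
    set.seed(as.integer(seed))
    eta <- matrix(rnorm(D * K), nrow = D, ncol = K)
    eps0 <- rnorm(D)
  }
  structure(list(eta = eta, eps0 = eps0, D = as.integer(D),
                 K = as.integer(K), scheme = scheme,
                 seed = as.integer(seed)),
            class = "draw_set")
}

#' True preference parameters for the choice simulator
#'
#' A `true_preferences` object fixes the data-generating process of
#' [simulate_choices()]: mean part-worths `beta`, which attributes have
#' person-level taste deviations and their SDs, the
#' scale-heterogeneity SD `tau` (respondent scale
#' `sigma_n = exp(-tau^2/2 + tau * e0_n)`, so `E[sigma_n] = 1`),
#' alternative-specific constants (first fixed at 0), the mixing
#' parameter `gamma` (0 = scaled mixed logit) and the per-situation
#' probability of an opt-out choice.
#'
#' `preset_truth()` returns the parameters of the published ram and ewe
#' G-MNL fits from the smallholder sheep survey (see
#' [sheep_gmnl_estimates()]), including their opt-out rates of 0.47%
#' and 0.4%.
#'
#' @param scenario `"ram_table6"` or `"ewe_table6"`, the ram and ewe
#'   models of the survey.
#' @return A `true_preferences` object.
#' @examples
#' preset_truth("ram_table6")$tau
#' @export
preset_truth <- function(scenario) {
  presets <- c("ram_table6", "ewe_table6")
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% presets) {
    stop("unknown scenario; available presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  model <- if (scenario == "ram_table6") "ram" else "ewe"
  est <- sheep_gmnl_estimates(model)
  attrs <- if (model == "ram") ram_attributes() else ewe_attributes()
  beta_rows <- est[est$role %in% c("fixed", "random_mean"), ]
  beta <- setNames(beta_rows$estimate, beta_rows$term)[attrs$name]
  sd_rows <- est[est$role == "random_sd", ]
  eta_sd <- setNames(sd_rows$estimate, sub("^sd_", "", sd_rows$term))
  asc <- c(0, est$estimate[est$role == "intercept"])
  true_preferences(
    attributes = attrs,
    beta = beta,
    random_attrs = names(eta_sd),
    eta_sd = eta_sd,
    tau = est$estimate[est$role == "scale"],
    asc = asc,
    gamma = 0,
    opt_out_rate = if (model == "ram") 0.0047 else 0.004
  )
}

#' @rdname preset_truth
#' @param attributes a [dce_attributes()] set.
#' @param beta named mean part-worth per attribute.
#' @param random_attrs attributes with person-level taste deviations.
#' @param eta_sd named SD of the deviation for each random attribute.
#' @param tau scale-heterogeneity SD (>= 0).
#' @param asc alternative-specific constants; first must be 0.
#' @param gamma mixing parameter in `[0, 1]`.
#' @param opt_out_rate per-situation probability that the recorded
#'   choice is the opt-out.
#' @export
true_preferences <- function(attributes, beta, random_attrs = character(0),
                             eta_sd = numeric(0), tau = 0,
                             asc = numeric(0), gamma = 0,
                             opt_out_rate = 0) {
  attributes <- as_dce_attributes(attributes)
  if (!all(names(beta) %in% attributes$name) ||
      length(beta) != nrow(attributes)) {
    stop("'beta' must be named after exactly the attribute set",
         call. = FALSE)
  }
  beta <- beta[attributes$name]
  if (!all(random_attrs %in% attributes$name)) {
    stop("'random_attrs' must be a subset of the attributes", call. = FALSE)
  }
  if (length(eta_sd) != length(random_attrs) ||
      !setequal(names(eta_sd), random_attrs)) {
    stop("'eta_sd' must be named after exactly 'random_attrs'",
         call. = FALSE)
  }
  if (any(eta_sd < 0)) stop("'eta_sd' must be nonnegative", call. = FALSE)
  if (tau < 0) stop("'tau' must be nonnegative", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("'gamma' must be in [0, 1]", call. = FALSE)
  if (length(asc) && asc[1] != 0) {
    stop("the first alternative-specific constant is the reference and",
         " must be 0", call. = FALSE)
  }
  if (opt_out_rate < 0 || opt_out_rate >= 1) {
    stop("'opt_out_rate' must be in [0, 1)", call. = FALSE)
  }
  structure(list(attributes = attributes, beta = beta,
                 random_attrs = random_attrs,
                 eta_sd = eta_sd[random_attrs], tau = tau, asc = asc,
                 gamma = gamma, opt_out_rate = opt_out_rate),
            class = "true_preferences")
}

#' @export
print.true_preferences <- function(x, ...) {
  cat("True preferences (G-MNL data-generating process)\n")
  cat("  beta: ", paste(sprintf("%s=%.4g", names(x$beta), x$beta),
                        collapse = ", "), "\n", sep = "")
  if (length(x$random_attrs)) {
    cat("  random: ", paste(sprintf("%s (sd %.4g)", x$random_attrs,
                                    x$eta_sd), collapse = ", "),
        "\n", sep = "")
  }
  cat("  tau = ", x$tau, ", gamma = ", x$gamma,
      ", opt-out rate = ", x$opt_out_rate, "\n", sep = "")
  invisible(x)
}

#' Blocked choice design for the bundled sheep scenarios
#'
#' Convenience wrapper building the 16-profile resolution-IV fraction
#' of the ram (6-attribute) or ewe (7-attribute) factorial, grouped
#' into four blocks with an opt-out in each, i.e. the instrument layout
#' of the smallholder sheep survey: four choice situations per
#' respondent, each offering four designed profiles plus "none".
#'
#' @param sex `"ram"` or `"ewe"`.
#' @param seed seed for the block assignment.
#' @return A `design_plan`.
#' @export
sheep_design <- function(sex = c("ram", "ewe"), seed = 2020L) {
  sex <- match.arg(sex)
  attrs <- if (sex == "ram") ram_attributes() else ewe_attributes()
  add_opt_out(assign_blocks(fractional_factorial(attrs, 16L), 4L,
                            seed = seed))
}

rgumbel <- function(n) -log(-log(runif(n)))

#' Simulate respondents choosing from a blocked design
#'
#' Draws choices from the generalized multinomial logit
#' data-generating process. Each respondent `n` receives taste
#' deviations `eta_n ~ N(0, diag(eta_sd^2))` on the random attributes
#' and a scale `sigma_n = exp(-tau^2/2 + tau * e0_n)` with
#' `e0_n ~ N(0,1)`; in every block (one choice situation per block) the
#' utility of designed alternative `i` is
#' `asc_i + x_i' (sigma_n beta + gamma eta_n + (1-gamma) sigma_n eta_n)`
#' plus i.i.d. standard Gumbel noise, and the alternative with maximal
#' utility is recorded as chosen. Independently, with probability
#' `opt_out_rate` the situation's recorded choice is the opt-out
#' instead (an exogenous thinning event; the opt-out carries no
#' utility). Fully reproducible from `seed`.
#'
#' @param plan a `design_plan`; its attributes must match `truth`'s.
#' @param truth a [true_preferences()] object.
#' @param n_respondents number of simulated respondents; each answers
#'   every block.
#' @param seed integer seed.
#' @return A [choice_data()] object with `n_respondents * n_blocks`
#'   situations.
#' @examples
#' plan <- sheep_design("ram")
#' dat <- simulate_choices(plan, preset_truth("ram_table6"), 50, seed = 1)
#' n_situations(dat)
#' @export
simulate_choices <- function(plan, truth, n_respondents, seed) {
  stopifnot(inherits(plan, "design_plan"),
            inherits(truth, "true_preferences"))
  if (!identical(plan$attributes$name, truth$attributes$name)) {
    stop("design plan and truth refer to different attribute sets",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  attrs <- truth$attributes$name
  k <- length(attrs)
  n <- as.integer(n_respondents)
  m <- profile_matrix(plan$profiles)
  storage.mode(m) <- "double"

  eta <- matrix(0, nrow = n, ncol = k, dimnames = list(NULL, attrs))
  for (a in truth$random_attrs) {
    eta[, a] <- rnorm(n, sd = truth$eta_sd[[a]])
  }
  sigma <- if (truth$tau > 0) {
    exp(-truth$tau^2 / 2 + truth$tau * rnorm(n))
  } else {
    rep(1, n)
  }
  # respondent-specific coefficient matrix (n x k)
  coef_n <- sigma * matrix(truth$beta, n, k, byrow = TRUE) +
    (truth$gamma + (1 - truth$gamma) * sigma) * eta

  pieces <- vector("list", plan$n_blocks)
  for (b in seq_len(plan$n_blocks)) {
    idx <- which(plan$block == b)
    xb <- m[idx, , drop = FALSE]
    j <- nrow(xb)
    asc <- if (length(truth$asc) >= j) truth$asc[seq_len(j)] else rep(0, j)
    u <- coef_n %*% t(xb) +
      matrix(asc, n, j, byrow = TRUE) +
      matrix(rgumbel(n * j), n, j)
    pick <- max.col(u, ties.method = "first")
    has_opt <- plan$opt_out[b]
    opt_pick <- if (has_opt && truth$opt_out_rate > 0) {
      runif(n) < truth$opt_out_rate
    } else {
      rep(FALSE, n)
    }
    n_alt <- j + as.integer(has_opt)
    block_df <- data.frame(
      respondent_id = rep(seq_len(n), each = n_alt),
      situation_id = b,
      alternative_id = rep(seq_len(n_alt), times = n),
      chosen = 0L,
      is_opt_out = rep(c(rep(0L, j), if (has_opt) 1L), times = n)
    )
    codes <- rbind(xb, if (has_opt) rep(0, k))
    code_block <- codes[rep(seq_len(n_alt), times = n), , drop = FALSE]
    block_df <- cbind(block_df, as.data.frame(code_block))
    chosen_alt <- ifelse(opt_pick, n_alt, pick)
    block_df$chosen[(seq_len(n) - 1L) * n_alt + chosen_alt] <- 1L
    pieces[[b]] <- block_df
  }
  choice_data(do.call(rbind, pieces), attributes = truth$attributes)
}
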