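# Shared fixtures: small attribute sets, design plans built directly
# from profile tables, and quick simulated datasets.

tiny_attrs <- function(k) {
  dce_attributes(paste0("a", seq_len(k)),
                 high_label = "high", low_label = "low")
}

# Build a design_plan directly from a profile table and block vector,
# bypassing the randomized block search (used where tests need full
# control over the layout).
manual_plan <- function(profiles, block, opt_out = TRUE) {
  n_blocks <- length(unique(block))
  structure(list(
    attributes = attr(profiles, "dce_attributes"),
    profiles = profiles,
    block = block,
    n_blocks = n_blocks,
    opt_out = rep(opt_out, n_blocks),
    resolution = attr(profiles, "resolution"),
    seed = NA_integer_
  ), class = "design_plan")
}

# MNL truth on the ram attribute set (no taste or scale heterogeneity).
ram_mnl_truth <- function(asc = c(0, 0.2863, -0.9403, 0.9929),
                          opt_out_rate = 0) {
  attrs <- ram_attributes()
  true_preferences(
    attrs,
    beta = setNames(c(0.5132, 0.3237, 0.2666, -0.1869, 0.2523, 0.8986),
                    attrs$name),
    asc = asc,
    opt_out_rate = opt_out_rate
  )
}

# Simulated, opt-out-filtered MNL dataset on the standard ram design.
quick_mnl_data <- function(n_respondents = 300, seed = 1, ...) {
  plan <- sheep_design("ram")
  drop_opt_outs(simulate_choices(plan, ram_mnl_truth(...), n_respondents,
                                 seed = seed))
}

# Central finite differences, for gradient checks.
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h)
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Independent alias-structure oracle: the resolution of a two-level
# design is the size of the smallest subset of columns whose
# elementwise product is constant across runs (Inf if none).
brute_force_resolution <- function(profiles) {
  m <- as.matrix(profiles[, setdiff(names(profiles), "profile_id")])
  n <- nrow(m)
  for (size in seq_len(ncol(m))) {
    subs <- utils::combn(ncol(m), size)
    for (j in seq_len(ncol(subs))) {
      if (abs(sum(apply(m[, subs[, j], drop = FALSE], 1, prod))) == n) {
        return(size)
      }
    }
  }
  Inf
}

# Calibration setting for the IIA test: 5 attributes, full 32-profile
# factorial in 8 blocks of 4. After dropping one alternative the
# restricted conditional logit keeps 8 x 2 = 16 within-situation
# contrasts for 7 parameters, so it stays comfortably identified in
# every replicate (the 4-block survey designs are exactly saturated
# there and can separate by chance).
calib_attrs <- function() {
  dce_attributes(paste0("a", 1:5), high_label = "high", low_label = "low")
}

calib_plan <- function() {
  assign_blocks(full_factorial(calib_attrs()), 8, seed = 7)
}

calib_truth <- function(tau = 0) {
  attrs <- calib_attrs()
  true_preferences(attrs,
                   beta = setNames(c(0.5, 0.3, -0.25, 0.2, 0.4),
                                   attrs$name),
                   asc = c(0, 0.2, -0.3, 0.4),
                   tau = tau)
}
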