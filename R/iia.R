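#' Hausman-McFadden test of the independence of irrelevant alternatives
#'
#' Under IIA, removing one alternative from every choice set (and the
#' situations that chose it) leaves the conditional-logit attribute
#' coefficients unchanged up to sampling noise. The test statistic is
#' `(b_r - b_f)' (V_r - V_f)^+ (b_r - b_f)` on the attribute
#' coefficients shared by the restricted (`r`) and full (`f`) fits,
#' evaluated on the positive part of `V_r - V_f`: the quadratic form is
#' accumulated over the eigendirections with positive eigenvalues and
#' the degrees of freedom equal their count. Negative eigenvalues of
#' the covariance difference are a known finite-sample artifact (the
#' restricted fit is not always less efficient direction-by-direction);
#' including them with a signed pseudo-inverse makes the test severely
#' undersized, while the positive-part form holds its nominal size.
#' The `non_psd` flag records whether any negative eigendirections were
#' projected out.
#'
#' @param data a validated, opt-out-filtered [choice_data()] object
#'   with at least 3 alternatives per situation.
#' @param drop_alternative the `alternative_id` to remove.
#' @return An object of classes `iia_test` and `htest` with
#'   `statistic`, `parameter` (df), `p.value`, `dropped_alternative`
#'   and `non_psd` flag.
#' @examples
#' plan <- sheep_design("ram")
#' truth <- preset_truth("ram_table6")
#' dat <- drop_opt_outs(simulate_choices(plan, truth, 150, seed = 3))
#' hausman_mcfadden(dat, drop_alternative = 2)
#' @export
hausman_mcfadden <- function(data, drop_alternative) {
  stopifnot(inherits(data, "choice_data"))
  alts <- sort(unique(data$alternative_id))
  if (length(alts) < 3L) {
    stop("need at least 3 alternatives before dropping", call. = FALSE)
  }
  if (!drop_alternative %in% alts) {
    stop("alternative ", drop_alternative, " not present", call. = FALSE)
  }
  full <- fit_mnl(data)

  key <- situation_key(data)
  chose_dropped <- unique(key[data$chosen == 1L &
                                data$alternative_id == drop_alternative])
  keep <- !(key %in% chose_dropped) &
    data$alternative_id != drop_alternative
  sub <- data[keep, , drop = FALSE]
  attr(sub, "dce_attributes") <- choice_attributes(data)
  class(sub) <- c("choice_data", "data.frame")
  if (length(unique(sub$alternative_id)) < 2L) {
    stop("fewer than 2 alternatives remain after dropping", call. = FALSE)
  }
  restricted <- fit_mnl(sub)

  common <- choice_attributes(data)$name
  d <- restricted$beta[common] - full$beta[common]
  v <- restricted$vcov[common, common, drop = FALSE] -
    full$vcov[common, common, drop = FALSE]
  es <- eigen((v + t(v)) / 2, symmetric = TRUE)
  tol <- max(abs(es$values)) * 1e-8
  pos <- es$values > tol
  non_psd <- any(es$values < -tol)
  if (all(!pos)) {
    # wholly negative covariance difference: no usable direction; the
    # test is inconclusive and reports no evidence against IIA
    warning("V_r - V_f has no positive eigenvalues; statistic set to 0",
            call. = FALSE)
    pos <- rep(FALSE, length(es$values))
  }
  # positive-part quadratic form: negative eigendirections of V_r - V_f
  # are finite-sample artifacts and are projected out; df counts the
  # retained directions
  proj <- drop(crossprod(es$vectors[, pos, drop = FALSE], d))
  stat <- sum(proj^2 / es$values[pos])
  df <- max(sum(pos), 1L)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(
    statistic = c(chisq = stat),
    parameter = c(df = df),
    p.value = p,
    method = "Hausman-McFadden test of IIA",
    data.name = paste0("choice data, alternative ", drop_alternative,
                       " removed"),
    dropped_alternative = drop_alternative,
    non_psd = non_psd,
    fit_full = full,
    fit_restricted = restricted
  ), class = c("iia_test", "htest"))
}
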