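#' Weighted rank-preference index
#'
#' Summarizes how frequently each item (a trait, selection criterion or
#' production objective) is ranked 1st-4th across respondents. With
#' rank weights `a = (4, 3, 2, 1)` and `X[n, m]` the proportion of
#' respondents ranking item `m` at rank `n`, the index of item `m` is
#' `sum_n a_n X[n, m] / sum_m sum_n a_n X[n, m]`, so the indices sum
#' to 1 (up to rounding of the inputs). Items with no rank information
#' (all `NA`, e.g. criteria not elicited for one sex) are excluded from
#' the denominator.
#'
#' @param proportions a data frame with an `item` column and one column
#'   per rank (`rank1 ... rank4`), or a numeric matrix with items in
#'   rows; values are proportions in `[0, 1]` (or raw counts, which
#'   only rescale the numerator and denominator together).
#' @param weights positive, typically decreasing rank weights; default
#'   `c(4, 3, 2, 1)`.
#' @return A data frame of class `rank_index` with columns `item`,
#'   `score` (weighted sum) and `index`, sorted by decreasing index.
#' @examples
#' rank_index(production_objective_ranks())
#' @export
rank_index <- function(proportions, weights = c(4, 3, 2, 1)) {
  if (is.data.frame(proportions) && "item" %in% names(proportions)) {
    items <- as.character(proportions$item)
    m <- as.matrix(proportions[, setdiff(names(proportions), "item"),
                               drop = FALSE])
  } else {
    m <- as.matrix(proportions)
    items <- rownames(m)
    if (is.null(items)) items <- paste0("item", seq_len(nrow(m)))
  }
  if (ncol(m) != length(weights)) {
    stop("'proportions' must have one column per rank weight (",
         length(weights), ")", call. = FALSE)
  }
  if (any(weights <= 0)) stop("'weights' must be positive", call. = FALSE)
  keep <- rowSums(is.na(m)) < ncol(m)
  m0 <- m[keep, , drop = FALSE]
  m0[is.na(m0)] <- 0
  score <- drop(m0 %*% weights)
  total <- sum(score)
  if (total <= 0) {
    stop("all rank proportions are zero; index undefined", call. = FALSE)
  }
  out <- data.frame(item = items[keep], score = score,
                    index = score / total)
  out <- out[order(-out$index, out$item), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rank_index", "data.frame")
  out
}

#' Flock-structure shares and the ram-to-ewe ratio
#'
#' Derived descriptive statistics from a flock-composition table: each
#' category's share of the mean total flock (as a percentage) and the
#' breeding ram to breeding ewe ratio `1 : round(ewes / rams)`.
#'
#' @param table a data frame with columns `category` and `overall_mean`
#'   including a `"total"` category row, as returned by
#'   [flock_composition()].
#' @return A list with `shares` (data frame of category and
#'   `share_pct`) and `ram_ewe_ratio` (the rounded ewes-per-ram count).
#' @examples
#' flock_shares(flock_composition())$ram_ewe_ratio  # 11
#' @export
flock_shares <- function(table) {
  stopifnot(all(c("category", "overall_mean") %in% names(table)))
  total <- table$overall_mean[table$category == "total"]
  if (length(total) != 1L) {
    stop("'table' must contain exactly one 'total' category row",
         call. = FALSE)
  }
  if (total <= 0) stop("total flock size is zero", call. = FALSE)
  cats <- table[table$category != "total", , drop = FALSE]
  shares <- data.frame(category = cats$category,
                       share_pct = 100 * cats$overall_mean / total)
  ewes <- cats$overall_mean[cats$category == "breeding_ewes"]
  rams <- cats$overall_mean[cats$category == "breeding_rams"]
  ratio <- if (length(ewes) == 1L && length(rams) == 1L && rams > 0) {
    round(ewes / rams)
  } else {
    NA_real_
  }
  list(shares = shares, ram_ewe_ratio = ratio)
}
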