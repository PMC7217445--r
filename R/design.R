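#' Full factorial of two-level effect-coded attributes
#'
#' Enumerates all `2^k` profiles of `k` two-level attributes, coded
#' +1/-1, in lexicographic order (first attribute varies slowest, +1
#' before -1).
#'
#' @param attributes a [dce_attributes()] set (or character vector of
#'   attribute names).
#' @return A data frame with a `profile_id` column followed by one
#'   +1/-1 integer column per attribute; the attribute metadata is kept
#'   in `attr(, "dce_attributes")`.
#' @examples
#' nrow(full_factorial(ram_attributes()))  # 64
#' nrow(full_factorial(ewe_attributes()))  # 128
#' @export
full_factorial <- function(attributes) {
  attributes <- as_dce_attributes(attributes)
  k <- nrow(attributes)
  n <- 2L^k
  m <- matrix(1L, nrow = n, ncol = k,
              dimnames = list(NULL, attributes$name))
  for (j in seq_len(k)) {
    m[, j] <- rep(rep(c(1L, -1L), each = 2L^(k - j)), length.out = n)
  }
  profiles_df(m, attributes, resolution = Inf)
}

profiles_df <- function(m, attributes, resolution = NA, generators = NULL) {
  out <- data.frame(profile_id = seq_len(nrow(m)), m,
                    check.names = FALSE)
  attr(out, "dce_attributes") <- attributes
  attr(out, "resolution") <- resolution
  if (!is.null(generators)) attr(out, "generators") <- generators
  class(out) <- c("dce_profiles", "data.frame")
  out
}

# Extract the +1/-1 code matrix from profiles in any accepted form.
profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  if (is.list(profiles) && !is.data.frame(profiles)) {
    lens <- lengths(profiles)
    if (length(unique(lens)) != 1L) {
      stop("ragged code vectors: profiles have differing lengths",
           call. = FALSE)
    }
    return(do.call(rbind, profiles))
  }
  if (is.data.frame(profiles)) {
    cols <- setdiff(names(profiles), "profile_id")
    return(as.matrix(profiles[, cols, drop = FALSE]))
  }
  stop("cannot interpret 'profiles'", call. = FALSE)
}

# Minimum-aberration generator catalog for regular two-level fractions.
# Key "k.q": k factors in 2^q runs; generators are index sets over the
# q base factors defining each added factor.
.fraction_catalog <- list(
  "3.2" = list(gen = list(c(1L, 2L)), res = 3L),
  "4.3" = list(gen = list(c(1L, 2L, 3L)), res = 4L),
  "5.3" = list(gen = list(c(1L, 2L), c(1L, 3L)), res = 3L),
  "5.4" = list(gen = list(c(1L, 2L, 3L, 4L)), res = 5L),
  "6.3" = list(gen = list(c(1L, 2L), c(1L, 3L), c(2L, 3L)), res = 3L),
  "6.4" = list(gen = list(c(1L, 2L, 3L), c(2L, 3L, 4L)), res = 4L),
  "6.5" = list(gen = list(c(1L, 2L, 3L, 4L, 5L)), res = 6L),
  "7.3" = list(gen = list(c(1L, 2L), c(1L, 3L), c(2L, 3L),
                          c(1L, 2L, 3L)), res = 3L),
  "7.4" = list(gen = list(c(1L, 2L, 3L), c(2L, 3L, 4L),
                          c(1L, 3L, 4L)), res = 4L),
  "7.5" = list(gen = list(c(1L, 2L, 3L, 4L), c(1L, 2L, 4L, 5L)), res = 4L),
  "8.4" = list(gen = list(c(2L, 3L, 4L), c(1L, 3L, 4L),
                          c(1L, 2L, 3L), c(1L, 2L, 4L)), res = 4L),
  "8.5" = list(gen = list(c(1L, 2L, 3L), c(1L, 2L, 4L),
                          c(2L, 3L, 4L, 5L)), res = 4L)
)

# Resolution of a regular fraction = shortest word in the defining
# contrast subgroup, enumerated from the generator words by bitmask XOR.
generator_resolution <- function(generators, q) {
  p <- length(generators)
  words <- vapply(seq_along(generators), function(i) {
    mask <- 0L
    for (b in generators[[i]]) mask <- bitwXor(mask, bitwShiftL(1L, b - 1L))
    bitwXor(mask, bitwShiftL(1L, q + i - 1L))  # add the generated letter
  }, integer(1))
  min_len <- Inf
  for (s in seq_len(2L^p - 1L)) {
    w <- 0L
    for (i in seq_len(p)) {
      if (bitwAnd(s, bitwShiftL(1L, i - 1L)) != 0L) w <- bitwXor(w, words[i])
    }
    len <- sum(bitwAnd(w, bitwShiftL(1L, 0:30)) != 0L)
    min_len <- min(min_len, len)
  }
  min_len
}

#' Regular two-level fractional factorial
#'
#' Builds a regular `2^(k-p)` fraction from standard minimum-aberration
#' generators, e.g. the 16-run resolution-IV fractions of 6 and 7
#' two-level attributes used to keep a choice experiment cognitively
#' manageable. Resolution IV guarantees no main effect is aliased with
#' any two-factor interaction.
#'
#' @inheritParams full_factorial
#' @param n_runs number of profiles; must be a power of two, at most
#'   `2^k`.
#' @param min_resolution minimum acceptable design resolution
#'   (default 4 = resolution IV).
#' @return A profile data frame as in [full_factorial()], with the
#'   achieved resolution in `attr(, "resolution")` and the generator
#'   words in `attr(, "generators")`.
#' @examples
#' d <- fractional_factorial(ram_attributes(), n_runs = 16)
#' attr(d, "resolution")  # 4
#' @export
fractional_factorial <- function(attributes, n_runs, min_resolution = 4) {
  attributes <- as_dce_attributes(attributes)
  k <- nrow(attributes)
  q <- log2(n_runs)
  if (n_runs < 2 || abs(q - round(q)) > 1e-9) {
    stop("'n_runs' must be a power of 2", call. = FALSE)
  }
  q <- as.integer(round(q))
  if (n_runs > 2^k) {
    stop("'n_runs' cannot exceed the full factorial size 2^k = ", 2^k,
         call. = FALSE)
  }
  if (q == k) {  # the fraction is the full factorial itself
    return(full_factorial(attributes))
  }
  key <- paste(k, q, sep = ".")
  entry <- .fraction_catalog[[key]]
  if (is.null(entry)) {
    stop("no generator catalog entry for ", k, " attributes in ", n_runs,
         " runs; supported fractions cover k <= 8", call. = FALSE)
  }
  achieved <- generator_resolution(entry$gen, q)
  stopifnot(achieved == entry$res)
  if (achieved < min_resolution) {
    stop("no regular fraction of resolution >= ", min_resolution,
         " exists for ", k, " attributes in ", n_runs,
         " runs; best achievable resolution is ", achieved, call. = FALSE)
  }
  base <- profile_matrix(full_factorial(attributes$name[seq_len(q)]))
  m <- matrix(0L, nrow = n_runs, ncol = k,
              dimnames = list(NULL, attributes$name))
  m[, seq_len(q)] <- base
  for (i in seq_along(entry$gen)) {
    m[, q + i] <- as.integer(apply(base[, entry$gen[[i]], drop = FALSE],
                                   1L, prod))
  }
  # deterministic lexicographic row order, +1 sorted first
  ord <- do.call(order, as.data.frame(-m))
  gens <- lapply(entry$gen, function(g) attributes$name[g])
  names(gens) <- attributes$name[q + seq_along(entry$gen)]
  profiles_df(m[ord, , drop = FALSE], attributes,
              resolution = achieved, generators = gens)
}

#' Orthogonality and resolution diagnostics for a set of profiles
#'
#' For an orthogonal array of `n` runs every coded column sums to zero
#' (level balance) and every pair of columns has inner product zero, so
#' the cross-product matrix equals `n * I`. The achieved resolution is
#' the size of the smallest set of columns whose elementwise product is
#' constant (fully confounded with the intercept); `Inf` for a full
#' factorial.
#'
#' @param profiles profile data frame, +1/-1 matrix, or list of code
#'   vectors (all of equal length).
#' @return An object of class `orthogonality_report`: list with
#'   `n_runs`, `balance` (column sums), `cross_product`, `max_offdiag`,
#'   `confounded_pairs`, `resolution` and logical `ok`.
#' @examples
#' check_orthogonality(full_factorial(ram_attributes()))$ok
#' @export
check_orthogonality <- function(profiles) {
  m <- profile_matrix(profiles)
  if (nrow(m) < 2L) stop("need at least 2 profiles", call. = FALSE)
  storage.mode(m) <- "double"
  n <- nrow(m)
  k <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("attr", seq_len(k))
  cp <- crossprod(m)
  off <- abs(cp - diag(n, k))
  bal <- colSums(m)
  pairs <- which(upper.tri(off) & abs(cp) >= n - 1e-9, arr.ind = TRUE)
  confounded <- if (nrow(pairs)) {
    data.frame(col_a = colnames(m)[pairs[, 1]],
               col_b = colnames(m)[pairs[, 2]],
               inner_product = cp[pairs])
  } else {
    data.frame(col_a = character(0), col_b = character(0),
               inner_product = numeric(0))
  }
  resolution <- Inf
  if (k <= 12L) {  # brute-force word search over column subsets
    for (size in seq_len(k)) {
      subs <- utils::combn(k, size)
      prods <- vapply(seq_len(ncol(subs)), function(j) {
        abs(sum(apply(m[, subs[, j], drop = FALSE], 1L, prod)))
      }, numeric(1))
      if (any(prods >= n - 1e-9)) {
        resolution <- size
        break
      }
    }
  } else {
    resolution <- NA
  }
  structure(list(
    n_runs = n,
    balance = bal,
    cross_product = cp,
    max_offdiag = max(off[upper.tri(off)], 0),
    confounded_pairs = confounded,
    resolution = resolution,
    ok = all(abs(bal) < 1e-9) && max(off[upper.tri(off)], 0) < 1e-9
  ), class = "orthogonality_report")
}

#' @export
print.orthogonality_report <- function(x, ...) {
  cat("Orthogonality diagnostic (", x$n_runs, " runs)\n", sep = "")
  cat("  balanced columns:    ", all(abs(x$balance) < 1e-9), "\n")
  cat("  pairwise orthogonal: ", x$max_offdiag < 1e-9,
      " (max |inner product| = ", x$max_offdiag, ")\n", sep = "")
  cat("  achieved resolution: ",
      if (is.infinite(x$resolution)) "full factorial" else x$resolution,
      "\n", sep = "")
  if (nrow(x$confounded_pairs)) {
    cat("  fully confounded column pairs:\n")
    print(x$confounded_pairs, row.names = FALSE)
  }
  invisible(x)
}

block_balance_score <- function(m, block) {
  sum(vapply(split(seq_len(nrow(m)), block), function(idx) {
    sum(abs(colSums(m[idx, , drop = FALSE])))
  }, numeric(1)))
}

# Smallest eigenvalue of the conditional-logit information matrix at
# beta = 0 (attributes + position dummies) for a block assignment; a
# positive value means every part-worth and ASC is identified when each
# block is one choice situation.
block_min_information <- function(m, block) {
  size <- nrow(m) / length(unique(block))
  k <- ncol(m)
  info <- matrix(0, k + size - 1L, k + size - 1L)
  w <- diag(1 / size, size) - matrix(1 / size^2, size, size)
  pos <- diag(size)[, -1L, drop = FALSE]
  for (idx in split(seq_len(nrow(m)), block)) {
    z <- cbind(m[idx, , drop = FALSE], pos)
    info <- info + crossprod(z, w %*% z)
  }
  min(eigen(info, symmetric = TRUE, only.values = TRUE)$values)
}

# Blocking objective: within-block level balance, with a hard penalty
# for assignments under which the choice model is not identified and a
# tiny tie-break favoring better-conditioned assignments.
block_objective <- function(m, block) {
  e <- block_min_information(m, block)
  block_balance_score(m, block) + 1000 * (e < 1e-6) - 1e-3 * min(e, 1)
}

#' Group profiles into blocks of choice alternatives
#'
#' Partitions the profiles into equal-sized blocks (one block = the set
#' of designed alternatives shown together in one choice situation),
#' using seeded randomized search that balances each attribute's +1/-1
#' counts within blocks as far as the arithmetic allows.
#'
#' @param profiles profile data frame from [full_factorial()] or
#'   [fractional_factorial()].
#' @param n_blocks number of blocks; must divide the number of profiles.
#' @param seed integer seed making the assignment reproducible.
#' @return An object of class `design_plan`: list with `attributes`,
#'   `profiles`, `block` (block index per profile), `n_blocks`,
#'   `opt_out` (per-block flag, all `FALSE` until [add_opt_out()]),
#'   `resolution`, `seed`.
#' @examples
#' plan <- assign_blocks(fractional_factorial(ram_attributes(), 16), 4,
#'                       seed = 1)
#' table(plan$block)
#' @export
assign_blocks <- function(profiles, n_blocks, seed) {
  m <- profile_matrix(profiles)
  n <- nrow(m)
  if (n %% n_blocks != 0L) {
    stop("'n_blocks' (", n_blocks, ") must divide the number of profiles (",
         n, ")", call. = FALSE)
  }
  if (anyDuplicated(m)) stop("profiles must be distinct", call. = FALSE)
  size <- n %/% n_blocks
  set.seed(as.integer(seed))
  best <- rep(seq_len(n_blocks), each = size)[sample.int(n)]
  best_score <- block_objective(m, best)
  # pairwise-swap hill climbing from several random starts
  for (start in 1:5) {
    block <- rep(seq_len(n_blocks), each = size)[sample.int(n)]
    score <- block_objective(m, block)
    improved <- TRUE
    while (improved && score > 0) {
      improved <- FALSE
      for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
          if (block[i] == block[j]) next
          cand <- block
          cand[c(i, j)] <- cand[c(j, i)]
          s <- block_objective(m, cand)
          if (s < score) {
            block <- cand
            score <- s
            improved <- TRUE
          }
        }
      }
    }
    if (score < best_score) {
      best <- block
      best_score <- score
    }
  }
  structure(list(
    attributes = attr(profiles, "dce_attributes"),
    profiles = profiles,
    block = best,
    n_blocks = as.integer(n_blocks),
    opt_out = rep(FALSE, n_blocks),
    resolution = attr(profiles, "resolution"),
    seed = as.integer(seed)
  ), class = "design_plan")
}

#' Add an opt-out alternative to every block
#'
#' Flags each block of a design plan as carrying a "none of these"
#' option, so a block of 4 designed profiles presents 5 choice options.
#' The opt-out carries no attribute codes and never enters the design
#' algebra; it exists so respondents are not forced to choose.
#' Idempotent: applying twice adds nothing.
#'
#' @param plan a `design_plan` from [assign_blocks()].
#' @return The plan with all `opt_out` flags set.
#' @export
add_opt_out <- function(plan) {
  stopifnot(inherits(plan, "design_plan"))
  if (plan$n_blocks < 1L) stop("plan has no blocks", call. = FALSE)
  plan$opt_out[] <- TRUE
  plan
}

#' @export
print.design_plan <- function(x, ...) {
  cat("Choice-experiment design plan\n")
  cat("  attributes: ", paste(x$attributes$name, collapse = ", "), "\n")
  cat("  profiles:   ", nrow(x$profiles), " in ", x$n_blocks,
      " blocks of ", nrow(x$profiles) / x$n_blocks, "\n", sep = "")
  res <- x$resolution
  cat("  resolution: ",
      if (is.null(res) || is.na(res)) "unknown"
      else if (is.infinite(res)) "full factorial" else res, "\n", sep = "")
  cat("  opt-out:    ", if (all(x$opt_out)) "present in every block"
      else "none", "\n", sep = "")
  invisible(x)
}

#' Minimum sample size for a choice experiment
#'
#' Rule-of-thumb lower bound `N > 500 * c / (t * a)` on the number of
#' respondents, where `c` is the highest number of levels of any
#' attribute, `t` the number of choice tasks per respondent and `a` the
#' number of alternatives per task. The bound itself is returned when it
#' is an integer (a study with two-level attributes, one task of four
#' alternatives needs 250 respondents).
#'
#' @param n_levels highest number of levels of any attribute (`c`).
#' @param n_tasks choice tasks per respondent (`t`).
#' @param n_alternatives alternatives per task (`a`).
#' @return Minimum integer number of respondents.
#' @examples
#' min_sample_size(2, 1, 4)  # 250
#' @export
min_sample_size <- function(n_levels, n_tasks, n_alternatives) {
  if (any(c(n_levels, n_tasks, n_alternatives) <= 0)) {
    stop("all sample-size inputs must be positive", call. = FALSE)
  }
  if (n_levels < 2) stop("'n_levels' must be at least 2", call. = FALSE)
  bound <- 500 * n_levels / (n_tasks * n_alternatives)
  as.integer(ceiling(bound - 1e-9))
}

#' Export / import a design plan as CSV
#'
#' Writes one row per alternative with columns `block`, `alternative`,
#' the attribute code columns (+1/-1; 0 on opt-out rows) and
#' `is_opt_out`. [read_design_csv()] reverses the operation, recovering
#' blocks, codes and opt-out flags; attribute level labels travel in the
#' JSON mirror written by [write_design_json()].
#'
#' @param plan a `design_plan`.
#' @param path file path.
#' @return `write_design_csv()` returns `path` invisibly;
#'   `read_design_csv()` returns a `design_plan`.
#' @export
write_design_csv <- function(plan, path) {
  stopifnot(inherits(plan, "design_plan"))
  m <- profile_matrix(plan$profiles)
  rows <- lapply(seq_len(plan$n_blocks), function(b) {
    idx <- which(plan$block == b)
    out <- data.frame(block = b, alternative = seq_along(idx),
                      m[idx, , drop = FALSE], is_opt_out = 0L,
                      check.names = FALSE)
    if (plan$opt_out[b]) {
      oo <- out[1L, ]
      oo$alternative <- length(idx) + 1L
      oo[, colnames(m)] <- 0L
      oo$is_opt_out <- 1L
      out <- rbind(out, oo)
    }
    out
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("block", "alternative", "is_opt_out")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("design CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  attr_cols <- setdiff(names(df), need)
  designed <- df[df$is_opt_out == 0L, , drop = FALSE]
  m <- as.matrix(designed[, attr_cols, drop = FALSE])
  storage.mode(m) <- "integer"
  attributes <- as_dce_attributes(attr_cols)
  profiles <- profiles_df(m, attributes)
  opt_blocks <- unique(df$block[df$is_opt_out == 1L])
  n_blocks <- length(unique(df$block))
  structure(list(
    attributes = attributes,
    profiles = profiles,
    block = as.integer(designed$block),
    n_blocks = as.integer(n_blocks),
    opt_out = seq_len(n_blocks) %in% opt_blocks,
    resolution = check_orthogonality(profiles)$resolution,
    seed = NA_integer_
  ), class = "design_plan")
}

#' @rdname write_design_csv
#' @export
write_design_json <- function(plan, path) {
  stopifnot(inherits(plan, "design_plan"))
  m <- profile_matrix(plan$profiles)
  obj <- list(
    attributes = plan$attributes,
    n_blocks = plan$n_blocks,
    opt_out = plan$opt_out,
    resolution = if (is.infinite(plan$resolution)) "full" else plan$resolution,
    blocks = lapply(seq_len(plan$n_blocks), function(b) {
      idx <- which(plan$block == b)
      list(block = b,
           profiles = as.data.frame(m[idx, , drop = FALSE]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
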