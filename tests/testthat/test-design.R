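test_that("full factorial enumerates all distinct profiles in order", {
  for (k in c(1, 3, 6, 7)) {
    ff <- full_factorial(tiny_attrs(k))
    m <- as.matrix(ff[, -1])
    expect_equal(nrow(ff), 2^k)
    expect_equal(nrow(unique(m)), 2^k)
    expect_true(all(m %in% c(-1L, 1L)))
    # lexicographic: first row all +1, last all -1, rows strictly decreasing
    expect_equal(unname(m[1, ]), rep(1L, k))
    expect_equal(unname(m[2^k, ]), rep(-1L, k))
  }
  expect_equal(nrow(full_factorial(ram_attributes())), 64)
  expect_equal(nrow(full_factorial(ewe_attributes())), 128)
  expect_error(full_factorial(character(0)), "at least one attribute")
})

test_that("full factorials are orthogonal arrays", {
  for (k in 2:8) {
    rep <- check_orthogonality(full_factorial(tiny_attrs(k)))
    expect_true(rep$ok)
    expect_equal(rep$cross_product, diag(2^k, k), ignore_attr = TRUE)
  }
})

test_that("16-run fractions of 6 and 7 attributes are resolution IV", {
  for (attrs in list(ram_attributes(), ewe_attributes())) {
    fr <- fractional_factorial(attrs, 16)
    expect_equal(nrow(fr), 16)
    expect_equal(attr(fr, "resolution"), 4)
    # independent alias oracle: no word shorter than 4 columns
    expect_equal(brute_force_resolution(fr), 4)
    rep <- check_orthogonality(fr)
    expect_true(rep$ok)
    expect_equal(rep$resolution, 4)
  }
})

test_that("a fraction is a coset of the full factorial group", {
  fr <- as.matrix(fractional_factorial(ram_attributes(), 16)[, -1])
  rows <- split(fr, row(fr))
  ref <- rows[[1]]
  # componentwise product of any two rows (relative to a reference row)
  # stays inside the fraction
  for (i in seq_along(rows)) {
    for (j in seq_len(4)) {
      prod_row <- rows[[i]] * rows[[j]] * ref
      expect_true(any(vapply(rows, function(r) all(r == prod_row),
                             logical(1))))
    }
  }
})

test_that("fraction requests outside the catalog fail informatively", {
  # 6 attributes in 8 runs: best regular fraction is resolution III
  expect_error(fractional_factorial(tiny_attrs(6), 8, min_resolution = 4),
               "best achievable resolution is 3")
  expect_error(fractional_factorial(tiny_attrs(4), 12), "power of 2")
  expect_error(fractional_factorial(tiny_attrs(3), 16), "cannot exceed")
  # full-factorial request is trivially feasible at any resolution
  fr <- fractional_factorial(tiny_attrs(3), 8, min_resolution = 4)
  expect_equal(nrow(fr), 8)
  expect_true(is.infinite(attr(fr, "resolution")))
})

test_that("orthogonality diagnostics flag defects", {
  m <- as.matrix(full_factorial(tiny_attrs(3))[, -1])
  dup <- cbind(m, a4 = m[, "a3"])  # duplicated column
  rep <- check_orthogonality(dup)
  expect_false(rep$ok)
  expect_true(nrow(rep$confounded_pairs) >= 1)
  expect_true(any(rep$confounded_pairs$col_a == "a3" &
                    rep$confounded_pairs$col_b == "a4"))
  expect_error(check_orthogonality(list(c(1, -1), c(1, -1, 1))), "ragged")
})

test_that("block assignment is balanced, reproducible and identified", {
  fr <- fractional_factorial(ram_attributes(), 16)
  plan <- assign_blocks(fr, 4, seed = 11)
  expect_equal(as.vector(table(plan$block)), rep(4L, 4))
  expect_identical(plan$block, assign_blocks(fr, 4, seed = 11)$block)
  expect_error(assign_blocks(fr, 3, seed = 1), "must divide")

  # single block is the identity partition
  one <- assign_blocks(full_factorial(tiny_attrs(2)), 1, seed = 1)
  expect_equal(unique(one$block), 1L)

  # Monte-Carlo comparison: the chosen assignment's level balance is no
  # worse than the median of random equal-size partitions
  m <- as.matrix(fr[, -1])
  score <- flockchoice:::block_balance_score(m, plan$block)
  set.seed(42)
  random_scores <- replicate(1000, {
    flockchoice:::block_balance_score(m, sample(rep(1:4, each = 4)))
  })
  expect_lte(score, median(random_scores))

  # every part-worth and ASC is identified when blocks are situations
  expect_gt(flockchoice:::block_min_information(m, plan$block), 1e-6)
})

test_that("opt-out augmentation is flagged, idempotent and persistent", {
  plan <- assign_blocks(fractional_factorial(ram_attributes(), 16), 4,
                        seed = 3)
  expect_false(any(plan$opt_out))
  plan1 <- add_opt_out(plan)
  expect_true(all(plan1$opt_out))
  expect_identical(add_opt_out(plan1), plan1)

  # each block exports 5 options: 4 designed + 1 opt-out
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv))
  write_design_csv(plan1, csv)
  exported <- read.csv(csv)
  expect_equal(as.vector(table(exported$block)), rep(5L, 4))
  expect_equal(sum(exported$is_opt_out), 4)

  back <- read_design_csv(csv)
  expect_true(all(back$opt_out))
  expect_equal(back$n_blocks, 4)
  expect_equal(as.matrix(back$profiles[, -1]),
               as.matrix(plan1$profiles[, -1])[order(plan1$block), ],
               ignore_attr = TRUE)
})

test_that("minimum sample size follows the 500c/(ta) rule", {
  expect_identical(min_sample_size(2, 1, 4), 250L)
  expect_identical(min_sample_size(2, 1, 1), 1000L)
  expect_identical(min_sample_size(2, 4, 4), 63L)  # ceil(62.5)
  expect_error(min_sample_size(0, 1, 4), "positive|at least")
  expect_error(min_sample_size(2, -1, 4), "positive")

  # monotone: non-decreasing in c, non-increasing in t and a
  for (cc in 2:4) for (tt in 1:3) for (aa in 1:3) {
    n <- min_sample_size(cc, tt, aa)
    expect_gte(min_sample_size(cc + 1, tt, aa), n)
    expect_lte(min_sample_size(cc, tt + 1, aa), n)
    expect_lte(min_sample_size(cc, tt, aa + 1), n)
  }
})
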