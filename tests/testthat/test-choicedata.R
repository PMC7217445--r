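make_situation <- function(resp, sit, chosen_alt, k = 2, with_opt = TRUE) {
  n_alt <- 4 + as.integer(with_opt)
  codes <- matrix(rep(c(1L, -1L), length.out = 4 * k), 4, k)
  if (with_opt) codes <- rbind(codes, rep(0L, k))
  df <- data.frame(respondent_id = resp, situation_id = sit,
                   alternative_id = seq_len(n_alt), chosen = 0L,
                   is_opt_out = c(rep(0L, 4), if (with_opt) 1L))
  df <- cbind(df, as.data.frame(codes))
  names(df)[6:(5 + k)] <- paste0("a", seq_len(k))
  df$chosen[chosen_alt] <- 1L
  df
}

test_that("well-formed datasets validate cleanly", {
  dat <- quick_mnl_data(20, seed = 2)
  expect_equal(nrow(validate_choices(dat)), 0)
})

test_that("validation names the offending situations", {
  df <- rbind(make_situation("r1", 1, 2), make_situation("r1", 2, 1),
              make_situation("r2", 1, 3))
  # two chosen alternatives in (r1, 1)
  bad <- df
  bad$chosen[bad$respondent_id == "r1" & bad$situation_id == 1 &
               bad$alternative_id == 3] <- 1L
  rep <- validate_choices(choice_data(bad))
  expect_equal(nrow(rep), 1)
  expect_equal(rep$respondent_id, "r1")
  expect_equal(rep$situation_id, "1")
  expect_match(rep$issue, "multiple chosen")

  # no chosen alternative
  bad2 <- df
  bad2$chosen[bad2$respondent_id == "r2"] <- 0L
  rep2 <- validate_choices(choice_data(bad2))
  expect_match(rep2$issue, "no chosen")

  # zero code on a designed row
  bad3 <- df
  bad3$a1[2] <- 0L
  rep3 <- validate_choices(choice_data(bad3))
  expect_true(any(grepl("zero code", rep3$issue)))

  # out-of-range codes are rejected at construction
  bad4 <- df
  bad4$a1[1] <- 2L
  expect_error(choice_data(bad4), "outside \\{-1, 0, \\+1\\}")
})

test_that("opt-out filtering removes chosen-opt-out situations wholly", {
  # 370 respondents x 4 situations with exactly 7 opt-out choices
  plan <- sheep_design("ram")
  dat <- simulate_choices(plan, ram_mnl_truth(opt_out_rate = 0), 370,
                          seed = 9)
  expect_equal(n_situations(dat), 1480)
  key <- paste(dat$respondent_id, dat$situation_id)
  force_opt <- unique(key)[c(3, 100, 250, 600, 900, 1200, 1401)]
  sel <- key %in% force_opt
  dat$chosen[sel] <- as.integer(dat$is_opt_out[sel] == 1L)
  filtered <- drop_opt_outs(dat)
  expect_equal(attr(filtered, "removed_situations"), 7)
  expect_equal(n_situations(filtered), 1473)
  expect_equal(sum(filtered$is_opt_out), 0)
  # chosen flags still sum to one per surviving situation
  per_sit <- tapply(filtered$chosen,
                    paste(filtered$respondent_id, filtered$situation_id),
                    sum)
  expect_true(all(per_sit == 1))
  # idempotent
  again <- drop_opt_outs(filtered)
  expect_equal(attr(again, "removed_situations"), 0)
  expect_equal(n_situations(again), 1473)
})

test_that("a dataset with no opt-outs passes through unchanged", {
  df <- rbind(make_situation("r1", 1, 2, with_opt = FALSE),
              make_situation("r2", 1, 4, with_opt = FALSE))
  dat <- choice_data(df)
  out <- drop_opt_outs(dat)
  expect_equal(as.data.frame(out), as.data.frame(dat),
               ignore_attr = TRUE)
  expect_equal(attr(out, "removed_situations"), 0)
})

test_that("all-opt-out datasets collapse with a warning", {
  df <- rbind(make_situation("r1", 1, 5), make_situation("r2", 1, 5))
  dat <- choice_data(df)
  expect_warning(out <- drop_opt_outs(dat), "empty")
  expect_equal(nrow(out), 0)
})

test_that("CSV round-trip is lossless", {
  dat <- quick_mnl_data(10, seed = 5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_choice_csv(dat, path)
  back <- read_choice_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(dat),
               ignore_attr = TRUE)
  expect_equal(choice_attributes(back)$name, choice_attributes(dat)$name)
  # write(read(x)) is stable byte-for-byte
  path2 <- tempfile(fileext = ".csv")
  on.exit(unlink(path2), add = TRUE)
  write_choice_csv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("schema violations and dialect quirks are handled", {
  dat <- quick_mnl_data(5, seed = 6)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_choice_csv(dat, path)
  lines <- readLines(path)

  # missing required column
  broken <- gsub("chosen", "pick", lines)
  path_b <- tempfile(fileext = ".csv")
  on.exit(unlink(path_b), add = TRUE)
  writeLines(broken, path_b)
  expect_error(read_choice_csv(path_b), "chosen")

  # CRLF endings and quoted headers parse identically
  path_c <- tempfile(fileext = ".csv")
  on.exit(unlink(path_c), add = TRUE)
  header <- paste(sprintf('"%s"', strsplit(lines[1], ",")[[1]]),
                  collapse = ",")
  writeLines(c(header, lines[-1]), path_c, sep = "\r\n")
  expect_equal(as.data.frame(read_choice_csv(path_c)),
               as.data.frame(dat), ignore_attr = TRUE)
})
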