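#' Long-format choice data
#'
#' Canonical container for stated-choice observations: one row per
#' alternative shown, with columns `respondent_id`, `situation_id`,
#' `alternative_id`, `chosen` (0/1), `is_opt_out` (0/1) and one
#' effect-coded +1/-1 column per attribute (0 on opt-out rows, which
#' carry no attribute codes). Exactly one row per (respondent,
#' situation) has `chosen = 1`.
#'
#' @param df a data frame with the schema above.
#' @param attributes a [dce_attributes()] set; if `NULL`, every
#'   non-schema column is taken as an attribute.
#' @return The data frame with class `choice_data` and the attribute
#'   metadata attached.
#' @export
choice_data <- function(df, attributes = NULL) {
  schema <- c("respondent_id", "situation_id", "alternative_id",
              "chosen", "is_opt_out")
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols)) {
    stop("choice data is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(attributes)) {
    attributes <- as_dce_attributes(setdiff(names(df), schema))
  } else {
    attributes <- as_dce_attributes(attributes)
    missing_attrs <- setdiff(attributes$name, names(df))
    if (length(missing_attrs)) {
      stop("choice data is missing attribute columns: ",
           paste(missing_attrs, collapse = ", "), call. = FALSE)
    }
  }
  df <- df[, c(schema, attributes$name)]
  df <- df[order(df$respondent_id, df$situation_id, df$alternative_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  df$chosen <- as.integer(df$chosen)
  df$is_opt_out <- as.integer(df$is_opt_out)
  for (a in attributes$name) {
    bad <- !df[[a]] %in% c(-1L, 0L, 1L)
    if (any(bad)) {
      stop("attribute '", a, "' has codes outside {-1, 0, +1} at row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "),
           call. = FALSE)
    }
    df[[a]] <- as.integer(df[[a]])
  }
  attr(df, "dce_attributes") <- attributes
  class(df) <- c("choice_data", "data.frame")
  df
}

#' Attribute metadata of a choice dataset
#' @param data a [choice_data()] object.
#' @return The [dce_attributes()] data frame attached to the dataset.
#' @export
choice_attributes <- function(data) attr(data, "dce_attributes")

situation_key <- function(data) {
  paste(data$respondent_id, data$situation_id, sep = "\r")
}

#' Validate a choice dataset
#'
#' Report-based check of the container invariants: exactly one chosen
#' alternative per situation, distinct alternative positions within a
#' situation, +1/-1 codes on designed rows and all-zero codes on
#' opt-out rows.
#'
#' @param data a [choice_data()] object.
#' @return A data frame with columns `respondent_id`, `situation_id`,
#'   `issue`; zero rows when the dataset is well formed.
#' @export
validate_choices <- function(data) {
  stopifnot(inherits(data, "choice_data"))
  attrs <- choice_attributes(data)$name
  key <- situation_key(data)
  issues <- list()
  add <- function(keys, issue) {
    if (!length(keys)) return()
    parts <- do.call(rbind, strsplit(unique(keys), "\r", fixed = TRUE))
    issues[[length(issues) + 1L]] <<- data.frame(
      respondent_id = parts[, 1], situation_id = parts[, 2], issue = issue)
  }
  n_chosen <- tapply(data$chosen, key, sum)
  add(names(n_chosen)[n_chosen == 0], "no chosen alternative")
  add(names(n_chosen)[n_chosen > 1], "multiple chosen alternatives")
  dup <- tapply(data$alternative_id, key, anyDuplicated)
  add(names(dup)[dup > 0], "duplicate alternative_id")
  first_alt <- tapply(data$alternative_id, key, min)
  add(names(first_alt)[first_alt != 1], "alternative_id does not start at 1")
  codes <- as.matrix(data[, attrs, drop = FALSE])
  bad_designed <- data$is_opt_out == 0L & apply(codes == 0L, 1L, any)
  add(key[bad_designed], "zero code on a designed alternative")
  bad_opt <- data$is_opt_out == 1L & apply(codes != 0L, 1L, any)
  add(key[bad_opt], "nonzero attribute code on an opt-out row")
  if (!length(issues)) {
    return(data.frame(respondent_id = character(0),
                      situation_id = character(0), issue = character(0)))
  }
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

#' Remove opt-out choices before estimation
#'
#' Choice situations whose chosen option is the opt-out are removed
#' entirely (they carry no information about attribute trade-offs) and
#' unchosen opt-out rows are dropped from the remaining situations, so
#' only designed alternatives enter estimation. This mirrors surveys
#' where a fraction of a percent of situations pick "none of these" and
#' those are ignored in the analysis. Idempotent.
#'
#' @param data a [choice_data()] object.
#' @return The filtered `choice_data`, with attributes
#'   `removed_situations` (count of situations whose choice was the
#'   opt-out) and `removed_rows` (total rows dropped).
#' @export
drop_opt_outs <- function(data) {
  stopifnot(inherits(data, "choice_data"))
  key <- situation_key(data)
  chosen_opt <- unique(key[data$chosen == 1L & data$is_opt_out == 1L])
  keep <- !(key %in% chosen_opt) & data$is_opt_out == 0L
  removed_rows <- sum(!keep)
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("all choice situations chose the opt-out; empty dataset",
            call. = FALSE)
  }
  attr(out, "dce_attributes") <- choice_attributes(data)
  attr(out, "removed_situations") <- length(chosen_opt)
  attr(out, "removed_rows") <- removed_rows
  class(out) <- c("choice_data", "data.frame")
  out
}

#' Number of choice situations in a dataset
#' @param data a [choice_data()] object.
#' @return Integer count of distinct (respondent, situation) pairs.
#' @export
n_situations <- function(data) {
  length(unique(situation_key(data)))
}

#' Read / write choice data as CSV
#'
#' The CSV schema is the canonical interchange format: columns
#' `respondent_id`, `situation_id`, `alternative_id`, `chosen`,
#' `is_opt_out`, then one +1/-1 column per attribute (0 on opt-out
#' rows). Reading then writing (or vice versa) is lossless.
#'
#' @param path file path.
#' @param data a [choice_data()] object.
#' @param attributes optional [dce_attributes()] giving level labels;
#'   by default attribute columns are inferred from the header.
#' @return `read_choice_csv()` returns a `choice_data`;
#'   `write_choice_csv()` returns `path` invisibly.
#' @export
read_choice_csv <- function(path, attributes = NULL) {
  df <- read.csv(path, check.names = FALSE)
  choice_data(df, attributes = attributes)
}

#' @rdname read_choice_csv
#' @export
write_choice_csv <- function(data, path) {
  stopifnot(inherits(data, "choice_data"))
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.choice_data <- function(x, n = 8L, ...) {
  cat("Choice data: ", length(unique(x$respondent_id)), " respondents, ",
      n_situations(x), " situations, ", nrow(x), " rows\n", sep = "")
  cat("  attributes: ", paste(choice_attributes(x)$name, collapse = ", "),
      "\n", sep = "")
  print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}
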