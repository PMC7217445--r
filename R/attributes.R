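#' Define a set of two-level effect-coded attributes
#'
#' Attributes in a two-level choice experiment are effect-coded: the
#' "high" level is coded +1 and the "low" level -1, so each part-worth
#' utility is a symmetric deviation from the attribute mean and
#' intercepts are not confounded with attribute effects.
#'
#' @param name character vector of unique attribute identifiers.
#' @param high_label label of the level coded +1.
#' @param low_label label of the level coded -1.
#' @param description optional free-text description per attribute.
#' @return A data frame of class `dce_attributes` with columns `name`,
#'   `description`, `high_label`, `low_label`.
#' @examples
#' dce_attributes(c("body_size", "coat_color"),
#'                high_label = c("large", "brown"),
#'                low_label  = c("small", "white"))
#' @export
dce_attributes <- function(name, high_label, low_label,
                           description = NA_character_) {
  if (length(name) < 1L) {
    stop("at least one attribute is required", call. = FALSE)
  }
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("attribute names must be unique: ",
         paste(unique(name[duplicated(name)]), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    name = name,
    description = rep_len(as.character(description), length(name)),
    high_label = rep_len(as.character(high_label), length(name)),
    low_label = rep_len(as.character(low_label), length(name)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dce_attributes", "data.frame")
  out
}

#' Ram and ewe attribute sets of the smallholder sheep choice experiment
#'
#' The six ram and seven ewe attributes used in the sheep
#' trait-preference survey these tools were built around, with their
#' effect-coded level labels (+1 level first). Rams carry ear size and
#' horn status; ewes carry lambing interval, mothering ability and
#' litter size; body size, coat color, growth rate and tail type are
#' shared.
#'
#' @return A `dce_attributes` data frame (6 rows for rams, 7 for ewes).
#' @examples
#' ram_attributes()
#' nrow(full_factorial(ewe_attributes()))
#' @export
ram_attributes <- function() {
  dce_attributes(
    name = c("body_size", "coat_color", "growth_rate",
             "ear_size", "horn", "tail_type"),
    high_label = c("large", "brown", "rapid (30 kg yearling)",
                   "large", "horned", "good (long, wide)"),
    low_label = c("small", "white", "slow (20 kg yearling)",
                  "small", "polled", "bad (small, thin)"),
    description = c(
      "height and body length of the ram",
      "predominant coat color",
      "yearling live weight at breeding age",
      "ear size of the ram",
      "presence or absence of horns",
      "length and width of the tail"
    )
  )
}

#' @rdname ram_attributes
#' @export
ewe_attributes <- function() {
  dce_attributes(
    name = c("body_size", "coat_color", "growth_rate",
             "lambing_interval", "mothering_ability", "litter_size",
             "tail_type"),
    high_label = c("large", "brown", "rapid (30 kg yearling)",
                   "short (3 lambings / 2 years)", "good", "twin",
                   "good (long, wide)"),
    low_label = c("small", "white", "slow (20 kg yearling)",
                  "long (1 lambing / year)", "poor", "single",
                  "bad (small, thin)"),
    description = c(
      "height and body length of the ewe",
      "predominant coat color",
      "yearling live weight at breeding age",
      "interval between successive lambings",
      "ability of the ewe to nourish her lambs",
      "number of lambs born per lambing",
      "length and width of the tail"
    )
  )
}

as_dce_attributes <- function(x) {
  if (inherits(x, "dce_attributes")) return(x)
  if (is.character(x)) {
    return(dce_attributes(x, high_label = "high", low_label = "low"))
  }
  stop("expected a 'dce_attributes' object or a character vector of names",
       call. = FALSE)
}
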