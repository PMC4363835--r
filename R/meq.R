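#' Load a Morningness-Eveningness Questionnaire instrument definition
#'
#' Reads a 19-item MEQ instrument (item texts, answer options, point values,
#' and time-range midpoints for the clock-time items) from a YAML file. The
#' package ships the canonical Horne-Ostberg (1976) scoring, whose per-item
#' minima sum to 16 and maxima to 86; translated variants that preserve the
#' scoring can be supplied via `path`.
#'
#' @param path Path to an instrument YAML file. `NULL` (default) loads the
#'   packaged Horne-Ostberg 1976 instrument.
#' @return An object of class `meq_instrument`: a list with `name`, `version`
#'   and `items`, where each item has `index`, `kind` (`"choice"` or
#'   `"time_scale"`), `text`, `scores`, `labels`, and for time-scale items
#'   `mids` (decimal hours; times after midnight are offset past 24).
#' @export
meq_instrument <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "meq_horne_ostberg_1976.yaml",
                        package = "chronoherit")
  }
  if (!file.exists(path)) stop("instrument file not found: ", path)
  raw <- yaml::read_yaml(path)
  items <- lapply(raw$items, function(it) {
    scores <- vapply(it$options, function(o) as.numeric(o$score), numeric(1))
    labels <- vapply(it$options, function(o) as.character(o$label), character(1))
    mids <- vapply(it$options, function(o) {
      if (is.null(o$mid)) NA_real_ else as.numeric(o$mid)
    }, numeric(1))
    list(index = as.integer(it$index), kind = it$kind, text = it$text,
         scores = scores, labels = labels, mids = mids)
  })
  items <- items[order(vapply(items, `[[`, integer(1), "index"))]
  obj <- structure(list(name = raw$name, version = raw$version, items = items),
                   class = "meq_instrument")
  validate_meq_instrument(obj)
  obj
}

validate_meq_instrument <- function(x) {
  if (length(x$items) != 19L) stop("an MEQ instrument must have 19 items, got ",
                                   length(x$items))
  idx <- vapply(x$items, `[[`, integer(1), "index")
  if (!identical(idx, 1:19)) stop("item indices must be exactly 1..19")
  for (it in x$items) {
    if (length(it$scores) == 0L) stop("item ", it$index, " has no options")
    if (any(it$scores < 0 | it$scores > 6))
      stop("item ", it$index, ": option scores must lie in 0..6")
    if (!it$kind %in% c("choice", "time_scale"))
      stop("item ", it$index, ": unknown kind '", it$kind, "'")
    if (it$kind == "time_scale" && any(is.na(it$mids)))
      stop("item ", it$index, ": time_scale options need midpoints")
  }
  lo <- sum(vapply(x$items, function(it) min(it$scores), numeric(1)))
  hi <- sum(vapply(x$items, function(it) max(it$scores), numeric(1)))
  if (lo != 16 || hi != 86)
    stop("instrument scale must span 16..86; this one spans ", lo, "..", hi)
  invisible(x)
}

#' @export
print.meq_instrument <- function(x, ...) {
  cat(x$name, "\n19 items; total score range 16-86\n")
  invisible(x)
}

#' Score one MEQ response vector
#'
#' Computes the total score (sum of the point values of the 19 selected
#' options), the chronotype category, and the preferred wake and bed times
#' (midpoints of the time ranges selected for Questions 1 and 2). Missing or
#' out-of-range responses are refused with an error naming the offending item;
#' no imputation is performed.
#'
#' @param responses Integer vector of length 19: the 1-based option index
#'   chosen for each item.
#' @param instrument An [meq_instrument()] object (default: packaged
#'   Horne-Ostberg 1976 scoring).
#' @param individual_id Optional identifier carried into the result.
#' @return An object of class `meq_record`: list with `individual_id`,
#'   `responses`, `total` (16-86), `category` (see [classify_meq()]),
#'   `preferred_wake` and `preferred_bed` (decimal hours).
#' @examples
#' ins <- meq_instrument()
#' rec <- score_meq(rep(1, 19), ins)  # first option everywhere
#' rec$total
#' @export
score_meq <- function(responses, instrument = meq_instrument(),
                      individual_id = NA_character_) {
  if (length(responses) != 19L)
    stop("exactly 19 responses required, got ", length(responses))
  responses <- as.numeric(responses)
  total <- 0
  for (k in 1:19) {
    r <- responses[k]
    nopt <- length(instrument$items[[k]]$scores)
    if (is.na(r))
      stop("item ", k, ": response missing (omissions must be rectified, not imputed)")
    if (r != as.integer(r) || r < 1 || r > nopt)
      stop("item ", k, ": response ", r, " is not a valid option index (1..",
           nopt, ")")
    total <- total + instrument$items[[k]]$scores[r]
  }
  structure(list(
    individual_id = individual_id,
    responses = as.integer(responses),
    total = as.integer(total),
    category = classify_meq(total),
    preferred_wake = instrument$items[[1L]]$mids[responses[1L]],
    preferred_bed = instrument$items[[2L]]$mids[responses[2L]]
  ), class = "meq_record")
}

#' @export
print.meq_record <- function(x, ...) {
  cat(sprintf("MEQ record%s: total %d (%s), wake %.2f h, bed %.2f h\n",
              if (is.na(x$individual_id)) "" else paste0(" ", x$individual_id),
              x$total, x$category, x$preferred_wake, x$preferred_bed))
  invisible(x)
}

#' Chronotype typology from an MEQ total score
#'
#' Assigns the five-band typology published with the scale: 16-30 definitely
#' evening, 31-41 moderately evening, 42-58 intermediate, 59-69 moderately
#' morning, 70-86 definitely morning. Boundaries are inclusive; the bands
#' partition the full 16-86 range.
#'
#' @param total Integer MEQ total score(s) in 16..86.
#' @return Factor with levels `definitely_evening`, `moderately_evening`,
#'   `intermediate`, `moderately_morning`, `definitely_morning`.
#' @export
classify_meq <- function(total) {
  total <- as.numeric(total)
  if (any(is.na(total)) || any(total < 16) || any(total > 86) ||
      any(total != floor(total)))
    stop("MEQ total must be an integer in 16..86")
  cut(total, breaks = c(15.5, 30.5, 41.5, 58.5, 69.5, 86.5),
      labels = meq_categories())
}

meq_categories <- function() {
  c("definitely_evening", "moderately_evening", "intermediate",
    "moderately_morning", "definitely_morning")
}

#' Preferred wake and bed times of a scored MEQ record
#'
#' Returns the midpoints (decimal hours) of the time ranges selected for
#' Question 1 (preferred rise time) and Question 2 (preferred bedtime).
#' Bedtimes after midnight are kept on the offset scale (01:30 -> 25.5) so
#' that cohort means are meaningful; set `wrap = TRUE` to fold back into
#' [0, 24).
#'
#' @param record An `meq_record` from [score_meq()].
#' @param wrap Fold times into [0, 24)? Default `FALSE`.
#' @return Named numeric vector `c(wake = , bed = )` in decimal hours.
#' @export
preferred_times <- function(record, wrap = FALSE) {
  stopifnot(inherits(record, "meq_record"))
  out <- c(wake = record$preferred_wake, bed = record$preferred_bed)
  if (wrap) out <- out %% 24
  out
}

#' Score a table of MEQ responses
#'
#' Vectorized scoring for a data frame with columns `individual_id` and
#' `q1`..`q19` (1-based option indices), the layout written by
#' [read_meq_responses()].
#'
#' @param responses Data frame with `individual_id` and `q1`..`q19`.
#' @param instrument An [meq_instrument()].
#' @return Data frame with `individual_id`, `meq_total`, `meq_category`,
#'   `preferred_wake`, `preferred_bed`.
#' @export
score_meq_table <- function(responses, instrument = meq_instrument()) {
  qcols <- paste0("q", 1:19)
  missing_cols <- setdiff(c("individual_id", qcols), names(responses))
  if (length(missing_cols) > 0)
    stop("responses table lacks column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(responses)
  recs <- lapply(seq_len(n), function(i) {
    rec <- try(score_meq(as.numeric(responses[i, qcols]), instrument,
                         individual_id = as.character(responses$individual_id[i])),
               silent = TRUE)
    if (inherits(rec, "try-error"))
      stop("individual ", responses$individual_id[i], ": ",
           attr(rec, "condition")$message)
    rec
  })
  data.frame(
    individual_id = vapply(recs, `[[`, character(1), "individual_id"),
    meq_total = vapply(recs, `[[`, integer(1), "total"),
    meq_category = vapply(recs, function(r) as.character(r$category), character(1)),
    preferred_wake = vapply(recs, `[[`, numeric(1), "preferred_wake"),
    preferred_bed = vapply(recs, `[[`, numeric(1), "preferred_bed"),
    stringsAsFactors = FALSE
  )
}

#' Read an MEQ response CSV
#'
#' @param path CSV with columns `individual_id`, `q1`..`q19`.
#' @return Data frame suitable for [score_meq_table()].
#' @export
read_meq_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  qcols <- paste0("q", 1:19)
  missing_cols <- setdiff(c("individual_id", qcols), names(df))
  if (length(missing_cols) > 0)
    stop("response file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Write scored MEQ records to CSV
#'
#' @param scored Data frame from [score_meq_table()].
#' @param path Output CSV path.
#' @export
write_meq_scores <- function(scored, path) {
  utils::write.csv(scored, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
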