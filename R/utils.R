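# Input coercion shared across the package.
#
# Convention: user-facing sample indices are 0-based, so time in seconds is
# sample_index * tr.  Internal R vectors are 1-based; conversion happens only
# in these helpers and at the point where indices enter or leave a tibble.

#' Extract the numeric sample vector from a time-course input
#'
#' Accepts a bare numeric vector or a data frame with a `value` column (the
#' shape returned by [synthesize_bold()] and [stimulus_function()]).
#'
#' @param tc numeric vector or data frame with a `value` column.
#' @param arg name used in error messages.
#' @return numeric vector of samples.
#' @keywords internal
#' @noRd
tc_values <- function(tc, arg = "tc") {
  if (is.data.frame(tc)) {
    if (!"value" %in% names(tc)) {
      abort(sprintf("`%s` must have a `value` column when given as a data frame.", arg))
    }
    v <- tc$value
  } else if (is.numeric(tc)) {
    v <- as.numeric(tc)
  } else {
    abort(sprintf("`%s` must be a numeric vector or a data frame with a `value` column.", arg))
  }
  if (anyNA(v)) abort(sprintf("`%s` contains missing values.", arg))
  v
}

# Pull a TR (seconds) out of a time-course input, falling back to `tr`.
tc_tr <- function(tc, tr = NULL) {
  if (!is.null(tr)) return(check_positive(tr, "tr"))
  if (is.data.frame(tc) && "time_s" %in% names(tc) && nrow(tc) >= 2) {
    return(tc$time_s[2] - tc$time_s[1])
  }
  a <- attr(tc, "tr", exact = TRUE)
  if (!is.null(a)) return(a)
  abort("`tr` must be supplied when the time course does not carry one.")
}

#' Extract 0-based onset indices from an onset input
#'
#' Accepts a bare numeric vector of 0-based sample indices or a data frame
#' with a `sample_index` column (the shape returned by [detect_onsets()] and
#' [simulate_impulse_train()]).
#'
#' @keywords internal
#' @noRd
onset_indices <- function(x, arg = "onsets") {
  if (is.data.frame(x)) {
    if (!"sample_index" %in% names(x)) {
      abort(sprintf("`%s` must have a `sample_index` column when given as a data frame.", arg))
    }
    idx <- x$sample_index
  } else if (is.numeric(x) || length(x) == 0L) {
    idx <- as.numeric(x)
  } else {
    abort(sprintf("`%s` must be a numeric vector or a data frame with a `sample_index` column.", arg))
  }
  idx <- as.numeric(idx)
  if (anyNA(idx)) abort(sprintf("`%s` contains missing indices.", arg))
  if (any(idx < 0)) abort(sprintf("`%s` contains negative sample indices.", arg))
  if (is.unsorted(idx, strictly = TRUE)) {
    idx <- sort(unique(idx))
  }
  idx
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  x
}

check_probability <- function(p, name = "prob") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    abort(sprintf("`%s` must lie strictly inside (0, 1).", name))
  }
  p
}

check_count <- function(n, name, min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < min || n != floor(n)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(n)
}

# Build the standard time-course tibble.
timecourse_tibble <- function(values, tr, clean = NULL) {
  n <- length(values)
  out <- tibble::tibble(
    sample_index = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) * tr,
    value = as.numeric(values)
  )
  if (!is.null(clean)) out$clean <- as.numeric(clean)
  attr(out, "tr") <- tr
  out
}
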