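#' Read a 4-D NIfTI time-series dataset
#'
#' Reads a NIfTI-1/2 file and checks that it is 4-D (x, y, z, time).  The
#' repetition time comes from the header's fourth pixdim entry unless `tr`
#' overrides it; a header TR of 0 counts as missing, and reading fails when
#' no TR can be determined.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param tr optional TR override in seconds.
#' @return list with `data` (4-D numeric array), `tr` (seconds) and
#'   `image` (the `niftiImage` carrying the affine and header).
#' @export
read_nifti_4d <- function(path, tr = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    abort(sprintf("expected a 4-D time-series NIfTI, got %d dimension(s).", length(d)))
  }
  header_tr <- RNifti::pixdim(img)[4L]
  tr <- tr %||% (if (!is.na(header_tr) && header_tr > 0) header_tr else NULL)
  if (is.null(tr)) {
    abort("TR missing from the NIfTI header (pixdim[4] == 0); supply `tr`.")
  }
  list(data = array(as.numeric(img), dim = d), tr = tr, image = img)
}

#' Write an array or connectivity volume as NIfTI
#'
#' @param x numeric/logical array, or an [fc_volume()] (its `values` are
#'   written; `NA` becomes 0 for binary masks only).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param template optional `niftiImage` whose header/affine is reused.
#' @param tr optional TR in seconds stored in pixdim[4] for 4-D data.
#' @return the path, invisibly.
#' @export
write_nifti <- function(x, path, template = NULL, tr = NULL) {
  if (inherits(x, "fc_volume")) x <- x$values
  if (is.logical(x)) x <- array(as.integer(x), dim = dim(x))
  img <- RNifti::asNifti(x, reference = template)
  if (!is.null(tr) && length(dim(x)) == 4L) {
    pd <- RNifti::pixdim(img)
    pd[4L] <- tr
    RNifti::pixdim(img) <- pd
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read onset trains from a tab-separated file
#'
#' Expects a header row and at least an `id` column plus `sample_index`
#' (0-based) or `time_s` (converted with `round(time_s / tr)`).  Rows are
#' sorted per id with a warning if out of order; duplicate or negative
#' indices within an id are rejected; unrecognised columns are kept with a
#' warning.
#'
#' @param path TSV path.
#' @param tr repetition time in seconds, needed when only `time_s` is
#'   present.
#' @return tibble with columns `id`, `sample_index`, `time_s` (and any
#'   extra columns found).
#' @export
read_onsets_tsv <- function(path, tr = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  known <- c("id", "sample_index", "time_s", "detector", "boundary", "component")
  if (!"id" %in% names(df)) {
    if ("component" %in% names(df)) df$id <- as.character(df$component)
    else df$id <- "timecourse"
  }
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warn(sprintf("ignoring unrecognised onset column(s): %s",
                 paste(extra, collapse = ", ")))
  }
  if (!"sample_index" %in% names(df)) {
    if (!"time_s" %in% names(df)) abort("need a `sample_index` or `time_s` column.")
    if (is.null(tr)) abort("`tr` is required to convert `time_s` to sample indices.")
    df$sample_index <- as.integer(round(df$time_s / tr))
  }
  if (any(df$sample_index < 0)) abort("negative sample indices are not allowed.")
  if (!"time_s" %in% names(df)) {
    df$time_s <- if (!is.null(tr)) df$sample_index * tr else NA_real_
  }
  out <- dplyr::group_by(df, .data$id)
  dup <- dplyr::summarise(out, d = anyDuplicated(.data$sample_index) > 0)
  if (any(dup$d)) abort("duplicate sample indices within an onset train.")
  unsorted <- dplyr::summarise(out, u = is.unsorted(.data$sample_index))
  if (any(unsorted$u)) warn("onset rows were out of order; sorting per id.")
  df <- dplyr::arrange(dplyr::ungroup(out), .data$id, .data$sample_index)
  tibble::as_tibble(df)
}

#' Write onset trains to a tab-separated file
#'
#' Emits 0-based `sample_index` plus a `time_s` column for human
#' inspection.  A single detection tibble (from [detect_onsets()]) gains an
#' `id` column of `"timecourse"`.
#'
#' @param trains tibble with `sample_index` and optionally `id`, `time_s`,
#'   `detector`, `boundary`.
#' @param path output TSV path.
#' @param tr repetition time used to fill `time_s` when absent.
#' @return the path, invisibly.
#' @export
write_onsets_tsv <- function(trains, path, tr = NULL) {
  if (!is.data.frame(trains) || !"sample_index" %in% names(trains)) {
    abort("`trains` must be a data frame with a `sample_index` column.")
  }
  df <- tibble::as_tibble(trains)
  if (!"id" %in% names(df)) df$id <- "timecourse"
  if (!"time_s" %in% names(df)) {
    if (is.null(tr)) abort("`tr` is required to emit the time_s column.")
    df$time_s <- df$sample_index * tr
  }
  lead <- intersect(c("id", "sample_index", "time_s", "detector", "boundary"),
                    names(df))
  df <- df[c(lead, setdiff(names(df), lead))]
  df <- dplyr::arrange(df, .data$id, .data$sample_index)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# JSON provenance sidecar written next to every CLI artifact.
write_sidecar <- function(path, config, seed) {
  obj <- list(
    config = config,
    seed = seed,
    package = "zfrfc",
    version = as.character(utils::packageVersion("zfrfc"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
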