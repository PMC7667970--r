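#' Read a bead distance table
#'
#' Reads a TSV of tissue-to-bead z distances with columns `mouse`, `stack`,
#' `d_um`. Rows with a missing or non-numeric distance are rejected with
#' their line numbers in a warning; the remainder is loaded. A header-only
#' file yields an empty table with a warning.
#'
#' @param path TSV path.
#' @return A tibble `mouse`, `stack`, `d_um`. Rejected data rows are
#'   reported via warning and counted in the `n_rejected` attribute.
#' @export
read_bead_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("mouse", "stack", "d_um")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort_data(sprintf("bead table is missing required column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    warning("bead table contains a header but no data rows")
    return(structure(tibble::tibble(mouse = character(0), stack = character(0),
                                    d_um = numeric(0)), n_rejected = 0L))
  }
  d <- suppressWarnings(as.numeric(raw$d_um))
  bad <- which(!is.finite(d))
  if (length(bad)) {
    warning(sprintf(
      "rejected %d malformed row(s) (file line%s %s): d_um is not a finite number",
      length(bad), if (length(bad) > 1) "s" else "",
      paste(bad + 1L, collapse = ", ")  # +1 for the header line
    ))
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  out <- tibble::tibble(mouse = raw$mouse[keep], stack = raw$stack[keep],
                        d_um = d[keep])
  attr(out, "n_rejected") <- length(bad)
  out
}

#' Read a thickness time-series table
#'
#' TSV with columns `mouse`, `location`, `time_min`, `thickness_um`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_thickness_table <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    mouse = readr::col_character(),
    location = readr::col_character(),
    time_min = readr::col_double(),
    thickness_um = readr::col_double()
  ))
  need <- c("mouse", "location", "time_min", "thickness_um")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    abort_data(sprintf("thickness table is missing required column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  out
}

#' Write a tibble as TSV
#'
#' Thin wrapper over [readr::write_tsv()] used by the pipeline so every
#' output goes through one writer (stable column order, no quoting
#' surprises); paired with the `read_*` functions above for lossless
#' round-trips.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
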