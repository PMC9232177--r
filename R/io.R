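# Report writers: plain-text artifacts that round-trip doubles exactly.

#' Write a numeric table as CSV with full double precision
#'
#' Doubles are serialized with 17 significant digits so reading the file
#' back reproduces the in-memory values bit-for-bit.
#'
#' @param x data frame or matrix.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_report_csv <- function(x, path) {
  df <- as.data.frame(x)
  for (k in seq_along(df))
    if (is.double(df[[k]])) df[[k]] <- sprintf("%.17g", df[[k]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a sensitivity solution in long format
#'
#' One row per (time, state, parameter, order): columns \code{time},
#' \code{state}, \code{param}, \code{order}, \code{value}, with order 0
#' rows holding the trajectory itself.
#'
#' @param sol a \code{sensitivity_solution}.
#' @return a data frame.
#' @export
sensitivity_long <- function(sol) {
  tr <- sol$trajectory
  states <- rownames(tr$states)
  d <- dim(sol$first_order)
  base <- data.frame(
    time = rep(tr$times, each = d[1]),
    state = rep(states, times = length(tr$times)),
    param = NA_character_, order = 0L,
    value = as.vector(tr$states))
  first <- data.frame(
    time = rep(tr$times, each = d[1] * d[2]),
    state = rep(states, times = d[2] * d[3]),
    param = rep(rep(sol$param_names, each = d[1]), times = d[3]),
    order = 1L,
    value = as.vector(sol$first_order))
  rbind(base, first)
}

#' Write a JSON run manifest
#'
#' Records the inputs needed to reproduce a run bit-for-bit: arbitrary
#' named fields (model, engine, steps, tolerances, seed) plus the package
#' version and a timestamp.  Requires the jsonlite package.
#'
#' @param path output file.
#' @param ... named manifest fields.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, ...) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_manifest requires the jsonlite package")
  fields <- list(...)
  fields$package <- as.character(utils::packageVersion("diffsens"))
  fields$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
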