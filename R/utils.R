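#' @keywords internal
"_PACKAGE"

# Internal logging: messages are emitted through one channel so the CLI can
# silence or redirect them with --log-level.
.gutnet_env <- new.env(parent = emptyenv())
.gutnet_env$log_level <- "info"

.log_levels <- c(debug = 1L, info = 2L, warning = 3L, quiet = 4L)

#' Set the package log level
#'
#' @param level one of "debug", "info", "warning", "quiet"
#' @return the previous level, invisibly
#' @export
set_log_level <- function(level = c("info", "debug", "warning", "quiet")) {
  level <- match.arg(level)
  old <- .gutnet_env$log_level
  .gutnet_env$log_level <- level
  invisible(old)
}

gn_log <- function(..., level = "info") {
  if (.log_levels[[level]] >= .log_levels[[.gutnet_env$log_level]]) {
    message(sprintf("[gutnet %s] ", level), ...)
  }
  invisible(NULL)
}

#' Write a machine-readable run manifest
#'
#' Records the parameters and seeds of a run as JSON so that any result file
#' can be traced back to the exact invocation that produced it.
#'
#' @param path output path for the JSON manifest
#' @param step name of the pipeline step
#' @param params named list of parameters (seeds included)
#' @param extra optional named list of additional fields (e.g. dropped IDs)
#' @return `path`, invisibly
#' @export
write_manifest <- function(path, step, params, extra = list()) {
  stopifnot(is.character(step), length(step) == 1L)
  manifest <- c(
    list(step = step, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         params = params),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# Align two ID vectors by intersection, preserving the order of the first,
# logging what was dropped. Used everywhere tables meet metadata.
align_ids <- function(ids_a, ids_b, what = "samples") {
  shared <- ids_a[ids_a %in% ids_b]
  dropped_a <- setdiff(ids_a, shared)
  dropped_b <- setdiff(ids_b, shared)
  if (length(dropped_a) || length(dropped_b)) {
    gn_log(sprintf("aligning %s: dropped %d from first set, %d from second (%s)",
                   what, length(dropped_a), length(dropped_b),
                   paste(utils::head(c(dropped_a, dropped_b), 5L), collapse = ", ")))
  }
  if (!length(shared)) stop("no shared ", what, " after ID alignment")
  shared
}
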