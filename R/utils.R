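# Internal helpers: classed error conditions and small validators.

sod_abort <- function(msg, class = "sodscreen_invalid_input", call. = FALSE) {
  cond <- structure(
    class = c(class, "sodscreen_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x))) {
    sod_abort(sprintf("`%s` must be a single finite number, got %s",
                      name, deparse(substitute(x))))
  }
  as.numeric(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    sod_abort(sprintf("`%s` must be TRUE or FALSE", name))
  }
  x
}

# NULL-coalescing
`%||%` <- function(a, b) if (is.null(a)) b else a

BAND_TYPES <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                "IX", "X", "XI")

#' Leveled logging
#'
#' Emits a leveled log line on stderr. The minimum level shown is controlled
#' by `options(sodscreen.verbosity = "debug"|"info"|"warning")` (default
#' `"info"`).
#'
#' @param level one of `"debug"`, `"info"`, `"warning"`.
#' @param msg message text.
#' @return invisibly, `NULL`.
#' @keywords internal
sod_log <- function(level = c("info", "debug", "warning"), msg) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warning = 3L)
  threshold <- getOption("sodscreen.verbosity", "info")
  if (!threshold %in% names(ranks)) threshold <- "info"
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(sprintf("[%s] %s", toupper(level), msg))
  }
  invisible(NULL)
}
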