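#' @keywords internal
"_PACKAGE"

# Structured error helper: every error carries a bbbmap_* condition class so
# callers (and the CLI) can map failure kinds to exit codes.
bbb_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "bbbmap_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

bbb_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) bbb_stop(class, msg, ...)
  invisible(TRUE)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Structured log line: "module | subject | operation | detail".  Level gating
# via options(bbbmap.log_level = "info"|"warn"|"quiet").
bbb_log <- function(module, operation, detail = "", subject = "-",
                    level = "info") {
  lv <- getOption("bbbmap.log_level", "warn")
  rank <- c(quiet = 0L, warn = 1L, info = 2L)
  if (rank[[lv]] >= rank[[level]] || level == "warn") {
    message(sprintf("[bbbmap] %s | %s | %s | %s", module, subject, operation,
                    detail))
  }
  invisible(NULL)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`, the standard agreement score for binary
#' segmentations. Returns `NaN` when both masks are empty.
#'
#' @param a,b Logical/0-1 arrays of identical shape.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  bbb_assert(length(a) == length(b), "bbbmap_data_error",
             "dice_coefficient: masks differ in length")
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Deterministic child seed derived from a base seed; kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 10007 + index * 97) %% 2147483647)
}
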