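# Internal helpers shared across modules.

#' @noRd
ps_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "poolscan_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

ps_validation_error <- function(msg, ...) ps_stop(msg, "poolscan_validation_error", ...)
ps_parse_error      <- function(msg, ...) ps_stop(msg, "poolscan_parse_error", ...)
ps_schema_error     <- function(msg, ...) ps_stop(msg, "poolscan_schema_error", ...)
ps_config_error     <- function(msg, ...) ps_stop(msg, "poolscan_config_error", ...)

#' @noRd
is_count <- function(x, positive = TRUE) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) &&
    (if (positive) x > 0 else x >= 0)
}

#' @noRd
is_prob <- function(x, open = TRUE) {
  length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
}

#' Round half away from zero
#'
#' Deterministic rounding used by the noise-free bioassay simulator: values
#' exactly halfway between integers round up (2.5 -> 3), unlike base
#' [round()]'s round-half-even.
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' @noRd
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    ps_schema_error("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Smallest p value carried into -log10 scores; keeps scores finite for
# astronomically small p.
P_FLOOR <- 1e-300
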