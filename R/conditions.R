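# Classed conditions so callers (and the CLI) can map failures to exit codes:
# usage errors -> 1, data validation errors -> 2, numerical failures -> 3.

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("od_usage_error", "od_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("od_data_error", "od_error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("od_numeric_error", "od_error")))
}

exit_code_for <- function(cond) {
  if (inherits(cond, "od_usage_error")) return(1L)
  if (inherits(cond, "od_data_error")) return(2L)
  if (inherits(cond, "od_numeric_error")) return(3L)
  3L
}
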