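# Shared helpers. Input/validation problems raise conditions of class
# "eggclock_input_error" so front ends can distinguish bad input (exit 2)
# from internal invariant violations (exit 3).

stop_input <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("eggclock_input_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixture shipped with the package.
eggclock_fixture <- function(file) {
  system.file("extdata", file, package = "eggclock", mustWork = TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
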