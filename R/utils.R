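# shared internal helpers

# stop() with a consistent prefix for user configuration mistakes
config_error <- function(...) {
  stop("configuration error: ", ..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# format numbers for text output without precision loss on round-trip
fmt_num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
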