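# internal helpers shared across modules

abort_stabindr <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "stabindr_error"), ...)
}

# round-half-up, matching how the printed tables round (base round() is
# round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# evaluate `code` under a fixed RNG seed without touching global RNG state;
# seed = NULL means "use whatever stream is active"
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  withr::with_seed(as.integer(seed), force(code))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
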