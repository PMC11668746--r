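# shared input checks; all user-facing errors go through rlang::abort with a
# class so callers (and tests) can catch them specifically

stop_input <- function(msg, class = "founderage_input_error") {
  abort(msg, class = class)
}

check_count <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || any(is.na(x)) || any(x != floor(x)) ||
      any(x < if (allow_zero) 0 else 1)) {
    stop_input(sprintf(
      "`%s` must be %s integer(s).", name,
      if (allow_zero) "non-negative" else "positive"
    ))
  }
  as.integer(x)
}

check_proportion <- function(x, name, open = FALSE) {
  lo_ok <- if (open) x > 0 else x >= 0
  hi_ok <- if (open) x < 1 else x <= 1
  if (!is.numeric(x) || any(is.na(x)) || !all(lo_ok & hi_ok)) {
    stop_input(sprintf("`%s` must lie in %s.", name,
                       if (open) "(0, 1)" else "[0, 1]"))
  }
  as.numeric(x)
}

check_dna <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop_input(sprintf("`%s` must be a single non-empty string.", name))
  }
  x <- toupper(x)
  if (grepl("[^ACGT]", x)) {
    stop_input(sprintf("`%s` must contain only A/C/G/T.", name))
  }
  x
}

# round-half-up at `digits` decimals; base round() ties to even, which is the
# wrong convention for reporting Mb lengths the way gels and papers print them
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
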