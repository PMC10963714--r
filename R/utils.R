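# internal helpers shared across modules

abort_if <- function(cond, msg, class = "ventrl_error") {
  if (isTRUE(cond)) rlang::abort(msg, class = class)
  invisible(NULL)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  abort_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
           sprintf("`%s` must be a single finite number.", name))
  lo_bad <- if (strict_lower) x <= lower else x < lower
  hi_bad <- if (strict_upper) x >= upper else x > upper
  abort_if(lo_bad || hi_bad,
           sprintf("`%s` = %g is outside its valid range.", name, x))
  invisible(x)
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stable per-unit seed derived from a global seed; kept below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
    h <- (h * 69069 + v + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
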