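#' @keywords internal
"_PACKAGE"

# Shared argument checks. Kept minimal: callers give context via `what`.

stop_metasem <- function(msg, class) {
  stop(structure(
    class = c(class, "metasem_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_metasem(sprintf("`%s` must be TRUE or FALSE", what), "metasem_arg_error")
  }
  x
}

check_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_metasem(sprintf("`%s` must be a whole number >= %d", what, min),
                 "metasem_arg_error")
  }
  as.integer(x)
}

check_number <- function(x, what, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min) &&
    (if (strict_max) x < max else x <= max)
  if (!ok) {
    stop_metasem(sprintf("`%s` must be a finite number in %s%s, %s%s",
                         what, if (strict_min) "(" else "[", format(min),
                         format(max), if (strict_max) ")" else "]"),
                 "metasem_arg_error")
  }
  as.numeric(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Population standard deviation (divide by n), per gene over rows of a matrix.
row_sd_pop <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowMeans((m - mu)^2))
}
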