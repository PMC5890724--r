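# Exact non-negative integer arithmetic on base-1e7 chunks (little-endian).
# Pattern counts grow past 2^53 for large (n, k); doubles silently lose
# exactness there, so counting runs on these instead.

EXACT_BASE <- 1e7

exactint <- function(x) {
  if (inherits(x, "exactint")) return(x)
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  chunks <- numeric(0)
  repeat {
    chunks <- c(chunks, x %% EXACT_BASE)
    x <- floor(x / EXACT_BASE)
    if (x == 0) break
  }
  structure(list(chunks = chunks), class = "exactint")
}

exact_add <- function(a, b) {
  ca <- a$chunks; cb <- b$chunks
  n <- max(length(ca), length(cb))
  ca <- c(ca, numeric(n - length(ca)))
  cb <- c(cb, numeric(n - length(cb)))
  s <- ca + cb
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- if (s[i] >= EXACT_BASE) 1 else 0
    s[i] <- s[i] - carry * EXACT_BASE
  }
  if (carry > 0) s <- c(s, carry)
  structure(list(chunks = s), class = "exactint")
}

# multiplier m must satisfy m * (BASE-1) + carry < 2^53; m <= ~9e8 is safe
exact_mul_small <- function(a, m) {
  stopifnot(m >= 0, m == floor(m), m < 9e8)
  if (m == 0) return(exactint(0))
  s <- a$chunks * m
  carry <- 0
  out <- numeric(length(s))
  for (i in seq_along(s)) {
    v <- s[i] + carry
    carry <- floor(v / EXACT_BASE)
    out[i] <- v - carry * EXACT_BASE
  }
  while (carry > 0) {
    out <- c(out, carry %% EXACT_BASE)
    carry <- floor(carry / EXACT_BASE)
  }
  while (length(out) > 1L && out[length(out)] == 0) out <- out[-length(out)]
  structure(list(chunks = out), class = "exactint")
}

# exact division by small d; errors if a remainder is left
exact_div_small <- function(a, d) {
  stopifnot(d >= 1, d == floor(d), d < 9e8)
  ch <- a$chunks
  out <- numeric(length(ch))
  rem <- 0
  for (i in rev(seq_along(ch))) {
    v <- rem * EXACT_BASE + ch[i]
    out[i] <- floor(v / d)
    rem <- v - out[i] * d
  }
  if (rem != 0) stop("exact_div_small: division is not exact")
  while (length(out) > 1L && out[length(out)] == 0) out <- out[-length(out)]
  structure(list(chunks = out), class = "exactint")
}

#' @export
as.character.exactint <- function(x, ...) {
  ch <- rev(x$chunks)
  paste0(formatC(ch[1], format = "d"),
         paste(formatC(ch[-1], width = 7, flag = "0", format = "d"),
               collapse = ""))
}

#' @export
as.double.exactint <- function(x, ...) {
  sum(x$chunks * EXACT_BASE^(seq_along(x$chunks) - 1))
}

#' @export
print.exactint <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}

exact_eq <- function(a, b) identical(a$chunks, b$chunks)
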