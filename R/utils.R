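# Internal helpers shared across modules.

# Round-half-up. Used for every integer target derived from a fraction
# (erosion target volume, responder counts, arm sizes) so that the same
# documented rule applies everywhere; R's round() is round-half-even.
round_half_up <- function(x) floor(x + 0.5)

# Deterministic seed mixing (Lehmer-style), keeps results reproducible from a
# single master seed while allowing any (level, iteration) cell to be re-run
# in isolation. All intermediate values stay below 2^53 so the arithmetic is
# exact in doubles; the result is a valid 32-bit seed.
mix_seed <- function(master, i = 0L, j = 0L) {
  m <- 2147483647
  s <- (abs(master) %% m)
  s <- (s * 48271) %% m
  s <- (s + i) %% m
  s <- (s * 48271) %% m
  s <- (s + j) %% m
  s <- (s * 48271) %% m
  as.integer(s)
}

# Wrap angles (degrees) into (-180, 180].
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_therinf <- function(...) stop(..., call. = FALSE)
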