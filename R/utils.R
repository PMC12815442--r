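# Internal utilities: seed substreams, stable hashing, largest-remainder
# apportionment, truncated-normal draws.

# 32-bit FNV-1a over the bytes of a string; returns a double in [0, 2^32).
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor for doubles holding 32-bit values (bitwXor needs integers < 2^31)
bitwXor_dbl <- function(a, b) {
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 65536 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

#' Derive a named substream seed from a master seed
#'
#' Stages of the simulation (demographics, components, noise, outcomes, ...)
#' each draw from their own seed derived deterministically from the master
#' seed and the stage name, so adding or reordering stages never perturbs
#' the draws of other stages.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(master, stage) {
  as.integer(fnv1a32(paste0(master, ":", stage)) %% 2147483645 + 1)
}

# Largest-remainder apportionment of n into counts proportional to props.
largest_remainder <- function(n, props) {
  stopifnot(abs(sum(props) - 1) < 1e-9)
  quota <- n * props
  k <- floor(quota)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(quota - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1
  }
  as.integer(k)
}

# Inverse-CDF draws from normal(mean, sd) truncated to [lo, hi].
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}
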