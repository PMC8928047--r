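# Internal helpers shared across modules.

# Deterministic sub-seed derivation: a counter-based linear congruential mix so
# replicate b of a run seeded with s is reproducible on its own (and replicates
# can run in any order). Result is always a valid 32-bit R seed.
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(k) * 30269 + 17) %% 2147483647)
}

# Truncated normal draws via inverse-CDF; bounds may be -Inf/Inf.
rtruncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  # guard against u == 0/1 at extreme truncation
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  qnorm(u, mean, sd)
}

# Mean of a normal(mean, sd) truncated to [lower, upper]; used by tests to
# turn configured (mu, sigma) into the actual target mean of a truncated draw.
etruncnorm <- function(mean, sd, lower = 0, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

require_fields <- function(df, fields, where) {
  missing_col <- setdiff(fields, names(df))
  if (length(missing_col) > 0) {
    stop(sprintf("%s: missing required field(s): %s", where,
                 paste(missing_col, collapse = ", ")), call. = FALSE)
  }
  for (f in fields) {
    if (anyNA(df[[f]])) {
      stop(sprintf("%s: missing values in required field '%s'", where, f),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Cheap FNV-1a content hash for run manifests (no external digest dependency).
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
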