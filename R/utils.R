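# Internal helpers shared across modules.

# Derive a reproducible child seed from a base seed and a stream label.
# Keeps results stable when unrelated streams (e.g. other authors) change,
# and stays below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate an expression with a temporary RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# path to a bundled data file
cm_extdata <- function(file) {
  path <- system.file("extdata", file, package = "cravingminer")
  if (!nzchar(path)) {
    abort(paste0("bundled data file not found: ", file))
  }
  path
}

# round half away from zero, matching how percentages are usually printed
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
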