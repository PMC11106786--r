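# Internal helpers: seeded RNG streams and small validators.

# Derive a per-stage seed from a single run seed so that stages consume
# independent RNG streams. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 65011 + 1) * 32749 + (h %% 32719)) %% 2147483629L
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483629), code)
}

abort_config <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = "audiodx_config_error", field = field)
}

assert_scalar_num <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_config(field, "must be a single finite number")
  }
  if (x < min || x > max) {
    abort_config(field, sprintf("must be in [%s, %s]", min, max))
  }
  invisible(x)
}

EAR_LEVELS <- c("left", "right")
CONDUCTION_LEVELS <- c("air", "bone")
LABEL_LEVELS <- c("normal", "tinnitus")
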