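# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream.  All stochastic operations in the package funnel through this so
# that (config, seed) -> output is a pure function.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a root seed and a counter, kept below 2^31.
derive_seed <- function(root, counter) {
  (as.numeric(root) * 1000003 + as.numeric(counter) * 7919) %% 2147483647
}

# Full-precision, locale-independent number formatting for deterministic
# text output ("%.17g" round-trips doubles exactly).
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

log_msg <- function(stage, event, ...) {
  extra <- c(...)
  line <- paste0("[", stage, "] ", event,
                 if (length(extra)) paste0(" ", paste(names(extra), extra,
                                                      sep = "=", collapse = " ")) else "")
  message(line)
  invisible(line)
}
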