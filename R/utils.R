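# Internal helpers: classed error conditions and deterministic seed derivation.

lgStop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "lyticgray_error"), call = call))
}

#' Derive a reproducible child seed from a master seed
#'
#' Hashes a master seed together with any number of string/integer labels
#' into a stable seed in `[1, 2^31 - 2]`. Used throughout the synthetic
#' module so that every generated case is a pure function of
#' `(master seed, group label, case index)` and independent streams never
#' collide by accident.
#'
#' @param seed Integer master seed.
#' @param ... Labels (characters or integers) identifying the stream.
#' @return A single integer seed.
#' @examples
#' deriveSeed(1, "MM2", 7)
#' @export
deriveSeed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  M <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% M
  for (part in list(...)) {
    codes <- utf8ToInt(paste0("|", as.character(part)))
    for (cc in codes) h <- (h * 31 + cc) %% M
  }
  as.integer(h %% (M - 1) + 1)
}

# Evaluate `expr` with a locally-set RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stable small hash of an arbitrary R object (used to fingerprint configs in
# run logs; not cryptographic).
lgHash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  sprintf("%08x", deriveSeed(0, txt))
}
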