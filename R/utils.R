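#' @importFrom stats dpois pchisq pnorm pt pf qnorm sd var optim glm poisson
#'   coef vcov logLik density bw.nrd0 ccf lm anova rnorm rlnorm runif rbinom
#'   dbeta setNames complete.cases
#' @importFrom utils head tail
#' @importFrom dplyr .data
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# 32-bit FNV-1a over a character scalar; used to fingerprint run configs in
# output logs without pulling in a hashing dependency.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    hb <- h %% 256
    h <- h - hb + bitwXor(hb, b)  # xor touches only the low byte (b < 256)
    # h * p mod 2^32, split so intermediates stay exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_callrhythm <- function(msg, class) {
  stop(structure(
    class = c(class, "callrhythm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
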