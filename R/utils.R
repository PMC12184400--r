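#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq plogis pnorm qlogis rbinom rgamma rnorm runif sd
#'   uniroot var predict coef glm binomial quantile setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

# Derive a reproducible child seed from a master seed and a character tag.
# Keeps results below 2^31 so they are valid R integer seeds.
child_seed <- function(master, tag) {
  codes <- utf8ToInt(as.character(tag))
  h <- as.numeric(master) %% 2147483647
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

# FNV-1a hash over the serialization of an R object, reported as hex.
# Used only to stamp pipeline artifacts; not cryptographic.
fnv1a_hash <- function(object) {
  bytes <- as.integer(serialize(object, NULL, version = 2))
  # drop the serialization header (R version stamp) so equal values hash equal
  bytes <- bytes[-seq_len(14)]
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_epiprs <- function(fmt, ..., class = "epiprs_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Population variance (divides by n): the simulator's variance bookkeeping is
# exact under this convention.
pop_var <- function(x) mean((x - mean(x))^2)
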