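#' @useDynLib hierseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rgamma rbeta dbeta dgamma dnorm
#'   optim t.test plogis qlogis complete.cases
#' @importFrom utils read.csv write.csv modifyList
NULL

# numerically safe softmax over a vector of logits
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

logit <- function(p) log(p) - log1p(-p)

# derive a 32-bit sub-seed from a master seed and a stream index
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
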