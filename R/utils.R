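#' @useDynLib mnf3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rgamma rnorm qgamma pgamma runif median var sd fft setNames predict
#' @importFrom utils write.csv read.csv modifyList
NULL

# Whole-sample symmetric (mirror) index: 1,2,...,n,n-1,...,2,1,2,... period 2n-2.
# Accepts any integer vector, returns indices in 1..n.
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- (i - 1L) %% (2L * n - 2L)
  over <- m >= n
  m[over] <- 2L * n - 2L - m[over]
  m + 1L
}

stop_mnf <- function(class, msg, ...) {
  stop(structure(class = c(class, "mnf_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_mnf("mnf_parameter_error", "'%s' must be a positive finite scalar", name)
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing global RNG state.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_mnf("mnf_parameter_error", "'seed' must be a single integer")
  withr::with_seed(as.integer(seed), expr)
}

# Derive k reproducible child seeds from one master seed.
derive_seeds <- function(seed, k) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
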