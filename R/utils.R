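#' @keywords internal
"_PACKAGE"

#' @useDynLib landgf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn .data
#' @importFrom stats cor dist prcomp qchisq pchisq p.adjust rnorm runif rbinom
#'   quantile sd var median setNames approx lm.fit kmeans
#' @importFrom tibble tibble as_tibble
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# upper-triangle vector of a square matrix (row < col order)
upper_tri_vec <- function(m) m[upper.tri(m)]

# all permutations of 1..n (n small); used by the exact Mantel null
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

# derive a stream sub-seed from a master seed; keeps values < 2^31
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12343L) %% 2147483629L
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1]", name))
  }
}
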