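#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm kmeans median pchisq pnorm quantile rbinom rlnorm
#'   rnbinom rnorm rpois runif sd var setNames rbeta cor hclust cutree as.dist
#'   optim dnbinom complete.cases
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

# internal argument checks ---------------------------------------------------

.assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

.assert_prob <- function(x, name) {
  .assert(is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1),
          sprintf("`%s` must be a proportion in [0, 1]", name))
}

.assert_count <- function(x, name, min = 0L) {
  .assert(is.numeric(x) && length(x) == 1L && is.finite(x) &&
            x >= min && x == floor(x),
          sprintf("`%s` must be a single integer >= %d", name, min))
}

# 1-D two-component Gaussian mixture ----------------------------------------

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Shared engine for the library-complexity split and the pollen-area
#' bimodality fit. Components are returned in increasing order of mean
#' (component 1 = smaller mean), so the fit is invariant to initialization
#' order.
#'
#' @param x numeric vector of observations (length >= 4).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return list with `means`, `sds`, `weights` (component order: small mean
#'   first), `loglik` (final), `loglik_trace`, `responsibilities` (matrix,
#'   column 1 = small component), `converged`, `n_iter`.
#' @keywords internal
gmm2_em <- function(x, max_iter = 500L, tol = 1e-8) {
  .assert(is.numeric(x) && length(x) >= 4L && all(is.finite(x)),
          "`x` must be numeric, finite, length >= 4")
  n <- length(x)
  # deterministic initialization: split at the median
  lo <- x <= median(x)
  if (all(lo) || !any(lo)) lo <- seq_len(n) <= n / 2
  mu <- c(mean(x[lo]), mean(x[!lo]))
  sg <- c(sd(x[lo]), sd(x[!lo]))
  floor_sd <- max(sd(x) * 1e-3, .Machine$double.eps)
  sg[!is.finite(sg) | sg < floor_sd] <- max(sd(x) / 4, floor_sd)
  w <- c(mean(lo), 1 - mean(lo))
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  resp <- matrix(0.5, n, 2L)
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sg[1])
    d2 <- w[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    resp <- cbind(d1 / tot, d2 / tot)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    sg[sg < floor_sd] <- floor_sd
    w <- nk / n
  }
  ord <- order(mu)
  list(means = mu[ord], sds = sg[ord], weights = w[ord],
       loglik = trace[length(trace)], loglik_trace = trace,
       responsibilities = resp[, ord, drop = FALSE],
       converged = converged, n_iter = iter)
}

# log-likelihood of a single-Gaussian fit, for BIC comparison
.loglik_1gauss <- function(x) {
  mu <- mean(x)
  sg <- sqrt(mean((x - mu)^2))
  sum(dnorm(x, mu, sg, log = TRUE))
}
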