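#' Reverse rank of centrality scores
#'
#' The largest value receives rank N and the smallest rank 1; ties get
#' midranks. This is the x-axis of the random-vs-scale-free regression.
#'
#' @param y numeric vector, length >= 3.
#' @return numeric ranks.
#' @export
reverse_rank <- function(y) {
  stopifnot(length(y) >= 3L)
  rank(y)
}

#' Ordinary least-squares linear fit, y = alpha + beta * x
#'
#' @param y,x numeric vectors; `x` must not be constant.
#' @param k parameter count charged in the AIC (default 2).
#' @return A `regression_fit` list: `model`, `alpha`, `beta`, `rss`
#'   (original scale), `r2`, `aic`, `n`, `k`.
#' @export
fit_linear <- function(y, x, k = 2L) {
  if (length(unique(x)) < 2L) stop("x is constant; cannot fit a line")
  if (length(y) < 3L) stop("need at least 3 observations")
  f <- lm(y ~ x)
  rss <- sum(resid(f)^2)
  tss <- sum((y - mean(y))^2)
  .fit("linear", alpha = unname(coef(f)[1L]), beta = unname(coef(f)[2L]),
       rss = rss, r2 = 1 - rss / tss, n = length(y), k = k)
}

#' Power-law fit, y = alpha * x^beta
#'
#' Fitted as ln y = ln alpha + beta ln x by ordinary least squares (the
#' standard curve-fit convention), then back-transformed; the residual sum
#' of squares is computed on the original y scale so linear and power fits
#' are AIC-comparable on one scale. `rss_scale = "log"` scores the fit by
#' its log-scale residuals instead.
#'
#' @param y,x strictly positive numeric vectors.
#' @param k parameter count charged in the AIC (default 2).
#' @param rss_scale `"original"` (default) or `"log"`.
#' @return A `regression_fit` (see [fit_linear()]).
#' @export
fit_power <- function(y, x, k = 2L, rss_scale = c("original", "log")) {
  rss_scale <- match.arg(rss_scale)
  if (any(y <= 0) || any(x <= 0)) {
    stop("power fit needs strictly positive y and x")
  }
  if (length(y) < 3L) stop("need at least 3 observations")
  f <- lm(log(y) ~ log(x))
  alpha <- exp(unname(coef(f)[1L]))
  beta <- unname(coef(f)[2L])
  fitted_y <- alpha * x^beta
  rss <- switch(rss_scale,
                original = sum((y - fitted_y)^2),
                log = sum(resid(f)^2))
  tss <- sum((y - mean(y))^2)
  .fit("power", alpha = alpha, beta = beta, rss = rss,
       r2 = 1 - sum((y - fitted_y)^2) / tss, n = length(y), k = k)
}

.fit <- function(model, alpha, beta, rss, r2, n, k) {
  structure(list(model = model, alpha = alpha, beta = beta, rss = rss,
                 r2 = r2, aic = aic_rss(n, rss, k), n = n, k = k),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("%s fit: alpha = %.4g, beta = %.4g, RSS = %.4g, R2 = %.3f, AIC = %.3f (n = %d, k = %d)\n",
              x$model, x$alpha, x$beta, x$rss, x$r2, x$aic, x$n, x$k))
  invisible(x)
}

#' AIC from a residual sum of squares
#'
#' AIC = n * ln(RSS / n) + 2k. A perfect fit (RSS = 0) gives -Inf.
#'
#' @param n number of observations (>= 1).
#' @param rss residual sum of squares (>= 0).
#' @param k number of fitted parameters.
#' @return numeric AIC (possibly -Inf).
#' @export
aic_rss <- function(n, rss, k = 2L) {
  stopifnot(n >= 1L, rss >= 0)
  if (rss == 0) {
    message("RSS = 0: AIC is -Inf (perfect fit)")
    return(-Inf)
  }
  n * log(rss / n) + 2 * k
}

#' Random-vs-scale-free network assessment
#'
#' Regresses eigenvector centrality on its reverse rank with both a linear
#' and a power model and compares them by RSS-based AIC. A stronger linear
#' fit (lower AIC) means no individual is disproportionately central: the
#' network is classified `random`. A stronger power fit indicates
#' hyper-central hub individuals: `scale_free`.
#'
#' @param centralities numeric vector of eigenvector centralities (> 0).
#' @param k AIC parameter count for both models (default 2, so the
#'   comparison reduces to RSS).
#' @param rss_scale passed to [fit_power()].
#' @return list: `verdict` (`"random"`/`"scale_free"`), `linear`, `power`
#'   fits, `x` (the reverse ranks).
#' @export
scale_free_assessment <- function(centralities, k = 2L,
                                  rss_scale = "original") {
  x <- reverse_rank(centralities)
  lin <- fit_linear(centralities, x, k = k)
  pow <- fit_power(centralities, x, k = k, rss_scale = rss_scale)
  verdict <- if (lin$aic < pow$aic) "random" else "scale_free"
  structure(list(verdict = verdict, linear = lin, power = pow, x = x),
            class = "scale_free_assessment")
}

#' @export
print.scale_free_assessment <- function(x, ...) {
  cat("Network classification:", x$verdict, "\n")
  print(x$linear)
  print(x$power)
  invisible(x)
}
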