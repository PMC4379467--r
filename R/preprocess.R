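#' Estimate normal-plus-exponential background parameters
#'
#' Fits, by the method of moments, the convolution model behind
#' single-channel microarray background correction: observed intensity
#' X = B + S with Gaussian background B ~ N(mu, sigma^2) and exponential
#' signal S with mean alpha. The exponential is the only skewed
#' component, so alpha is matched from the third central moment
#' (m3 = 2 alpha^3), then mu = mean(x) - alpha and
#' sigma^2 = max(var(x) - alpha^2, eps).
#'
#' When the moments are infeasible (non-positive third moment, or a
#' variance the exponential alone already exceeds) a robust fallback is
#' used with a warning: mu = min(x), sigma = sd(x)/10,
#' alpha = mean(x) - mu.
#'
#' @param column numeric vector of non-negative intensities (one array).
#' @return A list of class \code{normexp_params} with elements
#'   \code{mu}, \code{sigma}, \code{alpha}.
#' @export
estimate_normexp_params <- function(column) {
  x <- column[is.finite(column)]
  if (length(x) < 10L)
    stop("need at least 10 finite intensities to estimate background parameters",
         call. = FALSE)
  if (any(x < 0))
    stop("intensities must be non-negative", call. = FALSE)
  v <- stats::var(x)
  if (v == 0)
    stop("constant intensity column: background model is unidentifiable",
         call. = FALSE)
  m <- mean(x)
  m3 <- mean((x - m)^3)
  eps <- 1e-8
  if (m3 <= 0) {
    warning("non-positive third central moment; using fallback parameter estimates")
    mu <- min(x)
    sigma <- max(stats::sd(x) / 10, eps)
    alpha <- max(m - mu, eps)
  } else {
    alpha <- (m3 / 2)^(1 / 3)
    mu <- m - alpha
    sigma <- sqrt(max(v - alpha^2, eps))
  }
  structure(list(mu = mu, sigma = sigma, alpha = alpha),
            class = "normexp_params")
}

#' Normal-plus-exponential background correction
#'
#' Replaces each observed intensity by the posterior mean of the signal
#' given the fitted background model, plus a small offset that keeps all
#' corrected values strictly positive and damps low-intensity variance:
#' \deqn{E[S \mid X = x] = \mu_{sf} + \sigma
#'   \frac{\phi(\mu_{sf}/\sigma)}{\Phi(\mu_{sf}/\sigma)}, \qquad
#'   \mu_{sf} = x - \mu - \sigma^2/\alpha.}
#' The Mills-ratio term is evaluated on the log scale
#' (\code{exp(dnorm(log) - pnorm(log))}) so extreme arguments never
#' produce NaN.
#'
#' @param column numeric intensity vector.
#' @param params a \code{normexp_params} object
#'   (see \code{\link{estimate_normexp_params}}).
#' @param offset constant added after correction (default 50).
#' @return Corrected intensity vector, all values > 0.
#' @export
normexp_correct <- function(column, params, offset = 50) {
  stopifnot(inherits(params, "normexp_params"))
  if (!is.finite(params$sigma) || params$sigma <= 0 ||
      !is.finite(params$alpha) || params$alpha <= 0)
    stop("invalid background parameters: sigma and alpha must be positive",
         call. = FALSE)
  mu_sf <- column - params$mu - params$sigma^2 / params$alpha
  z <- mu_sf / params$sigma
  # log-scale Mills ratio: stable for z << 0 where dnorm/pnorm underflows
  mills <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  out <- mu_sf + params$sigma * mills + offset
  pmax(out, .Machine$double.xmin)
}

#' Quantile normalization
#'
#' Forces every column (array) to share one empirical distribution: the
#' reference is the row-wise mean of all columns' sorted values, and each
#' column's values are replaced by the reference value at their
#' within-column rank. Ties receive the mean of the tied reference
#' values (average-rank convention), which makes the operation
#' deterministic and idempotent.
#'
#' @param m numeric matrix (genes/probes x samples), no missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m) || any(!is.finite(m)))
    stop("quantile normalization requires a complete finite matrix", call. = FALSE)
  if (ncol(m) < 2L) {
    warning("single-column matrix: quantile normalization returns it unchanged")
    return(m)
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(x) {
    r <- rank(x, ties.method = "average")
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Elementwise log2 transform
#'
#' @param m numeric matrix with strictly positive entries.
#' @return log2-transformed matrix.
#' @export
log2_transform <- function(m) {
  m <- as.matrix(m)
  bad <- which(!(m > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    g <- if (!is.null(rownames(m))) rownames(m)[bad[1, 1]] else bad[1, 1]
    s <- if (!is.null(colnames(m))) colnames(m)[bad[1, 2]] else bad[1, 2]
    stop("non-positive value at gene '", g, "', sample '", s,
         "': cannot log2-transform", call. = FALSE)
  }
  log2(m)
}

#' Preprocess a raw cohort matrix
#'
#' Two protocols used for single-channel liver microarray cohorts:
#' \describe{
#'   \item{three_step}{per-column normal-plus-exponential background
#'     correction with offset 50, then quantile normalization between
#'     arrays, then log2 transformation (Agilent-style raw intensities).}
#'   \item{quantile_only}{quantile normalization only
#'     (BeadStudio-style summarized data); log2 is applied afterwards
#'     when the input looks unlogged (max value > 100).}
#' }
#'
#' @param raw gene/probe x sample matrix of non-negative intensities.
#' @param protocol \code{"three_step"} or \code{"quantile_only"}.
#' @param offset offset for the background-correction step.
#' @return Normalized log2 expression matrix.
#' @export
preprocess_cohort <- function(raw, protocol = c("three_step", "quantile_only"),
                              offset = 50) {
  protocol <- match.arg(protocol)
  raw <- as.matrix(raw)
  if (protocol == "three_step") {
    corrected <- apply(raw, 2, function(x) {
      normexp_correct(x, estimate_normexp_params(x), offset = offset)
    })
    dimnames(corrected) <- dimnames(raw)
    log2_transform(quantile_normalize(corrected))
  } else {
    out <- quantile_normalize(raw)
    if (max(out) > 100) out <- log2_transform(out)
    out
  }
}
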