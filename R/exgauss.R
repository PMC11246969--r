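#' Ex-Gaussian density and log-likelihood
#'
#' The ex-Gaussian distribution — a Gaussian with mean `mu` and SD `sigma`
#' convolved with an exponential with mean `tau` — models reaction-time
#' distributions with a slow right tail. Its mean is `mu + tau` and its
#' variance `sigma^2 + tau^2`. The log density is evaluated in the stable
#' form
#' `-log(tau) + sigma^2/(2 tau^2) - (x - mu)/tau + log Phi((x - mu)/sigma - sigma/tau)`
#' with the Gaussian CDF computed on the log scale, so large `mu/tau` ratios
#' do not overflow.
#'
#' @param x Quantiles (ms).
#' @param mu,sigma,tau Parameters in ms; `sigma > 0`, `tau > 0`.
#' @param log If `TRUE` return log densities.
#' @return Densities (or log densities) at `x`.
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  if (sigma <= 0 || tau <= 0) stop("sigma and tau must be positive")
  a <- (x - mu) / sigma
  s <- sigma / tau
  w <- a - s
  lp <- numeric(length(x))
  # direct form; its two large terms cancel catastrophically once w is very
  # negative (huge sigma/tau), so switch to the Mills-ratio expansion there,
  # where the cancellation is done analytically: s^2/2 - a*s - w^2/2 = -a^2/2
  direct <- w > -30
  lp[direct] <- -base::log(tau) + s^2 / 2 - a[direct] * s +
    stats::pnorm(w[direct], log.p = TRUE)
  if (!all(direct)) {
    wn <- w[!direct]
    lp[!direct] <- -base::log(tau) - a[!direct]^2 / 2 - base::log(-wn) -
      0.5 * base::log(2 * pi) + log1p(-1 / wn^2 + 3 / wn^4 - 15 / wn^6)
  }
  if (log) lp else exp(lp)
}

#' @rdname dexgauss
#' @param params Named list/vector with `mu`, `sigma`, `tau`.
#' @param rts Non-empty numeric vector of reaction times (ms).
#' @return `exgauss_loglik`: the summed log density; non-finite values signal
#'   parameter overflow.
#' @export
exgauss_loglik <- function(params, rts) {
  if (!length(rts)) stop("rts must be non-empty")
  sum(dexgauss(rts, params[["mu"]], params[["sigma"]], params[["tau"]],
               log = TRUE))
}

# moments initializer: tau0 from the third central moment (skewness),
# mu0 = mean - tau0, sigma0^2 = max(var - tau0^2, eps)
exgauss_moments_init <- function(rts) {
  m <- mean(rts); v <- stats::var(rts)
  m3 <- mean((rts - m)^3)
  tau0 <- max(if (m3 > 0) (m3 / 2)^(1 / 3) else sqrt(v) / 10, 1e-3)
  sigma0 <- sqrt(max(v - tau0^2, 0.01 * v))
  c(mu = m - tau0, sigma = sigma0, tau = tau0)
}

#' Fit the ex-Gaussian reaction-time model by maximum likelihood
#'
#' Parameters are estimated by MLE over `(mu, log sigma, log tau)` with
#' BFGS, initialized by moments (`tau0` from the skewness, `mu0 = mean -
#' tau0`, `sigma0^2 = max(var - tau0^2, eps)`). Missing values (omissions)
#' are dropped before fitting. If the optimizer fails to improve on the
#' initializer, the moments estimate is returned with `converged = FALSE`.
#'
#' @param rts Reaction times in ms; `NA`s (omissions) are removed. At least
#'   10 non-missing values are required; non-positive skewness triggers a
#'   warning (the exponential component is then barely identified).
#' @return An `exgauss_fit`: list with `mu`, `sigma`, `tau`, `loglik`,
#'   `n_used` and `converged`.
#' @export
fit_exgaussian <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < 10L) stop("need at least 10 non-omitted reaction times")
  if (mean((rts - mean(rts))^3) <= 0)
    warning("non-positive skewness: ex-Gaussian tail barely identified")
  init <- exgauss_moments_init(rts)
  nll <- function(par) {
    ll <- tryCatch(
      exgauss_loglik(list(mu = par[1L], sigma = exp(par[2L]),
                          tau = exp(par[3L])), rts),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e12 else -ll
  }
  start <- c(init[["mu"]], base::log(init[["sigma"]]), base::log(init[["tau"]]))
  opt <- tryCatch(stats::optim(start, nll, method = "BFGS",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
  init_ll <- exgauss_loglik(as.list(init), rts)
  if (is.null(opt) || -opt$value < init_ll) {
    fit <- as.list(init)
    fit$loglik <- init_ll
    fit$converged <- FALSE
  } else {
    fit <- list(mu = opt$par[1L], sigma = exp(opt$par[2L]),
                tau = exp(opt$par[3L]),
                loglik = -opt$value,
                converged = opt$convergence == 0L)
  }
  fit$n_used <- length(rts)
  class(fit) <- "exgauss_fit"
  fit
}

#' @export
print.exgauss_fit <- function(x, ...) {
  cat(sprintf(
    "<exgauss_fit> mu = %.1f ms, sigma = %.1f ms, tau = %.1f ms (n = %d%s)\n",
    x$mu, x$sigma, x$tau, x$n_used,
    if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

#' Flanker performance summary
#'
#' Counts correct, incorrect and omitted trials — a partition of the session —
#' overall and per trial type, with percentages.
#'
#' @param trials Trial-event data.frame (see [read_events]): needs
#'   `trial_index`, `type`, `response`, `correct`, `rt_ms`.
#' @param rt_min Anticipatory-response floor in ms: responses faster than this
#'   are flagged (counted in `n_anticipatory`) but retained.
#' @return A list with `total`, `correct`, `incorrect`, `omissions`,
#'   `pct_correct`, per-type counts/percentages (`by_type`), and
#'   `n_anticipatory`.
#' @export
performance_summary <- function(trials, rt_min = 100) {
  if (anyDuplicated(trials$trial_index))
    stop("duplicate trial indices")
  omitted <- trials$response == "none"
  correct <- trials$correct & !omitted
  incorrect <- !trials$correct & !omitted
  by_type <- do.call(rbind, lapply(split(trials, trials$type), function(d) {
    ok <- sum(d$correct & d$response != "none")
    data.frame(type = d$type[1L], n_trials = nrow(d), n_correct = ok,
               pct_correct = 100 * ok / nrow(d))
  }))
  rownames(by_type) <- NULL
  list(total = nrow(trials),
       correct = sum(correct),
       incorrect = sum(incorrect),
       omissions = sum(omitted),
       pct_correct = 100 * sum(correct) / nrow(trials),
       by_type = by_type,
       n_anticipatory = sum(!is.na(trials$rt_ms) & trials$rt_ms < rt_min))
}
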