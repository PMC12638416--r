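# Two-component Gaussian mixture fitted by EM on the pooled (unlabelled)
# marker values. The default constrains both components to a single shared
# SD, reading the similar-variance precondition as equality; the analytic
# intersection of the two weighted densities then provides an unsupervised
# diagnostic cutpoint.

.em_run <- function(x, w1, mu1, mu2, sigma, equal_sd, tol, max_iter) {
  n <- length(x)
  s1 <- s2 <- sigma
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w1 * dnorm(x, mu1, s1)
    d2 <- (1 - w1) * dnorm(x, mu2, s2)
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    r1 <- d1 / tot
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)  # weight collapse
    w1 <- n1 / n
    mu1 <- sum(r1 * x) / n1
    mu2 <- sum((1 - r1) * x) / n2
    if (equal_sd) {
      s1 <- s2 <- sqrt((sum(r1 * (x - mu1)^2) +
                          sum((1 - r1) * (x - mu2)^2)) / n)
    } else {
      s1 <- sqrt(sum(r1 * (x - mu1)^2) / n1)
      s2 <- sqrt(sum((1 - r1) * (x - mu2)^2) / n2)
    }
    if (min(s1, s2) < 1e-10 * sd(x)) return(NULL)  # variance collapse
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(w1 = w1, mu1 = mu1, mu2 = mu2, s1 = s1, s2 = s2,
       log_likelihood = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, n_iter = length(ll_trace),
       converged = converged, resp1 = r1)
}

#' Fit a two-component Gaussian mixture with a shared SD
#'
#' EM with responsibilities; the M-step pools the variance across both
#' components (a single sigma) unless `equal_sd = FALSE`. Initialization uses
#' a median split plus `n_starts - 1` random starts (seeded); the start with
#' the best log-likelihood wins. Starts that collapse (a vanishing weight or
#' sigma) are discarded; if every start collapses, an error is raised.
#'
#' @param values numeric vector, n >= 10, finite.
#' @param n_starts number of initializations (1 median split + random).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per start.
#' @param seed integer seed for the random starts.
#' @param equal_sd constrain both components to one pooled SD (default TRUE).
#' @return A `mixture_fit`: `weight_1`, `weight_2`, `mean_1`, `mean_2`
#'   (ordered `mean_1 < mean_2`), `shared_sd` (and `sd_1`/`sd_2` when
#'   `equal_sd = FALSE`), `log_likelihood`, `loglik_trace`, `n_iter`,
#'   `converged`, plus a `poorly_separated` flag with the mean posterior
#'   assignment certainty (`separation`) when the two components overlap
#'   heavily.
#' @export
fit_two_gaussian_equal_sd <- function(values, n_starts = 10, tol = 1e-10,
                                      max_iter = 1000, seed = 1,
                                      equal_sd = TRUE) {
  x <- values
  stopifnot(all(is.finite(x)))
  if (length(x) < 10) stop("mixture fit needs n >= 10", call. = FALSE)
  if (sd(x) == 0) stop("mixture fit undefined for constant input",
                       call. = FALSE)
  set.seed(seed)
  starts <- list(list(w1 = 0.5,
                      mu1 = mean(x[x <= median(x)]),
                      mu2 = mean(x[x > median(x)]),
                      sigma = sd(x)))
  for (i in seq_len(max(0, n_starts - 1))) {
    mus <- sort(sample(x, 2))
    starts[[i + 1]] <- list(w1 = runif(1, 0.3, 0.7),
                            mu1 = mus[1], mu2 = mus[2],
                            sigma = sd(x) * runif(1, 0.5, 1.5))
  }
  best <- NULL
  for (s in starts) {
    if (s$mu1 == s$mu2) s$mu2 <- s$mu2 + sd(x) / 10
    fit <- .em_run(x, s$w1, s$mu1, s$mu2, s$sigma, equal_sd, tol, max_iter)
    if (is.null(fit)) next
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  if (is.null(best)) {
    stop("all EM starts collapsed; mixture not identifiable on this input",
         call. = FALSE)
  }
  if (best$mu1 > best$mu2) {
    best <- within(best, {
      tmp <- mu1; mu1 <- mu2; mu2 <- tmp
      tmp <- s1; s1 <- s2; s2 <- tmp
      w1 <- 1 - w1
      resp1 <- 1 - resp1
    })
  }
  sep <- mean(pmax(best$resp1, 1 - best$resp1))
  structure(list(
    weight_1 = best$w1, weight_2 = 1 - best$w1,
    mean_1 = best$mu1, mean_2 = best$mu2,
    shared_sd = if (equal_sd) best$s1 else NA_real_,
    sd_1 = best$s1, sd_2 = best$s2, equal_sd = equal_sd,
    log_likelihood = best$log_likelihood,
    loglik_trace = best$loglik_trace,
    n_iter = best$n_iter, converged = best$converged,
    separation = sep,
    poorly_separated = (best$mu2 - best$mu1) < 2 * max(best$s1, best$s2),
    n = length(x)
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "2-component Gaussian mixture (n = %d): w = (%.3f, %.3f), means = (%.4g, %.4g), %s = %.4g\n",
    x$n, x$weight_1, x$weight_2, x$mean_1, x$mean_2,
    if (x$equal_sd) "shared sd" else "sds",
    if (x$equal_sd) x$shared_sd else x$sd_1))
  if (x$poorly_separated) {
    cat(sprintf("  note: components poorly separated (mean assignment certainty %.2f)\n",
                x$separation))
  }
  invisible(x)
}

#' Intersection cutpoint of the two mixture components
#'
#' Solves `w1 * phi(x; mu1, sd) = w2 * phi(x; mu2, sd)`. With the shared SD
#' the solution is closed-form:
#' `x* = (mu1 + mu2)/2 + sd^2 * log(w1/w2) / (mu2 - mu1)`,
#' which lies between the means whenever
#' `|log(w1/w2)| < (mu2 - mu1)^2 / (2 sd^2)`. In the unequal-SD mode the two
#' weighted densities intersect at the roots of a quadratic; the root between
#' the means is returned.
#'
#' @param fit a `mixture_fit` with distinct component means.
#' @return The cutpoint (score units).
#' @export
intersection_cutpoint <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$mean_1 == fit$mean_2) {
    stop("intersection undefined: equal component means", call. = FALSE)
  }
  if (fit$equal_sd) {
    return((fit$mean_1 + fit$mean_2) / 2 +
             fit$shared_sd^2 * log(fit$weight_1 / fit$weight_2) /
             (fit$mean_2 - fit$mean_1))
  }
  # w1/s1 exp(-(x-m1)^2/(2 s1^2)) = w2/s2 exp(-(x-m2)^2/(2 s2^2))
  a <- 1 / fit$sd_2^2 - 1 / fit$sd_1^2
  b <- 2 * (fit$mean_1 / fit$sd_1^2 - fit$mean_2 / fit$sd_2^2)
  cc <- fit$mean_2^2 / fit$sd_2^2 - fit$mean_1^2 / fit$sd_1^2 +
    2 * log((fit$weight_1 * fit$sd_2) / (fit$weight_2 * fit$sd_1))
  if (abs(a) < 1e-14) {
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("weighted densities do not intersect", call. = FALSE)
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > fit$mean_1 & roots < fit$mean_2]
  if (length(inside) == 0) {
    stop("no intersection between the component means", call. = FALSE)
  }
  inside[1]
}
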