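# Distribution specifications for Monte-Carlo inputs.

#' Distribution specifications
#'
#' A `dist_spec` names a parametric distribution (or point mass, or the
#' empirical distribution of observed values) for a Monte-Carlo model input,
#' with optional truncation to `[low, high]` enforced by rejection sampling
#' at draw time.
#'
#' @param value point-mass location.
#' @param mean,sd normal parameters (`sd >= 0`).
#' @param meanlog,sdlog log-scale parameters of the lognormal.
#' @param min,max,mode uniform / triangular parameters.
#' @param values observed values for the empirical distribution (resampled
#'   with replacement).
#' @param truncation optional numeric `c(low, high)`, `low < high`.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_lognormal(2.65, 0.34)
#' dist_point(1.6)
#' @name dist_spec
NULL

new_dist_spec <- function(kind, params, truncation = NULL) {
  if (!is.null(truncation)) {
    if (length(truncation) != 2 || !is.numeric(truncation) ||
        truncation[1] >= truncation[2]) {
      stop("'truncation' must be numeric c(low, high) with low < high",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, params = params, truncation = truncation),
            class = "dist_spec")
}

chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  chk(is.numeric(value) && length(value) == 1 && is.finite(value),
      "'value' must be a single finite number")
  new_dist_spec("point", list(value = value))
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd, truncation = NULL) {
  chk(is.finite(mean) && is.finite(sd) && sd >= 0,
      "normal requires finite mean and sd >= 0")
  new_dist_spec("normal", list(mean = mean, sd = sd), truncation)
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(meanlog, sdlog, truncation = NULL) {
  chk(is.finite(meanlog) && is.finite(sdlog) && sdlog >= 0,
      "lognormal requires finite meanlog and sdlog >= 0")
  new_dist_spec("lognormal", list(meanlog = meanlog, sdlog = sdlog),
                truncation)
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(min, max, truncation = NULL) {
  chk(is.finite(min) && is.finite(max) && min <= max,
      "uniform requires finite min <= max")
  new_dist_spec("uniform", list(min = min, max = max), truncation)
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(min, mode, max, truncation = NULL) {
  chk(is.finite(min) && is.finite(mode) && is.finite(max) &&
        min <= mode && mode <= max && min < max,
      "triangular requires min <= mode <= max with min < max")
  new_dist_spec("triangular", list(min = min, mode = mode, max = max),
                truncation)
}

#' @rdname dist_spec
#' @export
dist_empirical <- function(values, truncation = NULL) {
  chk(is.numeric(values) && length(values) >= 1 && all(is.finite(values)),
      "empirical requires at least one finite value")
  new_dist_spec("empirical", list(values = as.numeric(values)), truncation)
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- x$params
  ptxt <- if (x$kind == "empirical") {
    sprintf("n=%d values in [%g, %g]", length(p$values),
            min(p$values), max(p$values))
  } else {
    paste(names(p), signif(unlist(p), 6), sep = "=", collapse = ", ")
  }
  cat("<dist_spec> ", x$kind, "(", ptxt, ")", sep = "")
  if (!is.null(x$truncation)) {
    cat(sprintf(" truncated to [%g, %g]", x$truncation[1], x$truncation[2]))
  }
  cat("\n")
  invisible(x)
}

# raw draws, ignoring truncation
draw_raw <- function(spec, n) {
  p <- spec$params
  switch(spec$kind,
    point      = rep(p$value, n),
    normal     = stats::rnorm(n, p$mean, p$sd),
    lognormal  = stats::rlnorm(n, p$meanlog, p$sdlog),
    uniform    = stats::runif(n, p$min, p$max),
    triangular = {
      u <- stats::runif(n)
      fc <- (p$mode - p$min) / (p$max - p$min)
      lo <- u < fc
      out <- numeric(n)
      out[lo] <- p$min + sqrt(u[lo] * (p$max - p$min) * (p$mode - p$min))
      out[!lo] <- p$max - sqrt((1 - u[!lo]) * (p$max - p$min) * (p$max - p$mode))
      out
    },
    empirical  = sample(p$values, n, replace = TRUE),
    stop("unknown distribution kind: ", spec$kind, call. = FALSE)
  )
}

#' Draw from a distribution specification
#'
#' Draws `n` values, enforcing the spec's truncation bounds and any
#' additional physical bounds by rejection-and-redraw. The number of
#' rejected draws is returned alongside the values; rejection is capped at
#' `max_factor * n` total rejections before erroring.
#'
#' @param spec a [dist_spec].
#' @param n number of draws.
#' @param lower,upper physical bounds; draws outside
#'   `(lower, upper)` resp. `[lower, upper]` per `lower_strict` are redrawn.
#' @param lower_strict if `TRUE` values equal to `lower` are rejected too
#'   (e.g. body weight must be strictly positive).
#' @param max_factor rejection cap as a multiple of `n`.
#' @return list with `values` (length `n`) and `n_rejected`.
#' @export
draw_dist <- function(spec, n, lower = -Inf, upper = Inf,
                      lower_strict = FALSE, max_factor = 10) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  if (!is.null(spec$truncation)) {
    lower <- max(lower, spec$truncation[1])
    upper <- min(upper, spec$truncation[2])
  }
  ok_fun <- if (lower_strict) {
    function(v) v > lower & v <= upper
  } else {
    function(v) v >= lower & v <= upper
  }
  values <- draw_raw(spec, n)
  ok <- ok_fun(values)
  n_rejected <- 0L
  while (!all(ok)) {
    n_bad <- sum(!ok)
    n_rejected <- n_rejected + n_bad
    if (n_rejected > max_factor * n) {
      stop("rejection sampling exceeded ", max_factor, "x n draws; ",
           "distribution is incompatible with bounds [", lower, ", ", upper,
           "]", call. = FALSE)
    }
    values[!ok] <- draw_raw(spec, n_bad)
    ok <- ok_fun(values)
  }
  list(values = values, n_rejected = n_rejected)
}

#' Analytic mean of a distribution specification
#'
#' Mean of the untruncated distribution; used for convergence diagnostics.
#'
#' @param spec a [dist_spec].
#' @return the mean.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$kind,
    point      = p$value,
    normal     = p$mean,
    lognormal  = exp(p$meanlog + p$sdlog^2 / 2),
    uniform    = (p$min + p$max) / 2,
    triangular = (p$min + p$mode + p$max) / 3,
    empirical  = mean(p$values)
  )
}

#' Fit a concentration distribution to observed values
#'
#' Fits each candidate distribution family by maximum likelihood and selects
#' the best fit by Kolmogorov-Smirnov statistic (ties broken by
#' log-likelihood). Degenerate data (all values equal) yield a point mass.
#' `"empirical"` is honoured when it is the sole candidate, and is the
#' fallback (with a warning) when every parametric fit fails.
#'
#' @param x numeric vector of concentrations, or a sample table with a `cf`
#'   column; at least 5 positive values for parametric fitting.
#' @param candidates subset of `c("lognormal", "normal", "uniform",
#'   "empirical")`.
#' @return the selected [dist_spec], with attribute `"fit"` holding the
#'   per-candidate K-S statistics and log-likelihoods.
#' @examples
#' fit_concentration_dist(iranshahr_nitrate())
#' @export
fit_concentration_dist <- function(x, candidates = c("lognormal", "normal")) {
  if (is.data.frame(x)) x <- x$cf
  chk(is.numeric(x) && all(is.finite(x)), "concentrations must be finite")
  candidates <- match.arg(candidates,
                          c("lognormal", "normal", "uniform", "empirical"),
                          several.ok = TRUE)
  if (length(unique(x)) == 1) return(dist_point(x[1]))
  if (identical(candidates, "empirical")) return(dist_empirical(x))
  if (sum(x > 0) < 5) {
    stop("need at least 5 positive concentrations to fit a distribution",
         call. = FALSE)
  }

  fit_one <- function(kind) {
    tryCatch({
      f <- switch(kind,
        lognormal = fitdistrplus::fitdist(x, "lnorm"),
        normal    = fitdistrplus::fitdist(x, "norm"),
        uniform   = fitdistrplus::fitdist(x, "unif"),
        empirical = return(NULL)
      )
      est <- as.list(f$estimate)
      cdf <- switch(kind,
        lognormal = function(q) stats::plnorm(q, est$meanlog, est$sdlog),
        normal    = function(q) stats::pnorm(q, est$mean, est$sd),
        uniform   = function(q) stats::punif(q, est$min, est$max)
      )
      ks <- suppressWarnings(stats::ks.test(x, cdf)$statistic)
      spec <- switch(kind,
        lognormal = dist_lognormal(est$meanlog, est$sdlog),
        normal    = dist_normal(est$mean, est$sd),
        uniform   = dist_uniform(est$min, est$max)
      )
      list(kind = kind, spec = spec, ks = unname(ks), loglik = f$loglik)
    }, error = function(e) NULL)
  }

  fits <- Filter(Negate(is.null), lapply(setdiff(candidates, "empirical"),
                                         fit_one))
  if (length(fits) == 0) {
    warning("all parametric fits failed; falling back to the empirical ",
            "distribution")
    return(dist_empirical(x))
  }
  ks <- vapply(fits, `[[`, numeric(1), "ks")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  best <- order(ks, -ll)[1]
  spec <- fits[[best]]$spec
  attr(spec, "fit") <- data.frame(
    kind = vapply(fits, `[[`, character(1), "kind"),
    ks = ks, loglik = ll,
    selected = seq_along(fits) == best
  )
  spec
}
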