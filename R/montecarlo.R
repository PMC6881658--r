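# Monte-Carlo propagation of input uncertainty into the HQ distribution.

#' Monte-Carlo configuration
#'
#' Bundles the iteration count, RNG seed, reported percentiles and the input
#' distribution specs for concentration (`cf`), daily intake (`cd`) and body
#' weight (`bw`). Any input may be a point mass, which makes it
#' deterministic; `cd`/`bw` left `NULL` default to point masses at the
#' exposure group's values when the simulation runs.
#'
#' @param cf [dist_spec] for the nitrate concentration (mg/L).
#' @param cd,bw optional [dist_spec]s for intake (L/day) and body
#'   weight (kg).
#' @param n_iterations number of simulation draws (default 10000).
#' @param seed optional integer seed; fixed seed implies bit-reproducible
#'   results.
#' @param percentiles probabilities to report, all in (0, 1); includes 0.9
#'   (the P90) by default.
#' @param keep_draws if `TRUE` the per-draw table is kept on the result for
#'   audit.
#' @return an object of class `mc_config`.
#' @export
mc_config <- function(cf, cd = NULL, bw = NULL, n_iterations = 10000,
                      seed = NULL,
                      percentiles = c(0.05, 0.25, 0.5, 0.75, 0.9, 0.95),
                      keep_draws = FALSE) {
  chk(inherits(cf, "dist_spec"), "'cf' must be a dist_spec")
  for (s in list(cd, bw)) {
    chk(is.null(s) || inherits(s, "dist_spec"),
        "'cd'/'bw' must be NULL or dist_spec")
  }
  chk(is.numeric(n_iterations) && length(n_iterations) == 1 &&
        n_iterations >= 1, "'n_iterations' must be >= 1")
  chk(is.numeric(percentiles) && all(percentiles > 0 & percentiles < 1),
      "'percentiles' must lie in (0, 1)")
  structure(list(cf = cf, cd = cd, bw = bw,
                 n_iterations = as.integer(n_iterations), seed = seed,
                 percentiles = sort(percentiles), keep_draws = keep_draws),
            class = "mc_config")
}

#' Empirical percentile (type-7 quantile)
#'
#' Linear interpolation between order statistics, the default quantile
#' definition of [stats::quantile()] (type 7). `hq_percentile(x, 0.9)` is
#' the P90: the value not exceeded in 90% of draws.
#'
#' @param draws numeric vector of simulated values.
#' @param p probability or vector of probabilities in (0, 1).
#' @return percentile value(s), unnamed.
#' @export
hq_percentile <- function(draws, p) {
  chk(length(draws) >= 1, "'draws' must be non-empty")
  chk(all(p > 0 & p < 1), "'p' must lie in (0, 1)")
  unname(stats::quantile(draws, probs = p, type = 7, names = FALSE))
}

#' Probability of exceeding a hazard threshold
#'
#' Fraction of simulated HQ draws strictly above the threshold.
#'
#' @param draws numeric vector of simulated HQ values.
#' @param threshold acceptability threshold; 1 by convention.
#' @return probability in \[0, 1\].
#' @export
prob_exceedance <- function(draws, threshold = 1) {
  chk(length(draws) >= 1, "'draws' must be non-empty")
  mean(draws > threshold)
}

#' Contribution-to-variance sensitivity
#'
#' Attributes shares of the output variance to each stochastic input as the
#' squared Spearman rank correlation between the input's draws and the HQ
#' draws, normalized to sum to 1 over non-constant inputs. This is the
#' rank-correlation "contribution to variance" measure familiar from
#' spreadsheet risk tools; it is robust to the multiplicative form of the
#' exposure model.
#'
#' @param input_draws data frame or matrix of per-variable draws (one
#'   column per model input, e.g. `cf`, `cd`, `bw`).
#' @param hq_draws numeric vector of the corresponding HQ draws.
#' @return named numeric vector of fractions summing to 1; empty when every
#'   input is constant.
#' @export
sensitivity_ctv <- function(input_draws, hq_draws) {
  input_draws <- as.data.frame(input_draws)
  chk(nrow(input_draws) == length(hq_draws),
      "'input_draws' and 'hq_draws' must have matching length")
  if (length(unique(hq_draws)) < 2) {
    return(stats::setNames(numeric(0), character(0)))
  }
  varying <- vapply(input_draws, function(v) length(unique(v)) > 1,
                    logical(1))
  if (!any(varying)) return(stats::setNames(numeric(0), character(0)))
  rho2 <- vapply(input_draws[varying], function(v) {
    stats::cor(v, hq_draws, method = "spearman")^2
  }, numeric(1))
  rho2 / sum(rho2)
}

#' Simulate the hazard-quotient distribution for an exposure group
#'
#' Draws `n_iterations` independent (Cf, Cd, Bw) tuples from the configured
#' distributions, computes HQ = Cf * Cd / (Bw * RFD) for each draw, and
#' summarizes the resulting distribution. Physically impossible draws
#' (negative concentration, non-positive intake or body weight) under an
#' untruncated spec are rejected and redrawn, capped at 10x the iteration
#' count; the rejection counts are reported on the result.
#'
#' With every input a point mass the simulation collapses exactly onto the
#' deterministic assessment: sd = 0 and all percentiles equal the
#' deterministic HQ.
#'
#' @param group an exposure group (one-row data frame or list with `name`,
#'   `cd`, `bw`, `rfd`).
#' @param config an [mc_config()]; `cd`/`bw` specs default to point masses
#'   at the group's values.
#' @return an object of class `mc_result`: list with `group_name`,
#'   `n_iterations`, `mean`, `sd`, `percentiles` (named vector),
#'   `prob_exceedance` (P(HQ > 1)), `sensitivity` (contribution to
#'   variance), `n_rejected` (per input), and `draws` (data frame, only if
#'   `keep_draws`).
#' @examples
#' children <- subset(default_exposure_groups(), name == "children")
#' cfg <- mc_config(cf = fit_concentration_dist(iranshahr_nitrate()),
#'                  n_iterations = 2000, seed = 42)
#' simulate_hq(children, cfg)
#' @export
simulate_hq <- function(group, config) {
  chk(inherits(config, "mc_config"), "'config' must be an mc_config")
  group <- as.list(group)
  chk(!is.null(group$cd) && !is.null(group$bw) && !is.null(group$rfd) &&
        group$cd > 0 && group$bw > 0 && group$rfd > 0,
      "group must have positive cd, bw and rfd")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_iterations

  cd_spec <- if (is.null(config$cd)) dist_point(group$cd) else config$cd
  bw_spec <- if (is.null(config$bw)) dist_point(group$bw) else config$bw

  cf <- draw_dist(config$cf, n, lower = 0)
  cd <- draw_dist(cd_spec, n, lower = 0, lower_strict = TRUE)
  bw <- draw_dist(bw_spec, n, lower = 0, lower_strict = TRUE)

  # same association as the deterministic path: HQ = (Cf*Cd/Bw)/RFD, so
  # point-mass inputs collapse bitwise onto assess()
  hq <- (cf$values * cd$values / bw$values) / group$rfd
  inputs <- data.frame(cf = cf$values, cd = cd$values, bw = bw$values)

  res <- list(
    group_name = if (is.null(group$name)) NA_character_ else group$name,
    n_iterations = n,
    mean = mean(hq),
    sd = if (n > 1) stats::sd(hq) else 0,
    percentiles = stats::setNames(hq_percentile(hq, config$percentiles),
                                  sprintf("P%g", 100 * config$percentiles)),
    prob_exceedance = prob_exceedance(hq, 1),
    sensitivity = sensitivity_ctv(inputs, hq),
    n_rejected = c(cf = cf$n_rejected, cd = cd$n_rejected,
                   bw = bw$n_rejected),
    seed = config$seed
  )
  if (isTRUE(config$keep_draws)) res$draws <- cbind(inputs, hq = hq)
  structure(res, class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result> group:", x$group_name, " n =", x$n_iterations, "\n")
  cat(sprintf("  HQ mean %.4f  sd %.4f  P(HQ > 1) %.4f\n",
              x$mean, x$sd, x$prob_exceedance))
  cat("  percentiles:",
      paste(names(x$percentiles), sprintf("%.4f", x$percentiles),
            collapse = "  "), "\n")
  if (length(x$sensitivity)) {
    cat("  contribution to variance:",
        paste(names(x$sensitivity), sprintf("%.3f", x$sensitivity),
              collapse = "  "), "\n")
  }
  invisible(x)
}
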