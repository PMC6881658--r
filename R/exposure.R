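# Deterministic exposure model: EDI = Cf * Cd / Bw, HQ = EDI / RFD.

#' Default exposure groups
#'
#' The four exposure groups conventionally used for drinking-water nitrate
#' risk assessment, with daily water intake `cd` (L/day), body weight `bw`
#' (kg) and the oral reference dose for nitrate `rfd` (1.6 mg/kg/day, per
#' the US EPA Integrated Risk Information System).
#'
#' @return data frame with columns `name`, `cd`, `bw`, `rfd`; rows infant
#'   (0.08 L/day, 10 kg), children (0.85, 15), teenager (2, 50),
#'   adults (2.5, 78).
#' @export
default_exposure_groups <- function() {
  data.frame(
    name = c("infant", "children", "teenager", "adults"),
    cd   = c(0.08, 0.85, 2, 2.5),
    bw   = c(10, 15, 50, 78),
    rfd  = c(1.6, 1.6, 1.6, 1.6),
    stringsAsFactors = FALSE
  )
}

#' Define an exposure group
#'
#' @param name group label.
#' @param cd daily drinking-water intake, L/day (> 0).
#' @param bw body weight, kg (> 0).
#' @param rfd oral reference dose, mg/kg/day (> 0); 1.6 for nitrate.
#' @return one-row data frame usable wherever a group table is expected.
#' @examples
#' exposure_group("toddler", cd = 0.5, bw = 12)
#' @export
exposure_group <- function(name, cd, bw, rfd = 1.6) {
  validate_groups(data.frame(name = as.character(name), cd = cd, bw = bw,
                             rfd = rfd, stringsAsFactors = FALSE))
}

#' @keywords internal
validate_groups <- function(groups) {
  if (!is.data.frame(groups) || nrow(groups) == 0) {
    stop("'groups' must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c("name", "cd", "bw", "rfd") %in% names(groups))) {
    stop("'groups' must have columns name, cd, bw, rfd", call. = FALSE)
  }
  for (col in c("cd", "bw", "rfd")) {
    v <- groups[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("exposure-group parameter '", col, "' must be positive and finite",
           call. = FALSE)
    }
  }
  groups
}

#' Estimated daily intake
#'
#' EDI = Cf * Cd / Bw: contaminant mass ingested per kilogram body weight
#' per day (mg/kg/day) for a concentration `cf` (mg/L) and an exposure
#' group's daily intake and body weight.
#'
#' @param cf nitrate concentration(s), mg/L (>= 0, finite); vectorized.
#' @param group an exposure group (one-row data frame or list with `cd`,
#'   `bw`), e.g. one row of [default_exposure_groups()].
#' @return EDI in mg/kg/day, same length as `cf`.
#' @examples
#' children <- subset(default_exposure_groups(), name == "children")
#' compute_edi(12, children)  # 0.68
#' @export
compute_edi <- function(cf, group) {
  if (!is.numeric(cf) || any(!is.finite(cf)) || any(cf < 0)) {
    bad <- which(!is.finite(cf) | cf < 0)
    stop("negative or non-finite concentration at position(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  group <- as.list(group)
  if (is.null(group$cd) || is.null(group$bw) ||
      group$cd <= 0 || group$bw <= 0) {
    stop("exposure group must have positive 'cd' and 'bw'", call. = FALSE)
  }
  cf * group$cd / group$bw
}

#' Hazard quotient
#'
#' HQ = EDI / RFD. HQ below 1 indicates that harmful effects of the exposure
#' are not expected; HQ above 1 indicates that the non-carcinogenic risk
#' exceeds the acceptable level.
#'
#' @param edi estimated daily intake, mg/kg/day; vectorized.
#' @param rfd reference dose, mg/kg/day (> 0); 1.6 for nitrate.
#' @return dimensionless hazard quotient(s).
#' @examples
#' compute_hq(0.68, 1.6)  # 0.425
#' @export
compute_hq <- function(edi, rfd) {
  if (!is.numeric(rfd) || length(rfd) != 1 || !is.finite(rfd) || rfd <= 0) {
    stop("'rfd' must be a single positive number", call. = FALSE)
  }
  edi / rfd
}

#' Deterministic risk assessment of a sample table
#'
#' Computes EDI and HQ for every (sample, group) pair. Row order is
#' input order: samples outermost, groups within each sample.
#'
#' @param samples sample table (see [read_samples()] or
#'   [iranshahr_nitrate()]).
#' @param groups exposure-group table; defaults to
#'   [default_exposure_groups()].
#' @return data frame with one row per (sample, group): `sample_id`,
#'   `group`, `cf`, `edi`, `hq`.
#' @examples
#' res <- assess(iranshahr_nitrate())
#' head(res)
#' @export
assess <- function(samples, groups = default_exposure_groups()) {
  samples <- validate_samples(samples)
  groups <- validate_groups(groups)
  n_s <- nrow(samples)
  n_g <- nrow(groups)
  i_s <- rep(seq_len(n_s), each = n_g)
  i_g <- rep(seq_len(n_g), times = n_s)
  edi <- samples$cf[i_s] * groups$cd[i_g] / groups$bw[i_g]
  data.frame(
    sample_id = samples$id[i_s],
    group = groups$name[i_g],
    cf = samples$cf[i_s],
    edi = edi,
    hq = edi / groups$rfd[i_g],
    stringsAsFactors = FALSE
  )
}

#' Per-group summary of a risk assessment
#'
#' Mean, minimum, maximum and standard deviation (sample convention, n - 1)
#' of concentration, EDI and HQ for each group, in first-appearance order.
#'
#' @param results output of [assess()].
#' @return data frame with one row per group and columns
#'   `<var>_<stat>` for `var` in cf, edi, hq and `stat` in
#'   mean, min, max, sd.
#' @export
summarize_risk <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("'results' must be a non-empty data frame", call. = FALSE)
  }
  groups <- unique(results$group)
  one <- function(g) {
    r <- results[results$group == g, ]
    stats_of <- function(v) {
      c(mean = mean(v), min = min(v), max = max(v),
        sd = if (length(v) > 1) stats::sd(v) else 0)
    }
    out <- c(stats_of(r$cf), stats_of(r$edi), stats_of(r$hq))
    names(out) <- paste(rep(c("cf", "edi", "hq"), each = 4),
                        rep(c("mean", "min", "max", "sd"), 3), sep = "_")
    data.frame(group = g, as.list(out), stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(groups, one))
}

#' Flag hazard-quotient exceedances
#'
#' Strict comparison: a record is flagged iff `hq > threshold`; HQ exactly
#' at the threshold is regarded as at the acceptable limit, not above it.
#'
#' @param results output of [assess()].
#' @param threshold acceptability threshold (> 0 unless overridden); 1 by
#'   convention.
#' @return data frame `sample_id`, `group`, `hq`, `exceeds` (logical).
#' @export
exceedance_flags <- function(results, threshold = 1) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold)) {
    stop("'threshold' must be a single finite number", call. = FALSE)
  }
  data.frame(
    sample_id = results$sample_id,
    group = results$group,
    hq = results$hq,
    exceeds = results$hq > threshold,
    stringsAsFactors = FALSE
  )
}

#' Round as printed in survey tables
#'
#' Decimal round-half-up (the convention of the published reference tables:
#' ties like 0.53125 print as 0.5313), with a small guard for binary
#' floating-point representation of decimal halves.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 4, the published precision).
#' @return rounded vector.
#' @export
round_printed <- function(x, digits = 4) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}
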