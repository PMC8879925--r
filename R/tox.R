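#' Construct a dose-group mortality table
#'
#' Doses are in ug per fish; with the ~1-g average adult zebrafish body
#' weight they are numerically equal to mg/kg, recorded in
#' `dose_mg_per_kg`. `deaths` is normally an integer count but fractional
#' values are accepted (0 <= deaths <= n), which allows constructing exact
#' probit-linear tables for validation.
#'
#' @param dose_ug numeric doses (ug/fish), non-negative, unique.
#' @param n group sizes, >= 1.
#' @param deaths deaths per group, `0 <= deaths <= n`.
#' @param body_weight_g assumed body weight in g (default 1).
#' @return a `data.frame` of class `mortality_table` with columns
#'   `dose_ug, dose_mg_per_kg, n, deaths`.
#' @export
mortality_table <- function(dose_ug, n, deaths, body_weight_g = 1) {
  if (any(dose_ug < 0) || anyDuplicated(dose_ug)) {
    stop_invalid("invalid-argument: doses must be non-negative and unique")
  }
  if (any(n < 1)) stop_invalid("invalid-argument: n must be >= 1")
  if (any(deaths < 0) || any(deaths > n)) {
    stop_invalid("invalid-argument: deaths must satisfy 0 <= deaths <= n")
  }
  structure(data.frame(dose_ug = dose_ug,
                       dose_mg_per_kg = dose_ug / body_weight_g,
                       n = n, deaths = deaths),
            class = c("mortality_table", "data.frame"))
}

#' Abbott-style control-lethality correction
#'
#' Removes the baseline (zero-dose) lethality from every treated group:
#' `p' = (p - p0) / (1 - p0)`, clipped to `[0, 1]`. Treated groups with
#' observed mortality below control clip to 0% and are flagged. The
#' zero-dose row is removed from the returned fit set.
#'
#' @param table a [mortality_table()] containing a zero-dose row.
#' @return a `data.frame` of treated doses with columns
#'   `dose_ug, dose_mg_per_kg, n, deaths, percent_raw, percent_corrected,
#'   clipped`; attribute `control_rate` holds `p0`.
#' @export
control_correct <- function(table) {
  if (!any(table$dose_ug == 0)) {
    stop_invalid("invalid-argument: table must contain a zero-dose (control) row")
  }
  ctrl <- table[table$dose_ug == 0, , drop = FALSE]
  p0 <- ctrl$deaths[1] / ctrl$n[1]
  if (p0 >= 1) stop_invalid("degenerate-control: control lethality is 100%%")
  treated <- table[table$dose_ug > 0, , drop = FALSE]
  p <- treated$deaths / treated$n
  pc <- pmin(pmax((p - p0) / (1 - p0), 0), 1)
  out <- data.frame(treated[, c("dose_ug", "dose_mg_per_kg", "n", "deaths")],
                    percent_raw = 100 * p, percent_corrected = 100 * pc,
                    clipped = p < p0)
  rownames(out) <- NULL
  attr(out, "control_rate") <- p0
  out
}

#' Miller-Tainter probit transform of a percent mortality
#'
#' Applies the Miller-Tainter endpoint corrections — 0% is replaced by
#' `100 * 0.25/n` and 100% by `100 * (n - 0.25)/n` — and returns the
#' conventional probit `5 + qnorm(percent/100)`, finite for every n >= 1.
#'
#' @param percent percent mortality in `[0, 100]` (vectorized).
#' @param n group size(s), >= 1.
#' @return probit value(s).
#' @examples
#' probit_transform(50, 20)   # 5
#' probit_transform(0, 20)    # 5 + qnorm(0.0125) ~ 2.759
#' @export
probit_transform <- function(percent, n) {
  if (any(n < 1)) stop_invalid("invalid-argument: n must be >= 1")
  if (any(percent < 0) || any(percent > 100)) {
    stop_invalid("invalid-argument: percent must be in [0, 100]")
  }
  n <- rep_len(n, length(percent))
  percent <- ifelse(percent == 0, 100 * (0.25 / n), percent)
  percent <- ifelse(percent == 100, 100 * ((n - 0.25) / n), percent)
  5 + stats::qnorm(percent / 100)
}

#' Estimate LD50 by the Miller-Tainter graphical (probit regression) method
#'
#' Corrects treated-group mortality for control lethality (Abbott), maps
#' corrected percentages to probits with the Miller-Tainter endpoint
#' corrections, and fits an unweighted least-squares line of probit against
#' log10(dose mg/kg). The LD50 is the dose at fitted probit 5 (median
#' lethality): `ld50 = 10^((5 - intercept)/slope)`.
#'
#' @param table a [mortality_table()] with a zero-dose row and >= 2 treated
#'   doses (or the output of [control_correct()]).
#' @param ci logical; if `TRUE`, attach a nonparametric bootstrap
#'   percentile CI (resampling individual fish outcomes within dose).
#' @param ci_reps bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed seed for the bootstrap.
#' @return an object of class `ld50_estimate`: `ld50` (mg/kg), `slope`
#'   (probit per log10 dose), `intercept`, `r_squared`, the per-dose fit
#'   table, and optionally `ci`.
#' @export
fit_ld50 <- function(table, ci = FALSE, ci_reps = 1000, conf = 0.95,
                     seed = 1L) {
  corrected <- if (!is.null(table$percent_corrected)) {
    table
  } else if (any(table$dose_ug == 0)) {
    control_correct(table)
  } else {
    # no control row: correction is the identity (p0 = 0)
    data.frame(table[, c("dose_ug", "dose_mg_per_kg", "n", "deaths")],
               percent_corrected = 100 * table$deaths / table$n)
  }
  if (nrow(corrected) < 2) {
    stop_invalid("insufficient-data: need >= 2 treated doses")
  }
  probit <- probit_transform(corrected$percent_corrected, corrected$n)
  logd <- log10(corrected$dose_mg_per_kg)
  fit <- stats::lm(probit ~ logd)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || abs(slope) < 1e-12) {
    stop_invalid("non-identifiable: zero or undefined probit slope")
  }
  ld50 <- 10^((5 - intercept) / slope)
  ss_tot <- sum((probit - mean(probit))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  est <- structure(list(ld50 = ld50, slope = slope, intercept = intercept,
                        r_squared = r2,
                        fit_table = data.frame(
                          dose_mg_per_kg = corrected$dose_mg_per_kg,
                          n = corrected$n,
                          percent_corrected = corrected$percent_corrected,
                          probit = probit)),
                   class = "ld50_estimate")
  if (ci) {
    p0 <- attr(corrected, "control_rate") %||% 0
    est$ci <- bootstrap_ld50_ci(corrected, p0, ci_reps, conf, seed)
  }
  est
}

# Percentile bootstrap over individual fish outcomes: within each dose
# group (and the control), deaths are resampled binomially at the observed
# rate, then the whole estimation chain is re-run.
bootstrap_ld50_ci <- function(corrected, p0, reps, conf, seed) {
  n0 <- max(corrected$n)  # control group size proxy if not carried through
  with_seed(seed, {
    vals <- vapply(seq_len(reps), function(i) {
      d0 <- stats::rbinom(1, n0, p0)
      deaths <- stats::rbinom(nrow(corrected), corrected$n,
                              corrected$deaths / corrected$n)
      tab <- mortality_table(c(0, corrected$dose_ug),
                             c(n0, corrected$n), c(d0, deaths))
      out <- tryCatch(fit_ld50(tab)$ld50, error = function(e) NA_real_)
      out
    }, numeric(1))
    a <- (1 - conf) / 2
    stats::quantile(vals, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  })
}

#' @export
print.ld50_estimate <- function(x, ...) {
  cat(sprintf("LD50 = %.1f mg/kg (slope %.3f probit/log10-dose, r^2 %.3f)\n",
              x$ld50, x$slope, x$r_squared))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap CI: [%.1f, %.1f] mg/kg\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}
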