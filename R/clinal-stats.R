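#' Ordinary least-squares regression of a value on latitude
#'
#' Fits `value ~ latitude` and reports the slope, intercept, coefficient of
#' determination and the two-sided p-value of the slope (t with n - 2 df).
#' Latitudes are signed degrees (southern hemisphere negative); set
#' `use_absolute_latitude` to regress on |latitude| instead.
#'
#' @param table data frame with `latitude` and `value` columns (and
#'   optionally `population_id`).
#' @param use_absolute_latitude regress on absolute latitude.
#' @return a `cline_fit` list: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `residuals`, `fitted`, `n`, `table` and the underlying
#'   `lm` object.
#' @export
latitude_regression <- function(table, use_absolute_latitude = FALSE) {
  stopifnot(all(c("latitude", "value") %in% names(table)))
  if (nrow(table) < 3) stopf("need >= 3 populations for a cline regression")
  lat <- if (use_absolute_latitude) abs(table$latitude) else table$latitude
  if (var(lat) == 0) stopf("latitudes have zero variance")
  d <- data.frame(latitude = lat, value = table$value)
  fit <- lm(value ~ latitude, data = d)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 residuals = unname(stats::residuals(fit)),
                 fitted = unname(fitted(fit)), n = nrow(d),
                 table = table, lm = fit),
            class = "cline_fit")
}

#' Bonferroni-adjusted outlier screen on externally Studentized residuals
#'
#' Each point's externally Studentized residual (its residual standardized
#' by a variance estimate from the fit excluding that point) is referred to
#' a t distribution with n - 3 degrees of freedom; the two-sided p-value is
#' Bonferroni-multiplied by n and capped at 1. Points with adjusted
#' p < `alpha` are flagged. A point with leverage 1 has no defined residual
#' and is flagged degenerate instead.
#'
#' @param fit a `cline_fit` from [latitude_regression()].
#' @param alpha flagging threshold on the adjusted p-value.
#' @return data frame with `studentized`, `p`, `p_bonferroni`, `outlier`,
#'   `degenerate`, one row per population.
#' @export
studentized_outliers <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "cline_fit"))
  n <- fit$n
  if (n < 4) stopf("need >= 4 points for the outlier test")
  h <- hatvalues(fit$lm)
  degenerate <- abs(h - 1) < 1e-12
  ti <- rstudent(fit$lm)
  ti[degenerate] <- NA_real_
  p <- 2 * pt(-abs(ti), df = n - 3)
  p_bonf <- pmin(1, n * p)
  out <- data.frame(studentized = unname(ti), p = unname(p),
                    p_bonferroni = unname(p_bonf),
                    outlier = !is.na(p_bonf) & p_bonf < alpha,
                    degenerate = unname(degenerate))
  if (!is.null(fit$table$population_id)) {
    out <- cbind(population_id = fit$table$population_id, out)
  }
  out
}

#' Refit a cline excluding selected populations
#'
#' @param table clinal table as for [latitude_regression()].
#' @param exclude population ids (matched against `population_id`) or row
#'   indices to drop.
#' @inheritParams latitude_regression
#' @return a `cline_fit` on the reduced table.
#' @export
refit_excluding <- function(table, exclude, use_absolute_latitude = FALSE) {
  drop <- if (is.character(exclude)) {
    which(table$population_id %in% exclude)
  } else as.integer(exclude)
  keep <- setdiff(seq_len(nrow(table)), drop)
  if (length(keep) < 3) stopf("fewer than 3 populations left after exclusion")
  latitude_regression(table[keep, , drop = FALSE], use_absolute_latitude)
}

#' Screen a cline for outliers and report fits with and without them
#'
#' Convenience wrapper used by the pipeline: fits the cline, runs the
#' Bonferroni Studentized-residual screen, and refits excluding any flagged
#' populations.
#'
#' @inheritParams latitude_regression
#' @param alpha outlier threshold (adjusted p-value).
#' @return list with `fit`, `outliers`, and `refit` (`NULL` when nothing
#'   was flagged).
#' @export
cline_outlier_screen <- function(table, alpha = 0.05,
                                 use_absolute_latitude = FALSE) {
  fit <- latitude_regression(table, use_absolute_latitude)
  outl <- studentized_outliers(fit, alpha)
  refit <- NULL
  if (any(outl$outlier)) {
    refit <- refit_excluding(table, which(outl$outlier),
                             use_absolute_latitude)
  }
  list(fit = fit, outliers = outl, refit = refit)
}

#' Relative expression by the conventional delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` per sample; `ddCt` subtracts the mean
#' `dCt` of the calibrator samples; relative expression is `2^(-ddCt)`
#' (amplification efficiency taken as exactly 2).
#'
#' @param ct data frame with `sample_id`, `ct_target`, `ct_reference` and a
#'   logical `calibrator` column with at least one `TRUE`.
#' @return the input with `dct`, `ddct` and `relative_expression` columns.
#' @export
relative_expression_ddct <- function(ct) {
  stopifnot(all(c("sample_id", "ct_target", "ct_reference", "calibrator")
                %in% names(ct)))
  if (any(is.na(ct$ct_reference)) || any(is.na(ct$ct_target))) {
    stopf("missing Ct value")
  }
  if (!any(ct$calibrator)) stopf("no calibrator sample")
  dct <- ct$ct_target - ct$ct_reference
  ddct <- dct - mean(dct[ct$calibrator])
  out <- ct
  out$dct <- dct
  out$ddct <- ddct
  out$relative_expression <- 2^(-ddct)
  out
}
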