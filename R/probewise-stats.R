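#' Per-probe two-group fit for one developmental stage
#'
#' For the arrays of the requested stage, computes the North-minus-South
#' mean difference, the pooled within-group variance and its residual
#' degrees of freedom, independently for every probe. Stages are analysed
#' separately throughout the pipeline.
#'
#' @param mat normalized intensity matrix (probes x arrays).
#' @param design design table ([design_table()]).
#' @param stage stage label selecting the arrays.
#' @return data frame with `probe_id`, `effect`, `s2`, `df`, and the group
#'   sizes `n_north`, `n_south`.
#' @export
fit_probe_model <- function(mat, design, stage) {
  sel <- design[design$stage == stage, ]
  north <- sel$array_id[sel$cline_end == "North"]
  south <- sel$array_id[sel$cline_end == "South"]
  if (length(north) < 2 || length(south) < 2) {
    stopf("need >=2 arrays per group for stage %s (got %d North, %d South)",
          stage, length(north), length(south))
  }
  xn <- mat[, north, drop = FALSE]
  xs <- mat[, south, drop = FALSE]
  mn <- rowMeans(xn); ms <- rowMeans(xs)
  ssq <- rowSums((xn - mn)^2) + rowSums((xs - ms)^2)
  d <- length(north) + length(south) - 2L
  data.frame(probe_id = rownames(mat), effect = mn - ms, s2 = ssq / d,
             df = d, n_north = length(north), n_south = length(south),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Invert the trigamma function by Newton iteration (with the standard
# asymptotic shortcuts for extreme arguments).
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Estimate the variance-moderation prior by moment matching
#'
#' Models the per-probe sample variances as scaled-inverse-chi-squared draws
#' around a prior variance `s0^2` with prior degrees of freedom `d0`, and
#' estimates both by matching the mean and variance of `log(s2)` using
#' digamma/trigamma identities. When the spread of `log(s2)` does not
#' exceed what chi-squared sampling alone explains, `d0` is infinite and
#' `s0^2` is the bias-corrected mean variance.
#'
#' @param s2 per-probe sample variances (zeros are dropped).
#' @param d residual degrees of freedom shared by all probes.
#' @return list with `d0` (possibly `Inf`) and `s02`.
#' @export
estimate_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) == 0) stopf("all probe variances are zero; no variance structure")
  if (length(s2) < 10) stopf("need >=10 probes with positive variance")
  z <- log(s2)
  excess <- var(z) - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    log_s02 <- mean(z) - digamma(d / 2) + log(d / 2)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    log_s02 <- mean(z) - digamma(d / 2) + log(d / 2) +
      digamma(d0 / 2) - log(d0 / 2)
  }
  list(d0 = d0, s02 = exp(log_s02))
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each probe's variance toward the prior,
#' `s2_tilde = (d0 * s0^2 + d * s2) / (d0 + d)`, and tests the two-group
#' effect with `t = effect / sqrt(s2_tilde * (1/n1 + 1/n2))` on `d0 + d`
#' degrees of freedom (standard normal when `d0` is infinite). Two-sided
#' p-values. A probe whose moderated variance is exactly zero cannot be
#' tested; it is flagged `degenerate` with `p = 0`.
#'
#' @param effect,s2,d per-probe effect, variance, residual df (from
#'   [fit_probe_model()]).
#' @param prior list with `d0`, `s02` (from [estimate_prior()]).
#' @param n1,n2 group sizes.
#' @return data frame with `s2_moderated`, `t`, `df_total`, `p`,
#'   `degenerate`.
#' @export
moderated_t <- function(effect, s2, d, prior, n1, n2) {
  stopifnot(prior$d0 > 0, prior$s02 > 0)
  if (is.infinite(prior$d0)) {
    s2t <- rep(prior$s02, length(s2))
    df_total <- Inf
  } else {
    s2t <- (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
    df_total <- prior$d0 + d
  }
  se <- sqrt(s2t * (1 / n1 + 1 / n2))
  degenerate <- se == 0
  t <- ifelse(degenerate, sign(effect) * Inf, effect / se)
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t)) else
    2 * pt(-abs(t), df_total)
  p[degenerate] <- 0
  data.frame(s2_moderated = s2t, t = t, df_total = df_total, p = p,
             degenerate = degenerate)
}

#' Probe-wise moderated statistics for one stage
#'
#' Convenience wrapper: fits the per-probe two-group model, estimates the
#' moderation prior across probes, and returns moderated t-statistics and
#' p-values joined to the probe coordinates.
#'
#' @inheritParams fit_probe_model
#' @param probes optional probe table; if given, `chrom`, `start` and
#'   `label` columns are carried through for downstream calling.
#' @param prior optional pre-computed prior; estimated from the data when
#'   `NULL`.
#' @return data frame of per-probe statistics, position-ordered within
#'   chromosome when coordinates are available.
#' @export
probe_stats <- function(mat, design, stage, probes = NULL, prior = NULL) {
  fit <- fit_probe_model(mat, design, stage)
  if (is.null(prior)) prior <- estimate_prior(fit$s2, fit$df[1])
  mt <- moderated_t(fit$effect, fit$s2, fit$df[1], prior,
                    fit$n_north[1], fit$n_south[1])
  out <- cbind(fit[c("probe_id", "effect", "s2", "df")], mt)
  attr(out, "prior") <- prior
  if (!is.null(probes)) {
    keep <- intersect(c("probe_id", "chrom", "start", "end", "label"),
                      names(probes))
    out <- merge(probes[keep], out, by = "probe_id", sort = FALSE)
    out <- out[order(out$chrom, out$start), ]
    rownames(out) <- NULL
    attr(out, "prior") <- prior
  }
  out
}
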