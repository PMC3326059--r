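#' Windowed-percentile local background
#'
#' For each probe, the local background is the nearest-rank 5th percentile
#' (by default) of the intensities of the probe itself and the `half_window`
#' probes on each side — up to 1001 values for the default window — computed
#' within one array and one chromosome. Windows are truncated at chromosome
#' ends (no padding): for a truncated window of m values the value at rank
#' `ceiling(percentile/100 * m)` of the sorted window is used.
#'
#' @param values intensities of one array's probes on one chromosome,
#'   ordered by genomic position.
#' @param half_window probes on each side of the centre probe.
#' @param percentile percentile (0-100] defining the background level.
#' @return numeric vector of per-probe raw background values.
#' @export
local_background <- function(values, half_window = 500L, percentile = 5) {
  n <- length(values)
  if (n == 0L) stopf("empty chromosome: no intensities to estimate background")
  vapply(seq_len(n), function(i) {
    w <- values[max(1L, i - half_window):min(n, i + half_window)]
    k <- ceiling(percentile / 100 * length(w))
    sort(w, partial = k)[k]
  }, numeric(1))
}

#' Smooth a background profile by local regression
#'
#' Locally weighted linear regression (tricube weights, single gaussian
#' pass — the classic first-degree loess) of the raw background on genomic
#' position, evaluated at every probe. With fewer than 3 probes the raw
#' background is returned unchanged.
#'
#' @param positions probe positions (bp), same length as `background`.
#' @param background raw background values from [local_background()].
#' @param span loess span: fraction of probes in each local neighbourhood.
#' @return smoothed background vector, finite everywhere.
#' @export
smooth_background <- function(positions, background, span = 0.3) {
  stopifnot(length(positions) == length(background), span > 0, span <= 1)
  if (length(background) < 3L) return(background)
  fit <- stats::loess(background ~ positions, degree = 1, span = span,
                      family = "gaussian",
                      control = stats::loess.control(surface = "interpolate"))
  out <- predict(fit, data.frame(positions = positions))
  if (any(!is.finite(out))) stopf("local regression produced non-finite values")
  as.numeric(out)
}

#' Subtract a smoothed background profile
#'
#' Plain elementwise difference; negative results are preserved (the arsinh
#' normalization downstream is defined on all reals).
#'
#' @param values raw intensities.
#' @param background aligned smoothed background.
#' @return background-subtracted intensities.
#' @export
subtract_background <- function(values, background) {
  stopifnot(length(values) == length(background))
  values - background
}

#' Variance-stabilizing between-array normalization
#'
#' Each array j is transformed by `h_j(x) = asinh((x - a_j) / b_j)`, the
#' generalized-log transform. The reference array (first column) gets
#' offset and scale estimated from the across-array mean-sd relationship,
#' chosen so its transformed values are approximately homoskedastic across
#' the intensity range; every other array is then calibrated to match the
#' reference in median and median absolute deviation. The per-array offset
#' follows from the scale in closed form (medians commute with monotone
#' transforms); the scale is found by one-dimensional root finding on the
#' MAD. The transform is defined on all reals, so background-subtracted
#' negative values are fine.
#'
#' @param mat background-subtracted intensity matrix (probes x arrays,
#'   at least two columns).
#' @param reference column index of the reference array.
#' @return matrix of normalized values with attribute `calibration`, a data
#'   frame of the per-array (offset, scale) used.
#' @export
vsn_normalize <- function(mat, reference = 1L) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  mads <- apply(mat, 2, mad)
  if (any(mads == 0)) {
    stopf("degenerate array (zero MAD): %s",
          paste(colnames(mat)[mads == 0], collapse = ", "))
  }
  gp <- estimate_glog_params(mat)
  href <- asinh((mat[, reference] - gp$a) / gp$b)
  m_ref <- median(href); s_ref <- mad(href)
  if (s_ref == 0) stopf("degenerate reference array (zero MAD after transform)")
  q <- sinh(m_ref)
  out <- mat
  arr_names <- if (is.null(colnames(mat))) as.character(seq_len(ncol(mat)))
    else colnames(mat)
  calib <- data.frame(array = arr_names, offset = 0, scale = 1,
                      stringsAsFactors = FALSE)
  calib$offset[reference] <- gp$a
  calib$scale[reference] <- gp$b
  for (j in seq_len(ncol(mat))) {
    if (j == reference) {
      out[, j] <- href
      next
    }
    x <- mat[, j]
    med_j <- median(x)
    f <- function(logb) {
      b <- exp(logb)
      mad(asinh((x - (med_j - b * q)) / b)) - s_ref
    }
    grid <- seq(-30, 30, length.out = 121)
    fg <- vapply(grid, f, numeric(1))
    sc <- which(diff(sign(fg)) != 0)
    if (length(sc)) {
      logb <- uniroot(f, c(grid[sc[1]], grid[sc[1] + 1]),
                      tol = 1e-10)$root
    } else {
      logb <- grid[which.min(abs(fg))]
    }
    b <- exp(logb); a <- med_j - b * q
    out[, j] <- asinh((x - a) / b)
    calib$offset[j] <- a; calib$scale[j] <- b
  }
  attr(out, "calibration") <- calib
  out
}

# Estimate the glog offset and scale of the reference transform from the
# across-array mean-sd relationship. With noise sd(x) ~ s0 + k * mean(x),
# the transform asinh((x + s0/k) / s0) has approximately constant spread
# (it behaves as log(x + s0/k) above the noise floor and stays linear,
# hence finite, through zero and below). s0 and k are fitted robustly as a
# line through decile medians of per-probe (mean, sd).
estimate_glog_params <- function(mat) {
  mu <- rowMeans(mat)
  s <- sqrt(pmax(rowSums((mat - mu)^2), 0) / (ncol(mat) - 1))
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = 10, include.lowest = TRUE)
  bm <- tapply(mu, bins, median)
  bs <- tapply(s, bins, median)
  ok <- is.finite(bm) & is.finite(bs)
  cf <- coef(lm(bs[ok] ~ bm[ok]))
  s0 <- cf[[1]]; k <- cf[[2]]
  floor_b <- max(0.05 * stats::median(s), 1e-8)
  if (!is.finite(k) || k < 1e-3) {
    # additive noise only: no offset needed, scale at the noise floor
    list(a = 0, b = max(s0, floor_b))
  } else {
    list(a = -max(s0, 0) / k, b = max(s0, floor_b))
  }
}

#' Background-subtract and normalize an intensity matrix
#'
#' Runs the fixed preprocessing order: per (array, chromosome) block, the
#' windowed-percentile local background is estimated, smoothed by local
#' regression and subtracted; the background-subtracted matrix is then
#' variance-stabilized and calibrated across arrays.
#'
#' @param intensities raw intensity matrix, rows named by `probe_id`.
#' @param probes probe table giving `probe_id`, `chrom` and `start`; rows of
#'   `intensities` are processed in position order within each chromosome.
#' @param half_window,percentile see [local_background()].
#' @param span see [smooth_background()].
#' @return list with `normalized` (matrix, same dimnames), and the
#'   `background_raw` and `background_smooth` matrices for audit.
#' @export
preprocess_intensities <- function(intensities, probes, half_window = 500L,
                                   percentile = 5, span = 0.3) {
  stopifnot(all(probes$probe_id %in% rownames(intensities)))
  intensities <- intensities[probes$probe_id, , drop = FALSE]
  ord <- order(probes$chrom, probes$start)
  if (!identical(ord, seq_len(nrow(probes)))) {
    probes <- probes[ord, ]
    intensities <- intensities[ord, , drop = FALSE]
  }
  bg_raw <- bg_smooth <- intensities * 0
  for (ch in unique(probes$chrom)) {
    ri <- which(probes$chrom == ch)
    for (j in seq_len(ncol(intensities))) {
      raw <- local_background(intensities[ri, j], half_window, percentile)
      bg_raw[ri, j] <- raw
      bg_smooth[ri, j] <- smooth_background(probes$start[ri], raw, span)
    }
  }
  subtracted <- intensities - bg_smooth
  list(normalized = vsn_normalize(subtracted),
       background_raw = bg_raw, background_smooth = bg_smooth)
}
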