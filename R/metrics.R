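## Organ volumetry and the agreement-statistics suite: Dice similarity,
## Lin's concordance, RMSE, mean absolute percent error, zero-error counts,
## Bland-Altman limits on the percent scale, interobserver SD and ICC(2,1).

#' Organ volume in mL
#'
#' Volume = voxel count of the label times the voxel volume (mm^3) / 1000.
#'
#' @param map a [LabelMap-class].
#' @param organ organ name (`"right_kidney"`, `"left_kidney"`, `"spleen"`,
#'   `"liver"`) or an integer label value.
#' @return Volume in mL.
#' @export
#' @examples
#' m <- LabelMap(array(c(rep(1L, 2000), rep(0L, 48)), c(16, 16, 8)),
#'               spacing = c(1.25, 1.25, 5))
#' organVolume(m, "right_kidney")  # 2000 * 7.8125 mm^3 = 15.625 mL
organVolume <- function(map, organ) {
  stopifnot(is(map, "LabelMap"))
  lab <- if (is.character(organ)) .ORGAN_LABELS[[organ]] else as.integer(organ)
  sum(map@data == lab) * prod(map@spacing) / 1000
}

#' Per-organ volume report
#'
#' Per-organ volumes plus the composite ADPKD biomarkers: total kidney volume
#' (TKV = right + left, mL) and height-adjusted TKV (ht-TKV = TKV / height,
#' mL/m).
#'
#' @param map a standard-convention [LabelMap-class].
#' @param height_m subject height in metres (optional; ht-TKV is `NA`
#'   without it).
#' @return A list of class `"VolumeReport"`: per-organ mL, `TKV_mL`,
#'   `htTKV_mL_per_m`.
#' @export
volumeReport <- function(map, height_m = NA_real_) {
  v <- vapply(names(.ORGAN_LABELS)[-1], function(o) organVolume(map, o),
              numeric(1))
  tkv <- v[["right_kidney"]] + v[["left_kidney"]]
  structure(c(as.list(v),
              list(TKV_mL = tkv,
                   htTKV_mL_per_m = if (is.na(height_m)) NA_real_
                                    else tkv / height_m)),
            class = "VolumeReport")
}

#' @export
print.VolumeReport <- function(x, ...) {
  cat("Organ volumes (mL):\n")
  for (o in names(.ORGAN_LABELS)[-1])
    cat(sprintf("  %-13s %9.1f\n", o, x[[o]]))
  cat(sprintf("  %-13s %9.1f\n", "TKV", x$TKV_mL))
  if (!is.na(x$htTKV_mL_per_m))
    cat(sprintf("  %-13s %9.1f mL/m\n", "ht-TKV", x$htTKV_mL_per_m))
  invisible(x)
}

#' Dice similarity coefficient
#'
#' `DSC = 2|A n B| / (|A| + |B|)`; 1.0 is perfect agreement. Two empty masks
#' agree perfectly (both observers found nothing), so the both-empty case
#' returns 1.0.
#'
#' @param A,B congruent logical (or 0/1) arrays.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(A, B) {
  if (length(A) != length(B)) stop("masks must be congruent")
  a <- as.logical(A); b <- as.logical(B)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1.0)
  2 * sum(a & b) / denom
}

#' Lin's concordance correlation coefficient
#'
#' `2*s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with population (1/n)
#' moments. Penalizes both correlation loss and location/scale shift, so a
#' constant offset lowers concordance even when Pearson correlation is 1.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Concordance in `[-1, 1]`.
#' @export
concordance <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0)
    stop("concordance undefined: both series are constant")
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Root mean square error
#' @param x,y numeric vectors of equal length.
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  sqrt(mean((x - y)^2))
}

#' Mean absolute percent error
#'
#' Mean over cases of `|y_i - x_i| / x_i * 100`, with `x` the reference
#' (truth) series. Absolute per-case errors are averaged so over- and
#' under-estimates cannot cancel.
#'
#' @param x reference (truth) volumes; must be nonzero.
#' @param y comparison volumes.
#' @return Percent error (>= 0).
#' @export
meanPercentError <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (any(x == 0)) stop("percent error undefined for zero reference volumes")
  mean(abs(y - x) / x) * 100
}

#' Count of cases with zero volume error
#'
#' Cases whose two volumes are equal after rounding to the nearest
#' `rounding_mL` (1 mL by default, matching whole-mL reporting).
#'
#' @param x,y numeric volume series of equal length.
#' @param rounding_mL rounding unit in mL.
#' @return Integer count.
#' @export
zeroErrorCount <- function(x, y, rounding_mL = 1) {
  if (length(x) != length(y)) stop("series must have equal length")
  sum(round(x / rounding_mL) == round(y / rounding_mL))
}

#' Bland-Altman analysis on the percent scale
#'
#' Per case, the difference `(y - x) / mean(x, y) * 100` is paired with the
#' case mean; the bias is the mean difference and the 95% limits of
#' agreement are `bias +/- 1.96 * SD`.
#'
#' @param x reference volumes.
#' @param y comparison volumes.
#' @return A list of class `"blandAltman"`: `bias`, `lower`, `upper`,
#'   `differences` (percent), `means` (mL).
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  m <- (x + y) / 2
  if (any(m == 0)) stop("percent differences undefined for zero-mean pairs")
  d <- (y - x) / m * 100
  bias <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  structure(list(bias = bias, lower = bias - 1.96 * s,
                 upper = bias + 1.96 * s, differences = d, means = m),
            class = "blandAltman")
}

#' @export
print.blandAltman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%% scale): bias %.2f%%, 95%% limits [%.2f%%, %.2f%%], n = %d\n",
              x$bias, x$lower, x$upper, length(x$differences)))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#'
#' Scatter of percent differences against case means with bias and limit
#' lines, written to a standard image file when `file` is given.
#'
#' @param ba a [blandAltman()] result.
#' @param main plot title.
#' @param file optional PNG path; plots to the active device when `NULL`.
#' @export
plotBlandAltman <- function(ba, main = "Bland-Altman", file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(ba$means, ba$differences, pch = 19,
                 xlab = "Mean volume (mL)", ylab = "Difference (%)",
                 main = main)
  graphics::abline(h = ba$bias, lty = 1)
  graphics::abline(h = c(ba$lower, ba$upper), lty = 2)
  invisible(ba)
}

#' Mean interobserver standard deviation
#'
#' Per-case sample SD of the observers' volumes, averaged over cases.
#'
#' @param measurements numeric matrix, cases in rows, observers in columns.
#' @return Mean SD in the measurement units (mL).
#' @export
interobserverSD <- function(measurements) {
  m <- as.matrix(measurements)
  if (ncol(m) < 2) stop("need at least 2 observers")
  mean(apply(m, 1, sd))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC from the
#' variance decomposition: with the two-way mean squares MSR (rows/cases),
#' MSC (columns/raters) and MSE,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param measurements numeric matrix, n cases in rows, k observers in
#'   columns.
#' @return ICC estimate in `[-1, 1]` (up to estimation noise).
#' @export
icc <- function(measurements) {
  m <- as.matrix(measurements)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 cases and 2 observers")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Observer agreement summary per organ
#'
#' Interobserver SD and ICC(2,1) per organ from repeated measurements.
#'
#' @param measurements named list (one element per organ) of n x k matrices,
#'   cases in rows, observers in columns.
#' @return data.frame with `organ`, `mean_sd_mL`, `icc`.
#' @export
observerAgreement <- function(measurements) {
  do.call(rbind, lapply(names(measurements), function(org) {
    m <- measurements[[org]]
    data.frame(organ = org, mean_sd_mL = interobserverSD(m), icc = icc(m),
               stringsAsFactors = FALSE)
  }))
}

.REPORT_ORGANS <- c("right_kidney", "left_kidney", "liver", "spleen")

#' Evaluate predicted label maps against truth
#'
#' Assembles the per-organ agreement table between truth and predicted label
#' maps over a set of cases: mean Dice, Lin's concordance of the volume
#' series (NA when undefined, e.g. a single case), RMSE (mL), mean absolute
#' percent error, zero-error count and Bland-Altman bias/limits (percent
#' scale). Differences are signed as prediction minus truth.
#'
#' @param truth list of standard-convention [LabelMap-class] objects.
#' @param pred list of congruent predicted [LabelMap-class] objects.
#' @param observer_measurements optional named list of n x k matrices (per
#'   organ) to fill the interobserver SD and ICC columns.
#' @return An [AgreementReport-class].
#' @export
evaluateRun <- function(truth, pred, observer_measurements = NULL) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  n <- length(truth)
  rows <- lapply(.REPORT_ORGANS, function(org) {
    lab <- .ORGAN_LABELS[[org]]
    dices <- vapply(seq_len(n), function(i)
      dsc(voxelData(truth[[i]]) == lab, voxelData(pred[[i]]) == lab),
      numeric(1))
    vt <- vapply(truth, organVolume, numeric(1), organ = org)
    vp <- vapply(pred, organVolume, numeric(1), organ = org)
    conc <- if (n >= 2 && (var(vt) > 0 || var(vp) > 0))
      concordance(vt, vp) else NA_real_
    pe <- if (all(vt > 0)) meanPercentError(vt, vp) else NA_real_
    ba <- if (all((vt + vp) > 0)) blandAltman(vt, vp) else NULL
    data.frame(organ = org,
               dsc = mean(dices),
               concordance = conc,
               rmse_mL = rmse(vt, vp),
               mean_pct_error = pe,
               zero_error_n = zeroErrorCount(vt, vp),
               ba_bias_pct = if (is.null(ba)) NA_real_ else ba$bias,
               ba_lower_pct = if (is.null(ba)) NA_real_ else ba$lower,
               ba_upper_pct = if (is.null(ba)) NA_real_ else ba$upper,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$observer_sd_mL <- NA_real_
  tab$icc <- NA_real_
  if (!is.null(observer_measurements)) {
    oa <- observerAgreement(observer_measurements)
    i <- match(tab$organ, oa$organ)
    tab$observer_sd_mL <- oa$mean_sd_mL[i]
    tab$icc <- oa$icc[i]
  }
  new("AgreementReport", table = tab, n_cases = as.integer(n))
}

#' Write an agreement report as CSV
#'
#' @param report an [AgreementReport-class].
#' @param path output CSV path.
#' @export
exportReport <- function(report, path) {
  stopifnot(is(report, "AgreementReport"))
  write.csv(report@table, path, row.names = FALSE)
  invisible(path)
}
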