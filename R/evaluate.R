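# Volumetric overlap metrics and method-agreement statistics.

#' Overlap metrics of a segmentation against a reference
#'
#' Voxel-count based:
#' TPVF = |auto & truth| / |truth|;
#' FPVF = |auto \ truth| / (|retina| - |truth|) (the false-positive-eligible
#' retina volume between ILM and BM);
#' DSC  = 2 |auto & truth| / (|auto| + |truth|);
#' PPV  = |auto & truth| / |auto|.
#' Fractions in 0..1; multiply by 100 for the conventional percentages.
#' Degenerate denominators are reported as 0 with a flag rather than NaN.
#'
#' @param auto,truth,retina logical 3D masks on one grid; `truth` must be
#'   contained in `retina`.
#' @return `ped_metrics`: list `tpvf`, `fpvf`, `dsc`, `ppv`, `flags`.
#' @examples
#' a <- array(FALSE, c(10, 10, 10)); t <- a; r <- !a
#' a[1:10] <- TRUE; t[6:15] <- TRUE
#' compute_metrics(a, t, r)$dsc # 0.5
#' @export
compute_metrics <- function(auto, truth, retina) {
  if (!identical(dim(auto), dim(truth)) || !identical(dim(auto), dim(retina)))
    stop_param("compute_metrics: masks must share one grid")
  if (any(truth & !retina))
    stop_param("compute_metrics: truth mask must be contained in the retina mask")
  inter <- sum(auto & truth)
  va <- sum(auto); vg <- sum(truth); vr <- sum(retina)
  flags <- character(0)
  if (vg == 0) flags <- c(flags, "empty_truth")
  if (va == 0) flags <- c(flags, "empty_auto")
  if (vr <= vg) flags <- c(flags, "no_negative_volume")
  tpvf <- if (vg > 0) inter / vg else 0
  fpvf <- if (vr > vg) (va - inter) / (vr - vg) else 0
  dsc <- if (va + vg > 0) 2 * inter / (va + vg) else 0
  ppv <- if (va > 0) inter / va else 0
  structure(list(tpvf = tpvf, fpvf = fpvf, dsc = dsc, ppv = ppv, flags = flags),
            class = "ped_metrics")
}

#' @export
print.ped_metrics <- function(x, ...) {
  cat(sprintf("TPVF %.2f%%  FPVF %.3f%%  DSC %.2f%%  PPV %.2f%%%s\n",
              100 * x$tpvf, 100 * x$fpvf, 100 * x$dsc, 100 * x$ppv,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Agreement between two volume measurement series
#'
#' Ordinary least squares of `b` on `a` with R-squared, and Bland-Altman
#' agreement of the differences `a - b`: mean difference and the 95% limits
#' `mean +/- 1.96 sd` (sample sd, n - 1).
#'
#' @param a,b numeric vectors of paired volumes (length >= 3).
#' @return list `slope`, `intercept`, `r_squared`, `mean_diff`, `loa`
#'   (length-2 lower/upper limits of agreement), `sd_diff`.
#' @export
agreement_stats <- function(a, b) {
  if (length(a) != length(b)) stop_param("agreement_stats: length mismatch")
  if (length(a) < 3) stop_param("agreement_stats: need at least 3 pairs")
  fit <- lm(b ~ a)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((b - mean(b))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  dif <- a - b
  md <- mean(dif); sdd <- sd(dif)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, mean_diff = md, sd_diff = sdd,
       loa = c(md - 1.96 * sdd, md + 1.96 * sdd))
}

#' Two-sided paired t-test
#'
#' @param a,b numeric vectors of equal length (>= 2); constant differences
#'   are a degenerate case and are flagged.
#' @return list `t`, `p`, `df`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop_param("paired_t_test: length mismatch")
  if (length(a) < 2) stop_param("paired_t_test: need at least 2 pairs")
  dif <- a - b
  if (sd(dif) == 0) {
    if (all(dif == 0)) return(list(t = 0, p = 1, df = length(a) - 1, degenerate = TRUE))
    return(list(t = sign(mean(dif)) * Inf, p = 0, df = length(a) - 1, degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}
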