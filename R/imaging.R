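#' Dynamic contrast-enhanced signal series
#'
#' A T1-weighted signal time course for one region (tumour or contralateral
#' muscle) with the position of the contrast injection in the series.
#'
#' @param time_s acquisition times, seconds, strictly increasing.
#' @param signal signal intensity, arbitrary units, nonnegative.
#' @param injection_index index of the last pre-injection sample (samples
#'   `1..injection_index` form the baseline).
#' @param region region label, e.g. `"tumour"` or `"muscle"`.
#' @return An object of class `enhancement_curve`.
#' @export
enhancement_curve <- function(time_s, signal, injection_index,
                              region = "tumour") {
  stopifnot(length(time_s) == length(signal))
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (any(signal < 0)) stop("signal must be >= 0")
  if (injection_index < 1 || injection_index >= length(time_s))
    stop("injection_index must fall inside the series")
  structure(list(time_s = as.numeric(time_s), signal = as.numeric(signal),
                 injection_index = as.integer(injection_index),
                 region = region),
            class = "enhancement_curve")
}

#' Baseline-normalised enhancement
#'
#' Expresses the T1 enhancement relative to the pre-injection baseline:
#' `(S(t) - Sbar_pre) / Sbar_pre` where `Sbar_pre` is the mean of all
#' pre-injection samples (method `"relative"`; method `"ratio"` gives
#' `S(t) / Sbar_pre`).  The summary statistic is the mean (or peak)
#' normalised value over the whole post-injection window.  The relative
#' form is scale-free: multiplying the raw signal by any positive constant
#' leaves it unchanged.
#'
#' @param curve an [enhancement_curve()] with at least 2 baseline samples.
#' @param method `"relative"` (default) or `"ratio"`.
#' @param summary `"mean"` (default) or `"peak"` over the post-injection
#'   window.
#' @return An object of class `normalized_enhancement` with fields
#'   `time_s`, `normalized`, `summary`, `region`.
#' @export
#' @examples
#' ec <- enhancement_curve(seq(0, 90, 9), c(rep(100, 4), rep(150, 7)), 4)
#' normalize_enhancement(ec)$summary  # 0.5
normalize_enhancement <- function(curve, method = c("relative", "ratio"),
                                  summary = c("mean", "peak")) {
  method <- match.arg(method)
  summary <- match.arg(summary)
  if (curve$injection_index < 2)
    stop("at least 2 pre-injection samples are required")
  pre <- mean(curve$signal[seq_len(curve$injection_index)])
  if (pre == 0) stop("baseline mean is zero; cannot normalise")
  norm <- switch(method,
                 relative = (curve$signal - pre) / pre,
                 ratio = curve$signal / pre)
  post <- norm[(curve$injection_index + 1L):length(norm)]
  structure(list(time_s = curve$time_s, normalized = norm,
                 summary = switch(summary, mean = mean(post),
                                  peak = max(post)),
                 method = method, summary_stat = summary,
                 region = curve$region),
            class = "normalized_enhancement")
}

#' Compare enhancement summaries between two imaging sessions
#'
#' Two-sided t-test on per-animal enhancement summaries, paired by animal by
#' default (the same animals are imaged longitudinally).
#'
#' @param summaries_a,summaries_b numeric vectors of per-animal summaries
#'   (equal length and matching order when `paired`); each `n >= 2`.
#' @param paired logical, default `TRUE`.
#' @return A list with `difference` (mean of b - a), `t`, `df`, `p_value`.
#' @export
permeability_contrast <- function(summaries_a, summaries_b, paired = TRUE) {
  if (length(summaries_a) < 2 || length(summaries_b) < 2)
    stop("each session needs at least 2 animals")
  if (paired && length(summaries_a) != length(summaries_b))
    stop("paired comparison requires matched animals in both sessions")
  if (paired && sd(summaries_b - summaries_a) == 0) {
    d <- mean(summaries_b - summaries_a)
    return(list(difference = d, t = if (d == 0) 0 else Inf,
                df = length(summaries_a) - 1,
                p_value = if (d == 0) 1 else 0, paired = TRUE))
  }
  ht <- t.test(summaries_b, summaries_a, paired = paired)
  list(difference = unname(if (paired) ht$estimate else diff(rev(ht$estimate))),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, paired = paired)
}

#' Tumour volume from slice areas
#'
#' Volume of a manually delineated tumour: the area on each image slice
#' multiplied by the slice thickness, summed over slices.
#'
#' @param areas_mm2 per-slice tumour areas, mm^2, nonnegative.
#' @param thickness_mm slice thickness, mm (0.33 mm in the anatomical
#'   protocol the package mirrors).
#' @return Volume in mm^3.
#' @export
#' @examples
#' volume_from_slices(rep(26.1, 58), 0.33)  # ~500 mm^3
volume_from_slices <- function(areas_mm2, thickness_mm = 0.33) {
  if (length(areas_mm2) < 1) stop("at least one slice is required")
  if (any(areas_mm2 < 0)) stop("slice areas must be >= 0")
  if (thickness_mm <= 0) stop("slice thickness must be > 0")
  sum(areas_mm2) * thickness_mm
}
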