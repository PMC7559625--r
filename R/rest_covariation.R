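#' Rest-period inclusion by artifact-free fraction
#'
#' The segment covariation analysis relies on the continuity of the rest
#' data; subjects enter only when at least 66% (inclusive) of the rest
#' period is artifact-free.
#'
#' @param mask Combined validity [binary_mask()] over the rest span.
#' @param span Rest window `c(on, off)` (s).
#' @param min_fraction Inclusion threshold (default 0.66).
#' @return Logical flag.
#' @export
rest_inclusion <- function(mask, span = NULL, min_fraction = 0.66) {
  span <- span %||% c(mask$start, mask$start + length(mask$valid) / mask$rate)
  valid_fraction(mask, span) >= min_fraction
}

#' 1-s segment feature table for one subject's rest period
#'
#' Splits the rest period into 1 s segments on a common time base for EEG
#' and eye behavior: per segment, log alpha power `log(1 + mean POW)` per
#' region (electrodes aggregated across both hemispheres; missing when
#' fewer than `min_eeg_valid` of the 100 EEG samples survive the artifact
#' mask), means/variances of the conditioned continuous eye series, and
#' onset-in-segment counts for the discrete parameters. All continuous
#' columns are then z-scored within subject over their non-missing
#' segments.
#'
#' @param rec A [coreg_recording()] covering the rest period.
#' @param rest_span `c(on, off)` of the rest period (default the first
#'   120 s).
#' @param band Alpha band `c(center, halfband)` (Hz).
#' @param min_eeg_valid Minimum valid EEG samples per segment (default 10
#'   of 100; a segment containing a fully extended blink window still
#'   retains ~250 ms of EEG, and such segments must stay in the table
#'   because blink counts are among the correlates).
#' @param grouping See [electrode_grouping()].
#' @return Tibble with one row per segment (`segment` 0-based), columns
#'   `alpha_AF` ... `alpha_O`, `pd_mean`, `pd_var`, `aoev_mean`,
#'   `aoev_var`, `blink_count`, `fixation_count`, `saccade_count`,
#'   `microsaccade_count`, plus attributes `valid_fraction` and `included`.
#' @export
rest_segments <- function(rec, rest_span = c(0, 120), band = c(10.5, 2.0),
                          min_eeg_valid = 10,
                          grouping = electrode_grouping()) {
  duration <- recording_duration(rec)
  cond <- preprocess_eeg(rec)
  pow <- alpha_power(cond, center = band[1], halfband = band[2])
  eeg_mask <- build_eeg_mask(
    blinks = rec$events$blink %||% interval_set(),
    saccades = rec$events$saccade %||% interval_set(),
    manual = rec$events$manual %||% interval_set(),
    duration = duration, rate = 100
  )
  eye <- condition_eye(rec, scope = rest_span)
  combined <- mask_and(eeg_mask, eye$eye_mask)

  nseg <- floor(diff(rest_span))
  seg_on <- rest_span[1] + seq_len(nseg) - 1

  electrodes <- unique(grouping$electrode)
  logp <- vapply(seg_on, function(s) {
    per_el <- vapply(electrodes, function(ch) {
      mp <- mean_power(pow[[ch]], eeg_mask, c(s, s + 1), min_eeg_valid)
      log1p(mp)
    }, numeric(1))
    hemisphere_aggregate(per_el, grouping)
  }, numeric(length(unique(grouping$region))))

  feat <- dplyr::bind_rows(lapply(seg_on, function(s) {
    window_features(eye$pd_z, eye$aoev_ts, eye$events, c(s, s + 1))
  }))

  tab <- dplyr::bind_cols(
    tibble::tibble(segment = seq_len(nseg) - 1L),
    tibble::as_tibble(t(logp), .name_repair = ~ paste0("alpha_", .x)),
    feat[, c("pd_mean", "pd_var", "aoev_mean", "aoev_var",
             "blink_count", "fixation_count", "saccade_count",
             "microsaccade_count")]
  )

  zcols <- c(grep("^alpha_", names(tab), value = TRUE),
             "pd_mean", "pd_var", "aoev_mean", "aoev_var")
  for (cc in zcols) {
    v <- tab[[cc]]
    mu <- mean(v, na.rm = TRUE)
    sdv <- stats::sd(v, na.rm = TRUE)
    tab[[cc]] <- if (is.finite(sdv) && sdv > 0) (v - mu) / sdv else v * NA
  }

  attr(tab, "valid_fraction") <- valid_fraction(combined, rest_span)
  attr(tab, "included") <- rest_inclusion(combined, rest_span)
  attr(tab, "subject") <- rec$meta$subject %||% "s01"
  tab
}

#' Pearson correlation between two segment columns of one subject
#'
#' Correlates over segments where both columns are non-missing ("valid EEG
#' and eye-tracking data"); missing when fewer than `min_pairs` segments
#' remain or either column is degenerate (zero variance).
#'
#' @param tab A [rest_segments()] table.
#' @param xcol,ycol Column names.
#' @param min_pairs Minimum complete pairs (default 30 of 120, bounding
#'   the standard error of a single subject's r).
#' @return Pearson r or `NA`.
#' @export
subject_correlation <- function(tab, xcol, ycol, min_pairs = 30) {
  x <- tab[[xcol]]; y <- tab[[ycol]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < max(min_pairs, 3)) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Aggregate within-subject correlations across subjects via Fisher's z
#'
#' Each subject's r is Fisher z-transformed (`atanh`), the z values are
#' averaged and back-transformed (`tanh`) to the reported mean
#' correlation. Difference from zero is tested by a one-sample t test on
#' the z values; the confidence interval is built on the z scale from t
#' quantiles at level `1 - alpha` and back-transformed. `|r| = 1` is
#' clamped just inside the open interval with a warning.
#'
#' @param r Numeric vector of per-subject correlations (`NA` dropped).
#' @param alpha Significance level for the test/CI (default the
#'   Bonferroni level 0.05/40 of the 5-region x 8-parameter family).
#' @return One-row tibble: `n`, `mean_r`, `ci_lo`, `ci_hi`, `t`, `p`,
#'   `significant`.
#' @export
fisher_aggregate <- function(r, alpha = 0.05 / 40) {
  r <- r[!is.na(r)]
  if (length(r) < 2L) stop("need at least 2 non-missing correlations")
  if (any(abs(r) >= 1)) {
    warning("clamping |r| = 1 before the Fisher transform")
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  }
  z <- atanh(r)
  n <- length(z)
  mz <- mean(z)
  se <- stats::sd(z) / sqrt(n)
  tstat <- if (se == 0) {
    if (mz == 0) 0 else Inf * sign(mz)
  } else mz / se
  p <- if (is.infinite(tstat)) 0 else
    2 * stats::pt(abs(tstat), n - 1, lower.tail = FALSE)
  q <- stats::qt(1 - alpha / 2, n - 1)
  tibble::tibble(
    n = n, mean_r = tanh(mz),
    ci_lo = tanh(mz - q * se), ci_hi = tanh(mz + q * se),
    t = tstat, p = p, significant = p < alpha
  )
}

#' Rest covariation matrix: alpha power x eye parameters
#'
#' For every region x eye-parameter pair, correlates the columns within
#' each included subject, aggregates across subjects by Fisher's z and
#' flags significance at the Bonferroni level `alpha / 40`.
#'
#' @param segment_tables List of [rest_segments()] tables (excluded
#'   subjects — `attr(tab, "included")` FALSE — are skipped).
#' @param min_pairs See [subject_correlation()].
#' @param alpha Family-wise alpha (default 0.05; 40 cells).
#' @return Tibble with `region`, `parameter`, `n`, `mean_r`, `ci_lo`,
#'   `ci_hi`, `t`, `p`, `significant`.
#' @export
covariation_report <- function(segment_tables, min_pairs = 30, alpha = 0.05) {
  keep <- vapply(segment_tables, function(tt) {
    isTRUE(attr(tt, "included"))
  }, logical(1))
  segment_tables <- segment_tables[keep]
  if (length(segment_tables) < 2L) stop("fewer than 2 included subjects")
  regions <- sub("^alpha_", "",
                 grep("^alpha_", names(segment_tables[[1]]), value = TRUE))
  params <- c("pd_mean", "pd_var", "aoev_mean", "aoev_var",
              "blink_count", "fixation_count", "saccade_count",
              "microsaccade_count")
  thr_alpha <- alpha / (length(regions) * length(params))
  dplyr::bind_rows(lapply(regions, function(rg) {
    dplyr::bind_rows(lapply(params, function(pp) {
      rs <- vapply(segment_tables, function(tt) {
        subject_correlation(tt, paste0("alpha_", rg), pp, min_pairs)
      }, numeric(1))
      agg <- fisher_aggregate(rs, alpha = thr_alpha)
      dplyr::bind_cols(tibble::tibble(region = rg, parameter = pp), agg)
    }))
  }))
}

#' Heatmap of the covariation matrix
#'
#' @param report Output of [covariation_report()].
#' @return A ggplot object (regions x parameters, mean r fill, significant
#'   cells labelled in bold).
#' @export
plot_covariation <- function(report) {
  report$region <- factor(report$region, levels = c("AF", "F", "CT", "P", "O"))
  ggplot2::ggplot(report, ggplot2::aes(
    x = .data$parameter, y = .data$region, fill = .data$mean_r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$mean_r),
      fontface = ifelse(.data$significant, "bold", "plain")), size = 3) +
    ggplot2::scale_fill_gradient2(low = "darkorange", mid = "white",
                                  high = "purple4", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "EEG region", fill = "mean r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
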