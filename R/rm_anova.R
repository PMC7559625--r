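#' Repeated-measures ANOVA for fully crossed within-subject designs
#'
#' Classical univariate decomposition: replicate observations are first
#' collapsed to one cell mean per subject x cell; every within-subject
#' effect is then tested against its own subject x effect interaction,
#' `F = MS_effect / MS_error`, with partial eta squared
#' `SS_effect / (SS_effect + SS_error)`. Supports any fully crossed design
#' (2 x 2 up to 2 x 2 x 2 x 5 and beyond). Subjects with missing cells are
#' dropped with a warning. No sphericity correction is applied by default
#' (`gg = TRUE` adds Greenhouse-Geisser adjusted p values for effects with
#' more than one numerator df).
#'
#' @param data Long data frame/tibble.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns.
#' @param subject Name of the subject identifier column.
#' @param gg Add Greenhouse-Geisser corrected p values (`p_gg`, `eps_gg`).
#' @return Tibble with one row per effect: `effect`, `df_num`, `df_den`,
#'   `ss_effect`, `ss_error`, `F`, `p`, `peta_sq`, `degenerate` (TRUE when
#'   the error SS vanishes and F is reported as infinite).
#' @export
rm_anova <- function(data, dv = "value", within, subject = "subject",
                     gg = FALSE) {
  d <- tibble::as_tibble(data)[, c(subject, within, dv)]
  names(d) <- c(".subject", within, ".y")
  d <- d[stats::complete.cases(d), ]
  for (w in within) d[[w]] <- factor(d[[w]])
  d$.subject <- factor(d$.subject)

  # collapse replicates to cell means
  cells <- dplyr::group_by(d, dplyr::across(dplyr::all_of(c(".subject", within))))
  cells <- dplyr::summarise(cells, .y = mean(.data$.y), .groups = "drop")

  n_cells <- prod(vapply(cells[within], function(f) nlevels(f), integer(1)))
  counts <- table(cells$.subject)
  bad <- names(counts)[counts < n_cells]
  if (length(bad) > 0L) {
    warning("dropping ", length(bad), " subject(s) with missing cells: ",
            paste(bad, collapse = ", "))
    cells <- cells[!(cells$.subject %in% bad), ]
    cells$.subject <- droplevels(cells$.subject)
  }
  n_subj <- nlevels(cells$.subject)
  if (n_subj < 2L) stop("need at least 2 complete subjects")

  fml <- stats::as.formula(paste(
    ".y ~ .subject *", paste(within, collapse = " * ")))
  fit <- stats::aov(fml, data = cells)
  tab <- summary(fit)[[1]]
  term_names <- trimws(rownames(tab))
  term_sets <- lapply(strsplit(term_names, ":"), sort)

  find_term <- function(set) {
    hit <- which(vapply(term_sets, function(s) identical(s, sort(set)),
                        logical(1)))
    if (length(hit) != 1L) stop("internal: term lookup failed")
    hit
  }

  effects <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(within, k, simplify = FALSE)
  }), recursive = FALSE)

  rows <- lapply(effects, function(eff) {
    ie <- find_term(eff)
    ierr <- find_term(c(".subject", eff))
    ss_e <- tab[ie, "Sum Sq"]; df_e <- tab[ie, "Df"]
    ss_r <- tab[ierr, "Sum Sq"]; df_r <- tab[ierr, "Df"]
    degen <- ss_r < 1e-12 * max(ss_e, 1)
    fval <- if (degen) Inf else (ss_e / df_e) / (ss_r / df_r)
    tibble::tibble(
      effect = paste(eff, collapse = ":"),
      df_num = df_e, df_den = df_r,
      ss_effect = ss_e, ss_error = ss_r,
      F = fval,
      p = if (degen) NA_real_ else stats::pf(fval, df_e, df_r, lower.tail = FALSE),
      peta_sq = if (ss_e + ss_r > 0) ss_e / (ss_e + ss_r) else NA_real_,
      degenerate = degen
    )
  })
  out <- dplyr::bind_rows(rows)

  if (gg) {
    out$eps_gg <- NA_real_
    out$p_gg <- out$p
    for (i in seq_len(nrow(out))) {
      eff <- strsplit(out$effect[i], ":")[[1]]
      if (out$df_num[i] < 2 || out$degenerate[i]) next
      eps <- gg_epsilon(cells, eff, within)
      out$eps_gg[i] <- eps
      out$p_gg[i] <- stats::pf(out$F[i], eps * out$df_num[i],
                               eps * out$df_den[i], lower.tail = FALSE)
    }
  }
  out
}

# Greenhouse-Geisser epsilon for one effect: project each subject's cell
# means onto the effect's orthonormal contrast space and apply the
# eigenvalue formula to the resulting covariance matrix.
gg_epsilon <- function(cells, eff, within) {
  other <- setdiff(within, eff)
  m <- cells
  if (length(other) > 0L) {
    m <- dplyr::group_by(m, dplyr::across(dplyr::all_of(c(".subject", eff))))
    m <- dplyr::summarise(m, .y = mean(.data$.y), .groups = "drop")
  }
  m <- dplyr::arrange(m, dplyr::across(dplyr::all_of(c(".subject", eff))))
  q_levels <- vapply(eff, function(f) nlevels(m[[f]]), integer(1))
  n_subj <- nlevels(m$.subject)
  y <- matrix(m$.y, nrow = n_subj, byrow = TRUE)
  contr <- function(k) {
    c0 <- stats::contr.helmert(k)
    qr.Q(qr(c0))
  }
  cm <- Reduce(kronecker, lapply(q_levels, contr))
  s <- stats::cov(y %*% cm)
  lam <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  sum(lam)^2 / (length(lam) * sum(lam^2))
}
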