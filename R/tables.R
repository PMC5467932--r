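#' Group-comparison and correlation tables for a cohort
#'
#' Reproduces the statistical surface of a two-arm imaging study on a
#' subject table: (1) for every measure, the PH (all non-control subjects
#' pooled) vs control group summaries (mean, SD, n) with a two-sample t
#' test computed from those summaries; (2) for every (PET measure, echo or
#' clinical measure) pair, the Spearman rank correlation over the whole
#' cohort with its two-sided p value, using pairwise-complete
#' observations. No multiple-comparison correction is applied (pilot-study
#' convention); p values are reported at full precision together with
#' their journal-style display rounding.
#'
#' @param subjects data.frame with a `group` column (`"control"` is the
#'   reference; all other groups are pooled as PH) and numeric measure
#'   columns; typically [make_cohort()] output passed through
#'   [derive_echo()].
#' @param pet_measures,other_measures character vectors of column names to
#'   compare/correlate. Defaults cover the standard PET quantities and the
#'   echo/clinical correlates present in the table.
#' @param method `"welch"` (default) or `"pooled"` t test.
#' @return list of two data.frames: `comparisons` (one row per measure)
#'   and `correlations` (one row per PET x correlate pair).
#' @export
build_tables <- function(subjects,
                         pet_measures = NULL,
                         other_measures = NULL,
                         method = c("welch", "pooled")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(subjects), "group" %in% names(subjects))
  groups <- unique(subjects$group)
  if (length(groups) < 2 || !("control" %in% groups))
    stop("cohort must contain a control group and at least one other group",
         call. = FALSE)
  is_ph <- subjects$group != "control"

  default_pet <- c("rvedv", "rvesv", "rvef", "rv_sv", "rv_lv_ratio",
                   "lung_suvm", "lung_suvl", "lung_suvt")
  default_other <- c("rvsp", "tapse", "tei_index", "fractional_shortening",
                     "s_prime", "ra_volume", "rv_thickness", "strain",
                     "pvr_est", "ntprobnp", "x6mwd", "hrr", "camphor")
  pet_measures <- pet_measures %||% intersect(default_pet, names(subjects))
  other_measures <- other_measures %||% intersect(default_other, names(subjects))
  numeric_cols <- names(subjects)[vapply(subjects, is.numeric, logical(1))]
  compare_cols <- intersect(unique(c(pet_measures, other_measures)), numeric_cols)
  if (length(compare_cols) == 0) stop("no numeric measures found", call. = FALSE)

  comp <- lapply(compare_cols, function(mv) {
    x1 <- subjects[[mv]][is_ph]
    x2 <- subjects[[mv]][!is_ph]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2 ||
        (stats::sd(x1) == 0 && stats::sd(x2) == 0 && mean(x1) != mean(x2)))
      return(data.frame(measure = mv, mean_ph = NA, sd_ph = NA, n_ph = length(x1),
                        mean_control = NA, sd_control = NA, n_control = length(x2),
                        t = NA, df = NA, p = NA, p_display = NA, method = method))
    tt <- t_test_from_summary(mean(x1), stats::sd(x1), length(x1),
                              mean(x2), stats::sd(x2), length(x2),
                              method = method)
    data.frame(measure = mv,
               mean_ph = mean(x1), sd_ph = stats::sd(x1), n_ph = length(x1),
               mean_control = mean(x2), sd_control = stats::sd(x2),
               n_control = length(x2),
               t = tt$statistic, df = tt$df, p = tt$p_two_sided,
               p_display = tt$p_display, method = method,
               stringsAsFactors = FALSE)
  })
  comparisons <- do.call(rbind, comp)

  pairs <- expand.grid(pet = intersect(pet_measures, numeric_cols),
                       correlate = intersect(other_measures, numeric_cols),
                       stringsAsFactors = FALSE)
  corr <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- subjects[[pairs$pet[i]]]
    y <- subjects[[pairs$correlate[i]]]
    res <- tryCatch(spearman_cor(x, y), error = function(e) NULL)
    data.frame(pet = pairs$pet[i], correlate = pairs$correlate[i],
               rho = if (is.null(res)) NA_real_ else res$statistic,
               n = if (is.null(res)) sum(stats::complete.cases(x, y)) else res$n,
               p = if (is.null(res)) NA_real_ else res$p_two_sided,
               p_display = if (is.null(res)) NA_real_ else res$p_display,
               stringsAsFactors = FALSE)
  })
  correlations <- do.call(rbind, corr)
  rownames(comparisons) <- rownames(correlations) <- NULL
  list(comparisons = comparisons, correlations = correlations)
}
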