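#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = target Ct - reference Ct (e.g. GAPDH); ddCt is the mean
#' dCt of the treated group minus the mean dCt of the control group; the
#' fold change is 2^-ddCt. Adding a constant to both target and reference Ct
#' of every sample leaves the fold change unchanged.
#'
#' @param treated,control data.frames with numeric columns `target_ct` and
#'   `reference_ct` (positive, finite), one row per sample.
#' @return list with `fold_change`, `ddct`, and per-group per-sample `dct`
#'   vectors.
#' @export
#' @examples
#' ddct_fold_change(
#'   treated = data.frame(target_ct = 25, reference_ct = 20),
#'   control = data.frame(target_ct = 24, reference_ct = 20))$fold_change
ddct_fold_change <- function(treated, control) {
  get_dct <- function(df, name) {
    if (!is.data.frame(df) || nrow(df) == 0L) {
      stop(sprintf("`%s` group is empty", name), call. = FALSE)
    }
    if (!all(c("target_ct", "reference_ct") %in% names(df))) {
      stop(sprintf("`%s` needs columns target_ct and reference_ct", name),
           call. = FALSE)
    }
    ct <- c(df$target_ct, df$reference_ct)
    if (any(!is.finite(ct)) || any(ct <= 0)) {
      stop(sprintf("`%s` Ct values must be positive and finite", name),
           call. = FALSE)
    }
    df$target_ct - df$reference_ct
  }
  dct_treated <- get_dct(treated, "treated")
  dct_control <- get_dct(control, "control")
  ddct <- mean(dct_treated) - mean(dct_control)
  list(fold_change = 2^(-ddct), ddct = ddct,
       dct = list(treated = dct_treated, control = dct_control))
}

#' Two-group comparison (two-sample t-test)
#'
#' Two-sided two-sample t-test, pooled-variance by default with an
#' unequal-variance (Welch) option. Significance is conventionally called at
#' p < 0.05.
#'
#' @param x,y numeric vectors (each of length at least 2).
#' @param var_equal use the pooled-variance test (default TRUE).
#' @return list with `statistic` (t), `df`, `p_value` and `method`.
#' @export
two_group_test <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  fit <- stats::t.test(x, y, var.equal = var_equal,
                       alternative = "two.sided")
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value, method = fit$method)
}

#' Chi-square test on a frequency table
#'
#' Thin contract over `stats::chisq.test` for 2x2 (or larger) frequency
#' tables, with Yates continuity correction on by default for 2x2 tables.
#'
#' @param tab matrix of non-negative counts with at least 2 rows and
#'   2 columns.
#' @param correct apply the continuity correction (2x2 only; default TRUE).
#' @return list with `statistic`, `df`, `p_value` and `method`.
#' @export
frequency_test <- function(tab, correct = TRUE) {
  if (!is.matrix(tab) || nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("tab must be a matrix with at least 2 rows and 2 columns",
         call. = FALSE)
  }
  if (any(tab < 0) || any(!is.finite(tab))) {
    stop("tab must contain non-negative finite counts", call. = FALSE)
  }
  fit <- stats::chisq.test(tab, correct = correct)
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value, method = fit$method)
}

#' Read qPCR Ct records from CSV
#'
#' Expects columns `sample`, `group` ("control" or "treated"), `target_ct`,
#' `reference_ct`.
#'
#' @param path CSV file.
#' @return list with `treated` and `control` data.frames, ready for
#'   [ddct_fold_change()].
#' @export
read_ct_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "target_ct", "reference_ct")
  if (!all(need %in% names(df))) {
    stop(sprintf("Ct CSV needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$group), c("control", "treated"))
  if (length(bad) > 0) {
    stop(sprintf("unknown group value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  list(treated = df[df$group == "treated", , drop = FALSE],
       control = df[df$group == "control", , drop = FALSE])
}
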