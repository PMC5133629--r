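#' Housekeeping-normalized Ct (delta Ct)
#'
#' Subtracts the housekeeping Ct from the target gene Ct. With several
#' housekeeping genes their Ct values are combined by arithmetic mean, which
#' corresponds to the geometric mean of their expression levels — the
#' standard multi-reference normalization.
#'
#' @param ct_target target gene Ct (cycles), scalar or vector.
#' @param ct_housekeeping housekeeping Ct: scalar, or vector/list of several
#'   housekeeping gene Cts (averaged).
#' @return delta Ct in cycles.
#' @examples
#' delta_ct(25, 20)        # 5
#' delta_ct(25, c(19, 21)) # 5
#' @export
delta_ct <- function(ct_target, ct_housekeeping) {
  hk <- unlist(ct_housekeeping)
  if (length(hk) == 0) stop("at least one housekeeping Ct is required")
  if (any(!is.finite(ct_target)) || any(!is.finite(hk)))
    stop("Ct values must be finite")
  ct_target - mean(hk)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddCt = dCt_sample - dCt_calibrator`; fold change `2^(-ddCt)` (one PCR
#' cycle is one doubling, with no amplification-efficiency correction);
#' log fold change in the requested base.
#'
#' @param delta_ct_sample sample delta Ct (cycles).
#' @param delta_ct_calibrator calibrator delta Ct (cycles).
#' @param log_base 2 or 10, base of the reported log fold change.
#' @return list: `delta_delta_ct`, `fold_change`, `log_fold`, `log_base`.
#' @examples
#' ddct_fold_change(5, 5)$fold_change    # 1
#' ddct_fold_change(4, 5)$log_fold       # log2 fold = 1
#' @export
ddct_fold_change <- function(delta_ct_sample, delta_ct_calibrator,
                             log_base = 2) {
  if (!log_base %in% c(2, 10)) stop("log_base must be 2 or 10")
  ddct <- delta_ct_sample - delta_ct_calibrator
  fold <- 2^(-ddct)
  list(delta_delta_ct = ddct, fold_change = fold,
       log_fold = log(fold, base = log_base), log_base = log_base)
}

#' Unpaired two-sample Student's t-test on delta-Ct groups
#'
#' Pooled-variance (equal-variance) t with `n_a + n_b - 2` degrees of
#' freedom and two-sided p — the comparison applied to delta-Ct values
#' throughout the expression analysis. Its square is the two-group ANOVA F
#' of [f_test()].
#'
#' @param group_a,group_b delta-Ct vectors, each of length >= 2.
#' @return list: `t`, `p`, `df`, `degenerate` (zero pooled variance).
#' @export
compare_dct <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 values")
  sp2 <- (sum((group_a - mean(group_a))^2) +
          sum((group_b - mean(group_b))^2)) /
         (length(group_a) + length(group_b) - 2)
  if (sp2 == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, p = 1, df = length(group_a) + length(group_b) - 2,
                  degenerate = TRUE))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, p = 0,
                df = length(group_a) + length(group_b) - 2, degenerate = TRUE))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Full delta-delta-Ct analysis of a Ct table
#'
#' For every gene and condition: per-replicate delta Ct against the
#' (replicate-matched) mean housekeeping Ct, delta-delta Ct against the mean
#' calibrator delta Ct, per-replicate fold changes summarized by their mean,
#' and an unpaired two-sample Student's t-test of the condition's delta-Ct
#' values against the calibrator's.
#'
#' @param ct_table data.frame with columns `sample_id`, `condition`, `gene`,
#'   `ct_value`, `replicate`.
#' @param housekeeping character vector of housekeeping gene names present in
#'   the table (e.g. `"18S"`, or `c("B2M", "RPL13A")`).
#' @param calibrator condition name used as calibrator (e.g. `"flat"`, or a
#'   reference-cDNA pseudo-condition).
#' @param log_base 2 or 10 for the reported log fold change.
#' @return data.frame, one row per gene x non-housekeeping condition:
#'   `gene`, `condition`, `delta_ct`, `delta_delta_ct`, `fold_change`
#'   (geometric mean of per-replicate folds), `log_fold`, `t_stat`,
#'   `p_value`, `n_replicates`.
#' @export
ddct_analysis <- function(ct_table, housekeeping, calibrator, log_base = 2) {
  need <- c("sample_id", "condition", "gene", "ct_value", "replicate")
  miss <- setdiff(need, names(ct_table))
  if (length(miss)) stop("ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(ct_table$ct_value)) || any(ct_table$ct_value <= 0))
    stop("Ct values must be finite and positive")
  if (!all(housekeeping %in% ct_table$gene))
    stop("housekeeping gene(s) absent from the table")
  if (!calibrator %in% ct_table$condition)
    stop(sprintf("calibrator condition '%s' absent from the table", calibrator))

  # per-condition x replicate mean housekeeping Ct
  hk <- ct_table[ct_table$gene %in% housekeeping, ]
  hk_mean <- stats::aggregate(ct_value ~ condition + replicate, hk, mean)
  names(hk_mean)[names(hk_mean) == "ct_value"] <- "hk_ct"

  tg <- ct_table[!ct_table$gene %in% housekeeping, ]
  tg <- merge(tg, hk_mean, by = c("condition", "replicate"))
  if (nrow(tg) == 0) stop("no target gene shares a condition/replicate with housekeeping genes")
  tg$dct <- tg$ct_value - tg$hk_ct

  out <- list(); k <- 0L
  for (g in unique(tg$gene)) {
    cal_dct <- tg$dct[tg$gene == g & tg$condition == calibrator]
    if (length(cal_dct) == 0)
      stop(sprintf("gene '%s' has no calibrator measurements", g))
    for (cond in setdiff(unique(tg$condition[tg$gene == g]), calibrator)) {
      dct <- tg$dct[tg$gene == g & tg$condition == cond]
      ddct_rep <- dct - mean(cal_dct)
      # geometric mean of per-replicate folds (= 2^(-mean ddCt)): the average
      # on the log scale, and exactly 1 when a condition is its own calibrator
      fold <- 2^(-mean(ddct_rep))
      tt <- if (length(dct) >= 2 && length(cal_dct) >= 2)
        compare_dct(dct, cal_dct) else list(t = NA_real_, p = NA_real_)
      k <- k + 1L
      out[[k]] <- data.frame(gene = g, condition = cond,
                             delta_ct = mean(dct),
                             delta_delta_ct = mean(ddct_rep),
                             fold_change = fold,
                             log_fold = log(fold, base = log_base),
                             t_stat = tt$t, p_value = tt$p,
                             n_replicates = length(dct))
    }
  }
  do.call(rbind, out)
}
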