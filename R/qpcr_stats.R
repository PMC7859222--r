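# qPCR-side numerics: copies per cell, excess over endogenous levels,
# delta-delta-Ct fold change with a 2-SD outlier rule, and standard-curve
# quantification.

AVOGADRO <- 6.02214076e23

#' Copies per cell from a molar concentration and a cell volume
#'
#' copies = concentration (mol/L) x Avogadro x volume (converted from um^3
#' to L, 1 um^3 = 1e-15 L).
#'
#' @param concentration_molar concentration in mol/L (>= 0).
#' @param volume_um3 cell volume in um^3 (>= 0).
#' @return list with `concentration`, `cell_volume`, `copies_per_cell`.
#' @export
copies_per_cell <- function(concentration_molar, volume_um3) {
  if (concentration_molar < 0 || volume_um3 < 0)
    stop("concentration and volume must be non-negative")
  list(concentration = concentration_molar,
       cell_volume = volume_um3,
       copies_per_cell = concentration_molar * AVOGADRO * volume_um3 * 1e-15)
}

#' Fold excess of an introduced copy number over an endogenous upper bound
#'
#' @param cpc introduced copies per cell.
#' @param endogenous_upper_cpc upper bound of the endogenous range (> 0).
#' @return the ratio cpc / endogenous_upper_cpc.
#' @export
excess_ratio <- function(cpc, endogenous_upper_cpc) {
  if (endogenous_upper_cpc <= 0)
    stop("endogenous upper bound must be positive")
  cpc / endogenous_upper_cpc
}

#' Delta-delta-Ct log2 fold changes with a single-pass 2-SD outlier rule
#'
#' Within each (target, compartment) stratum: dCt = ct_target -
#' ct_reference; ddCt = dCt - mean(dCt of the control group in the same
#' stratum); log2FC = -ddCt. Then, within each (target, compartment, group),
#' samples with |log2FC - group mean| > `k_sd` x group SD are flagged as
#' outliers in one pass and excluded from the reported group statistics.
#'
#' @param records data.frame with columns sample_id, group, compartment,
#'   target, ct_target, ct_reference.
#' @param control_group label of the control group.
#' @param k_sd outlier cutoff in group SDs (default 2).
#' @return list of class `fold_change_result`: `samples` (per-sample dCt,
#'   ddCt, log2_fc, outlier flag), `groups` (per-stratum mean, sd, n after
#'   exclusion, outlier sample ids), `metadata` (baseline and outlier-rule
#'   description).
#' @export
delta_delta_ct <- function(records, control_group, k_sd = 2) {
  need <- c("sample_id", "group", "compartment", "target",
            "ct_target", "ct_reference")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  bad <- !is.finite(records$ct_target) | !is.finite(records$ct_reference) |
    records$ct_target <= 0 | records$ct_reference <= 0
  if (any(bad))
    stop("non-finite or non-positive Ct for samples: ",
         paste(records$sample_id[bad], collapse = ", "))
  if (!control_group %in% records$group)
    stop(sprintf("control group '%s' absent from records", control_group))
  rec <- records
  rec$delta_ct <- rec$ct_target - rec$ct_reference
  rec$delta_delta_ct <- NA_real_
  strata <- unique(rec[, c("target", "compartment")])
  for (i in seq_len(nrow(strata))) {
    in_str <- rec$target == strata$target[i] &
      rec$compartment == strata$compartment[i]
    ctrl <- in_str & rec$group == control_group
    if (!any(ctrl))
      stop(sprintf("no control sample in stratum (%s, %s)",
                   strata$target[i], strata$compartment[i]))
    rec$delta_delta_ct[in_str] <-
      rec$delta_ct[in_str] - mean(rec$delta_ct[ctrl])
  }
  rec$log2_fc <- -rec$delta_delta_ct
  rec$outlier <- FALSE
  groups <- unique(rec[, c("target", "compartment", "group")])
  gstats <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    k <- which(rec$target == groups$target[i] &
                 rec$compartment == groups$compartment[i] &
                 rec$group == groups$group[i])
    fc <- rec$log2_fc[k]
    m <- mean(fc); s <- stats::sd(fc)
    out <- if (length(k) >= 2 && is.finite(s) && s > 0)
      abs(fc - m) > k_sd * s else rep(FALSE, length(k))
    rec$outlier[k] <- out
    kept <- fc[!out]
    gstats[[i]] <- data.frame(
      target = groups$target[i], compartment = groups$compartment[i],
      group = groups$group[i],
      mean_log2_fc = if (length(kept)) mean(kept) else NA_real_,
      sd_log2_fc = if (length(kept) >= 2) stats::sd(kept) else NA_real_,
      n = length(kept),
      outliers = paste(rec$sample_id[k][out], collapse = ";")
    )
  }
  structure(list(
    samples = rec,
    groups = do.call(rbind, gstats),
    metadata = list(
      baseline = sprintf("mean delta-Ct of group '%s' per (target, compartment) stratum",
                         control_group),
      outlier_rule = sprintf(
        "single pass: |log2FC - group mean| > %g x group SD, per (target, compartment, group)",
        k_sd))
  ), class = "fold_change_result")
}

#' Standard-curve quantification of qPCR unknowns
#'
#' Fits ct = m log10(amount) + b by least squares over the standards, maps
#' unknown Ct values back through the curve, and reports the amplification
#' efficiency 10^(-1/m) - 1.
#'
#' @param standards data.frame with columns `amount` (> 0) and `ct`.
#' @param unknown_cts numeric Ct values to quantify.
#' @return list with `slope`, `intercept`, `efficiency`, `r_squared`, and
#'   `amounts` for the unknowns.
#' @export
standard_curve_quantify <- function(standards, unknown_cts = numeric(0)) {
  stopifnot(all(c("amount", "ct") %in% names(standards)))
  if (any(standards$amount <= 0))
    stop("standard amounts must be positive")
  if (length(unique(standards$amount)) < 2)
    stop("need >= 2 distinct standard amounts")
  fit <- stats::lm(ct ~ log10(amount), data = standards)
  m <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  if (!is.finite(m) || abs(m) < 1e-8)
    stop("degenerate standard curve (zero slope)")
  sst <- sum((standards$ct - mean(standards$ct))^2)
  list(slope = m, intercept = b,
       efficiency = 10^(-1 / m) - 1,
       r_squared = 1 - sum(stats::residuals(fit)^2) / sst,
       amounts = 10^((unknown_cts - b) / m))
}
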