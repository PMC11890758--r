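#' @name downstream
#' @title Downstream formulas: comparative Ct, DEG filtering, tumor volumes
NULL

#' Relative expression by the comparative-Ct (2^-ddCt) method
#'
#' dCt = target Ct - reference Ct within each condition; ddCt = dCt(treated)
#' - dCt(control); relative expression is `2^(-ddCt)` (reference gene
#' typically GAPDH).
#'
#' @param target_ct_treated,ref_ct_treated Ct of target and reference gene
#'   in the treated condition.
#' @param target_ct_control,ref_ct_control same in the control condition.
#' @return fold change (vectorized); 1 when the two dCt are equal.
#' @examples
#' ddct_fold_change(25, 20, 27, 20)  # ddCt = -2 -> 4
#' @export
ddct_fold_change <- function(target_ct_treated, ref_ct_treated,
                             target_ct_control, ref_ct_control) {
  cts <- c(target_ct_treated, ref_ct_treated, target_ct_control,
           ref_ct_control)
  if (any(!is.finite(cts))) .err("os_value_error", "non-finite Ct value")
  if (any(cts < 10 | cts > 40)) {
    warning("Ct value(s) outside the typical 10-40 cycle range")
  }
  ddct <- (target_ct_treated - ref_ct_treated) -
    (target_ct_control - ref_ct_control)
  2^(-ddct)
}

#' Comparative-Ct fold change from a long Ct table
#'
#' Replicate Ct values are averaged per (condition, gene) before the
#' dCt/ddCt arithmetic.
#'
#' @param ct_table data.frame with columns `gene`, `ct`, `condition`
#'   (values `"treated"` / `"control"`).
#' @param target target gene name.
#' @param reference reference (housekeeping) gene name.
#' @return fold change of the target, treated over control, normalized to
#'   the reference gene.
#' @export
ddct_from_table <- function(ct_table, target, reference) {
  .require_columns(ct_table, c("gene", "ct", "condition"), "Ct table")
  mean_ct <- function(gene, condition) {
    v <- ct_table$ct[ct_table$gene == gene & ct_table$condition == condition]
    if (!length(v)) {
      .err("os_data_error", "no Ct for gene ", gene, " in ", condition)
    }
    mean(v)
  }
  ddct_fold_change(mean_ct(target, "treated"), mean_ct(reference, "treated"),
                   mean_ct(target, "control"), mean_ct(reference, "control"))
}

#' Filter differential-expression results by effect size and significance
#'
#' Retains genes with `|log2fc| >= lfc_cutoff` and `padj <= padj_cutoff`
#' (both inclusive). The differential-expression model itself is upstream;
#' this consumes its result table.
#'
#' @param records data.frame with columns `gene`, `log2fc`, `padj`.
#' @param lfc_cutoff inclusive absolute log2 fold-change threshold.
#' @param padj_cutoff inclusive adjusted-p threshold.
#' @return the retained rows, original order preserved (idempotent).
#' @export
deg_filter <- function(records, lfc_cutoff = 1, padj_cutoff = 0.05) {
  .require_columns(records, c("gene", "log2fc", "padj"), "DEG table")
  if (any(records$padj < 0 | records$padj > 1, na.rm = TRUE)) {
    .err("os_value_error", "padj values must lie in [0, 1]")
  }
  keep <- !is.na(records$log2fc) & !is.na(records$padj) &
    abs(records$log2fc) >= lfc_cutoff & records$padj <= padj_cutoff
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Caliper tumor volume
#'
#' `volume = length * width^2 / 2` (mm^3). If a width exceeds its length
#' the two are swapped with a warning, so the result is invariant to
#' argument order.
#'
#' @param length,width caliper measurements in mm (positive).
#' @return volume in mm^3 (vectorized).
#' @examples
#' tumor_volume(10, 5)  # 125
#' @export
tumor_volume <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0)) {
    .err("os_value_error", "tumor dimensions must be positive and finite")
  }
  swap <- width > length
  if (any(swap)) {
    warning("width > length for ", sum(swap),
            " measurement(s); dimensions swapped")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  length * width^2 / 2
}

#' Percent reduction in tumor volume
#'
#' @param v_start volume at treatment start (mm^3, positive).
#' @param v_end volume at endpoint (mm^3).
#' @return `100 * (v_start - v_end) / v_start` (vectorized).
#' @examples
#' percent_reduction(300, 175)  # ~41.7
#' @export
percent_reduction <- function(v_start, v_end) {
  if (any(!is.finite(v_start)) || any(!is.finite(v_end))) {
    .err("os_value_error", "non-finite volume")
  }
  if (any(v_start <= 0)) {
    .err("os_value_error", "starting volume must be positive")
  }
  100 * (v_start - v_end) / v_start
}
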