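#' @name htip
#' @title Immune co-culture screen statistics
#'
#' @description
#' A phenotypic screen run in two parallel arms — cancer cells alone
#' (`minus_pbmc`) and cancer cells co-cultured with activated PBMCs
#' (`plus_pbmc`). Compound effect in each arm is normalized to percent of
#' control, \eqn{\%C = 100 (S_{compound} - S_{blank}) / (S_{positive} -
#' S_{blank})}, where the blank wells carry PBMCs/medium only with DMSO and
#' the positive wells DMSO plus cancer cells. Immune-dependent killers are
#' ranked by the selectivity index \eqn{\%C_{-PBMC} / \%C_{+PBMC}}: values
#' far above 1 mean the compound kills only when immune cells are present.
NULL

#' Percent of control
#'
#' @param s_compound compound-well signal.
#' @param s_blank blank-control signal (PBMCs/medium only, DMSO).
#' @param s_positive positive-control signal (DMSO plus cancer cells).
#' @return `100 * (s_compound - s_blank) / (s_positive - s_blank)`
#'   (vectorized). Values may exceed 100 (proliferative) or fall below 0
#'   (cytotoxic beyond blank) and are reported unclamped.
#' @export
percent_of_control <- function(s_compound, s_blank, s_positive) {
  if (any(!is.finite(s_compound)) || any(!is.finite(s_blank)) ||
      any(!is.finite(s_positive))) {
    .err("os_value_error", "non-finite signal")
  }
  if (any(s_positive == s_blank)) {
    .err("os_signal_error",
         "degenerate controls: S_positive equals S_blank")
  }
  100 * (s_compound - s_blank) / (s_positive - s_blank)
}

#' Immune-killing selectivity index
#'
#' @param pc_minus percent-of-control without PBMCs.
#' @param pc_plus percent-of-control with PBMCs.
#' @return `pc_minus / pc_plus` (vectorized). Where `pc_plus <= 0` the
#'   killing is saturated and the index is reported as `Inf` — a sentinel
#'   that ranks above every finite value — rather than an error.
#' @export
selectivity_index <- function(pc_minus, pc_plus) {
  if (any(!is.finite(pc_minus)) || any(!is.finite(pc_plus))) {
    .err("os_value_error", "non-finite percent-of-control")
  }
  ifelse(pc_plus <= 0, Inf, pc_minus / pc_plus)
}

#' Cancer-cell viability after PBMC background subtraction
#'
#' @param total_signal viability signal of the co-culture well.
#' @param pbmc_alone_signal signal of the PBMC-alone control.
#' @return `total_signal - pbmc_alone_signal`, floored at 0 (vectorized).
#' @export
cancer_viability <- function(total_signal, pbmc_alone_signal) {
  if (any(!is.finite(total_signal)) || any(!is.finite(pbmc_alone_signal))) {
    .err("os_value_error", "non-finite signal")
  }
  pmax(total_signal - pbmc_alone_signal, 0)
}

#' Filter segmented objects by area
#'
#' Keeps objects strictly larger than the threshold; with the default
#' 400 um^2 this selects the larger cancer cells over effector immune cells
#' in co-culture images (the segmentation itself happens upstream).
#'
#' @param objects data.frame with an area column (um^2).
#' @param threshold strict lower bound on area.
#' @param area_col name of the area column.
#' @return the rows with `area > threshold`.
#' @export
filter_objects_by_area <- function(objects, threshold = 400,
                                   area_col = "area") {
  .require_columns(objects, area_col, "object table")
  a <- objects[[area_col]]
  if (any(a < 0, na.rm = TRUE)) {
    .err("os_value_error", "object areas must be nonnegative")
  }
  out <- objects[!is.na(a) & a > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a four-parameter logistic (variable-slope sigmoidal) dose-response
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + 10^((log10(ic50) - log10(dose)) * hill))`
#' via Levenberg-Marquardt ([minpack.lm::nls.lm]), the same variable-slope
#' parameterization used by standard dose-response software. The midpoint is
#' estimated on the log10 scale. One parameterization covers inhibition and
#' activation: the sign of `hill` distinguishes them, and `ic50` is the
#' midpoint concentration (IC50 or EC50 depending on readout).
#'
#' @param dose positive concentrations (molar); at least 4 points spanning
#'   at least 2 log10 units.
#' @param response responses (percent or intensity).
#' @return object of class `dose_response_fit`: `top`, `bottom`, `hill`,
#'   `ic50`, `r2`, `rss`, `converged`. Non-convergence yields
#'   `converged = FALSE` with `NA` parameters, not an error.
#' @export
fit_4pl <- function(dose, response) {
  if (length(dose) != length(response)) {
    .err("os_value_error", "dose and response lengths differ")
  }
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    .err("os_value_error", "doses must be positive and finite")
  }
  if (length(dose) < 4L) {
    .err("os_data_error", "insufficient data: need >= 4 dose points")
  }
  span <- log10(max(dose) / min(dose))
  if (span < 2) {
    .err("os_data_error",
         "insufficient dose span: need >= 2 log10 units, got ",
         sprintf("%.2f", span))
  }
  ld <- log10(dose)
  hill0 <- if (stats::cor(ld, response) >= 0) 1 else -1
  mid <- (max(response) + min(response)) / 2
  lec0 <- ld[which.min(abs(response - mid))]
  resid_fn <- function(p) {
    response - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
                  (1 + 10^((p[["lec"]] - ld) * p[["hill"]])))
  }
  starts <- list(
    c(top = max(response), bottom = min(response), hill = hill0, lec = lec0),
    c(top = max(response), bottom = min(response), hill = hill0,
      lec = stats::median(ld)),
    c(top = max(response), bottom = min(response), hill = 2 * hill0,
      lec = lec0))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.list(s), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    # info codes 1-3 indicate a satisfied convergence criterion
    if (!is.null(fit) && fit$info %in% 1:3 &&
        (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(structure(list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
                          ic50 = NA_real_, r2 = NA_real_, rss = NA_real_,
                          converged = FALSE),
                     class = "dose_response_fit"))
  }
  cf <- unlist(best$par)
  rss <- best$deviance
  tss <- sum((response - mean(response))^2)
  structure(list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 hill = unname(cf["hill"]), ic50 = 10^unname(cf["lec"]),
                 r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 rss = rss, converged = TRUE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: top = %.4g, bottom = %.4g, hill = %.3g, IC50/EC50 = %.4g M (r2 = %.4f)\n",
    x$top, x$bottom, x$hill, x$ic50, x$r2))
  invisible(x)
}

#' Predict from a 4PL fit
#'
#' @param object a `dose_response_fit`.
#' @param dose concentrations at which to evaluate the fitted curve.
#' @param ... unused.
#' @return fitted responses.
#' @export
predict.dose_response_fit <- function(object, dose, ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + 10^((log10(object$ic50) - log10(dose)) * object$hill))
}

#' Normalized AUC of an effector-dose killing curve
#'
#' Trapezoidal area of viability against log10 effector dose, divided by
#' the area of a flat 100%-viability curve over the same span: 1 means no
#' killing, values toward 0 mean complete killing.
#'
#' @param effector_doses strictly increasing positive effector doses
#'   (PBMC:target ratios or counts).
#' @param viabilities percent viability at each dose.
#' @return normalized AUC in `[0, ~1]`.
#' @export
killing_curve_auc <- function(effector_doses, viabilities) {
  if (length(effector_doses) != length(viabilities)) {
    .err("os_value_error", "dose and viability lengths differ")
  }
  if (length(effector_doses) < 3L) {
    .err("os_data_error", "need >= 3 dose points")
  }
  if (any(effector_doses <= 0) || any(diff(effector_doses) <= 0)) {
    .err("os_value_error", "effector doses must be positive and strictly increasing")
  }
  l <- log10(effector_doses)
  pracma::trapz(l, viabilities) / (100 * (max(l) - min(l)))
}

#' Score an immune co-culture screen from annotated plate data
#'
#' Per plate, the blank (`role == "blank"`) and positive (`role ==
#' "positive"`) control wells are averaged; each compound well is normalized
#' to percent-of-control against its own plate's controls; per-compound %C
#' is the mean over replicate wells within each arm (`condition` column,
#' `minus_pbmc` / `plus_pbmc`); the selectivity index is computed from the
#' two arm means.
#'
#' @param annotated measurement table joined to its plate map, with a
#'   `viability_signal` channel.
#' @return data.frame with one row per compound: `compound`, `pc_minus`,
#'   `pc_plus`, `selectivity` (`Inf` flags saturated killing), `rank`
#'   (1 = most selective; ties broken by compound name).
#' @export
score_htip_screen <- function(annotated) {
  .require_columns(annotated,
                   c("plate_id", "viability_signal", "role", "construct",
                     "condition", "replicate"),
                   "annotated HTiP table")
  ctrl_mean <- function(role) {
    sub <- annotated[annotated$role == role, , drop = FALSE]
    if (nrow(sub) == 0L) {
      .err("os_data_error", "no '", role, "' control wells found")
    }
    tapply(sub$viability_signal, sub$plate_id, mean)
  }
  sb <- ctrl_mean("blank")
  sp <- ctrl_mean("positive")
  cmp <- annotated[annotated$role == "compound", , drop = FALSE]
  if (nrow(cmp) == 0L) .err("os_data_error", "no compound wells found")
  sb_w <- sb[cmp$plate_id]
  sp_w <- sp[cmp$plate_id]
  if (anyNA(sb_w) || anyNA(sp_w)) {
    .err("os_data_error", "plate(s) without both control types: ",
         paste(unique(cmp$plate_id[is.na(sb_w) | is.na(sp_w)]), collapse = ", "))
  }
  cmp$pc <- percent_of_control(cmp$viability_signal, as.numeric(sb_w),
                               as.numeric(sp_w))
  agg <- stats::aggregate(pc ~ construct + condition, data = cmp, FUN = mean)
  pcm <- agg$pc[match(paste(unique(cmp$construct), "minus_pbmc"),
                      paste(agg$construct, agg$condition))]
  pcp <- agg$pc[match(paste(unique(cmp$construct), "plus_pbmc"),
                      paste(agg$construct, agg$condition))]
  if (anyNA(pcm) || anyNA(pcp)) {
    .err("os_data_error", "compound(s) missing one screen arm")
  }
  res <- data.frame(compound = unique(cmp$construct),
                    pc_minus = pcm, pc_plus = pcp,
                    selectivity = selectivity_index(pcm, pcp),
                    stringsAsFactors = FALSE)
  ord <- order(-res$selectivity, res$compound)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Nominate immune-killing sensitizers from compound results
#'
#' @param results data.frame from [score_htip_screen()] (needs `compound`
#'   and `selectivity` columns).
#' @param si_cutoff inclusive selectivity threshold (default 2).
#' @return the nominated rows, saturated-killing (`Inf`) flags first, then
#'   selectivity descending, ties broken by compound name; `rank`
#'   renumbered.
#' @export
nominate_sensitizers <- function(results, si_cutoff = 2) {
  .require_columns(results, c("compound", "selectivity"), "compound results")
  if (nrow(results) == 0L) .err("os_data_error", "no compound results")
  hits <- results[results$selectivity >= si_cutoff, , drop = FALSE]
  hits <- hits[order(-hits$selectivity, hits$compound), , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits
}
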