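#' @name bret
#' @title BRET saturation-curve quantification and PPI scoring
#'
#' @description
#' A candidate protein pair is assayed by titrating acceptor (Venus-tagged)
#' against donor (Nluc-tagged) construct and reading the energy-transfer
#' ratio. The specific signal, net BRET, follows a one-site hyperbola in the
#' acceptor/donor expression ratio X:
#'
#' \deqn{Y = \frac{BRET_{max} \cdot X}{BRET_{50} + X}}
#'
#' where \eqn{BRET_{max}} is the saturation plateau (a proxy for the fraction
#' of donor engaged) and \eqn{BRET_{50}} the half-saturation point (a proxy
#' for relative affinity). Each replicate curve is fitted independently; the
#' per-replicate signal is the exact area under the fitted curve over a
#' common X range, and an interaction is scored by the fold-of-change (FOC)
#' of its mean AUC over the larger of two empty-vector control AUC means,
#' with an equal-variance two-tailed Student's t-test against the pooled
#' control AUCs. Hits satisfy FOC >= 4.0 and p <= 0.001 (both inclusive).
NULL

#' BRET ratio of acceptor emission over donor luminescence
#'
#' @param F535 acceptor-window intensity at 535 nm.
#' @param L460 donor luminescence at 460 nm; must be positive.
#' @return `F535 / L460` (vectorized).
#' @export
bret_ratio <- function(F535, L460) {
  if (any(!is.finite(F535)) || any(!is.finite(L460))) {
    .err("os_value_error", "non-finite intensity")
  }
  if (any(L460 <= 0)) {
    .err("os_signal_error", "degenerate donor signal: L460 must be > 0")
  }
  F535 / L460
}

#' Net BRET: pair ratio minus the donor-only control ratio
#'
#' May be negative; negative values are excluded at the fitting stage, not
#' here.
#'
#' @param ratio_pair BRET ratio of the donor + acceptor pair.
#' @param ratio_donor_only BRET ratio of the donor-only control.
#' @return `ratio_pair - ratio_donor_only` (vectorized).
#' @export
net_bret <- function(ratio_pair, ratio_donor_only) {
  if (any(!is.finite(ratio_pair)) || any(!is.finite(ratio_donor_only))) {
    .err("os_value_error", "non-finite BRET ratio")
  }
  ratio_pair - ratio_donor_only
}

#' Acceptor/donor expression ratio (Venus FI over L460)
#'
#' Venus fluorescence is read on a black plate seeded and transfected
#' side-by-side with the white luminescence plate, so FI and L460 wells are
#' paired by identical plate position; see [bret_screen_curves()] for the
#' well-pairing pipeline.
#'
#' @param venus_fi Venus fluorescence intensity.
#' @param L460 donor luminescence; must be positive.
#' @return `venus_fi / L460` (vectorized).
#' @export
acceptor_donor_ratio <- function(venus_fi, L460) {
  if (any(!is.finite(venus_fi)) || any(!is.finite(L460))) {
    .err("os_value_error", "non-finite intensity")
  }
  if (any(L460 <= 0)) {
    .err("os_signal_error", "degenerate donor signal: L460 must be > 0")
  }
  venus_fi / L460
}

#' TR-FRET ratio
#'
#' @param F665 acceptor emission at 665 nm.
#' @param F620 donor (terbium) emission at 620 nm; must be positive.
#' @return `(F665 / F620) * 1e4` (vectorized).
#' @export
trfret_ratio <- function(F665, F620) {
  if (any(!is.finite(F665)) || any(!is.finite(F620))) {
    .err("os_value_error", "non-finite intensity")
  }
  if (any(F620 <= 0)) {
    .err("os_signal_error", "degenerate donor signal: F620 must be > 0")
  }
  (F665 / F620) * 1e4
}

#' TR-FRET fold-of-change over the empty-vector control
#'
#' @param signal TR-FRET ratio of the pair.
#' @param empty_vector_signal TR-FRET ratio of the empty-vector control;
#'   must be positive.
#' @return `signal / empty_vector_signal`.
#' @export
trfret_foc <- function(signal, empty_vector_signal) {
  if (any(!is.finite(signal)) || any(!is.finite(empty_vector_signal))) {
    .err("os_value_error", "non-finite TR-FRET signal")
  }
  if (any(empty_vector_signal <= 0)) {
    .err("os_signal_error", "empty-vector TR-FRET signal must be > 0")
  }
  signal / empty_vector_signal
}

#' Build a saturation point set with the exclusion flag
#'
#' Points with negative X or negative Y are flagged `excluded` and never
#' enter a fit; raw values are kept untouched.
#'
#' @param x acceptor/donor ratios.
#' @param y net BRET values.
#' @param replicate replicate index (recycled).
#' @return data.frame with columns `x`, `y`, `replicate`, `excluded`.
#' @export
saturation_points <- function(x, y, replicate = 1L) {
  if (length(x) != length(y)) .err("os_value_error", "x and y lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    .err("os_value_error", "non-finite saturation point")
  }
  data.frame(x = x, y = y, replicate = as.integer(replicate),
             excluded = x < 0 | y < 0)
}

#' Fit the hyperbolic BRET saturation model
#'
#' Least-squares fit of `y = bret_max * x / (bret50 + x)` by variable
#' projection: for a candidate `bret50` the optimal `bret_max` has a closed
#' form, so the residual sum of squares is minimized by a 1-D Brent search
#' on `log(bret50)`. This is deterministic and needs no starting values.
#' Points flagged `excluded` (negative X or Y) are dropped before fitting.
#'
#' @param x either a numeric vector of acceptor/donor ratios, or a
#'   data.frame with columns `x`, `y` and optionally `excluded`.
#' @param y net BRET values when `x` is a vector.
#' @return object of class `saturation_fit`: `bret_max`, `bret50`,
#'   `n_points_used`, `rss`, `converged`. A flat all-zero curve yields
#'   `bret_max = 0` with `bret50 = NA` and `converged = FALSE` (the
#'   half-saturation point is unidentifiable).
#' @examples
#' x <- c(0.25, 0.5, 1, 2, 4, 8)
#' fit_saturation(x, 0.2 * x / (1 + x))
#' @export
fit_saturation <- function(x, y = NULL) {
  pts <- if (is.data.frame(x)) x else data.frame(x = x, y = y)
  if (is.null(pts$excluded)) pts$excluded <- pts$x < 0 | pts$y < 0
  use <- !pts$excluded & is.finite(pts$x) & is.finite(pts$y)
  xu <- pts$x[use]
  yu <- pts$y[use]
  n <- length(xu)
  if (n < 3L || length(unique(xu)) < 2L) {
    .err("os_data_error",
         "insufficient data: need >= 3 non-excluded points with >= 2 distinct x")
  }
  if (max(yu) <= 0) {
    return(structure(list(bret_max = 0, bret50 = NA_real_,
                          n_points_used = n, rss = sum(yu^2),
                          converged = FALSE),
                     class = "saturation_fit"))
  }
  xmax <- max(xu)
  rss_at <- function(lb50) {
    w <- xu / (exp(lb50) + xu)
    bhat <- max(0, sum(w * yu) / sum(w * w))
    sum((yu - bhat * w)^2)
  }
  lo <- log(1e-4 * xmax)
  hi <- log(1e4 * xmax)
  opt <- stats::optimize(rss_at, c(lo, hi), tol = 1e-10)
  b50 <- exp(opt$minimum)
  w <- xu / (b50 + xu)
  bmax <- max(0, sum(w * yu) / sum(w * w))
  rss <- sum((yu - bmax * w)^2)
  at_boundary <- opt$minimum < lo + 1e-6 || opt$minimum > hi - 1e-6
  structure(list(bret_max = bmax, bret50 = b50, n_points_used = n,
                 rss = rss, converged = is.finite(rss) && !at_boundary),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf(
    "Saturation fit: BRETmax = %.4g, BRET50 = %.4g (n = %d, RSS = %.3g, %s)\n",
    x$bret_max, x$bret50, x$n_points_used, x$rss,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Exact area under a fitted saturation curve
#'
#' Closed-form integral of the hyperbola over `[0, x_max]`:
#' `bret_max * (x_max - bret50 * log((bret50 + x_max) / bret50))`.
#'
#' @param fit a `saturation_fit`, or a numeric `bret_max` value.
#' @param x_max upper integration bound (positive).
#' @param bret50 half-saturation value when `fit` is numeric.
#' @return the AUC; 0 whenever `bret_max` is 0 (any `x_max`).
#' @export
saturation_auc <- function(fit, x_max, bret50 = NULL) {
  if (inherits(fit, "saturation_fit")) {
    bmax <- fit$bret_max
    b50 <- fit$bret50
  } else {
    bmax <- fit
    b50 <- bret50
  }
  if (any(!is.finite(x_max)) || any(x_max <= 0)) {
    .err("os_value_error", "x_max must be positive")
  }
  out <- bmax * (x_max - b50 * log((b50 + x_max) / b50))
  out[bmax == 0] <- 0
  out
}

.curve_list <- function(curves) {
  if (is.data.frame(curves)) {
    if (!"replicate" %in% names(curves)) return(list(curves))
    return(split(curves, curves$replicate))
  }
  curves
}

.usable_xmax <- function(d) {
  excl <- if (!is.null(d$excluded)) d$excluded else (d$x < 0 | d$y < 0)
  if (all(excl)) NA_real_ else max(d$x[!excl])
}

#' Score one candidate interaction from replicate saturation curves
#'
#' Each replicate curve (the pair plus the two empty-vector controls) is
#' fitted independently; per-replicate AUCs are integrated to a common bound
#' `x_max` — the minimum over all curves of each curve's largest usable
#' (non-excluded) X — so every AUC covers the same domain. FOC is the mean
#' pair AUC over the larger control AUC mean; significance is an
#' equal-variance two-tailed Student's t-test of the pair AUC replicates
#' against the pooled control AUC replicates, unadjusted.
#'
#' @param ppi_curves list of per-replicate data.frames (`x`, `y`), or a
#'   single data.frame with a `replicate` column (split internally).
#' @param ctrl1_curves,ctrl2_curves same structure for the two empty-vector
#'   control series.
#' @param foc_cutoff,p_cutoff inclusive hit thresholds.
#' @param donor,acceptor labels carried into the result.
#' @return object of class `ppi_score` (see [score_ppi_auc()]).
#' @export
score_ppi <- function(ppi_curves, ctrl1_curves, ctrl2_curves,
                      foc_cutoff = 4, p_cutoff = 0.001,
                      donor = NA_character_, acceptor = NA_character_) {
  ppi <- .curve_list(ppi_curves)
  c1 <- .curve_list(ctrl1_curves)
  c2 <- .curve_list(ctrl2_curves)
  all_curves <- c(ppi, c1, c2)
  xm <- vapply(all_curves, .usable_xmax, numeric(1))
  if (anyNA(xm)) {
    .err("os_data_error", "a replicate curve has no usable points")
  }
  x_max <- min(xm)
  if (x_max <= 0) .err("os_data_error", "common integration bound is not positive")
  auc_of <- function(d) {
    tryCatch(saturation_auc(fit_saturation(d), x_max),
             error = function(e) NA_real_)
  }
  auc_ppi <- vapply(ppi, auc_of, numeric(1))
  auc_c1 <- vapply(c1, auc_of, numeric(1))
  auc_c2 <- vapply(c2, auc_of, numeric(1))
  score_ppi_auc(auc_ppi[!is.na(auc_ppi)], auc_c1[!is.na(auc_c1)],
                auc_c2[!is.na(auc_c2)], foc_cutoff = foc_cutoff,
                p_cutoff = p_cutoff, donor = donor, acceptor = acceptor,
                x_max = x_max)
}

#' Score an interaction from per-replicate AUC values
#'
#' Core of [score_ppi()], exposed so that AUC-level results can be scored
#' directly. FOC = `mean(auc_ppi) / max(mean(auc_ctrl1), mean(auc_ctrl2))`;
#' p from `t.test(auc_ppi, c(auc_ctrl1, auc_ctrl2), var.equal = TRUE)`.
#' If neither control mean is positive the score is flagged non-callable
#' (`callable = FALSE`, FOC and hit status `NA`).
#'
#' @param auc_ppi,auc_ctrl1,auc_ctrl2 per-replicate AUC vectors; each
#'   control needs at least 2 usable replicates.
#' @inheritParams score_ppi
#' @param x_max common integration bound, carried into the result.
#' @return object of class `ppi_score` with fields `donor`, `acceptor`,
#'   `auc_ppi`, `auc_ctrl1`, `auc_ctrl2`, `x_max`, `foc`, `p_foc`,
#'   `is_hit`, `callable`.
#' @export
score_ppi_auc <- function(auc_ppi, auc_ctrl1, auc_ctrl2,
                          foc_cutoff = 4, p_cutoff = 0.001,
                          donor = NA_character_, acceptor = NA_character_,
                          x_max = NA_real_) {
  if (length(auc_ppi) < 2L) {
    .err("os_data_error", "insufficient replicates: need >= 2 usable PPI AUCs")
  }
  if (length(auc_ctrl1) < 2L || length(auc_ctrl2) < 2L) {
    .err("os_data_error",
         "insufficient replicates: each control needs >= 2 usable AUCs")
  }
  denom <- max(mean(auc_ctrl1), mean(auc_ctrl2))
  pooled <- c(auc_ctrl1, auc_ctrl2)
  callable <- is.finite(denom) && denom > 0
  foc <- if (callable) mean(auc_ppi) / denom else NA_real_
  p_foc <- tryCatch(
    stats::t.test(auc_ppi, pooled, var.equal = TRUE)$p.value,
    error = function(e) {
      # zero-variance degenerate case: identical groups are null, else certain
      if (isTRUE(all.equal(mean(auc_ppi), mean(pooled)))) 1 else 0
    })
  is_hit <- if (callable) foc >= foc_cutoff && p_foc <= p_cutoff else NA
  structure(list(donor = donor, acceptor = acceptor,
                 auc_ppi = auc_ppi, auc_ctrl1 = auc_ctrl1,
                 auc_ctrl2 = auc_ctrl2, x_max = x_max,
                 foc = foc, p_foc = p_foc, is_hit = is_hit,
                 callable = callable),
            class = "ppi_score")
}

#' @export
as.data.frame.ppi_score <- function(x, ...) {
  data.frame(donor = x$donor, acceptor = x$acceptor,
             n_rep_ppi = length(x$auc_ppi),
             auc_ppi = mean(x$auc_ppi),
             auc_ctrl1 = mean(x$auc_ctrl1),
             auc_ctrl2 = mean(x$auc_ctrl2),
             x_max = x$x_max, foc = x$foc, p_foc = x$p_foc,
             is_hit = x$is_hit, callable = x$callable,
             stringsAsFactors = FALSE)
}

#' @export
print.ppi_score <- function(x, ...) {
  cat(sprintf("PPI score %s ~ %s: FOC = %.3g, p = %.3g, hit = %s\n",
              x$donor, x$acceptor, x$foc, x$p_foc, x$is_hit))
  invisible(x)
}

#' Extract hit calls from a table of PPI scores
#'
#' @param scores a data.frame of scores (one row per pair, as produced by
#'   [score_bret_screen()]) or a list of `ppi_score` objects.
#' @return rows with `is_hit = TRUE`, sorted by FOC descending; ties broken
#'   by smaller p, then acceptor name (deterministic order).
#' @export
call_hits <- function(scores) {
  if (!is.data.frame(scores)) {
    scores <- do.call(rbind, lapply(scores, as.data.frame))
  }
  if (nrow(scores) == 0L) .err("os_data_error", "no scores to call hits from")
  hits <- scores[scores$is_hit %in% TRUE, , drop = FALSE]
  hits <- hits[order(-hits$foc, hits$p_foc, hits$acceptor), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Assemble per-construct saturation curves from annotated plate data
#'
#' Consumes a measurement table joined to its plate map (see
#' [join_plate_map()]) carrying `L460`, `F535` and `venus_fi` channels. The
#' donor-only BRET baseline is estimated per (plate, replicate) as the mean
#' raw ratio of the map's `blank` wells; net BRET of every titration well is
#' its raw ratio minus that baseline, and X is `venus_fi / L460` of the same
#' well (black/white plates seeded side-by-side share positions, so both
#' channels sit on one logical plate ID).
#'
#' @param annotated annotated measurement data.frame.
#' @return data.frame with `plate_id`, `construct`, `role`, `replicate`,
#'   `x`, `y`, `excluded` for all `ppi`, `ctrl_donor_only` and
#'   `ctrl_acceptor_only` wells.
#' @export
bret_screen_curves <- function(annotated) {
  .require_columns(annotated,
                   c("plate_id", "well", "L460", "F535", "venus_fi",
                     "role", "construct", "replicate"),
                   "annotated BRET table")
  blanks <- annotated[annotated$role == "blank", , drop = FALSE]
  if (nrow(blanks) == 0L) {
    .err("os_data_error", "no donor-only baseline (role 'blank') wells found")
  }
  blank_ratio <- bret_ratio(blanks$F535, blanks$L460)
  bkey <- paste(blanks$plate_id, blanks$replicate)
  baseline <- tapply(blank_ratio, bkey, mean)

  series <- annotated[annotated$role %in%
                        c("ppi", "ctrl_donor_only", "ctrl_acceptor_only"), ,
                      drop = FALSE]
  skey <- paste(series$plate_id, series$replicate)
  base <- baseline[skey]
  if (anyNA(base)) {
    .err("os_join_error", "no baseline wells for plate/replicate: ",
         paste(unique(skey[is.na(base)]), collapse = ", "))
  }
  ratio <- bret_ratio(series$F535, series$L460)
  x <- acceptor_donor_ratio(series$venus_fi, series$L460)
  y <- net_bret(ratio, as.numeric(base))
  data.frame(plate_id = series$plate_id, construct = series$construct,
             role = series$role, replicate = series$replicate,
             x = x, y = y, excluded = x < 0 | y < 0,
             stringsAsFactors = FALSE)
}

#' Score every candidate interaction in a BRET screen
#'
#' Groups the curve table by plate, takes each plate's two empty-vector
#' control series (`ctrl_acceptor_only` = empty donor, `ctrl_donor_only` =
#' empty acceptor), and scores every `ppi` construct on that plate against
#' them with [score_ppi()].
#'
#' @param curves curve table from [bret_screen_curves()].
#' @param foc_cutoff,p_cutoff inclusive hit thresholds.
#' @param donor label for the shared donor construct.
#' @return data.frame with one row per scored construct.
#' @export
score_bret_screen <- function(curves, foc_cutoff = 4, p_cutoff = 0.001,
                              donor = "donor") {
  out <- list()
  for (pid in unique(curves$plate_id)) {
    pc <- curves[curves$plate_id == pid, , drop = FALSE]
    c1 <- pc[pc$role == "ctrl_acceptor_only", , drop = FALSE]
    c2 <- pc[pc$role == "ctrl_donor_only", , drop = FALSE]
    if (nrow(c1) == 0L || nrow(c2) == 0L) {
      .err("os_data_error", "plate ", pid, " lacks an empty-vector control series")
    }
    for (g in unique(pc$construct[pc$role == "ppi"])) {
      gc <- pc[pc$role == "ppi" & pc$construct == g, , drop = FALSE]
      sc <- score_ppi(split(gc, gc$replicate),
                      split(c1, c1$replicate),
                      split(c2, c2$replicate),
                      foc_cutoff = foc_cutoff, p_cutoff = p_cutoff,
                      donor = donor, acceptor = g)
      out[[length(out) + 1L]] <- as.data.frame(sc)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full BRET screen pipeline from plate tables
#'
#' Convenience wrapper: join map, assemble curves, score, in one call.
#'
#' @param measurements measurement data.frame (wide, with `L460`, `F535`,
#'   `venus_fi`).
#' @param map plate map data.frame.
#' @inheritParams score_bret_screen
#' @return score table from [score_bret_screen()].
#' @export
run_bret_screen <- function(measurements, map, foc_cutoff = 4,
                            p_cutoff = 0.001, donor = "donor") {
  ann <- join_plate_map(measurements, map)
  score_bret_screen(bret_screen_curves(ann), foc_cutoff = foc_cutoff,
                    p_cutoff = p_cutoff, donor = donor)
}
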