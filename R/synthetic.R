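#' @name synthetic_data
#' @title Seeded synthetic screen generators with known ground truth
#'
#' @description
#' Generators that emit plate tables, plate maps and truth records with the
#' statistical structure the scoring pipeline assumes: hyperbolic BRET
#' titration series with additive Gaussian noise and dual empty-vector
#' controls in four replicates; paired -PBMC/+PBMC co-culture viability
#' plates with lognormal multiplicative noise and planted immune-dependent
#' killers; and 4PL dose-response tables. Every generator is a pure
#' function of its specification (seed included): repeated calls are
#' identical, and the caller's RNG state is left untouched.
NULL

#' Specification of a synthetic BRET interaction screen
#'
#' Defaults mirror the screen scale this calculus was designed for: an
#' 85-ORF acceptor library with 16 true interactors, four replicate
#' titration series per construct, two empty-vector control series per
#' plate, and a six-point acceptor/donor grid. Hit plateaus (`bmax_hit`)
#' default to Uniform(0.1, 0.3); nulls and controls sit at a small bystander
#' plateau `bmax_null`. Assay noise is additive Gaussian on net BRET with
#' sd `noise_sd_frac * bmax_scale` — a plate-wide noise floor expressed as a
#' fraction of the typical hit plateau, shared by hits, nulls and controls.
#'
#' @param n_genes number of acceptor constructs.
#' @param n_interactors number of true interactors among them.
#' @param genes,interactors explicit names (defaults generated; interactors
#'   default to the first `n_interactors` genes).
#' @param bmax_hit plateau of true interactors: a single value, or a
#'   length-2 uniform range.
#' @param bmax_null bystander plateau of non-interactors and controls.
#' @param bret50_range log-uniform range for hit/null half-saturation.
#' @param bret50_ctrl half-saturation of the control series.
#' @param noise_sd_frac noise sd as a fraction of `bmax_scale`.
#' @param bmax_scale reference plateau defining the assay noise floor.
#' @param n_replicates replicate titration series per construct.
#' @param x_grid acceptor/donor titration values.
#' @param seed integer seed; fully determines the generated screen.
#' @return object of class `bret_screen_truth`.
#' @export
bret_screen_truth <- function(n_genes = 85, n_interactors = 16,
                              genes = sprintf("OI%03d", seq_len(n_genes)),
                              interactors = genes[seq_len(n_interactors)],
                              bmax_hit = c(0.1, 0.3), bmax_null = 0.02,
                              bret50_range = c(0.5, 4), bret50_ctrl = 1,
                              noise_sd_frac = 0.05, bmax_scale = 0.2,
                              n_replicates = 4,
                              x_grid = c(0.25, 0.5, 1, 2, 4, 8),
                              seed = 1) {
  if (!all(interactors %in% genes)) {
    .err("os_config_error", "interactors must be a subset of genes")
  }
  if (!length(x_grid) || any(x_grid <= 0)) {
    .err("os_config_error", "x_grid must be positive")
  }
  if (length(bmax_hit) > 2 || any(bmax_hit < 0) || bmax_null < 0 ||
      noise_sd_frac < 0 || any(bret50_range <= 0)) {
    .err("os_config_error", "invalid distribution specification")
  }
  structure(list(genes = genes, interactors = interactors,
                 bmax_hit = bmax_hit, bmax_null = bmax_null,
                 bret50_range = bret50_range, bret50_ctrl = bret50_ctrl,
                 noise_sd_frac = noise_sd_frac, bmax_scale = bmax_scale,
                 n_replicates = as.integer(n_replicates),
                 x_grid = x_grid, seed = as.integer(seed)),
            class = "bret_screen_truth")
}

#' Simulate replicate saturation curves from known parameters
#'
#' Draws `y = bmax * x / (bret50 + x) + N(0, noise_sd)` on the given grid.
#' Uses the current RNG stream unless `seed` is given.
#'
#' @param bmax,bret50 generating hyperbola parameters.
#' @param x_grid acceptor/donor values.
#' @param noise_sd additive Gaussian noise sd on net BRET.
#' @param n_replicates number of curves.
#' @param seed optional seed (RNG state restored afterwards).
#' @return list of `n_replicates` data.frames with columns `x`, `y`.
#' @export
simulate_saturation_curves <- function(bmax, bret50, x_grid, noise_sd,
                                       n_replicates = 4, seed = NULL) {
  draw <- function() {
    lapply(seq_len(n_replicates), function(r) {
      data.frame(x = x_grid,
                 y = bmax * x_grid / (bret50 + x_grid) +
                   stats::rnorm(length(x_grid), 0, noise_sd))
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Sequential well assignment within one plate.
.plate_wells <- function(n, geometry) {
  dims <- .plate_dims(geometry)
  if (n > dims[["rows"]] * dims[["cols"]]) {
    .err("os_layout_error", "plate overflow: ", n, " wells requested")
  }
  idx <- seq_len(n) - 1L
  well_id(idx %/% dims[["cols"]] + 1L, idx %% dims[["cols"]] + 1L)
}

#' Generate a synthetic BRET interaction screen
#'
#' Emits white/black-plate channel intensities (`L460`, `F535`, `venus_fi`
#' on one logical plate ID, mirroring side-by-side seeded plates), a plate
#' map, and the gene-level truth record. Each 1536-well plate carries a
#' subset of genes (all replicates), its own two empty-vector control
#' series, and donor-only baseline (`blank`) wells per replicate. Donor
#' luminescence varies lognormally around 1e5 counts; the raw BRET ratio is
#' a donor-only baseline of 0.10 plus the noisy net-BRET value.
#'
#' @param truth a [bret_screen_truth()] specification.
#' @return list of class `bret_screen_data`: `measurements`, `map`, `truth`
#'   (data.frame with per-gene `interactor`, `bmax`, `bret50`).
#' @export
generate_bret_screen <- function(truth) {
  stopifnot(inherits(truth, "bret_screen_truth"))
  withr::with_seed(truth$seed, {
    genes <- truth$genes
    ng <- length(genes)
    nrep <- truth$n_replicates
    npts <- length(truth$x_grid)
    noise_sd <- truth$noise_sd_frac * truth$bmax_scale
    r0 <- 0.10          # donor-only baseline BRET ratio
    n_blank <- 8L       # baseline wells per replicate group

    is_hit <- genes %in% truth$interactors
    bmax <- ifelse(is_hit,
                   if (length(truth$bmax_hit) == 2)
                     stats::runif(ng, truth$bmax_hit[1], truth$bmax_hit[2])
                   else truth$bmax_hit,
                   truth$bmax_null)
    b50 <- exp(stats::runif(ng, log(truth$bret50_range[1]),
                            log(truth$bret50_range[2])))
    truth_df <- data.frame(gene = genes, interactor = is_hit,
                           bmax = bmax, bret50 = b50,
                           stringsAsFactors = FALSE)

    ctrl_overhead <- 2L * nrep * npts + n_blank * nrep
    per_gene <- nrep * npts
    genes_per_plate <- (1536L - ctrl_overhead) %/% per_gene
    plate_of <- (seq_len(ng) - 1L) %/% genes_per_plate + 1L

    meas <- list()
    map <- list()
    for (p in unique(plate_of)) {
      pid <- sprintf("P%02d", p)
      pgenes <- which(plate_of == p)
      series <- rbind(
        expand.grid(construct = "BLANK", role = "blank",
                    replicate = seq_len(nrep), point = seq_len(n_blank),
                    stringsAsFactors = FALSE),
        expand.grid(construct = "EV_NLUC", role = "ctrl_acceptor_only",
                    replicate = seq_len(nrep), point = seq_len(npts),
                    stringsAsFactors = FALSE),
        expand.grid(construct = "EV_VENUS", role = "ctrl_donor_only",
                    replicate = seq_len(nrep), point = seq_len(npts),
                    stringsAsFactors = FALSE))
      for (g in pgenes) {
        series <- rbind(series,
                        expand.grid(construct = genes[g], role = "ppi",
                                    replicate = seq_len(nrep),
                                    point = seq_len(npts),
                                    stringsAsFactors = FALSE))
      }
      nw <- nrow(series)
      wells <- .plate_wells(nw, 1536)
      L460 <- stats::rlnorm(nw, log(1e5), sqrt(log(1 + 0.1^2)))
      blank_row <- series$role == "blank"
      x <- ifelse(blank_row, 0, truth$x_grid[series$point])
      gi <- match(series$construct, genes)
      bm <- ifelse(blank_row, 0,
                   ifelse(is.na(gi), truth$bmax_null, bmax[gi]))
      bb <- ifelse(is.na(gi), truth$bret50_ctrl, b50[gi])
      y <- ifelse(blank_row, 0, bm * x / (bb + x)) +
        stats::rnorm(nw, 0, noise_sd)
      meas[[p]] <- data.frame(plate_id = pid, well = wells,
                              L460 = L460, F535 = pmax((r0 + y) * L460, 0),
                              venus_fi = x * L460,
                              stringsAsFactors = FALSE)
      map[[p]] <- data.frame(plate_id = pid, well = wells,
                             role = series$role, construct = series$construct,
                             condition = NA_character_,
                             replicate = series$replicate,
                             stringsAsFactors = FALSE)
    }
    structure(list(measurements = do.call(rbind, meas),
                   map = do.call(rbind, map),
                   truth = truth_df),
              class = "bret_screen_data")
  })
}

#' Specification of a synthetic immune co-culture screen
#'
#' Defaults mirror a 2036-compound library screen with three planted
#' immune-dependent sensitizers of true selectivity 5, three replicate
#' wells per compound per arm on 384-well plates, and 10% lognormal
#' (coefficient-of-variation) assay noise on viability signals.
#'
#' @param n_compounds library size.
#' @param n_sensitizers planted immune-dependent killers.
#' @param compounds,sensitizers explicit names (sensitizers default to the
#'   first `n_sensitizers` compounds).
#' @param true_si true selectivity index of each sensitizer (recycled).
#' @param assay_noise_cv lognormal CV of well signals.
#' @param n_replicates replicate wells per compound per arm.
#' @param plate_geometry 384 (default) or another supported geometry.
#' @param s_blank,s_positive mean signals of the blank (PBMCs/medium only)
#'   and positive (DMSO + cancer cells) control wells.
#' @param seed integer seed.
#' @return object of class `htip_screen_truth`.
#' @export
htip_screen_truth <- function(n_compounds = 2036, n_sensitizers = 3,
                              compounds = sprintf("CMPD%04d",
                                                  seq_len(n_compounds)),
                              sensitizers = compounds[seq_len(n_sensitizers)],
                              true_si = 5, assay_noise_cv = 0.10,
                              n_replicates = 3, plate_geometry = 384,
                              s_blank = 2000, s_positive = 20000,
                              seed = 1) {
  if (!all(sensitizers %in% compounds)) {
    .err("os_config_error", "sensitizers must be a subset of compounds")
  }
  if (assay_noise_cv < 0 || any(true_si <= 0) || s_positive == s_blank) {
    .err("os_config_error", "invalid screen specification")
  }
  .plate_dims(plate_geometry)
  structure(list(compounds = compounds, sensitizers = sensitizers,
                 true_si = rep_len(true_si, length(sensitizers)),
                 assay_noise_cv = assay_noise_cv,
                 n_replicates = as.integer(n_replicates),
                 plate_geometry = plate_geometry,
                 s_blank = s_blank, s_positive = s_positive,
                 seed = as.integer(seed)),
            class = "htip_screen_truth")
}

#' Generate a synthetic immune co-culture (HTiP) screen
#'
#' Inert compounds have true percent-of-control ~100 in both arms;
#' sensitizers keep ~100 in the cancer-alone arm and drop to `100 /
#' true_si` in the +PBMC arm. Well signals are
#' `s_blank + pc/100 * (s_positive - s_blank)` times a mean-1 lognormal
#' noise factor; each plate carries 16 blank and 16 positive control wells.
#'
#' @param truth an [htip_screen_truth()] specification.
#' @return list of class `htip_screen_data`: `measurements` (with
#'   `viability_signal`), `map`, `truth` (per-compound `sensitizer`,
#'   `true_si`).
#' @export
generate_htip_screen <- function(truth) {
  stopifnot(inherits(truth, "htip_screen_truth"))
  withr::with_seed(truth$seed, {
    cmpds <- truth$compounds
    nc <- length(cmpds)
    cv <- truth$assay_noise_cv
    sdlog <- sqrt(log(1 + cv^2))
    dims <- .plate_dims(truth$plate_geometry)
    cap <- dims[["rows"]] * dims[["cols"]]
    n_ctrl <- 16L
    per_plate <- cap - 2L * n_ctrl
    n_plates <- ceiling(nc / per_plate)

    si_of <- rep(1, nc)
    si_of[match(truth$sensitizers, cmpds)] <- truth$true_si
    truth_df <- data.frame(compound = cmpds,
                           sensitizer = cmpds %in% truth$sensitizers,
                           true_si = si_of, stringsAsFactors = FALSE)

    noise <- function(n) {
      if (cv == 0) rep(1, n) else stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    }
    meas <- list()
    map <- list()
    k <- 0L
    for (arm in c("minus_pbmc", "plus_pbmc")) {
      for (rep_i in seq_len(truth$n_replicates)) {
        for (p in seq_len(n_plates)) {
          pid <- sprintf("%s_R%d_P%02d",
                         if (arm == "minus_pbmc") "M" else "P", rep_i, p)
          idx <- ((p - 1L) * per_plate + 1L):min(p * per_plate, nc)
          pc_true <- if (arm == "plus_pbmc") 100 / si_of[idx] else
            rep(100, length(idx))
          roles <- c(rep("blank", n_ctrl), rep("positive", n_ctrl),
                     rep("compound", length(idx)))
          constructs <- c(rep("DMSO_BLANK", n_ctrl),
                          rep("DMSO_CELLS", n_ctrl), cmpds[idx])
          mu <- c(rep(truth$s_blank, n_ctrl),
                  rep(truth$s_positive, n_ctrl),
                  truth$s_blank + pc_true / 100 *
                    (truth$s_positive - truth$s_blank))
          nw <- length(mu)
          wells <- .plate_wells(nw, truth$plate_geometry)
          k <- k + 1L
          meas[[k]] <- data.frame(plate_id = pid, well = wells,
                                  viability_signal = mu * noise(nw),
                                  stringsAsFactors = FALSE)
          map[[k]] <- data.frame(plate_id = pid, well = wells,
                                 role = roles, construct = constructs,
                                 condition = arm, replicate = rep_i,
                                 stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(measurements = do.call(rbind, meas),
                   map = do.call(rbind, map),
                   truth = truth_df),
              class = "htip_screen_data")
  })
}

#' Generate a synthetic 4PL dose-response table
#'
#' Responses are drawn from the variable-slope logistic model with
#' multiplicative Gaussian noise (`response * (1 + N(0, noise_cv))`).
#'
#' @param ic50 midpoint concentration (molar).
#' @param top,bottom,hill remaining 4PL parameters.
#' @param n_doses number of dose points, evenly log-spaced.
#' @param dose_range length-2 molar range (default 1 nM to 30 uM).
#' @param noise_cv multiplicative noise fraction.
#' @param seed integer seed.
#' @return list of class `dose_response_data`: `data` (columns `dose`,
#'   `response`) and `truth` (the generating parameters).
#' @export
generate_dose_response <- function(ic50, top = 100, bottom = 0, hill = 1,
                                   n_doses = 8,
                                   dose_range = c(1e-9, 30e-6),
                                   noise_cv = 0.05, seed = 1) {
  if (any(dose_range <= 0) || dose_range[2] <= dose_range[1]) {
    .err("os_config_error", "dose range must be positive and increasing")
  }
  if (ic50 <= 0) .err("os_config_error", "ic50 must be positive")
  withr::with_seed(seed, {
    dose <- 10^seq(log10(dose_range[1]), log10(dose_range[2]),
                   length.out = n_doses)
    mu <- bottom + (top - bottom) /
      (1 + 10^((log10(ic50) - log10(dose)) * hill))
    response <- mu * (1 + stats::rnorm(n_doses, 0, noise_cv))
    structure(list(data = data.frame(dose = dose, response = response),
                   truth = list(top = top, bottom = bottom, hill = hill,
                                ic50 = ic50, noise_cv = noise_cv,
                                seed = seed)),
              class = "dose_response_data")
  })
}
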