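# Synthetic dose-response data. Monotherapy follows Hill curves; pairwise
# combination surfaces follow the Bliss independence null (product of the
# two growth fractions) plus a localized Gaussian synergy/antagonism bump in
# log-dose space and measurement noise. Cell-line expression profiles are
# low-rank latent-factor draws, and the same latent factors shift each
# cell's drug EC50s, so expression is genuinely informative about response.

# a static library of valid small-molecule SMILES strings; drugs beyond the
# list reuse it with simple chain-growth (appended carbons) for uniqueness
.smiles_library <- c(
  "CCO", "CC(=O)O", "c1ccccc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  "CC(=O)Oc1ccccc1C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CCN(CC)CC",
  "C1CCCCC1", "c1ccncc1", "CC(N)C(=O)O", "NC(=O)c1ccccc1", "COc1ccccc1",
  "CC(C)O", "OCC(O)CO", "Clc1ccccc1", "CCOC(=O)C", "N#Cc1ccccc1",
  "CC(=O)Nc1ccc(O)cc1", "OC(=O)c1ccccc1O", "CSCC(N)C(=O)O"
)

#' Hill monotherapy response
#'
#' The sigmoidal single-drug growth fraction
#' \deqn{g(r) = 1 / (1 + (r/\mathrm{EC50})^h)}
#' with midpoint `ec50` and slope `h`; strictly decreasing in dose, with
#' values in (0, 1).
#'
#' @param dose Positive dose(s).
#' @param ec50 Positive midpoint concentration.
#' @param slope Positive Hill slope.
#' @return Growth fraction(s) in (0, 1).
#' @export
hill_response <- function(dose, ec50, slope) {
  if (any(dose <= 0) || any(ec50 <= 0) || any(slope <= 0)) {
    stop("dose, ec50 and slope must all be strictly positive", call. = FALSE)
  }
  1 / (1 + (dose / ec50)^slope)
}

#' Configure the synthetic dataset generator
#'
#' Defaults emulate a combination screen: full 5 x 5 dose-response matrices
#' on a log-spaced dose grid, 78-gene expression profiles, and moderate
#' measurement noise.
#'
#' @param n_drugs,n_cells Library sizes.
#' @param doses Strictly increasing positive dose grid (default 5 log-spaced
#'   doses from 0.01 to 100, shared by both drugs).
#' @param ec50_log10_range Range of per-drug baseline log10 EC50.
#' @param slope_range Range of per-drug Hill slopes.
#' @param bump_amplitude_range Range of the localized synergy deviation's
#'   amplitude A (negative values = antagonism).
#' @param bump_width_range Range of the bump width w in natural-log dose
#'   units.
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise on the growth-fraction scale (applied to mono and combo rows).
#' @param expression_length Genes per cell-line profile.
#' @param n_factors Latent factors behind expression and EC50 shifts.
#' @param expression_noise_sd Noise added to the expression profiles.
#' @param factor_effect_sd Standard deviation of the latent-factor effect on
#'   each drug's log EC50 across cells.
#' @param scale `"fraction"` (default) or `"percent"`; the latter multiplies
#'   every emitted response by 100, exercising the percent-growth
#'   normalization paths.
#' @param seed Master seed; generation is bit-reproducible.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 8L, n_cells = 4L,
                             doses = 10^seq(-2, 2, length.out = 5L),
                             ec50_log10_range = c(-1.5, 1.5),
                             slope_range = c(0.8, 2.5),
                             bump_amplitude_range = c(-0.3, 0.3),
                             bump_width_range = c(0.5, 1.5),
                             noise_sd = 0.05,
                             expression_length = 78L,
                             n_factors = 4L,
                             expression_noise_sd = 0.1,
                             factor_effect_sd = 0.4,
                             scale = c("fraction", "percent"),
                             seed = 1L) {
  scale <- match.arg(scale)
  stopifnot(n_drugs >= 2L, n_cells >= 1L, all(doses > 0), !is.unsorted(doses, strictly = TRUE),
            noise_sd >= 0, expression_length >= 1L, n_factors >= 1L,
            expression_noise_sd >= 0, factor_effect_sd >= 0)
  structure(list(n_drugs = as.integer(n_drugs), n_cells = as.integer(n_cells),
                 doses = doses, ec50_log10_range = ec50_log10_range,
                 slope_range = slope_range,
                 bump_amplitude_range = bump_amplitude_range,
                 bump_width_range = bump_width_range, noise_sd = noise_sd,
                 expression_length = as.integer(expression_length),
                 n_factors = as.integer(n_factors),
                 expression_noise_sd = expression_noise_sd,
                 factor_effect_sd = factor_effect_sd, scale = scale,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate one combination dose-response surface
#'
#' Noise-free value at doses (r1, r2):
#' \deqn{g_1(r_1) g_2(r_2) + A \exp\{-[(\log r_1 - \mu_1)^2 + (\log r_2 - \mu_2)^2] / (2 w^2)\}}
#' i.e. the Bliss product of the two Hill curves plus a localized Gaussian
#' deviation in log-dose space; Gaussian noise with standard deviation
#' `noise_sd` is then added per grid cell.
#'
#' @param drug1,drug2,cell Identifiers stamped onto the emitted rows.
#' @param hill1,hill2 Lists with `ec50` and `slope` for the two drugs.
#' @param bump List with `amplitude`, `mu1`, `mu2` (log-dose center) and
#'   `width`; `amplitude = 0` disables the deviation.
#' @param doses1,doses2 Dose grids for the two drugs.
#' @param noise_sd Measurement noise standard deviation.
#' @param seed Optional seed for the noise draw.
#' @return A combo table with one row per grid cell, plus a `truth` column
#'   holding the noise-free surface value.
#' @export
generate_combo_surface <- function(drug1, drug2, cell, hill1, hill2, bump,
                                   doses1, doses2, noise_sd = 0, seed = NULL) {
  grid <- expand.grid(dose1 = doses1, dose2 = doses2)
  g1 <- hill_response(grid$dose1, hill1$ec50, hill1$slope)
  g2 <- hill_response(grid$dose2, hill2$ec50, hill2$slope)
  dev <- bump$amplitude * exp(-((log(grid$dose1) - bump$mu1)^2 +
                                  (log(grid$dose2) - bump$mu2)^2) / (2 * bump$width^2))
  truth <- g1 * g2 + dev
  eps <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(nrow(grid), sd = noise_sd))
  } else rep(0, nrow(grid))
  data.frame(drug1 = drug1, drug2 = drug2, dose1 = grid$dose1,
             dose2 = grid$dose2, cell = cell, response = truth + eps,
             truth = truth, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dataset
#'
#' Emits the four mutually consistent tables every other module consumes --
#' combination responses for all unordered drug pairs in all cell lines,
#' monotherapy curves, a SMILES drug library, and a cell-line expression
#' matrix -- together with the generating ground truth for recovery tests.
#'
#' Cell-line latent factors z (one vector per cell) produce the expression
#' profile (z times a loading matrix, plus noise) *and* shift each drug's
#' log EC50 by a drug-specific linear combination of z, so expression
#' carries real signal about drug sensitivity.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `combo`, `mono`, `drugs`, `expression`, `truth`
#'   (ground-truth parameters: per-drug/cell EC50 matrix, slopes, per-surface
#'   bump parameters, latent factors and loadings) and `config`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    drug_ids <- sprintf("D%02d", seq_len(cfg$n_drugs))
    cell_ids <- sprintf("C%02d", seq_len(cfg$n_cells))
    smiles <- vapply(seq_len(cfg$n_drugs), function(i) {
      base <- .smiles_library[((i - 1L) %% length(.smiles_library)) + 1L]
      cycle <- (i - 1L) %/% length(.smiles_library)
      if (cycle > 0L) paste0(base, strrep("C", cycle)) else base
    }, character(1L))
    drugs <- data.frame(drug_id = drug_ids, smiles = smiles,
                        stringsAsFactors = FALSE)

    p <- cfg$n_factors
    Z <- matrix(stats::rnorm(cfg$n_cells * p), cfg$n_cells, p,
                dimnames = list(cell_ids, NULL))
    loadings <- matrix(stats::rnorm(p * cfg$expression_length, sd = 1 / sqrt(p)),
                       p, cfg$expression_length)
    expr <- Z %*% loadings +
      matrix(stats::rnorm(cfg$n_cells * cfg$expression_length,
                          sd = cfg$expression_noise_sd),
             cfg$n_cells, cfg$expression_length)
    colnames(expr) <- sprintf("G%03d", seq_len(cfg$expression_length))

    base_log10 <- stats::runif(cfg$n_drugs, cfg$ec50_log10_range[1L],
                               cfg$ec50_log10_range[2L])
    slopes <- stats::runif(cfg$n_drugs, cfg$slope_range[1L], cfg$slope_range[2L])
    effect <- matrix(stats::rnorm(cfg$n_drugs * p, sd = cfg$factor_effect_sd / sqrt(p)),
                     cfg$n_drugs, p)
    # natural-log EC50 per (drug, cell)
    log_ec50 <- log(10) * matrix(base_log10, cfg$n_drugs, cfg$n_cells) +
      effect %*% t(Z)
    dimnames(log_ec50) <- list(drug_ids, cell_ids)

    mono <- expand.grid(drug = drug_ids, cell = cell_ids, dose = cfg$doses,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mono <- mono[order(mono$drug, mono$cell, mono$dose), c("drug", "dose", "cell")]
    rownames(mono) <- NULL
    di <- match(mono$drug, drug_ids)
    ci <- match(mono$cell, cell_ids)
    mono$response <- hill_response(mono$dose, exp(log_ec50[cbind(di, ci)]),
                                   slopes[di]) +
      stats::rnorm(nrow(mono), sd = cfg$noise_sd)

    lo <- log(min(cfg$doses))
    hi <- log(max(cfg$doses))
    pairs <- utils::combn(seq_len(cfg$n_drugs), 2L)
    surfaces <- vector("list", ncol(pairs) * cfg$n_cells)
    bumps <- vector("list", length(surfaces))
    s <- 0L
    for (pidx in seq_len(ncol(pairs))) {
      i <- pairs[1L, pidx]
      j <- pairs[2L, pidx]
      for (c_ in seq_len(cfg$n_cells)) {
        s <- s + 1L
        bump <- list(
          amplitude = stats::runif(1L, cfg$bump_amplitude_range[1L],
                                   cfg$bump_amplitude_range[2L]),
          mu1 = stats::runif(1L, lo, hi),
          mu2 = stats::runif(1L, lo, hi),
          width = stats::runif(1L, cfg$bump_width_range[1L],
                               cfg$bump_width_range[2L])
        )
        surf <- generate_combo_surface(
          drug_ids[i], drug_ids[j], cell_ids[c_],
          hill1 = list(ec50 = exp(log_ec50[i, c_]), slope = slopes[i]),
          hill2 = list(ec50 = exp(log_ec50[j, c_]), slope = slopes[j]),
          bump = bump, doses1 = cfg$doses, doses2 = cfg$doses,
          noise_sd = cfg$noise_sd, seed = NULL
        )
        bump$drug1 <- drug_ids[i]
        bump$drug2 <- drug_ids[j]
        bump$cell <- cell_ids[c_]
        surfaces[[s]] <- surf
        bumps[[s]] <- bump
      }
    }
    combo <- do.call(rbind, surfaces)
    rownames(combo) <- NULL
    truth_values <- combo$truth
    combo$truth <- NULL

    if (cfg$scale == "percent") {
      combo$response <- combo$response * 100
      mono$response <- mono$response * 100
      truth_values <- truth_values * 100
    }

    list(combo = combo, mono = mono, drugs = drugs, expression = expr,
         truth = list(log_ec50 = log_ec50, slopes = slopes,
                      base_log10_ec50 = base_log10,
                      bumps = do.call(rbind, lapply(bumps, as.data.frame)),
                      latent = Z, loadings = loadings, effect = effect,
                      noise_free = truth_values),
         config = cfg)
  })
}

#' Write a synthetic dataset's four tables to disk
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if absent); writes `combos.csv`,
#'   `mono.csv`, `drugs.csv` and `expression.csv`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_combo_table(dataset$combo, file.path(dir, "combos.csv"))
  utils::write.csv(dataset$mono, file.path(dir, "mono.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(dataset$drugs, file.path(dir, "drugs.csv"), row.names = FALSE,
                   quote = FALSE)
  expr <- data.frame(cell = rownames(dataset$expression), dataset$expression,
                     check.names = FALSE)
  utils::write.csv(expr, file.path(dir, "expression.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
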