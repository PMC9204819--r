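#' Notch region on the log2 intensity scale
#'
#' The depleted band in the Orbitrap reporter-ion intensity distribution.
#' Defaults are the benchmark boundaries 4.25 and 5.75 (log2 intensity).
#'
#' @param lower,upper Lower and upper band boundaries, log2 intensity units.
#' @return An object of class `notch_region`.
#' @export
notch_region <- function(lower = 4.25, upper = 5.75) {
  stopifnot(is.numeric(lower), is.numeric(upper))
  if (!(lower < upper)) stop("notch lower boundary must be below upper")
  structure(list(lower = lower, upper = upper), class = "notch_region")
}

#' Apply the notch distortion to log2 intensities
#'
#' Models the artifact as a discontinuous piecewise-linear monotone map:
#' values at or above the upper boundary are unchanged; values below it are
#' mapped to `lower - slope * (upper - x)`, so the open band
#' `(lower, upper)` contains no outputs and sub-band values are
#' systematically underestimated, never missing.
#'
#' @param x Numeric vector (or matrix) of log2 intensities; `NA` passes
#'   through.
#' @param notch A [notch_region()].
#' @param slope Positive slope of the sub-band branch; 1 is a uniform
#'   downward shift by the band width.
#' @return Distorted log2 intensities with the shape of `x`.
#' @export
apply_notch_artifact <- function(x, notch, slope = 1) {
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0) {
    stop("`slope` must be a single positive number")
  }
  below <- !is.na(x) & x < notch$upper
  x[below] <- notch$lower - slope * (notch$upper - x[below])
  x
}

#' Build the two-species mixing design
#'
#' Each channel carries a fixed yeast peptide mass determined by its group
#' and is filled to `total_mass` with human peptides. The benchmark design
#' spikes 5, 10 and 30 ug of yeast into the 1x, 2x and 6x groups and fills
#' each channel to 100 ug, implying ground-truth fold changes from 1.06
#' (human 95/90) to 6 (yeast 30/5).
#'
#' @param yeast_by_group Named numeric vector, group label -> yeast mass (ug).
#' @param total_mass Total peptide mass per channel (ug).
#' @param channels A [channel_set()] whose groups are named in
#'   `yeast_by_group`.
#' @return An object of class `mix_design` with per-channel `yeast_mass`,
#'   `human_mass` and `total_mass`.
#' @examples
#' d <- build_mix_design()
#' d$human_mass
#' @export
build_mix_design <- function(yeast_by_group = c("1x" = 5, "2x" = 10, "6x" = 30),
                             total_mass = 100, channels = channel_set()) {
  groups <- channels$groups
  if (!all(groups %in% names(yeast_by_group))) {
    stop("every channel group needs a yeast mass in `yeast_by_group`")
  }
  yeast <- stats::setNames(yeast_by_group[groups], channels$labels)
  if (any(yeast <= 0) || any(yeast >= total_mass)) {
    stop("yeast mass must be positive and below the total mass in every channel")
  }
  structure(list(channels = channels,
                 yeast_mass = yeast,
                 human_mass = stats::setNames(total_mass - yeast,
                                              channels$labels),
                 total_mass = total_mass),
            class = "mix_design")
}

# Internal: per-species mass by group (masses are constant within a group).
species_mass_by_group <- function(design, species) {
  m <- if (species == "yeast") design$yeast_mass else design$human_mass
  tapply(m, design$channels$groups, function(v) {
    if (length(unique(v)) != 1L) stop("mass differs within a group")
    v[1]
  })
}

#' Ground-truth log2 fold changes implied by a mixing design
#'
#' @param design A [build_mix_design()] design.
#' @param contrasts List of group pairs `c(numerator, denominator)`.
#' @return Tibble with columns `contrast`, `species`, `log2fc`.
#' @export
expected_log2fc <- function(design,
                            contrasts = list(c("2x", "1x"), c("6x", "1x"))) {
  rows <- lapply(contrasts, function(ct) {
    lab <- paste0(ct[1], "_vs_", ct[2])
    tibble::tibble(
      contrast = lab,
      species = c("yeast", "human"),
      log2fc = c(
        log2(species_mass_by_group(design, "yeast")[[ct[1]]] /
               species_mass_by_group(design, "yeast")[[ct[2]]]),
        log2(species_mass_by_group(design, "human")[[ct[1]]] /
               species_mass_by_group(design, "human")[[ct[2]]])
      )
    )
  })
  dplyr::bind_rows(rows)
}

#' Range of ground-truth fold changes over all pairwise group comparisons
#'
#' Enumerates, for both species and every unordered pair of groups, the fold
#' change expressed as a ratio >= 1, and returns the full set plus its range.
#'
#' @param design A [build_mix_design()] design.
#' @return A list with `folds` (tibble of species, pair, fold) and `range`
#'   (`c(min, max)`).
#' @export
fold_change_range <- function(design) {
  groups <- unique(design$channels$groups)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(c("yeast", "human"), function(sp) {
    m <- species_mass_by_group(design, sp)
    dplyr::bind_rows(lapply(pairs, function(pr) {
      tibble::tibble(species = sp, pair = paste(pr, collapse = "/"),
                     fold = max(m[pr]) / min(m[pr]))
    }))
  })
  folds <- dplyr::bind_rows(rows)
  list(folds = folds, range = range(folds$fold))
}

#' Simulation parameters for the spike-in generator
#'
#' Defaults emulate the benchmark acquisition: a 10-plex with ~3% of reporter
#' intensities below the notch upper boundary, moderate co-isolation
#' interference (mean ~10%, compressing the 6-fold yeast ratio to ~4.8-fold)
#' and multiplicative reporter noise.
#'
#' @param n_yeast_proteins,n_human_proteins Number of simulated proteins per
#'   species.
#' @param psm_per_protein `c(mean, dispersion)` of the shifted
#'   negative-binomial PSM count per protein (minimum 1; dispersion 0 gives a
#'   shifted Poisson).
#' @param mean_log2_abundance,base_abundance_sd Mean and sd (log2 units) of
#'   per-protein base abundance.
#' @param psm_scale_sd Sd (log2 units) of the per-PSM ionization scale.
#' @param reporter_noise_sd Sd (log2 units) of multiplicative reporter noise.
#' @param interference_dist Function `n -> n` draws in `[0, 1]`: the
#'   co-isolated interference fraction per PSM.
#' @param missing_rate Probability that a cell below `detection_floor` (log2)
#'   is recorded as missing.
#' @param detection_floor Log2 intensity below which values may drop out.
#' @param notch Optional [notch_region()] distortion; `NULL` disables it.
#' @param notch_slope Slope of the sub-band branch of the distortion.
#' @param sn_noise Typical noise level dividing the mean observed intensity
#'   to give the average reporter S/N.
#' @param sn_spread_sd Sd (log2 units) of the per-spectrum noise level around
#'   `sn_noise`; spectra vary in injection time and noise, so S/N is not a
#'   deterministic function of intensity.
#' @param seed Integer seed; all stages derive named streams from it.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_yeast_proteins = 180, n_human_proteins = 620,
                       psm_per_protein = c(mean = 4, dispersion = 1),
                       mean_log2_abundance = 11, base_abundance_sd = 2.5,
                       psm_scale_sd = 1, reporter_noise_sd = 0.15,
                       interference_dist = function(n) stats::rbeta(n, 1.5, 13.5),
                       missing_rate = 0.3, detection_floor = 3,
                       notch = notch_region(), notch_slope = 1,
                       sn_noise = 16, sn_spread_sd = 1, seed = 1234L) {
  p <- list(n_yeast_proteins = n_yeast_proteins,
            n_human_proteins = n_human_proteins,
            psm_per_protein = psm_per_protein,
            mean_log2_abundance = mean_log2_abundance,
            base_abundance_sd = base_abundance_sd,
            psm_scale_sd = psm_scale_sd,
            reporter_noise_sd = reporter_noise_sd,
            interference_dist = interference_dist,
            missing_rate = missing_rate,
            detection_floor = detection_floor,
            notch = notch, notch_slope = notch_slope,
            sn_noise = sn_noise, sn_spread_sd = sn_spread_sd,
            seed = as.integer(seed))
  with(p, {
    if (n_yeast_proteins <= 0 || n_human_proteins <= 0)
      stop("protein counts must be positive")
    if (psm_per_protein[["mean"]] < 1 || psm_per_protein[["dispersion"]] < 0)
      stop("psm_per_protein mean must be >= 1 and dispersion >= 0")
    if (base_abundance_sd < 0 || psm_scale_sd < 0 || reporter_noise_sd < 0)
      stop("standard deviations must be non-negative")
    if (missing_rate < 0 || missing_rate > 1)
      stop("missing_rate must lie in [0, 1]")
    if (!is.function(interference_dist))
      stop("interference_dist must be a function of n")
  })
  structure(p, class = "sim_params")
}

# Internal: random tryptic-looking peptide sequences, unique within a run.
random_sequences <- function(n, min_len = 7, max_len = 18) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # no K/R internally
  lens <- sample(min_len:max_len, n, replace = TRUE)
  seqs <- vapply(lens, function(l) {
    paste0(paste(sample(aa, l - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1))
  while (anyDuplicated(seqs)) {
    d <- which(duplicated(seqs))
    seqs[d] <- paste0(substr(seqs[d], 1, nchar(seqs[d]) - 1),
                      vapply(d, function(i)
                        paste(sample(aa, 2, replace = TRUE), collapse = ""),
                        character(1)),
                      sample(c("K", "R"), length(d), replace = TRUE))
  }
  seqs
}

#' Simulate a two-species spike-in TMT experiment
#'
#' Generates a PSM table with known ground truth. Each protein receives a
#' log-normal base abundance and a species-specific channel profile
#' proportional to its species' per-channel mass; each PSM receives an
#' ionization scale. Observed intensities are a mixture of the true signal
#' and a channel-flat co-isolation background (fraction `i` per PSM, drawn
#' from `interference_dist`, which compresses ratios toward 1), perturbed by
#' multiplicative log-normal noise, optionally distorted by the notch
#' artifact, and thinned to missing below the detection floor. Quality
#' metrics are emitted consistently: `coisolation_pct = 100 * i` and
#' `avg_sn` is the mean non-missing intensity over `sn_noise`.
#'
#' @param design A [build_mix_design()] design.
#' @param params A [sim_params()] object.
#' @return A list with `table` (a species-annotated [psm_table()]) and
#'   `truth` (list with `proteins`, `expected` log2 fold changes and the
#'   `design`).
#' @export
simulate_experiment <- function(design, params) {
  stopifnot(inherits(design, "mix_design"), inherits(params, "sim_params"))
  cs <- design$channels
  nch <- length(cs$labels)

  # Protein layer: species, base abundances, PSM counts.
  set.seed(stage_seed(params$seed, "proteins"))
  n_prot <- params$n_yeast_proteins + params$n_human_proteins
  proteins <- tibble::tibble(
    protein = c(sprintf("YST%04d", seq_len(params$n_yeast_proteins)),
                sprintf("HUM%04d", seq_len(params$n_human_proteins))),
    species = rep(c("yeast", "human"),
                  c(params$n_yeast_proteins, params$n_human_proteins)),
    base_log2 = stats::rnorm(n_prot, params$mean_log2_abundance,
                             params$base_abundance_sd)
  )
  mu <- params$psm_per_protein[["mean"]] - 1
  disp <- params$psm_per_protein[["dispersion"]]
  n_psm <- 1L + if (disp > 0) {
    stats::rnbinom(n_prot, mu = mu, size = 1 / disp)
  } else {
    stats::rpois(n_prot, mu)
  }

  # Peptide layer: ~2 PSMs per peptide on average, for redundancy analyses.
  set.seed(stage_seed(params$seed, "peptides"))
  pep_per_prot <- pmax(1L, ceiling(n_psm / 2))
  prot_idx <- rep(seq_len(n_prot), n_psm)
  pep_idx <- unlist(lapply(seq_len(n_prot), function(i) {
    sample.int(pep_per_prot[i], n_psm[i], replace = TRUE)
  }))
  pep_key <- paste0(prot_idx, "_", pep_idx)
  pep_levels <- unique(pep_key)
  seqs <- stats::setNames(random_sequences(length(pep_levels)), pep_levels)

  n <- length(prot_idx)
  # Channel profiles: within a species, intensity tracks the species mass,
  # scaled to mean 1 across channels so base abundance sets the overall level.
  w_yeast <- design$yeast_mass / mean(design$yeast_mass)
  w_human <- design$human_mass / mean(design$human_mass)
  w <- rbind(yeast = w_yeast, human = w_human)

  set.seed(stage_seed(params$seed, "signal"))
  scale_log2 <- proteins$base_log2[prot_idx] +
    stats::rnorm(n, 0, params$psm_scale_sd)
  true <- outer(2^scale_log2, rep(1, nch)) *
    w[proteins$species[prot_idx], , drop = FALSE]

  # Co-isolation: mixture with a channel-flat background (the bulk has equal
  # total mass per channel), which compresses all ratios toward 1.
  set.seed(stage_seed(params$seed, "interference"))
  i_frac <- pmin(1, pmax(0, params$interference_dist(n)))
  obs <- (1 - i_frac) * true + i_frac * rowMeans(true)

  set.seed(stage_seed(params$seed, "noise"))
  obs <- obs * 2^matrix(stats::rnorm(n * nch, 0, params$reporter_noise_sd),
                        n, nch)

  lobs <- log2(obs)
  if (!is.null(params$notch)) {
    lobs <- apply_notch_artifact(lobs, params$notch, params$notch_slope)
  }

  set.seed(stage_seed(params$seed, "missing"))
  dropout <- matrix(stats::runif(n * nch) < params$missing_rate, n, nch) &
    lobs < params$detection_floor
  lobs[dropout] <- NA

  intens <- 2^lobs
  colnames(intens) <- cs$labels

  set.seed(stage_seed(params$seed, "metrics"))
  noise_level <- params$sn_noise * 2^stats::rnorm(n, 0, params$sn_spread_sd)
  avg_sn <- unname(rowMeans(intens, na.rm = TRUE)) / noise_level
  delta_cn <- stats::rbeta(n, 2, 1.5)

  psms <- tibble::tibble(
    psm_id = sprintf("PSM%06d", seq_len(n)),
    sequence = unname(seqs[pep_key]),
    master_proteins = proteins$protein[prot_idx],
    species = proteins$species[prot_idx],
    delta_cn = delta_cn,
    coisolation_pct = 100 * i_frac,
    avg_sn = avg_sn
  )
  psms <- dplyr::bind_cols(psms, tibble::as_tibble(intens))
  all_missing <- rowSums(!is.na(intens)) == 0
  psms <- psms[!all_missing, , drop = FALSE]

  tab <- psm_table(psms, cs,
                   provenance = sprintf("simulated spike-in (seed %d)",
                                        params$seed))
  truth <- list(proteins = proteins[, c("protein", "species")],
                expected = expected_log2fc(design),
                design = design)
  list(table = tab, truth = truth)
}
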