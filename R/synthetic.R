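#' Ground-truth melting parameters for the synthetic-data generator
#'
#' Declares the true melting model from which noisy survival datasets are
#' generated, enabling closed-loop parameter-recovery tests. Defaults mirror
#' the experimental protocol: triplicate survival rates over a 30-95 degC
#' incubation grid, with additive Gaussian noise on survival (sd 0.05) and
#' multiplicative lognormal noise on band intensities (sd 0.1).
#'
#' @param model `"single"` or `"double"` Boltzmann sigmoid.
#' @param S_top,S_bottom plateau survival values.
#' @param T_half transition midpoint (degC) for the single model.
#' @param w transition width (degC) for the single model.
#' @param T1,T2 first/second transition midpoints for the double model
#'   (`T1 < T2`).
#' @param w1,w2 transition widths for the double model.
#' @param phi mixing fraction of the first transition (double model).
#' @param noise_sd Gaussian sd added to survival values.
#' @param intensity_sd lognormal sd on band intensities.
#' @param replicates replicate count (3, as in triplicate gels).
#' @param temperatures incubation grid in degC (strictly increasing).
#' @return an object of class `melt_truth` with a `curve(T)` function.
#' @export
melt_truth <- function(model = c("single", "double"),
                       S_top = 1, S_bottom = 0,
                       T_half = 53, w = 3,
                       T1 = 40, T2 = 60, w1 = 2.5, w2 = 2.5, phi = 0.5,
                       noise_sd = 0.05, intensity_sd = 0.1,
                       replicates = 3L,
                       temperatures = seq(30, 95, by = 5)) {
  model <- match.arg(model)
  stopifnot(noise_sd >= 0, intensity_sd >= 0, replicates >= 1,
            all(diff(temperatures) > 0))
  if (model == "double") stopifnot(T1 < T2, phi >= 0, phi <= 1)
  curve <- if (model == "single") {
    function(T) boltzmann_curve(T, S_top, S_bottom, T_half, w)
  } else {
    function(T) double_boltzmann_curve(T, S_top, S_bottom, T1, w1, T2, w2, phi)
  }
  structure(list(model = model, S_top = S_top, S_bottom = S_bottom,
                 T_half = T_half, w = w, T1 = T1, T2 = T2, w1 = w1, w2 = w2,
                 phi = phi, noise_sd = noise_sd, intensity_sd = intensity_sd,
                 replicates = as.integer(replicates),
                 temperatures = temperatures, curve = curve),
            class = "melt_truth")
}

#' Generate a synthetic survival-rate dataset
#'
#' Survival at each grid temperature is the true melting curve plus seeded
#' Gaussian noise (values are not clipped: gel densitometry can exceed 1).
#' The truth is stored as an attribute for recovery tests.
#'
#' @param truth a [melt_truth()].
#' @param seed integer RNG seed.
#' @return a `survival_dataset` data frame with columns `temperature_C`,
#'   `replicate`, `survival` and attribute `truth`.
#' @export
gen_survival_dataset <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "melt_truth"))
  Tg <- truth$temperatures
  n <- length(Tg) * truth$replicates
  noise <- if (truth$noise_sd > 0) {
    with_seed(seed, stats::rnorm(n, 0, truth$noise_sd))
  } else rep(0, n)
  out <- data.frame(
    temperature_C = rep(Tg, times = truth$replicates),
    replicate = rep(seq_len(truth$replicates), each = length(Tg)),
    survival = rep(truth$curve(Tg), times = truth$replicates) + noise)
  attr(out, "truth") <- truth
  class(out) <- c("survival_dataset", "data.frame")
  out
}

#' Generate a synthetic gel band-intensity table
#'
#' Intensities are linear in loaded mass (`intensity = mass * gain`) times
#' seeded multiplicative lognormal noise with unit median, plus one standard
#' band of known mass — emulating quantification against a ladder band.
#'
#' @param masses named numeric vector of band masses (ng); names become band
#'   ids in lane `"sample"`.
#' @param standard_mass known mass (ng) of the standard band.
#' @param gain intensity per ng.
#' @param noise_sd lognormal sigma (0 = noiseless).
#' @param seed RNG seed.
#' @return a `band_table` data frame with columns `lane`, `band`,
#'   `intensity`, `role`, `known_mass`, `temperature_C`.
#' @export
gen_band_table <- function(masses, standard_mass, gain = 100,
                           noise_sd = 0.1, seed = NULL) {
  stopifnot(all(masses >= 0), standard_mass > 0)
  n <- length(masses) + 1L
  lnoise <- if (noise_sd > 0) {
    with_seed(seed, stats::rlnorm(n, meanlog = 0, sdlog = noise_sd))
  } else rep(1, n)
  out <- data.frame(
    lane = c("ladder", rep("sample", length(masses))),
    band = c("standard", names(masses) %||% paste0("band", seq_along(masses))),
    intensity = c(standard_mass, unname(masses)) * gain * lnoise,
    role = c("standard", rep("target", length(masses))),
    known_mass = c(standard_mass, rep(NA_real_, length(masses))),
    temperature_C = NA_real_)
  class(out) <- c("band_table", "data.frame")
  out
}

#' Generate a survival-mode band table from a true survival design
#'
#' Emits one target band per (temperature, replicate) with intensity
#' proportional to the designed survival, plus a 4 degC control band per
#' replicate, so that [survival_rates()] applied to the noiseless table
#' recovers the designed survival matrix exactly.
#'
#' @param survival a data frame `temperature_C`, `replicate`, `survival`
#'   (e.g. [gen_survival_dataset()] output), or a [melt_truth()] from which a
#'   noiseless design is taken.
#' @param gain control-band intensity.
#' @param noise_sd lognormal sigma applied to every band.
#' @param seed RNG seed.
#' @return a `band_table` data frame with per-replicate `control` bands and
#'   per-temperature `target` bands.
#' @export
gen_survival_band_table <- function(survival, gain = 100, noise_sd = 0,
                                    seed = NULL) {
  if (inherits(survival, "melt_truth")) {
    tr <- survival
    survival <- data.frame(
      temperature_C = rep(tr$temperatures, times = tr$replicates),
      replicate = rep(seq_len(tr$replicates), each = length(tr$temperatures)),
      survival = rep(tr$curve(tr$temperatures), times = tr$replicates))
  }
  reps <- unique(survival$replicate)
  n <- nrow(survival) + length(reps)
  lnoise <- if (noise_sd > 0) {
    with_seed(seed, stats::rlnorm(n, meanlog = 0, sdlog = noise_sd))
  } else rep(1, n)
  ctrl <- data.frame(
    lane = paste0("control_rep", reps), band = "target",
    intensity = gain * lnoise[seq_along(reps)],
    role = "control", known_mass = NA_real_, temperature_C = 4,
    replicate = reps)
  tgt <- data.frame(
    lane = sprintf("T%g_rep%d", survival$temperature_C, survival$replicate),
    band = "target",
    intensity = survival$survival * gain * lnoise[length(reps) + seq_len(nrow(survival))],
    role = "target", known_mass = NA_real_,
    temperature_C = survival$temperature_C,
    replicate = survival$replicate)
  out <- rbind(ctrl, tgt)
  rownames(out) <- NULL
  class(out) <- c("band_table", "data.frame")
  out
}

# reconfiguration mask fixtures: straight-seam carving patterns on the 6x6
# J4-I lattice with the reference ligatable-nick counts (96, 96, 108 of 120)
reconfig_fixture_list <- function() {
  rows_seam <- function(rs) unlist(lapply(rs, function(r) sprintf("e_r%dc%d_S", r, 0:5)))
  cols_seam <- function(cs) unlist(lapply(cs, function(c) sprintf("e_r%dc%d_E", 0:5, c)))
  shape <- function(rr, cc) {
    g <- expand.grid(row = rr, col = cc)
    lapply(seq_len(nrow(g)), function(i) c(g$row[i], g$col[i]))
  }
  list(
    fig4a_mask = list(base = "J4-I",
                      mask = list(cut_edges = rows_seam(c(1, 3))),
                      target_shape = shape(2:3, 0:5)),
    fig4b_mask = list(base = "J4-I",
                      mask = list(cut_edges = cols_seam(c(1, 3))),
                      target_shape = shape(0:5, 2:3)),
    fig4c_mask = list(base = "J4-I",
                      mask = list(cut_edges = cols_seam(2)),
                      target_shape = shape(0:5, 0:2))
  )
}

#' Tube-closure design variants
#'
#' The sheet-to-tube lattice and its controls: complementary 3-nt overhangs
#' (`"comp3"`, tubulates only when ligated), non-complementary overhangs
#' (`"noncomp"`, stays planar), complementary but unligatable overhangs
#' (`"unlig"`, stays planar), and the 10-bp sticky-end positive control
#' (`"sticky10"`, tubular with or without ligation).
#'
#' @param variant one of `"comp3"`, `"noncomp"`, `"unlig"`, `"sticky10"`.
#' @return a [lattice_design()].
#' @export
tube_design <- function(variant = c("comp3", "noncomp", "unlig", "sticky10")) {
  variant <- match.arg(variant)
  base <- builtin_design("fig4d_tube")
  switch(variant,
    comp3 = base,
    noncomp = {
      base$boundary$complementary <- FALSE
      base$name <- "fig4d_tube_noncomp"
      base
    },
    unlig = {
      base$mask <- list(cut_edges = sprintf("b_r%d_EW", 0:5))
      base$name <- "fig4d_tube_unlig"
      base
    },
    sticky10 = {
      base$boundary$length <- 10L
      base$name <- "fig4d_tube_sticky10"
      base
    })
}

#' Write the shipped design and mask fixtures
#'
#' Regenerates every design/mask JSON fixture from the package's internal
#' definitions. Deterministic: repeated generation is byte-identical.
#'
#' @param dir output directory (created if needed).
#' @return data frame with columns `file`, `md5`.
#' @export
gen_fixture_designs <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(builtin_design_list())) {
    path <- file.path(dir, paste0(nm, ".json"))
    write_lattice_design(builtin_design(nm), path)
    files <- c(files, path)
  }
  for (nm in names(reconfig_fixture_list())) {
    path <- file.path(dir, paste0(nm, ".json"))
    jsonlite::write_json(reconfig_fixture_list()[[nm]], path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, path)
  }
  data.frame(file = files, md5 = unname(tools::md5sum(files)),
             row.names = NULL)
}
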