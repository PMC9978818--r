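#' Convert a mass concentration to molar
#'
#' @param mass_ug_ml Concentration in micrograms per milliliter.
#' @param mw Molecular weight in g/mol (> 0). Typical values: IgG 1.5e5,
#'   Fab 5.0e4.
#' @return Molar concentration.
#' @examples
#' mass_to_molar(5, 1.5e5)  # ~3.33e-8 M for 5 ug/ml IgG
#' @export
mass_to_molar <- function(mass_ug_ml, mw) {
  if (any(mw <= 0)) stop("'mw' must be positive", call. = FALSE)
  if (any(mass_ug_ml < 0))
    stop("mass concentration must be non-negative", call. = FALSE)
  (mass_ug_ml * 1e-3) / mw # ug/ml == mg/L; mg/L -> g/L -> mol/L
}

#' Reference monoclonal antibodies for the NPNA repeat epitope
#'
#' Kinetic constants of three IgG1 monoclonal antibodies against the
#' malaria circumsporozoite NPNA-repeat peptide, spanning the avidity range
#' used throughout this package's validation scenarios: a high-avidity mAb
#' (AB334), an intermediate one ~4.3-fold faster in kd (AB315) and a
#' low-avidity one ~660-fold faster (AB395).
#'
#' @return A data.frame with columns `label`, `ka` (1/(M s)), `kd` (1/s)
#'   and `mw` (g/mol).
#' @export
npna3_mabs <- function() {
  data.frame(label = c("AB334", "AB315", "AB395"),
             ka = c(8.2e4, 1.8e5, 4.7e5),
             kd = c(5.6e-5, 2.4e-4, 3.7e-2),
             mw = rep(1.5e5, 3),
             stringsAsFactors = FALSE)
}

#' Simulate a sensorgram of an antibody mixture
#'
#' Forward-simulates a mixture of antibodies competing for one immobilized
#' epitope (see [simulate_competing()]) and wraps the total response as a
#' [sensorgram] with baseline, association and dissociation phases, adding
#' i.i.d. Gaussian instrument noise and optional linear drift. The ground
#' truth (per-component curves, rates, end-of-association occupancy
#' fractions) is returned alongside so recovery can be checked without
#' re-simulation.
#'
#' Default conditions mirror a standard BLI mixture experiment: 5 ug/ml
#' total IgG (3.33e-8 M at mw 1.5e5), a 300 s association and 600 s
#' dissociation sampled at 5 Hz, and a noise floor of 0.005 response units.
#'
#' @param species A data.frame with columns `label`, `ka`, `kd` and
#'   optionally `mw` (default IgG, 1.5e5 g/mol), e.g. rows of
#'   [npna3_mabs()].
#' @param share Mixing shares, one per species, summing to 1.
#' @param share_mode `"molar"` (canonical) or `"mass"`; for equal
#'   molecular weights the two coincide.
#' @param total_mass_ug_ml Total mixture concentration in ug/ml.
#' @param rmax Surface capacity in response units.
#' @param t_assoc,t_dissoc Phase durations in seconds.
#' @param t_baseline Baseline duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param sigma Gaussian noise standard deviation in response units.
#' @param drift_slope Linear baseline drift in response units per second.
#' @param seed Integer seed for the noise.
#' @param sample_id Sample identifier for the sensorgram.
#' @return A list with elements `sensorgram` and `truth`; `truth` carries
#'   `system`, `sim` (the noiseless [simulate_competing()] output), molar
#'   concentrations, the end-of-association occupancy `fractions`, and the
#'   component responses at the end of association.
#' @export
simulate_mixture_sensorgram <- function(species, share,
                                        share_mode = c("molar", "mass"),
                                        total_mass_ug_ml = 5,
                                        rmax = 1,
                                        t_assoc = 300, t_dissoc = 600,
                                        t_baseline = 30, rate = 5,
                                        sigma = 0.005, drift_slope = 0,
                                        seed = 1L, sample_id = "mixture") {
  share_mode <- match.arg(share_mode)
  stopifnot(is.data.frame(species), nrow(species) == length(share),
            all(c("label", "ka", "kd") %in% names(species)),
            t_assoc > 0, t_dissoc > 0, rate > 0, sigma >= 0)
  if (abs(sum(share) - 1) > 1e-9)
    stop("'share' must sum to 1", call. = FALSE)
  mw <- if ("mw" %in% names(species)) species$mw else rep(1.5e5, nrow(species))
  if (share_mode == "mass") {
    conc <- mass_to_molar(share * total_mass_ug_ml, mw)
  } else {
    # molar shares at a fixed total mass: total molar follows from the
    # share-weighted mean molecular weight
    total_molar <- total_mass_ug_ml * 1e-3 / sum(share * mw)
    conc <- share * total_molar
  }
  sys <- competing_system(ka = species$ka, kd = species$kd, conc = conc,
                          labels = species$label, mw = mw, rmax = rmax)
  dt <- 1 / rate
  sim <- simulate_competing(sys, t_assoc = t_assoc, t_dissoc = t_dissoc,
                            dt = dt)
  t_b <- seq(0, t_baseline, by = dt)
  n_all <- length(t_b) + length(sim$assoc$times) + length(sim$dissoc$times)
  noise <- if (sigma > 0 || drift_slope != 0)
    with_seed(seed, stats::rnorm(n_all, 0, sigma)) else numeric(n_all)
  clock <- c(t_b, t_baseline + sim$assoc$times,
             t_baseline + t_assoc + sim$dissoc$times)
  noise <- noise + drift_slope * clock
  i1 <- seq_along(t_b)
  i2 <- length(t_b) + seq_along(sim$assoc$times)
  i3 <- length(t_b) + length(sim$assoc$times) + seq_along(sim$dissoc$times)
  sg <- sensorgram(list(
    baseline = timecourse(t_b, noise[i1]),
    association = timecourse(sim$assoc$times, sim$assoc$total + noise[i2]),
    dissociation = timecourse(sim$dissoc$times,
                              sim$dissoc$total + noise[i3])),
    sample_id = sample_id, analyte_conc = sum(conc))
  n_assoc <- nrow(sim$assoc$components)
  truth <- list(system = sys, sim = sim, conc = conc,
                end_assoc_response = sim$assoc$components[n_assoc, ],
                fractions = occupancy_fractions(sim, t_assoc),
                sigma = sigma, drift_slope = drift_slope, seed = seed,
                scenario = list(t_assoc = t_assoc, t_dissoc = t_dissoc,
                                t_baseline = t_baseline, rate = rate))
  list(sensorgram = sg, truth = truth)
}

#' Simulate a multi-exponential dissociation phase directly
#'
#' Generates a dissociation trace straight from the sum-of-exponentials
#' model plus Gaussian noise — the exact data-generating process the
#' avidity-binning fit assumes — for unit-level testing without an
#' association stage.
#'
#' @param alpha,kd Component amplitudes and rate constants.
#' @param r_inf Constant residual response.
#' @param t_dissoc Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param sigma Gaussian noise SD in response units.
#' @param seed Integer seed.
#' @return A list with `phase` (a [dissociation_phase]) and `truth`
#'   (`alpha`, `kd`, `r_inf`, `fractions`).
#' @export
simulate_polyclonal_dissociation <- function(alpha, kd, r_inf = 0,
                                             t_dissoc = 600, rate = 5,
                                             sigma = 0.005, seed = 1L) {
  stopifnot(t_dissoc > 0, rate > 0, sigma >= 0)
  times <- seq(0, t_dissoc, by = 1 / rate)
  y <- sum_exp_response(times, alpha, kd, r_inf)
  if (sigma > 0)
    y <- y + with_seed(seed, stats::rnorm(length(times), 0, sigma))
  list(phase = dissociation_phase(times, y, window = c(0, t_dissoc),
                                  source = "synthetic"),
       truth = list(alpha = alpha, kd = kd, r_inf = r_inf,
                    fractions = compute_fractions(alpha), sigma = sigma,
                    seed = seed))
}

#' Write a deterministic suite of synthetic fixtures
#'
#' Generates the canonical validation set — the three reference mAbs alone,
#' a binary mixing-ratio ladder (95:5 to 5:95), a ternary 1:1:1 mixture,
#' short/long association variants, and one direct two-exponential
#' dissociation — as tidy CSVs with a ground-truth JSON each, all
#' deterministic for a given seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; per-fixture seeds are derived from it.
#' @return Invisibly, a data.frame manifest (`name`, `csv`, `truth`).
#' @export
make_fixture_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mabs <- npna3_mabs()
  sub_seed <- function(i) as.integer((as.double(seed) * 1000 + i) %% 2147483647)
  specs <- list()
  for (j in 1:3)
    specs[[paste0("mono_", mabs$label[j])]] <-
      list(species = mabs[j, ], share = 1)
  pair <- mabs[c(1, 3), ]
  for (r in c(95, 75, 50, 25, 5))
    specs[[sprintf("binary_%02d_%02d", r, 100 - r)]] <-
      list(species = pair, share = c(r, 100 - r) / 100)
  specs[["ternary_1_1_1"]] <- list(species = mabs, share = rep(1 / 3, 3))
  specs[["binary_25_75_assoc100"]] <-
    list(species = pair, share = c(0.25, 0.75), t_assoc = 100)
  specs[["binary_25_75_assoc1800"]] <-
    list(species = pair, share = c(0.25, 0.75), t_assoc = 1800)

  manifest <- data.frame(name = character(), csv = character(),
                         truth = character(), stringsAsFactors = FALSE)
  i <- 0L
  for (nm in names(specs)) {
    i <- i + 1L
    sp <- specs[[nm]]
    out <- simulate_mixture_sensorgram(
      sp$species, sp$share, seed = sub_seed(i), sample_id = nm,
      t_assoc = if (is.null(sp$t_assoc)) 300 else sp$t_assoc)
    csv <- file.path(dir, paste0(nm, ".csv"))
    tr <- file.path(dir, paste0(nm, "_truth.json"))
    write_sensorgrams(out$sensorgram, csv)
    .write_truth_json(out$truth, tr)
    manifest <- rbind(manifest, data.frame(name = nm, csv = csv, truth = tr,
                                           stringsAsFactors = FALSE))
  }
  i <- i + 1L
  out <- simulate_polyclonal_dissociation(alpha = c(0.4, 0.1),
                                          kd = c(5.6e-5, 3.7e-2),
                                          seed = sub_seed(i))
  nm <- "polyclonal_biexp"
  csv <- file.path(dir, paste0(nm, ".csv"))
  tr <- file.path(dir, paste0(nm, "_truth.json"))
  sg <- sensorgram(list(dissociation = timecourse(out$phase$times,
                                                  out$phase$responses)),
                   sample_id = nm)
  write_sensorgrams(sg, csv)
  jsonlite::write_json(out$truth, tr, auto_unbox = TRUE, digits = NA)
  manifest <- rbind(manifest, data.frame(name = nm, csv = csv, truth = tr,
                                         stringsAsFactors = FALSE))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

.write_truth_json <- function(truth, path) {
  sys <- truth$system
  jsonlite::write_json(list(
    labels = sys$labels, ka = sys$ka, kd = sys$kd, conc = truth$conc,
    rmax = sys$rmax, end_assoc_response = truth$end_assoc_response,
    fractions = as.list(truth$fractions), sigma = truth$sigma,
    drift_slope = truth$drift_slope, seed = truth$seed,
    scenario = truth$scenario),
    path, auto_unbox = TRUE, digits = NA)
}
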