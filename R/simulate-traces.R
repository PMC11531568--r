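#' Parameters for simulating an ALEX camera trace
#'
#' Bundles the ground-truth geometry, photophysics and detection parameters
#' of a simulated alternating-laser-excitation trace of a single
#' donor-acceptor pair. The defaults emulate a TIRF/EMCCD measurement at
#' 100 ms exposure: a few hundred detected donor-excitation photons per
#' frame, weak leakage/direct-excitation crosstalk, an imperfect detection
#' factor and unequal excitation intensities, single-step photobleaching of
#' each dye with geometric waiting times, and a small Poisson background.
#'
#' @param true_distance Donor-acceptor distance in nm (> 0).
#' @param pair [fluorophore_pair()] supplying the Forster radius.
#' @param frames Number of alternation cycles; each cycle contributes one
#'   donor-excitation frame (I_DD, I_DA) and one acceptor-excitation frame
#'   (I_AA).
#' @param exposure Camera exposure per frame in ms (metadata only).
#' @param mean_donor_photons_per_frame Mean number of photons absorbed by
#'   the donor per donor-excitation frame (the donor photon budget N_D).
#' @param alpha Donor leakage into the acceptor channel (>= 0).
#' @param delta Acceptor direct excitation by the donor laser (>= 0).
#' @param gamma Detection-efficiency/quantum-yield factor (> 0).
#' @param beta Excitation-balance factor (> 0).
#' @param donor_bleach_rate,acceptor_bleach_rate Per-frame bleaching
#'   probabilities in \[0, 1\].
#' @param background_per_channel Mean background photons per frame and
#'   channel (Poisson).
#' @param read_noise_sd Optional Gaussian read noise (photons, sd).
#' @param seed Optional integer seed.
#' @return List of class `trace_sim_params`.
#' @export
trace_sim_params <- function(true_distance = 4.8,
                             pair = fluorophore_pair("cy3b_T"),
                             frames = 200L,
                             exposure = 100,
                             mean_donor_photons_per_frame = 300,
                             alpha = 0.08, delta = 0.06,
                             gamma = 0.85, beta = 1.2,
                             donor_bleach_rate = 0.004,
                             acceptor_bleach_rate = 0.010,
                             background_per_channel = 2,
                             read_noise_sd = 0,
                             seed = NULL) {
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stopifnot(num_ok(true_distance), num_ok(alpha), num_ok(delta),
            num_ok(gamma), num_ok(beta), num_ok(mean_donor_photons_per_frame),
            num_ok(donor_bleach_rate), num_ok(acceptor_bleach_rate),
            num_ok(background_per_channel), num_ok(read_noise_sd))
  if (true_distance <= 0) stop("true_distance must be > 0")
  if (alpha < 0 || delta < 0 || gamma <= 0 || beta <= 0) {
    stop("invalid correction factors: need alpha, delta >= 0 and gamma, beta > 0")
  }
  if (donor_bleach_rate < 0 || donor_bleach_rate > 1 ||
      acceptor_bleach_rate < 0 || acceptor_bleach_rate > 1) {
    stop("bleach rates must lie in [0, 1]")
  }
  if (mean_donor_photons_per_frame < 0 || background_per_channel < 0 ||
      read_noise_sd < 0) {
    stop("photon means and noise must be >= 0")
  }
  if (frames < 1) stop("frames must be >= 1")
  structure(list(
    true_distance = true_distance, pair = pair, frames = as.integer(frames),
    exposure = exposure,
    mean_donor_photons_per_frame = mean_donor_photons_per_frame,
    alpha = alpha, delta = delta, gamma = gamma, beta = beta,
    donor_bleach_rate = donor_bleach_rate,
    acceptor_bleach_rate = acceptor_bleach_rate,
    background_per_channel = background_per_channel,
    read_noise_sd = read_noise_sd, seed = seed
  ), class = "trace_sim_params")
}

geom_bleach_frame <- function(rate) {
  # first frame index at which the dye is dark; Inf = survives the trace
  if (rate <= 0) return(Inf)
  rgeom(1L, rate) + 1L
}

#' Simulate one ALEX-FRET intensity trace with ground truth
#'
#' Draws a three-channel camera trace (`I_DD`, `I_DA`, `I_AA`) frame by
#' frame. While both dyes are alive the channel means are
#' \deqn{E[I_{DD}] = (1-E) N_D + bg}
#' \deqn{E[I_{DA}] = \gamma E N_D + \alpha (1-E) N_D + \delta \beta\gamma N_D + bg}
#' \deqn{E[I_{AA}] = \beta \gamma N_D + bg}
#' with E the true transfer efficiency set by `true_distance` and the pair's
#' Forster radius. After the acceptor bleaches the FRET and direct-excitation
#' contributions drop to zero and the donor intensity rises to \eqn{N_D};
#' after the donor bleaches only background remains in the donor-excitation
#' channels. Shot noise is Poisson per channel, with optional Gaussian read
#' noise.
#'
#' @param params [trace_sim_params()].
#' @param species `"fret"` (default), `"donor-only"` (acceptor absent) or
#'   `"acceptor-only"` (donor absent).
#' @return List with `trace` (data.frame `frame, I_DD, I_DA, I_AA`) and
#'   `truth` (true efficiency, per-channel bleach frames, correction factors,
#'   species).
#' @export
simulate_alex_trace <- function(params, species = c("fret", "donor-only",
                                                    "acceptor-only")) {
  stopifnot(inherits(params, "trace_sim_params"))
  species <- match.arg(species)
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- params
  n <- p$frames
  N_D <- p$mean_donor_photons_per_frame
  E_true <- distance_to_efficiency(p$true_distance, p$pair$R0)

  donor_bleach <- if (species == "acceptor-only") 0 else
    geom_bleach_frame(p$donor_bleach_rate)
  acceptor_bleach <- if (species == "donor-only") 0 else
    geom_bleach_frame(p$acceptor_bleach_rate)

  fr <- seq_len(n)
  d_alive <- as.numeric(fr < donor_bleach | donor_bleach == Inf)
  if (species == "acceptor-only") d_alive <- rep(0, n)
  a_alive <- as.numeric(fr < acceptor_bleach | acceptor_bleach == Inf)
  if (species == "donor-only") a_alive <- rep(0, n)

  E_eff <- ifelse(d_alive > 0 & a_alive > 0, E_true, 0)
  mu_dd <- d_alive * (1 - E_eff) * N_D + p$background_per_channel
  mu_aa <- a_alive * p$beta * p$gamma * N_D + p$background_per_channel
  mu_da <- d_alive * (p$gamma * E_eff * N_D + p$alpha * (1 - E_eff) * N_D) +
    p$delta * a_alive * p$beta * p$gamma * N_D + p$background_per_channel

  draw <- function(mu) {
    x <- rpois(n, mu)
    if (p$read_noise_sd > 0) x <- x + rnorm(n, 0, p$read_noise_sd)
    x
  }
  trace <- data.frame(frame = fr, I_DD = draw(mu_dd), I_DA = draw(mu_da),
                      I_AA = draw(mu_aa))
  truth <- list(
    true_efficiency = if (species == "fret") E_true else 0,
    true_distance = p$true_distance,
    donor_bleach_frame = donor_bleach,
    acceptor_bleach_frame = acceptor_bleach,
    species = species,
    factors = correction_factors(p$alpha, p$delta, p$gamma, p$beta),
    background_per_channel = p$background_per_channel
  )
  list(trace = trace, truth = truth)
}

#' Simulate a cohort of ALEX traces with donor-only / acceptor-only species
#'
#' Generates a labelled mixture of doubly-labelled FRET traces and
#' singly-labelled contaminants, as needed to estimate the leakage and
#' direct-excitation correction factors from the data itself.
#'
#' @param n_traces Number of traces (>= 1).
#' @param params [trace_sim_params()] shared by all traces; `params$seed`
#'   seeds the whole cohort.
#' @param donor_only_fraction,acceptor_only_fraction Fractions in \[0, 1\]
#'   with sum <= 1.
#' @return List of class `trace_set`; each element carries `trace`, `truth`,
#'   `species` and `id`.
#' @export
simulate_trace_cohort <- function(n_traces, params, donor_only_fraction = 0,
                                  acceptor_only_fraction = 0) {
  stopifnot(inherits(params, "trace_sim_params"))
  if (n_traces < 1) stop("n_traces must be >= 1")
  f_d <- donor_only_fraction; f_a <- acceptor_only_fraction
  if (f_d < 0 || f_a < 0 || f_d > 1 || f_a > 1 || f_d + f_a > 1) {
    stop("species fractions must lie in [0, 1] and sum to <= 1")
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  params_inner <- params
  params_inner$seed <- NULL
  n_d <- round(f_d * n_traces)
  n_a <- round(f_a * n_traces)
  if (n_d + n_a > n_traces) n_a <- n_traces - n_d
  species <- sample(c(rep("donor-only", n_d), rep("acceptor-only", n_a),
                      rep("fret", n_traces - n_d - n_a)))
  out <- lapply(seq_len(n_traces), function(i) {
    sim <- simulate_alex_trace(params_inner, species = species[i])
    sim$species <- species[i]
    sim$id <- sprintf("trace_%04d", i)
    sim
  })
  structure(out, class = "trace_set", params = params)
}

#' @export
print.trace_set <- function(x, ...) {
  sp <- table(vapply(x, `[[`, "", "species"))
  cat(sprintf("trace_set: %d traces (%s)\n", length(x),
              paste(names(sp), sp, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write / read a trace set as delimited text plus JSON truth sidecars
#'
#' Each trace is stored as `<id>.csv` with columns `frame,I_DD,I_DA,I_AA`;
#' its ground truth (when present) as `<id>.json` next to it, paired by
#' basename.
#'
#' @param trace_set A `trace_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trace_set <- function(trace_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in trace_set) {
    write.csv(tr$trace, file.path(dir, paste0(tr$id, ".csv")),
              row.names = FALSE)
    if (!is.null(tr$truth)) {
      truth <- tr$truth
      truth$factors <- unclass(truth$factors)
      jsonlite::write_json(truth, file.path(dir, paste0(tr$id, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}

#' @rdname write_trace_set
#' @export
read_trace_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no trace CSV files found in ", dir)
  out <- lapply(files, function(f) {
    trace <- read.csv(f)
    need <- c("frame", "I_DD", "I_DA", "I_AA")
    if (!all(need %in% names(trace))) {
      stop("trace file ", f, " lacks columns ", paste(need, collapse = ","))
    }
    jf <- sub("\\.csv$", ".json", f)
    truth <- if (file.exists(jf)) jsonlite::read_json(jf, simplifyVector = TRUE)
    list(trace = trace[need], truth = truth,
         species = if (!is.null(truth)) truth$species else "unknown",
         id = sub("\\.csv$", "", basename(f)))
  })
  structure(out, class = "trace_set")
}
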