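#' Correction factor bundle for ALEX-FRET
#'
#' @param alpha Donor leakage into the acceptor channel (>= 0).
#' @param delta Acceptor direct excitation by the donor laser (>= 0).
#' @param gamma Detection-efficiency/quantum-yield factor (> 0).
#' @param beta Excitation-balance factor (> 0).
#' @return List of class `correction_factors`.
#' @export
correction_factors <- function(alpha = 0, delta = 0, gamma = 1, beta = 1) {
  stopifnot(alpha >= 0, delta >= 0, gamma > 0, beta > 0,
            all(is.finite(c(alpha, delta, gamma, beta))))
  structure(list(alpha = alpha, delta = delta, gamma = gamma, beta = beta),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat(sprintf("correction_factors: alpha=%.4f delta=%.4f gamma=%.4f beta=%.4f\n",
              x$alpha, x$delta, x$gamma, x$beta))
  invisible(x)
}

#' Detect single-step intensity changes in a trace channel
#'
#' Two-window mean-shift detector: at each frame the difference between the
#' mean of the following `min_dwell` frames and the mean of the preceding
#' `min_dwell` frames is compared against `threshold` times a robust noise
#' estimate (median absolute deviation of the first difference, scaled).
#' Candidate frames are reduced to local extrema separated by at least
#' `min_dwell` frames.
#'
#' @param x Numeric intensity series (length >= 2 * min_dwell).
#' @param min_dwell Minimum dwell (window) length in frames.
#' @param threshold Step amplitude threshold in multiples of the noise sd.
#' @return data.frame with `frame` (first frame of the new level), `sign`
#'   (+1 rise, -1 drop) and `amplitude`, sorted by frame.
#' @export
detect_bleach_steps <- function(x, min_dwell = 5L, threshold = 3) {
  n <- length(x)
  if (n < 2L * min_dwell) stop("series shorter than 2 * min_dwell")
  cs <- c(0, cumsum(x))
  win_mean <- function(from, to) (cs[to + 1L] - cs[from]) / (to - from + 1L)
  t_cand <- (min_dwell + 1L):(n - min_dwell + 1L)
  shift <- vapply(t_cand, function(t) {
    win_mean(t, t + min_dwell - 1L) - win_mean(t - min_dwell, t - 1L)
  }, numeric(1))
  # local noise: MAD of first differences in a window around each candidate,
  # so quiet (post-bleach) stretches do not deflate the threshold for the
  # live part of the trace (and vice versa)
  dx <- diff(x)
  halfwin <- 2L * min_dwell
  noise_sd <- vapply(t_cand, function(t) {
    idx <- max(1L, t - halfwin):min(length(dx), t + halfwin - 1L)
    mad(dx[idx]) / sqrt(2)
  }, numeric(1))
  # photon-counting floor: even if the empirical MAD collapses (quiet dark
  # stretches), the mean-shift of Poisson counts has standard error
  # sqrt(2 * mu / min_dwell)
  loc_mean <- vapply(t_cand, function(t) {
    (win_mean(t, t + min_dwell - 1L) + win_mean(t - min_dwell, t - 1L)) / 2
  }, numeric(1))
  pois_floor <- sqrt(2 * pmax(loc_mean, 0) / min_dwell)
  thr <- pmax(threshold * pmax(noise_sd, pois_floor),
              .Machine$double.eps^0.5)
  cand <- which(abs(shift) > thr)
  if (length(cand) == 0L) {
    return(data.frame(frame = integer(0), sign = integer(0),
                      amplitude = numeric(0)))
  }
  # greedy non-maximum suppression: largest |shift| first, minimum separation
  ord <- cand[order(-abs(shift[cand]))]
  keep <- integer(0)
  for (i in ord) {
    if (all(abs(i - keep) >= min_dwell)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  data.frame(frame = t_cand[keep],
             sign = ifelse(shift[keep] > 0, 1L, -1L),
             amplitude = abs(shift[keep]))
}

# Per-trace, per-channel background. Each donor-excitation channel (I_DD,
# I_DA) is only at background once the donor has bleached, so both use the
# window after the last downward step of I_DD; I_AA uses the window after
# its own last downward step. A window is accepted only when the channel
# level there is clearly below the preceding signal (guards against
# spurious step detections); channels whose fluorophore never bleaches
# within the trace fall back to 0 -- their background is not observable
# trace-wise.
estimate_background <- function(trace, min_dwell = 5L, threshold = 3) {
  out <- c(I_DD = 0, I_DA = 0, I_AA = 0)
  n <- nrow(trace)
  last_down <- function(x) {
    st <- tryCatch(detect_bleach_steps(x, min_dwell, threshold),
                   error = function(e) NULL)
    down <- if (!is.null(st)) st$frame[st$sign < 0] else integer(0)
    if (length(down)) max(down) else NA_integer_
  }
  dark_mean <- function(x, f) {
    if (is.na(f)) return(NA_real_)
    post <- x[seq.int(min(f + 1L, n), n)]
    pre_level <- mean(x[seq_len(max(f - 2L, 1L))])
    if (length(post) >= min_dwell && mean(post) < 0.5 * pre_level) {
      mean(post)
    } else NA_real_
  }
  f_donor <- last_down(trace$I_DD)
  bg_dd <- dark_mean(trace$I_DD, f_donor)
  if (is.finite(bg_dd)) {
    out[["I_DD"]] <- bg_dd
    post <- trace$I_DA[seq.int(min(f_donor + 1L, n), n)]
    out[["I_DA"]] <- mean(post)
  }
  bg_aa <- dark_mean(trace$I_AA, last_down(trace$I_AA))
  if (is.finite(bg_aa)) out[["I_AA"]] <- bg_aa
  out
}

#' Select valid single-pair FRET traces
#'
#' A trace is accepted when its acceptor-excitation channel (I_AA) shows
#' exactly one downward bleach step, the donor channel shows no downward
#' step before the acceptor bleach and at most one afterwards, and the donor
#' intensity rises (anticorrelation) at the acceptor bleach frame. This
#' automates the manual trace curation used with camera-based smFRET:
#' single-step photobleaching in both channels plus a donor rise upon
#' acceptor photobleaching.
#'
#' @param trace_set A `trace_set` (only `"fret"`-species or unknown-species
#'   traces are considered; known contaminants keep their labels so selection
#'   performance can be audited).
#' @param min_dwell,threshold Passed to [detect_bleach_steps()].
#' @return List of class `trace_selection`: `accepted` (a `trace_set` whose
#'   elements gain `acceptor_bleach_frame` and `donor_bleach_frame`) and
#'   `rejected_ids`.
#' @export
select_fret_traces <- function(trace_set, min_dwell = 5L, threshold = 3) {
  accepted <- list()
  rejected <- character(0)
  for (tr in trace_set) {
    ok <- FALSE
    f_acc <- NA_integer_
    f_don <- NA_integer_
    n <- nrow(tr$trace)
    steps_aa <- tryCatch(detect_bleach_steps(tr$trace$I_AA, min_dwell, threshold),
                         error = function(e) NULL)
    steps_dd <- tryCatch(detect_bleach_steps(tr$trace$I_DD, min_dwell, threshold),
                         error = function(e) NULL)
    if (!is.null(steps_aa) && !is.null(steps_dd)) {
      down_aa <- steps_aa[steps_aa$sign < 0, , drop = FALSE]
      down_dd <- steps_dd[steps_dd$sign < 0, , drop = FALSE]
      if (nrow(down_aa) == 1L) {
        f_acc <- down_aa$frame[1]
        pre_ok <- f_acc > min_dwell
        no_early_donor_loss <- !any(down_dd$frame < f_acc - 1L)
        single_donor_step <- sum(down_dd$frame >= f_acc - 1L) <= 1L
        f_don <- if (any(down_dd$frame >= f_acc - 1L)) {
          min(down_dd$frame[down_dd$frame >= f_acc - 1L])
        } else n + 1L
        post_end <- min(f_don - 1L, n)
        rise_ok <- FALSE
        if (pre_ok && post_end - f_acc + 1L >= min_dwell) {
          rise_ok <- mean(tr$trace$I_DD[f_acc:post_end]) >
            mean(tr$trace$I_DD[1:(f_acc - 1L)])
        }
        # single-step photobleaching means the acceptor-excitation channel
        # drops to (near) background -- a residual level indicates a second
        # acceptor fluorophore
        aa_pre <- mean(tr$trace$I_AA[1:max(f_acc - 2L, 1L)])
        aa_post <- mean(tr$trace$I_AA[min(f_acc + 1L, n):n])
        dark_ok <- aa_post < 0.25 * aa_pre
        ok <- pre_ok && no_early_donor_loss && single_donor_step &&
          rise_ok && dark_ok
      }
    }
    if (ok) {
      tr$acceptor_bleach_frame <- f_acc
      tr$donor_bleach_frame <- f_don
      accepted[[length(accepted) + 1L]] <- tr
    } else {
      rejected <- c(rejected, tr$id %||% "")
    }
  }
  structure(list(accepted = structure(accepted, class = "trace_set"),
                 rejected_ids = rejected),
            class = "trace_selection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate leakage (alpha) and direct excitation (delta)
#'
#' From singly-labelled species: alpha is the mean over donor-only traces of
#' the background-subtracted ratio I_DA / I_DD, delta the mean over
#' acceptor-only traces of I_DA / I_AA, each computed on the pre-bleach
#' window of the live channel.
#'
#' @param trace_set A `trace_set` containing species labels (as produced by
#'   [simulate_trace_cohort()] or [read_trace_set()]).
#' @param min_dwell,threshold Passed to step detection for windowing.
#' @return List with `alpha` and `delta`.
#' @export
estimate_alpha_delta <- function(trace_set, min_dwell = 5L, threshold = 3) {
  species <- vapply(trace_set, function(tr) tr$species %||% "unknown", "")
  d_only <- trace_set[species == "donor-only"]
  a_only <- trace_set[species == "acceptor-only"]
  if (length(d_only) == 0L || length(a_only) == 0L) {
    stop("need at least one donor-only and one acceptor-only trace")
  }
  ratio_live <- function(tr, live_ch, num_ch) {
    bg <- estimate_background(tr$trace, min_dwell, threshold)
    st <- tryCatch(detect_bleach_steps(tr$trace[[live_ch]], min_dwell, threshold),
                   error = function(e) NULL)
    down <- if (!is.null(st)) st$frame[st$sign < 0] else integer(0)
    last <- if (length(down)) min(down) - 2L else nrow(tr$trace)
    if (last < min_dwell) return(NA_real_)
    idx <- seq_len(last)
    den <- mean(tr$trace[[live_ch]][idx]) - bg[[live_ch]]
    num <- mean(tr$trace[[num_ch]][idx]) - bg[[num_ch]]
    # the live channel must carry real signal, not just background
    if (den <= max(20, 5 * bg[[live_ch]])) return(NA_real_)
    num / den
  }
  alpha <- mean(vapply(d_only, ratio_live, numeric(1), "I_DD", "I_DA"),
                na.rm = TRUE)
  delta <- mean(vapply(a_only, ratio_live, numeric(1), "I_AA", "I_DA"),
                na.rm = TRUE)
  list(alpha = max(alpha, 0), delta = max(delta, 0))
}

#' Estimate the detection factor gamma across acceptor bleach steps
#'
#' For each accepted trace, gamma is the ratio of the drop of the
#' crosstalk-corrected FRET signal (I_DA' = I_DA - alpha I_DD - delta I_AA)
#' to the rise of the donor signal across the acceptor bleach frame. The
#' returned value is the mean (or median) of the per-trace estimates.
#'
#' @param selection Result of [select_fret_traces()], or a `trace_set` whose
#'   elements carry `acceptor_bleach_frame`.
#' @param alpha,delta Crosstalk factors used for correction.
#' @param min_dwell Minimum window length on each side of the bleach.
#' @param average `"mean"` (default, matching the use of mean correction
#'   factors), `"median"` as a robust option, or `"pooled"`: the
#'   rise-weighted ratio estimator
#'   \eqn{\sum_i \Delta I_{DA,i}' / \sum_i \Delta I_{DD,i}}, which stays
#'   well-behaved when individual donor rises are only a few photons (the
#'   per-trace ratio is then heavy-tailed).
#' @return Scalar gamma estimate.
#' @export
estimate_gamma <- function(selection, alpha = 0, delta = 0, min_dwell = 5L,
                           average = c("mean", "median", "pooled")) {
  average <- match.arg(average)
  traces <- if (inherits(selection, "trace_selection")) selection$accepted
            else selection
  per_trace <- lapply(traces, function(tr) {
    f_acc <- tr$acceptor_bleach_frame
    if (is.null(f_acc) || is.na(f_acc)) return(NULL)
    n <- nrow(tr$trace)
    f_don <- min(tr$donor_bleach_frame %||% (n + 1L), n + 1L)
    # one guard frame on each side of the detected step absorbs +/-1
    # detection offsets
    pre <- seq_len(max(f_acc - 2L, 0L))
    post_from <- f_acc + 1L
    post_to <- min(f_don - 2L, n)
    if (post_from > post_to) return(NULL)
    post <- seq.int(post_from, post_to)
    if (length(pre) < min_dwell || length(post) < min_dwell) return(NULL)
    bg <- estimate_background(tr$trace, min_dwell)
    m <- function(ch, idx) mean(tr$trace[[ch]][idx]) - bg[[ch]]
    da_p <- function(idx) m("I_DA", idx) - alpha * m("I_DD", idx) -
      delta * m("I_AA", idx)
    d_dd <- m("I_DD", post) - m("I_DD", pre)
    se <- sqrt(stats::var(tr$trace$I_DD[pre]) / length(pre) +
                 stats::var(tr$trace$I_DD[post]) / length(post))
    if (!is.finite(d_dd)) return(NULL)
    c(num = da_p(pre) - da_p(post), den = d_dd, se = se)
  })
  per_trace <- do.call(rbind, per_trace[!vapply(per_trace, is.null, TRUE)])
  if (is.null(per_trace) || nrow(per_trace) == 0L) {
    stop("no usable bleach windows for gamma estimation")
  }
  if (average == "pooled") {
    if (sum(per_trace[, "den"]) <= 0) {
      stop("no usable bleach windows for gamma estimation")
    }
    return(sum(per_trace[, "num"]) / sum(per_trace[, "den"]))
  }
  # per-trace ratios: keep only traces whose donor rise is resolved well
  # above its standard error, otherwise the ratio is unstable
  ok <- per_trace[, "den"] > 3 * per_trace[, "se"]
  vals <- per_trace[ok, "num"] / per_trace[ok, "den"]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("no usable bleach windows for gamma estimation")
  if (average == "mean") mean(vals) else median(vals)
}

#' Estimate the excitation-balance factor beta
#'
#' beta normalizes for the different excitation intensities and absorption
#' cross-sections of donor and acceptor. It is computed as the ratio of the
#' average direct acceptor-excitation signal to the average total corrected
#' donor-excitation signal over the pre-bleach windows of doubly-labelled
#' traces:
#' \deqn{\beta = avg(I_{AA}) / avg(\gamma I_{DD} + F_{corr})}
#' where \eqn{F_{corr} = I_{DA} - \alpha I_{DD} - \delta I_{AA}}. The
#' denominator is the donor emission as it would be observed without FRET
#' quenching; in the absence of energy transfer it reduces to
#' \eqn{avg(\gamma I_{DD})}.
#'
#' @param selection Result of [select_fret_traces()] or a `trace_set` with
#'   `acceptor_bleach_frame` entries (traces without one use their full
#'   length).
#' @param gamma Detection factor (> 0).
#' @param alpha,delta Crosstalk factors.
#' @param min_dwell Minimum pre-bleach window length.
#' @return Scalar beta estimate.
#' @export
compute_beta <- function(selection, gamma, alpha = 0, delta = 0,
                         min_dwell = 5L) {
  stopifnot(gamma > 0)
  traces <- if (inherits(selection, "trace_selection")) selection$accepted
            else selection
  if (length(traces) == 0L) stop("empty trace set")
  num <- den <- numeric(0)
  for (tr in traces) {
    n <- nrow(tr$trace)
    f_acc <- tr$acceptor_bleach_frame %||% (n + 1L)
    if (is.na(f_acc)) f_acc <- n + 1L
    pre <- seq_len(min(f_acc - 2L, n))
    if (length(pre) < min_dwell) next
    bg <- estimate_background(tr$trace, min_dwell)
    m <- function(ch) mean(tr$trace[[ch]][pre]) - bg[[ch]]
    f_corr <- m("I_DA") - alpha * m("I_DD") - delta * m("I_AA")
    num <- c(num, m("I_AA"))
    den <- c(den, gamma * m("I_DD") + f_corr)
  }
  if (length(num) == 0L) stop("no usable pre-bleach windows")
  if (mean(den) <= 0) stop("zero or negative denominator in beta estimate")
  mean(num) / mean(den)
}

#' Corrected FRET efficiency and stoichiometry from window intensities
#'
#' Applies the full ALEX correction on (window-averaged) intensities:
#' \deqn{F_{corr} = I_{DA} - \alpha I_{DD} - \delta I_{AA}}
#' \deqn{E = F_{corr} / (\gamma I_{DD} + F_{corr})}
#' \deqn{S = (\gamma I_{DD} + F_{corr}) /
#'          (\gamma I_{DD} + F_{corr} + I_{AA}/\beta)}
#'
#' @param i_dd,i_da,i_aa Window-averaged intensities (vectorized).
#' @param factors [correction_factors()].
#' @return data.frame with `E` and `S`; rows with zero denominators are
#'   returned as `NA` and flagged via the `excluded` attribute.
#' @export
compute_e_s <- function(i_dd, i_da, i_aa, factors = correction_factors()) {
  stopifnot(inherits(factors, "correction_factors"))
  f_corr <- i_da - factors$alpha * i_dd - factors$delta * i_aa
  den_e <- factors$gamma * i_dd + f_corr
  den_s <- den_e + i_aa / factors$beta
  # E is undefined without donor-excited signal; S is still defined (0 for
  # a pure acceptor-only species) as long as its own denominator is nonzero
  E <- ifelse(den_e == 0, NA_real_, f_corr / den_e)
  S <- ifelse(den_s == 0, NA_real_, den_e / den_s)
  out <- data.frame(E = E, S = S)
  attr(out, "excluded") <- which(den_e == 0 | den_s == 0)
  out
}

#' Per-trace E,S points over pre-bleach windows
#'
#' Computes one background-subtracted (E, S) point per accepted trace from
#' all frames before the first detected bleach in either channel.
#'
#' @param selection Result of [select_fret_traces()].
#' @param factors [correction_factors()].
#' @param min_dwell Minimum usable window length.
#' @return data.frame with `id`, `E`, `S`.
#' @export
es_points <- function(selection, factors, min_dwell = 5L) {
  traces <- if (inherits(selection, "trace_selection")) selection$accepted
            else selection
  rows <- lapply(traces, function(tr) {
    n <- nrow(tr$trace)
    f_first <- min(tr$acceptor_bleach_frame %||% (n + 1L),
                   tr$donor_bleach_frame %||% (n + 1L), n + 1L, na.rm = TRUE)
    pre <- seq_len(min(f_first - 2L, n))
    if (length(pre) < min_dwell) return(NULL)
    bg <- estimate_background(tr$trace, min_dwell)
    es <- compute_e_s(mean(tr$trace$I_DD[pre]) - bg[["I_DD"]],
                      mean(tr$trace$I_DA[pre]) - bg[["I_DA"]],
                      mean(tr$trace$I_AA[pre]) - bg[["I_AA"]], factors)
    if (!is.finite(es$E[1])) return(NULL)
    data.frame(id = tr$id %||% NA_character_, E = es$E[1], S = es$S[1])
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Fit a Gaussian to the corrected FRET efficiency population
#'
#' Histograms E for points whose stoichiometry falls inside `s_window` and
#' fits a single Gaussian to the bin counts by least squares.
#'
#' @param es data.frame with columns `E` and `S` (e.g. from [es_points()]).
#' @param s_window Stoichiometry acceptance window (default 0.3-0.7, the
#'   doubly-labelled band).
#' @param nbins Number of histogram bins over the E range of the selected
#'   points.
#' @param on_fail `"error"` (default) or `"moments"`: fall back to the
#'   sample mean/sd when the least-squares fit does not converge.
#' @return List of class `fret_population`: `mean_E`, `sigma_E`, `n_traces`,
#'   `s_window`.
#' @export
fit_es_population <- function(es, s_window = c(0.3, 0.7), nbins = 25L,
                              on_fail = c("error", "moments")) {
  on_fail <- match.arg(on_fail)
  keep <- es$S >= s_window[1] & es$S <= s_window[2] & is.finite(es$E)
  e <- es$E[keep]
  if (length(e) < 10L) stop("fewer than 10 points inside the S window")
  if (sd(e) < 1e-12) {
    pop <- list(mean_E = mean(e), sigma_E = 0, n_traces = length(e),
                s_window = s_window)
    class(pop) <- "fret_population"
    return(pop)
  }
  # bin over the population core (median +/- 6 robust sd) so single stray
  # outliers from near-degenerate windows cannot dictate the bin width
  core_sd <- max(mad(e), sd(e) / 10)
  lo <- max(median(e) - 6 * core_sd, min(e) - 1e-9)
  hi <- min(median(e) + 6 * core_sd, max(e) + 1e-9)
  e_fit <- e[e >= lo & e <= hi]
  breaks <- seq(lo - 1e-12, hi + 1e-12, length.out = nbins + 1L)
  h <- graphics::hist(e_fit, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sig^2)), data = df,
                      start = list(A = max(df$y), mu = median(e), sig = max(core_sd, 1e-4)),
                      lower = c(0, -0.5, 1e-6), upper = c(Inf, 1.5, 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    if (on_fail == "error") stop("Gaussian population fit did not converge")
    mean_E <- mean(e); sigma_E <- sd(e)
  } else {
    cf <- coef(fit)
    mean_E <- unname(cf["mu"]); sigma_E <- abs(unname(cf["sig"]))
  }
  structure(list(mean_E = mean_E, sigma_E = sigma_E, n_traces = length(e),
                 s_window = s_window), class = "fret_population")
}

#' @export
print.fret_population <- function(x, ...) {
  cat(sprintf("FRET population: E = %.3f +/- %.3f (n = %d, S in [%.2f, %.2f])\n",
              x$mean_E, x$sigma_E, x$n_traces, x$s_window[1], x$s_window[2]))
  invisible(x)
}

#' Full ALEX correction pipeline on a simulated or imported cohort
#'
#' Convenience wrapper: selects valid FRET traces, estimates alpha/delta from
#' singly-labelled species (when present), gamma across acceptor bleach
#' steps, beta from the excitation balance, computes per-trace E,S and fits
#' the population Gaussian.
#'
#' @param trace_set A `trace_set`.
#' @param factors Optional fixed [correction_factors()]; when `NULL`
#'   (default) all four factors are estimated from the data.
#' @param s_window Stoichiometry window for the population fit.
#' @param min_dwell,threshold Trace-selection parameters.
#' @param gamma_average Averaging mode handed to [estimate_gamma()]; the
#'   pipeline default is the pooled (rise-weighted) estimator, which stays
#'   stable for weak-FRET samples where individual donor rises are tiny.
#' @return List with `population`, `es`, `factors`, `selection`.
#' @export
analyze_trace_set <- function(trace_set, factors = NULL,
                              s_window = c(0.3, 0.7), min_dwell = 5L,
                              threshold = 3, gamma_average = "pooled") {
  sel <- select_fret_traces(trace_set, min_dwell, threshold)
  if (is.null(factors)) {
    species <- vapply(trace_set, function(tr) tr$species %||% "unknown", "")
    ad <- if (any(species == "donor-only") && any(species == "acceptor-only")) {
      estimate_alpha_delta(trace_set, min_dwell, threshold)
    } else list(alpha = 0, delta = 0)
    gamma <- estimate_gamma(sel, ad$alpha, ad$delta, min_dwell,
                            average = gamma_average)
    beta <- compute_beta(sel, gamma, ad$alpha, ad$delta, min_dwell)
    factors <- correction_factors(ad$alpha, ad$delta, gamma, beta)
  }
  es <- es_points(sel, factors, min_dwell)
  pop <- fit_es_population(es, s_window)
  list(population = pop, es = es, factors = factors, selection = sel)
}
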