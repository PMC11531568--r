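#' Photon distribution analysis model
#'
#' Describes the generative model for shot-noise-limited donor/acceptor
#' photon ratios: one or more Gaussian-distributed distance states, an
#' empirical distribution of total donor-excitation photons per window, the
#' Forster radius, the correction factors that map a distance to the
#' apparent acceptor fraction, and optional per-channel Poisson background.
#'
#' @param states data.frame with columns `distance_nm`, `width_nm`,
#'   `occupancy` (occupancies must sum to 1, widths >= 0).
#' @param counts Integer vector of total photons N per window, or a
#'   data.frame `N, prob` giving the count distribution directly.
#' @param R0 Forster radius in nm.
#' @param factors [correction_factors()].
#' @param background Length-2 numeric, mean background photons per window in
#'   the donor and acceptor channel.
#' @return List of class `pda_model`.
#' @export
pda_model <- function(states, counts, R0,
                      factors = correction_factors(),
                      background = c(donor = 0, acceptor = 0)) {
  stopifnot(is.data.frame(states),
            all(c("distance_nm", "width_nm", "occupancy") %in% names(states)),
            all(states$width_nm >= 0), all(states$distance_nm > 0),
            abs(sum(states$occupancy) - 1) < 1e-8, R0 > 0,
            all(background >= 0))
  if (is.data.frame(counts)) {
    stopifnot(all(c("N", "prob") %in% names(counts)), nrow(counts) > 0)
    nd <- counts
    nd$prob <- nd$prob / sum(nd$prob)
  } else {
    if (length(counts) == 0L) stop("empty photon-count distribution")
    tb <- table(round(counts))
    nd <- data.frame(N = as.integer(names(tb)),
                     prob = as.numeric(tb) / sum(tb))
  }
  structure(list(states = states, counts = nd, R0 = R0, factors = factors,
                 background = background), class = "pda_model")
}

# apparent acceptor fraction among donor-excitation photons at distance r:
# acceptor channel collects the gamma-weighted FRET photons, leakage, and
# the mean direct-excitation contribution; the donor channel the quenched
# donor emission
pda_apparent_eps <- function(r, R0, factors) {
  E <- 1 / (1 + (r / R0)^6)
  acc <- factors$gamma * E + factors$alpha * (1 - E) +
    factors$delta * factors$beta * factors$gamma
  acc / (acc + (1 - E))
}

trunc_pois_support <- function(lambda, tol = 1e-10) {
  if (lambda <= 0) return(data.frame(k = 0L, p = 1))
  lo <- qpois(tol, lambda); hi <- qpois(1 - tol, lambda)
  k <- lo:hi
  p <- dpois(k, lambda)
  data.frame(k = k, p = p / sum(p))
}

#' Predicted shot-noise-limited photon-ratio distribution
#'
#' For every total photon count N in the model's count distribution and
#' every quadrature draw of the state distance r (Gaussian, truncated
#' positive), acceptor counts follow Binomial(N, eps(r)) with eps the
#' correction-adjusted apparent efficiency; per-channel Poisson background
#' counts are added, and the probability mass of the resulting proximity
#' ratio I_DA / (I_DA + I_DD) is accumulated into the requested bins.
#'
#' @param model [pda_model()].
#' @param breaks Bin boundaries partitioning \[0, 1\] (default 40 bins).
#' @param n_quad Number of equal-probability quadrature nodes for a state's
#'   distance distribution (only used when its width is > 0).
#' @return data.frame with `lo`, `hi`, `mid`, `prob` (sums to 1).
#' @export
pda_predict <- function(model, breaks = seq(0, 1, length.out = 41L),
                        n_quad = 21L) {
  stopifnot(inherits(model, "pda_model"))
  if (abs(breaks[1]) > 1e-12 || abs(breaks[length(breaks)] - 1) > 1e-12) {
    stop("breaks must partition [0, 1]")
  }
  nb <- length(breaks) - 1L
  prob <- numeric(nb)
  bgd <- trunc_pois_support(model$background[[1]])
  bga <- trunc_pois_support(model$background[[2]])
  for (si in seq_len(nrow(model$states))) {
    st <- model$states[si, ]
    if (st$width_nm > 0) {
      z <- stats::qnorm((seq_len(n_quad) - 0.5) / n_quad)
      r_nodes <- pmax(st$distance_nm + st$width_nm * z, 1e-6)
      r_w <- rep(1 / n_quad, n_quad)
    } else {
      r_nodes <- st$distance_nm
      r_w <- 1
    }
    for (ri in seq_along(r_nodes)) {
      eps <- pda_apparent_eps(r_nodes[ri], model$R0, model$factors)
      for (ni in seq_len(nrow(model$counts))) {
        N <- model$counts$N[ni]
        pN <- model$counts$prob[ni] * st$occupancy * r_w[ri]
        if (N > 0) {
          lo <- qbinom(1e-12, N, eps); hi <- qbinom(1 - 1e-12, N, eps)
          acc <- lo:hi
          pa <- dbinom(acc, N, eps)
          pa <- pa / sum(pa)
        } else {
          acc <- 0L; pa <- 1
        }
        for (ti in seq_len(nrow(bga))) {
          for (ui in seq_len(nrow(bgd))) {
            tot <- N + bga$k[ti] + bgd$k[ui]
            w <- pN * pa * bga$p[ti] * bgd$p[ui]
            if (tot == 0) next
            ratio <- (acc + bga$k[ti]) / tot
            bin <- pmin(pmax(findInterval(ratio, breaks,
                                          rightmost.closed = TRUE), 1L), nb)
            for (b in unique(bin)) prob[b] <- prob[b] + sum(w[bin == b])
          }
        }
      }
    }
  }
  if (sum(prob) <= 0) stop("empty photon-count distribution")
  prob <- prob / sum(prob)
  data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
             mid = (breaks[-1] + breaks[-length(breaks)]) / 2, prob = prob)
}

#' Extract per-trace PDA windows from selected traces
#'
#' Aggregates the raw donor-excitation photon counts (I_DD, I_DA) of each
#' accepted trace over its pre-bleach window into one PDA window.
#'
#' @param selection Result of [select_fret_traces()] or a `trace_set`.
#' @param min_dwell Minimum pre-bleach window length.
#' @return data.frame with `I_DD`, `I_DA` (summed counts per window).
#' @export
pda_windows <- function(selection, min_dwell = 5L) {
  traces <- if (inherits(selection, "trace_selection")) selection$accepted
            else selection
  rows <- lapply(traces, function(tr) {
    n <- nrow(tr$trace)
    f_first <- min(tr$acceptor_bleach_frame %||% (n + 1L),
                   tr$donor_bleach_frame %||% (n + 1L), n + 1L, na.rm = TRUE)
    pre <- seq_len(min(f_first - 2L, n))
    if (length(pre) < min_dwell) return(NULL)
    data.frame(I_DD = sum(tr$trace$I_DD[pre]), I_DA = sum(tr$trace$I_DA[pre]))
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Fit a PDA model to an observed donor/acceptor count histogram
#'
#' Fits the mean distance and width of a single limited-width state (the
#' occupancy is 1) by minimizing the Pearson chi-square between the observed
#' proximity-ratio histogram and the PDA prediction, using the empirical
#' photon-count distribution of the windows.
#'
#' @param windows data.frame with raw per-window counts `I_DD`, `I_DA`
#'   (>= 100 windows).
#' @param R0 Forster radius in nm.
#' @param factors [correction_factors()] describing the setup.
#' @param n_states Number of states; only 1 is supported (matching the
#'   fixed number of limited-width states used for this analysis).
#' @param breaks Ratio histogram bin boundaries.
#' @param background Per-window background means (donor, acceptor).
#' @param start Optional starting values `c(distance_nm, width_nm)`.
#' @return List of class `pda_fit`: `distance_nm`, `width_nm`, `chisq`,
#'   `dof`, `chisq_red`, `predicted`, `observed`, `convergence`.
#' @export
pda_fit <- function(windows, R0, factors = correction_factors(),
                    n_states = 1L, breaks = seq(0, 1, length.out = 41L),
                    background = c(0, 0), start = NULL) {
  if (n_states != 1L) stop("only a single limited-width state is supported")
  stopifnot(is.data.frame(windows), all(c("I_DD", "I_DA") %in% names(windows)))
  if (nrow(windows) < 100L) stop("need >= 100 windows for a PDA fit")
  N <- round(windows$I_DD + windows$I_DA)
  ratio <- windows$I_DA / pmax(N, 1)
  nb <- length(breaks) - 1L
  obs <- tabulate(pmin(pmax(findInterval(ratio, breaks,
                                         rightmost.closed = TRUE), 1L), nb),
                  nbins = nb)
  n_tot <- sum(obs)
  # compress the count distribution to at most 50 support points
  tb <- table(N)
  nd <- data.frame(N = as.integer(names(tb)), prob = as.numeric(tb) / sum(tb))
  if (nrow(nd) > 50L) {
    qs <- unique(round(quantile(N, probs = (seq_len(50L) - 0.5) / 50)))
    grp <- qs[pmax(findInterval(nd$N, qs), 1L)]
    nd <- aggregate(prob ~ grp, data.frame(grp = grp, prob = nd$prob), sum)
    names(nd) <- c("N", "prob")
  }
  if (is.null(start)) {
    eps0 <- min(max(mean(ratio), 0.01), 0.99)
    # invert the apparent-efficiency map numerically for the start value
    r_grid <- seq(0.2 * R0, 3 * R0, length.out = 400)
    r0_start <- r_grid[which.min(abs(pda_apparent_eps(r_grid, R0, factors) - eps0))]
    start <- c(r0_start, 0.05 * R0)
  }
  # greedy merge of adjacent bins until each merged bin expects >= 5
  # counts: the usual validity condition for a Pearson goodness-of-fit
  merged_chisq <- function(obs, expd, min_expected = 5) {
    o_acc <- e_acc <- 0
    o_m <- e_m <- numeric(0)
    for (k in seq_along(obs)) {
      o_acc <- o_acc + obs[k]; e_acc <- e_acc + expd[k]
      if (e_acc >= min_expected) {
        o_m <- c(o_m, o_acc); e_m <- c(e_m, e_acc)
        o_acc <- e_acc <- 0
      }
    }
    if (e_acc > 0 && length(e_m)) {
      o_m[length(o_m)] <- o_m[length(o_m)] + o_acc
      e_m[length(e_m)] <- e_m[length(e_m)] + e_acc
    }
    list(chisq = sum((o_m - e_m)^2 / e_m), n_bins = length(e_m))
  }
  predict_for <- function(par) {
    states <- data.frame(distance_nm = par[1], width_nm = max(par[2], 0),
                         occupancy = 1)
    pda_predict(pda_model(states, nd, R0, factors,
                          c(background[1], background[2])), breaks)
  }
  objective <- function(par) {
    expd <- n_tot * predict_for(par)$prob
    sum((obs - expd)^2 / pmax(expd, 0.5))   # smooth floored Pearson
  }
  opt <- optim(start, objective, method = "L-BFGS-B",
               lower = c(0.2 * R0, 0), upper = c(4 * R0, R0),
               control = list(maxit = 200))
  pred <- predict_for(opt$par)
  mg <- merged_chisq(obs, n_tot * pred$prob)
  dof <- mg$n_bins - 1L - 2L
  if (opt$convergence != 0) {
    warning("PDA fit did not fully converge: ", opt$message %||% opt$convergence)
  }
  structure(list(distance_nm = opt$par[1], width_nm = opt$par[2],
                 chisq = mg$chisq, dof = dof,
                 chisq_red = mg$chisq / max(dof, 1L),
                 predicted = pred, observed = obs,
                 convergence = opt$convergence),
            class = "pda_fit")
}

#' @export
print.pda_fit <- function(x, ...) {
  cat(sprintf("PDA fit: r = %.2f nm, width = %.2f nm, chi2/dof = %.2f\n",
              x$distance_nm, x$width_nm, x$chisq_red))
  invisible(x)
}
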