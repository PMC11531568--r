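test_that("step detection finds clean steps and ignores constant series", {
  expect_equal(nrow(detect_bleach_steps(rep(100, 50))), 0L)
  x <- c(rep(100, 49), rep(0, 51))
  st <- detect_bleach_steps(x)
  expect_equal(st$frame, 50L)
  expect_equal(st$sign, -1L)
  expect_equal(st$amplitude, 100)
  expect_error(detect_bleach_steps(c(1, 2, 3), min_dwell = 5), "min_dwell")
})

test_that("step detection locates simulated bleach frames within 2 frames", {
  set.seed(17)
  hits <- replicate(200, {
    f_true <- sample(30:170, 1)
    x <- rpois(200, ifelse(seq_len(200) < f_true, 300, 2))
    st <- detect_bleach_steps(x)
    down <- st$frame[st$sign < 0]
    length(down) >= 1 && min(abs(down - f_true)) <= 2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("trace selection accepts single-pair traces and rejects multi-step decays", {
  good <- make_noiseless_trace(E = 0.6, f_acc = 100L)
  # add mild noise so the MAD-based threshold is meaningful
  set.seed(2)
  good$trace[2:4] <- lapply(good$trace[2:4], function(v) rpois(length(v), v + 1))
  sel <- select_fret_traces(structure(list(good), class = "trace_set"))
  expect_length(sel$accepted, 1L)
  expect_lt(abs(sel$accepted[[1]]$acceptor_bleach_frame - 100L), 3L)

  # two-step acceptor decay (two acceptors) must be rejected
  two_acc <- good
  two_acc$trace$I_AA <- rpois(200, c(rep(600, 59), rep(300, 60), rep(2, 81)))
  sel2 <- select_fret_traces(structure(list(two_acc), class = "trace_set"))
  expect_length(sel2$accepted, 0L)
})

test_that("most multi-fluorophore contaminants are rejected", {
  p <- trace_sim_params(true_distance = 4.8, seed = 12)
  singles <- simulate_trace_cohort(140, p)
  # contaminants: superpositions of two independent dye pairs
  contam <- lapply(1:30, function(i) {
    a <- singles[[2 * i - 1]]; b <- singles[[2 * i]]
    a$trace[2:4] <- a$trace[2:4] + b$trace[2:4]
    a$id <- sprintf("contam_%02d", i)
    a
  })
  sel <- select_fret_traces(structure(contam, class = "trace_set"))
  expect_lte(length(sel$accepted), 3L)   # >= 90% rejected
})

test_that("alpha and delta come out exactly on constructed single-dye traces", {
  d_only <- list(trace = data.frame(frame = 1:50, I_DD = rep(200, 50),
                                    I_DA = rep(20, 50), I_AA = rep(0, 50)),
                 species = "donor-only", id = "d")
  a_only <- list(trace = data.frame(frame = 1:50, I_DD = rep(0, 50),
                                    I_DA = rep(0, 50), I_AA = rep(300, 50)),
                 species = "acceptor-only", id = "a")
  ts <- structure(list(d_only, a_only), class = "trace_set")
  ad <- estimate_alpha_delta(ts)
  expect_equal(ad$alpha, 0.1, tolerance = 1e-12)
  expect_equal(ad$delta, 0, tolerance = 1e-12)
  expect_error(estimate_alpha_delta(structure(list(d_only),
                                              class = "trace_set")),
               "at least one")
})

test_that("alpha and delta are recovered from a noisy cohort within 0.01", {
  p <- trace_sim_params(true_distance = 4.8, alpha = 0.08, delta = 0.05,
                        seed = 23)
  ts <- simulate_trace_cohort(100, p, 0.3, 0.3)
  ad <- estimate_alpha_delta(ts)
  expect_lt(abs(ad$alpha - 0.08), 0.01)
  expect_lt(abs(ad$delta - 0.05), 0.01)
})

test_that("gamma is exact on noiseless traces and recovered from noisy cohorts", {
  for (g in c(1, 1.5)) {
    tr <- make_noiseless_trace(E = 0.6, gamma = g, f_acc = 100L)
    ts <- structure(list(tr), class = "trace_set")
    expect_equal(estimate_gamma(ts), g, tolerance = 1e-9)
  }
  p <- trace_sim_params(true_distance = 5.5, gamma = 0.9, seed = 41)
  sel <- select_fret_traces(simulate_trace_cohort(100, p))
  g_hat <- estimate_gamma(sel, alpha = p$alpha, delta = p$delta)
  expect_lt(abs(g_hat - 0.9), 0.05)
  g_pooled <- estimate_gamma(sel, alpha = p$alpha, delta = p$delta,
                             average = "pooled")
  expect_lt(abs(g_pooled - 0.9), 0.05)
  expect_error(estimate_gamma(structure(list(), class = "trace_set")),
               "no usable")
})

test_that("beta equals the excitation-balance ratio and is recovered from cohorts", {
  flat <- function(iaa) {
    list(trace = data.frame(frame = 1:50, I_DD = rep(100, 50),
                            I_DA = rep(0, 50), I_AA = rep(iaa, 50)),
         species = "fret", id = "b", acceptor_bleach_frame = NA,
         donor_bleach_frame = NA)
  }
  expect_equal(compute_beta(structure(list(flat(100)), class = "trace_set"),
                            gamma = 1), 1, tolerance = 1e-12)
  expect_equal(compute_beta(structure(list(flat(200)), class = "trace_set"),
                            gamma = 1), 2, tolerance = 1e-12)
  p <- trace_sim_params(true_distance = 5.5, beta = 1.3, seed = 43)
  sel <- select_fret_traces(simulate_trace_cohort(100, p))
  b_hat <- compute_beta(sel, gamma = p$gamma, alpha = p$alpha,
                        delta = p$delta)
  expect_lt(abs(b_hat - 1.3), 0.05)
})

test_that("E and S follow the correction equations exactly", {
  es <- compute_e_s(100, 100, 100, correction_factors(0, 0, 1, 1))
  expect_equal(es$E, 0.5)
  expect_equal(es$S, 2 / 3)
  # donor-only: I_DA is pure leakage, no acceptor signal
  es2 <- compute_e_s(100, 10, 0, correction_factors(alpha = 0.1))
  expect_equal(es2$E, 0)
  expect_equal(es2$S, 1)
  es3 <- compute_e_s(100, 20, 100, correction_factors(0.1, 0.05, 1, 1))
  expect_equal(es3$E, 5 / 105)
  expect_equal(es3$S, 105 / 205)
  bad <- compute_e_s(0, 0, 0, correction_factors())
  expect_true(is.na(bad$E))
  expect_equal(attr(bad, "excluded"), 1L)
})

test_that("correction round-trips exactly on noiseless windows (machine precision)", {
  N <- 250
  for (E in c(0.1, 0.3, 0.55, 0.84, 0.9)) {
    for (g in c(0.8, 1, 1.4)) {
      f <- correction_factors(alpha = 0.07, delta = 0.04, gamma = g,
                              beta = 1.25)
      i_dd <- (1 - E) * N
      i_aa <- f$beta * f$gamma * N
      i_da <- f$gamma * E * N + f$alpha * i_dd + f$delta * i_aa
      es <- compute_e_s(i_dd, i_da, i_aa, f)
      expect_equal(es$E, E, tolerance = 1e-12)
      expect_equal(es$S, 0.5, tolerance = 1e-12)
    }
  }
})

test_that("corrected E is invariant under common rescaling of all channels", {
  f <- correction_factors(0.08, 0.06, 0.85, 1.2)
  base <- compute_e_s(48, 240, 306, f)
  for (k in c(0.1, 3, 42)) {
    scaled <- compute_e_s(48 * k, 240 * k, 306 * k, f)
    expect_equal(scaled$E, base$E, tolerance = 1e-12)
    expect_equal(scaled$S, base$S, tolerance = 1e-12)
  }
})

test_that("stoichiometry separates donor-only and acceptor-only species", {
  f <- correction_factors(0.08, 0.06, 0.85, 1.2)
  donor_only <- compute_e_s(300, 0.08 * 300, 0, f)
  expect_equal(donor_only$S, 1, tolerance = 1e-9)
  acceptor_only <- compute_e_s(0, 0.06 * 306, 306, f)
  expect_equal(acceptor_only$S, 0, tolerance = 1e-9)
})

test_that("population fitting recovers Gaussian parameters", {
  set.seed(9)
  es <- data.frame(E = rnorm(113, 0.84, 0.06), S = runif(113, 0.35, 0.65))
  pop <- fit_es_population(es)
  expect_equal(pop$mean_E, 0.84, tolerance = 0.02)
  expect_equal(pop$n_traces, 113L)
  # degenerate: identical values
  es2 <- data.frame(E = rep(0.5, 20), S = rep(0.5, 20))
  pop2 <- fit_es_population(es2)
  expect_equal(pop2$mean_E, 0.5)
  expect_equal(pop2$sigma_E, 0)
  expect_error(fit_es_population(data.frame(E = rnorm(5), S = rep(0.5, 5))),
               "fewer than 10")
})

test_that("full pipeline recovers true efficiencies with small bias (200 traces)", {
  pair <- fluorophore_pair("cy3b_T")
  e_targets <- c(0.1, 0.3, 0.55, 0.84, 0.90)
  for (i in seq_along(e_targets)) {
    E <- e_targets[i]
    d <- pair$R0 * (1 / E - 1)^(1 / 6)
    p <- trace_sim_params(true_distance = d, pair = pair, seed = 100 + i)
    an <- analyze_trace_set(simulate_trace_cohort(200, p, 0.15, 0.15))
    expect_lt(abs(an$population$mean_E - E), 0.02)
  }
})
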