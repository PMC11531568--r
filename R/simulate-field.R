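#' Parameters for simulating a localization field
#'
#' Describes a synthetic single-molecule localization dataset emulating
#' dSTORM output over a flat membrane region: receptor clusters placed by a
#' homogeneous Poisson process, each re-localized several times across
#' blinking bursts with Gaussian localization error, plus uniform noise
#' localizations.
#'
#' @param area_um2 Field area in square micrometers (> 0; a square field).
#' @param cluster_density Clusters per square micrometer (>= 0).
#' @param localizations_per_cluster Mean localizations per cluster (Poisson,
#'   at least 1 drawn).
#' @param localization_precision Per-axis localization error sd in nm.
#' @param frame_count Number of camera frames.
#' @param noise_density Uniform noise localizations per square micrometer.
#' @param mean_burst_length Mean length (frames) of a blinking burst.
#' @param seed Optional integer seed.
#' @return List of class `field_params`.
#' @export
field_params <- function(area_um2 = 100, cluster_density = 3,
                         localizations_per_cluster = 60,
                         localization_precision = 10,
                         frame_count = 10000L, noise_density = 0.1,
                         mean_burst_length = 3, seed = NULL) {
  stopifnot(area_um2 > 0, cluster_density >= 0, noise_density >= 0,
            localizations_per_cluster > 0, localization_precision >= 0,
            frame_count >= 1, mean_burst_length >= 1)
  structure(list(area_um2 = area_um2, cluster_density = cluster_density,
                 localizations_per_cluster = localizations_per_cluster,
                 localization_precision = localization_precision,
                 frame_count = as.integer(frame_count),
                 noise_density = noise_density,
                 mean_burst_length = mean_burst_length, seed = seed),
            class = "field_params")
}

#' Simulate a dSTORM-like localization field with known cluster truth
#'
#' Cluster (receptor) positions follow a homogeneous spatial Poisson process
#' with the requested density; each cluster emits localizations grouped into
#' blinking bursts of consecutive frames, scattered around the true position
#' with the stated localization precision. Noise localizations are uniform
#' in space and time.
#'
#' @param params [field_params()].
#' @return List with `localizations` (data.frame `x_nm, y_nm, frame`) and
#'   `truth` (data.frame of cluster centers `x_nm, y_nm` plus counts).
#' @export
simulate_localization_field <- function(params) {
  stopifnot(inherits(params, "field_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  side_nm <- sqrt(params$area_um2) * 1000
  n_clusters <- rpois(1L, params$cluster_density * params$area_um2)
  rows <- list()
  truth <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      n_locs = integer(0))
  if (n_clusters > 0) {
    cx <- runif(n_clusters, 0, side_nm)
    cy <- runif(n_clusters, 0, side_nm)
    n_locs <- pmax(rpois(n_clusters, params$localizations_per_cluster), 1L)
    for (i in seq_len(n_clusters)) {
      k <- n_locs[i]
      frames <- integer(0)
      while (length(frames) < k) {
        len <- min(1L + rgeom(1L, 1 / params$mean_burst_length),
                   k - length(frames))
        start <- sample.int(params$frame_count, 1L)
        frames <- c(frames, seq.int(start, length.out = len))
      }
      frames <- pmin(frames, params$frame_count)
      rows[[i]] <- data.frame(
        x_nm = cx[i] + rnorm(k, 0, params$localization_precision),
        y_nm = cy[i] + rnorm(k, 0, params$localization_precision),
        frame = frames)
    }
    truth <- data.frame(x_nm = cx, y_nm = cy, n_locs = n_locs)
  }
  n_noise <- rpois(1L, params$noise_density * params$area_um2)
  if (n_noise > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      x_nm = runif(n_noise, 0, side_nm),
      y_nm = runif(n_noise, 0, side_nm),
      frame = sample.int(params$frame_count, n_noise, replace = TRUE))
  }
  locs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x_nm = numeric(0), y_nm = numeric(0), frame = integer(0))
  locs <- locs[order(locs$frame), , drop = FALSE]
  rownames(locs) <- NULL
  list(localizations = locs, truth = truth)
}

#' Read a localization table from delimited text
#'
#' Accepts plain `x_nm, y_nm, frame` headers as well as Picasso-style
#' column names (`x [nm]`, `y [nm]`, `frame`).
#'
#' @param path CSV file path.
#' @return data.frame with `x_nm`, `y_nm`, `frame`.
#' @export
read_localizations <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  nm <- names(df)
  pick <- function(cands) {
    hit <- match(tolower(cands), tolower(nm))
    hit <- hit[!is.na(hit)]
    if (!length(hit)) stop("missing localization column (looked for ",
                           paste(cands, collapse = "/"), ")")
    df[[hit[1]]]
  }
  out <- data.frame(x_nm = pick(c("x_nm", "x [nm]", "x")),
                    y_nm = pick(c("y_nm", "y [nm]", "y")),
                    frame = pick("frame"))
  if (any(!is.finite(out$x_nm)) || any(!is.finite(out$y_nm))) {
    stop("non-finite coordinates in localization table")
  }
  out
}
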