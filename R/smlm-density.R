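#' Localization precision by nearest-neighbor analysis (NeNA)
#'
#' Collects, for every pair of consecutive frames, the distance from each
#' localization to its nearest neighbour in the next frame, and fits the
#' distance histogram with the NeNA model
#' \eqn{p(d) = A \, d/(2\sigma^2) \exp(-d^2/(4\sigma^2)) + B d}
#' (repeated localization of the same emitter in consecutive frames, plus a
#' linear term for unrelated neighbours). Returns sigma, the per-frame
#' localization precision.
#'
#' @param locs data.frame with `x_nm`, `y_nm`, `frame`.
#' @param max_distance Histogram upper limit in nm (default 4x the distance
#'   median, capped below by 10 nm).
#' @param nbins Histogram bins.
#' @return Sigma in nm; the fitted curve is attached as attribute `fit`.
#' @export
nena_precision <- function(locs, max_distance = NULL, nbins = 50L) {
  stopifnot(all(c("x_nm", "y_nm", "frame") %in% names(locs)))
  if (nrow(locs) < 100L || length(unique(locs$frame)) < 2L) {
    stop("need >= 100 localizations spanning >= 2 frames")
  }
  by_frame <- split(seq_len(nrow(locs)), locs$frame)
  fr <- as.integer(names(by_frame))
  d_all <- numeric(0)
  for (i in seq_along(fr)) {
    j <- match(fr[i] + 1L, fr)
    if (is.na(j)) next
    a <- locs[by_frame[[i]], c("x_nm", "y_nm")]
    b <- locs[by_frame[[j]], c("x_nm", "y_nm")]
    d2 <- outer(a$x_nm, b$x_nm, "-")^2 + outer(a$y_nm, b$y_nm, "-")^2
    d_all <- c(d_all, sqrt(apply(d2, 1, min)))
  }
  if (length(d_all) < 50L) stop("insufficient consecutive-frame pairs")
  if (quantile(d_all, 0.9) < 1e-9) return(0)
  if (is.null(max_distance)) {
    max_distance <- max(4 * median(d_all), 10)
  }
  d_use <- d_all[d_all <= max_distance]
  h <- graphics::hist(d_use, breaks = seq(0, max_distance,
                                          length.out = nbins + 1L),
                      plot = FALSE)
  df <- data.frame(d = h$mids, y = h$density)
  sig0 <- median(d_use) / sqrt(2 * log(2)) / sqrt(2)
  fit <- minpack.lm::nlsLM(
    y ~ A * d / (2 * sig^2) * exp(-d^2 / (4 * sig^2)) + B * d, data = df,
    start = list(A = 1, sig = max(sig0, 0.5), B = 1e-6),
    lower = c(0, 1e-3, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  sigma <- unname(coef(fit)["sig"])
  attr(sigma, "fit") <- fit
  sigma
}

#' Link repeated localizations of the same emitter across frames
#'
#' Two localizations belong to the same binding event when they are within
#' `radius` of each other and separated by at most `max_dark_frames` dark
#' frames (i.e. a frame difference of `max_dark_frames + 1` or less);
#' linking is the transitive closure of this relation. Each linked group is
#' merged to its mean position and first frame.
#'
#' @param locs data.frame `x_nm, y_nm, frame`.
#' @param radius Link radius in nm (> 0).
#' @param max_dark_frames Maximum tolerated dark frames between
#'   localizations (default 5).
#' @return data.frame `x_nm, y_nm, frame, n_locs` of merged events; the
#'   group index per input row is attached as attribute `group`.
#' @export
link_localizations <- function(locs, radius, max_dark_frames = 5L) {
  stopifnot(radius > 0, max_dark_frames >= 0)
  n <- nrow(locs)
  if (n == 0L) {
    out <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      frame = integer(0), n_locs = integer(0))
    attr(out, "group") <- integer(0)
    return(out)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(locs$frame)
  fr <- locs$frame[ord]
  max_gap <- max_dark_frames + 1L
  # sliding frame window; candidate pairs restricted by frame difference
  lo <- 1L
  for (k in seq_len(n)) {
    while (fr[k] - fr[lo] > max_gap) lo <- lo + 1L
    if (lo < k) {
      cand <- ord[lo:(k - 1L)]
      cand <- cand[locs$frame[cand] < locs$frame[ord[k]]]
      if (length(cand)) {
        d2 <- (locs$x_nm[cand] - locs$x_nm[ord[k]])^2 +
          (locs$y_nm[cand] - locs$y_nm[ord[k]])^2
        for (j in cand[d2 <= radius^2]) {
          ri <- find(j); rk <- find(ord[k])
          if (ri != rk) parent[rk] <- ri
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  grp <- match(root, unique(root))
  out <- data.frame(
    x_nm = as.numeric(tapply(locs$x_nm, grp, mean)),
    y_nm = as.numeric(tapply(locs$y_nm, grp, mean)),
    frame = as.integer(tapply(locs$frame, grp, min)),
    n_locs = as.integer(tapply(grp, grp, length)))
  rownames(out) <- NULL
  attr(out, "group") <- grp
  out
}

#' DBSCAN clustering of localizations
#'
#' Standard DBSCAN semantics: a point is a core point when at least
#' `min_pts` points (counting itself) lie within `eps`; clusters grow from
#' core points in input order, and border points are assigned to the first
#' core cluster that reaches them (deterministic tie-break). Non-reachable
#' points are labelled noise (0).
#'
#' @param locs data.frame with `x_nm`, `y_nm` (extra columns ignored) or an
#'   n x 2 coordinate matrix.
#' @param eps Neighbourhood radius in nm (> 0).
#' @param min_pts Minimum neighbourhood size for a core point (>= 1).
#' @return List of class `cluster_result`: `labels` (0 = noise),
#'   `n_clusters`, `parameters`.
#' @export
dbscan_clusters <- function(locs, eps, min_pts) {
  stopifnot(eps > 0, min_pts >= 1)
  xy <- if (is.data.frame(locs)) cbind(locs$x_nm, locs$y_nm) else rbind(locs)
  n <- nrow(xy)
  labels <- integer(n)
  if (n == 0L) {
    return(structure(list(labels = labels, n_clusters = 0L,
                          parameters = list(eps = eps, min_pts = min_pts)),
                     class = "cluster_result"))
  }
  # bucket grid for neighbourhood queries
  cell <- eps
  ix <- floor(xy[, 1] / cell); iy <- floor(xy[, 2] / cell)
  key <- paste(ix, iy)
  buckets <- split(seq_len(n), key)
  neighbours <- function(i) {
    ks <- as.vector(outer(ix[i] + (-1:1), iy[i] + (-1:1), paste))
    cand <- unlist(buckets[ks], use.names = FALSE)
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    cand[d2 <= eps^2]
  }
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbours(i)
    if (length(nb) < min_pts) next     # noise unless claimed later
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) labels[j] <- cl
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbours(j)
        if (length(nbj) >= min_pts) {
          queue <- c(queue, nbj[!visited[nbj] | labels[nbj] == 0L])
        }
      }
    }
  }
  structure(list(labels = labels, n_clusters = cl,
                 parameters = list(eps = eps, min_pts = min_pts)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters, %d noise points (eps=%.1f, minPts=%d)\n",
              x$n_clusters, sum(x$labels == 0L), x$parameters$eps,
              x$parameters$min_pts))
  invisible(x)
}

#' Cluster density per unit area
#'
#' @param result `cluster_result`.
#' @param area_um2 Cell (analysis region) area in square micrometers (> 0).
#' @return Clusters per square micrometer.
#' @export
cluster_density <- function(result, area_um2) {
  stopifnot(inherits(result, "cluster_result"))
  if (area_um2 <= 0) stop("area must be > 0")
  result$n_clusters / area_um2
}

#' Full dSTORM receptor-density analysis
#'
#' Chains the published analysis recipe: NeNA localization precision, then
#' linking of repeated localizations with radius 6 x NeNA (capped at 0.45
#' camera pixels) and 5 dark frames, then DBSCAN with radius 2 x NeNA
#' (capped at 0.15 pixels) and a minimum of 10 localizations, then cluster
#' count divided by the cell area.
#'
#' @param locs data.frame `x_nm, y_nm, frame`.
#' @param area_um2 Analysis region area in square micrometers.
#' @param pixel_nm Camera pixel size in nm (default 157).
#' @param link_factor,link_cap_px Link radius rule (6 x NeNA, 0.45 px cap).
#' @param eps_factor,eps_cap_px DBSCAN radius rule (2 x NeNA, 0.15 px cap).
#' @param max_dark_frames,min_pts Remaining recipe parameters.
#' @return List with `density`, `n_clusters`, `nena_nm`, `link_radius_nm`,
#'   `eps_nm`, `linked`, `clusters`.
#' @export
smlm_density_pipeline <- function(locs, area_um2, pixel_nm = 157,
                                  link_factor = 6, link_cap_px = 0.45,
                                  eps_factor = 2, eps_cap_px = 0.15,
                                  max_dark_frames = 5L, min_pts = 10L) {
  sigma <- as.numeric(nena_precision(locs))
  link_radius <- min(link_factor * sigma, link_cap_px * pixel_nm)
  eps <- min(eps_factor * sigma, eps_cap_px * pixel_nm)
  linked <- link_localizations(locs, link_radius, max_dark_frames)
  clusters <- dbscan_clusters(linked, eps, min_pts)
  list(density = cluster_density(clusters, area_um2),
       n_clusters = clusters$n_clusters, nena_nm = sigma,
       link_radius_nm = link_radius, eps_nm = eps,
       linked = linked, clusters = clusters)
}
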