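# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs.

# exhaustive binomial photon-ratio distribution (no background, zero width):
# mass over ratios a/N for every N in the (tabulated) count distribution
oracle_binomial_ratio <- function(counts, eps, breaks) {
  tb <- table(counts)
  Ns <- as.integer(names(tb))
  pN <- as.numeric(tb) / sum(tb)
  nb <- length(breaks) - 1L
  prob <- numeric(nb)
  for (i in seq_along(Ns)) {
    N <- Ns[i]
    a <- 0:N
    p <- dbinom(a, N, eps) * pN[i]
    bin <- pmin(pmax(findInterval(a / N, breaks, rightmost.closed = TRUE),
                     1L), nb)
    for (b in unique(bin)) prob[b] <- prob[b] + sum(p[bin == b])
  }
  prob / sum(prob)
}

# transitive-closure linking oracle: connected components of the graph with
# an edge between localizations within `radius` whose frame difference is
# between 1 and max_dark_frames + 1
oracle_link_groups <- function(locs, radius, max_dark_frames) {
  n <- nrow(locs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      df <- abs(locs$frame[j] - locs$frame[i])
      d <- sqrt((locs$x_nm[i] - locs$x_nm[j])^2 +
                  (locs$y_nm[i] - locs$y_nm[j])^2)
      if (df >= 1 && df <= max_dark_frames + 1 && d <= radius) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] > 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# brute-force DBSCAN semantics: core points, components over core-core
# edges, border points adjacent to >= 1 core cluster, the rest noise
oracle_dbscan <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  d <- as.matrix(dist(xy))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- which(vapply(nbrs, length, 1L) >= min_pts)
  comp <- integer(n)                      # cluster id per core point
  cur <- 0L
  for (i in core) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] > 0L) next
      comp[v] <- cur
      stack <- c(stack, intersect(nbrs[[v]], core[comp[core] == 0L]))
    }
  }
  border_opts <- lapply(seq_len(n), function(i) {
    if (comp[i] > 0L) return(comp[i])
    unique(comp[intersect(nbrs[[i]], core)])
  })
  list(core = core, core_labels = comp, border_options = border_opts)
}

# canonical form of a partition (labels -> order of first appearance)
canonical_partition <- function(labels) {
  match(labels, unique(labels[labels != 0])) * (labels != 0)
}

# noiseless ALEX trace with an acceptor bleach at frame `f_acc` (and
# optional donor bleach), built directly from the channel expectations
make_noiseless_trace <- function(E, N = 300, gamma = 1, alpha = 0, delta = 0,
                                 beta = 1, frames = 200L, f_acc = 100L,
                                 f_don = NA, id = "t") {
  fr <- seq_len(frames)
  a_alive <- fr < f_acc
  d_alive <- if (is.na(f_don)) rep(TRUE, frames) else fr < f_don
  Ee <- ifelse(a_alive & d_alive, E, 0)
  i_dd <- d_alive * (1 - Ee) * N
  i_aa <- a_alive * beta * gamma * N
  i_da <- d_alive * (gamma * Ee * N + alpha * (1 - Ee) * N) + delta * i_aa
  list(trace = data.frame(frame = fr, I_DD = i_dd, I_DA = i_da, I_AA = i_aa),
       truth = NULL, species = "fret", id = id,
       acceptor_bleach_frame = f_acc,
       donor_bleach_frame = if (is.na(f_don)) frames + 1L else f_don)
}

# hand-built accessible volume (for pair-statistics tests)
manual_av <- function(points, weights = NULL) {
  points <- rbind(points)
  if (is.null(weights)) weights <- rep(1 / nrow(points), nrow(points))
  structure(list(points = points, weights = weights,
                 sub_av = rep(1L, nrow(points)),
                 attachment = points[1, ], params = NULL,
                 site = list(chain = "A", resno = 1)),
            class = "accessible_volume")
}

# random rigid-body transform applied to a coordinate matrix
random_rigid <- function(xyz, seed) {
  set.seed(seed)
  q <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(q))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t(R %*% t(xyz)) + matrix(runif(3, -20, 20), nrow(xyz), 3, byrow = TRUE)
}
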