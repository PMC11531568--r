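#' Accessible-volume simulation parameters
#'
#' The dye linker is modelled as a flexible cylinder of length
#' `linker_length` and width `linker_width`; the dye itself as an ellipsoid
#' approximated by up to three spheres of radii `dye_radii` (the "3AV"
#' model; a single radius gives the classic 1AV).
#'
#' @param linker_length Linker length in Angstrom (> 0).
#' @param linker_width Linker (cylinder) width in Angstrom.
#' @param dye_radii Numeric vector of 1 or 3 dye radii in Angstrom.
#' @param grid_spacing Grid spacing in Angstrom; must lie in
#'   (0, linker_length / 5\].
#' @param attachment_atom Atom name of the anchor on the labelled residue
#'   (default `"CB"`; the dye replaces the side chain beyond it).
#' @return List of class `av_parameters`.
#' @export
av_parameters <- function(linker_length, linker_width = 4.5,
                          dye_radii = 3.5, grid_spacing = 1.0,
                          attachment_atom = "CB") {
  stopifnot(linker_length > 0, linker_width > 0, all(dye_radii > 0),
            length(dye_radii) %in% c(1L, 3L))
  if (grid_spacing <= 0 || grid_spacing > linker_length / 5) {
    stop("grid_spacing must lie in (0, linker_length/5]")
  }
  structure(list(linker_length = linker_length, linker_width = linker_width,
                 dye_radii = dye_radii, grid_spacing = grid_spacing,
                 attachment_atom = attachment_atom),
            class = "av_parameters")
}

#' Dye presets for AV simulations
#'
#' Cylinder-linker and 3AV ellipsoid radii for the two maleimide dyes used
#' on the InlB labelling sites: Cy3B (linker 18.5 A, radii 3.4/8.2/3.0 A)
#' and ATTO 647N (linker 21.0 A, radii 7.15/4.5/1.5 A); linker width 4.5 A
#' for both.
#'
#' @param dye `"cy3b"` or `"atto647n"`.
#' @param ... Overrides passed to [av_parameters()].
#' @return `av_parameters`.
#' @export
av_dye_preset <- function(dye = c("cy3b", "atto647n"), ...) {
  dye <- match.arg(dye)
  defaults <- switch(dye,
    cy3b = list(linker_length = 18.5, linker_width = 4.5,
                dye_radii = c(3.4, 8.2, 3.0)),
    atto647n = list(linker_length = 21.0, linker_width = 4.5,
                    dye_radii = c(7.15, 4.5, 1.5)))
  args <- utils::modifyList(defaults, list(...))
  do.call(av_parameters, args)
}

# mark grid nodes lying within `radii[k]` of `centers[k, ]`; returns a
# logical vector over the flattened grid (x fastest)
mark_within <- function(gx, gy, gz, centers, radii) {
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  out <- logical(nx * ny * nz)
  if (NROW(centers) == 0L) return(out)
  h <- if (nx > 1) gx[2] - gx[1] else 1
  for (k in seq_len(NROW(centers))) {
    r <- radii[k]
    cx <- centers[k, 1]; cy <- centers[k, 2]; cz <- centers[k, 3]
    ix <- which(abs(gx - cx) <= r)
    iy <- which(abs(gy - cy) <= r)
    iz <- which(abs(gz - cz) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - cx)^2
    dy2 <- (gy[iy] - cy)^2
    dz2 <- (gz[iz] - cz)^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    lin <- outer(outer(ix, (iy - 1L) * nx, "+"), (iz - 1L) * nx * ny, "+")
    out[lin[d2 <= r * r]] <- TRUE
  }
  out
}

#' Accessible volume of a dye around a labelling site
#'
#' Grid construction of the sterically allowed dye positions: a cubic grid
#' (spacing `params$grid_spacing`) is centred on the attachment atom, grid
#' nodes whose linker path would clash with protein atoms (van der Waals
#' radius plus half the linker width) are removed, and geodesic path lengths
#' from the attachment point are computed on the remaining 26-connected grid
#' graph (so the linker can bend around obstacles). A node belongs to the
#' accessible volume of dye radius R if its path length does not exceed the
#' linker length and a sphere of radius R centred there clears all protein
#' atoms. With three radii the three single-radius volumes are united with
#' equal 1/3 weights (3AV); weights are uniform within each sub-volume.
#'
#' Atoms of the labelled residue are not obstacles for the linker path (the
#' linker emanates from it), and its side-chain atoms beyond the attachment
#' atom are not obstacles for the dye either (the dye replaces the side
#' chain).
#'
#' @param structure `structure_model`.
#' @param chain,resno Labelling site address.
#' @param params [av_parameters()].
#' @return Object of class `accessible_volume`: `points` (n x 3 matrix, A),
#'   `weights` (sum to 1), `sub_av` (dye-radius index per point),
#'   `attachment` (xyz), `params`.
#' @export
compute_av <- function(structure, chain, resno, params) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(params, "av_parameters"))
  a <- structure$atoms
  at_site <- a$chain == chain & a$resno == resno
  if (!any(at_site)) stop("labelling site ", chain, ":", resno, " not found")
  anchor <- which(at_site & a$elety == params$attachment_atom)
  if (length(anchor) != 1L) {
    stop("attachment atom '", params$attachment_atom, "' not found at site ",
         chain, ":", resno)
  }
  origin <- as.numeric(a[anchor, c("x", "y", "z")])

  L <- params$linker_length
  h <- params$grid_spacing
  half <- floor(L / h)
  g1 <- (-half:half) * h
  gx <- origin[1] + g1; gy <- origin[2] + g1; gz <- origin[3] + g1
  nx <- length(gx)

  # obstacle sets
  backbone <- c("N", "CA", "C", "O", "CB", "H", "HA")
  path_obs <- !at_site                       # whole labelled residue ignored
  dye_obs <- !at_site | (at_site & a$elety %in% backbone)
  reach <- L + max(a$vdw) + max(params$dye_radii, params$linker_width / 2)
  d_or2 <- (a$x - origin[1])^2 + (a$y - origin[2])^2 + (a$z - origin[3])^2
  near <- d_or2 <= reach^2
  path_atoms <- a[path_obs & near, , drop = FALSE]
  dye_atoms <- a[dye_obs & near, , drop = FALSE]

  blocked <- mark_within(gx, gy, gz, as.matrix(path_atoms[, c("x", "y", "z")]),
                         path_atoms$vdw + params$linker_width / 2)
  src <- (half) + nx * (half) + nx * nx * (half)    # 0-based centre index
  blocked[src + 1L] <- FALSE
  geo <- .grid_geodesic(nx, nx, nx, blocked, src, h)

  grid_xyz <- cbind(rep(gx, times = nx * nx),
                    rep(rep(gy, each = nx), times = nx),
                    rep(gz, each = nx * nx))
  within <- is.finite(geo) & geo <= L

  pts <- list(); sub <- list()
  dm <- as.matrix(dye_atoms[, c("x", "y", "z")])
  for (i in seq_along(params$dye_radii)) {
    clash <- mark_within(gx, gy, gz, dm, dye_atoms$vdw + params$dye_radii[i])
    ok <- within & !clash
    if (any(ok)) {
      pts[[length(pts) + 1L]] <- grid_xyz[ok, , drop = FALSE]
      sub[[length(sub) + 1L]] <- rep(i, sum(ok))
    }
  }
  if (length(pts) == 0L) {
    stop("accessible volume is empty: site ", chain, ":", resno,
         " is fully buried")
  }
  if (length(pts) < length(params$dye_radii)) {
    warning("some dye-radius sub-volumes are empty; weights renormalized ",
            "over the non-empty ones")
  }
  n_sub <- length(pts)
  w <- unlist(lapply(pts, function(p) rep(1 / (n_sub * nrow(p)), nrow(p))))
  structure(list(points = do.call(rbind, pts), weights = w,
                 sub_av = unlist(sub), attachment = origin, params = params,
                 site = list(chain = chain, resno = resno)),
            class = "accessible_volume")
}

#' @export
print.accessible_volume <- function(x, ...) {
  cat(sprintf("accessible_volume: %d grid points (%d sub-volumes), site %s:%s\n",
              nrow(x$points), length(unique(x$sub_av)),
              x$site$chain, x$site$resno))
  invisible(x)
}

#' Weighted centroid (mean dye position) of an accessible volume
#' @param av `accessible_volume`.
#' @return xyz vector in Angstrom.
#' @export
av_centroid <- function(av) {
  colSums(av$points * av$weights) / sum(av$weights)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Inter-dye distance and efficiency statistics of two accessible volumes
#'
#' Over the product measure of the two weighted point clouds this computes
#' the mean inter-dye distance \eqn{\langle r \rangle}, the isotropically
#' averaged mean efficiency \eqn{\langle E \rangle = \langle 1/(1 +
#' (r/R_0)^6) \rangle} (static regime, kappa^2 = 2/3 folded into R0), and
#' the FRET-averaged distance \eqn{R_E = R_0 (1/\langle E\rangle - 1)^{1/6}}
#' -- the distance an efficiency measurement would report. Pairing is
#' exhaustive when the product of point counts permits, otherwise a
#' stratified weighted subsample with a fixed seed is used.
#'
#' @param av_donor,av_acceptor `accessible_volume` objects.
#' @param R0 Forster radius in nm.
#' @param max_pairs Exhaustive-pairing budget (default 4e6 pairs).
#' @param seed Seed for the subsampling fallback.
#' @return List with `mean_R_nm`, `mean_E`, `R_E_nm`, `n_pairs`,
#'   `exhaustive`.
#' @export
pair_distance_stats <- function(av_donor, av_acceptor, R0, max_pairs = 4e6,
                                seed = 1L) {
  stopifnot(inherits(av_donor, "accessible_volume"),
            inherits(av_acceptor, "accessible_volume"), R0 > 0)
  p1 <- av_donor$points; w1 <- av_donor$weights
  p2 <- av_acceptor$points; w2 <- av_acceptor$weights
  n1 <- nrow(p1); n2 <- nrow(p2)
  if (n1 == 0L || n2 == 0L) stop("empty accessible volume")
  exhaustive <- as.double(n1) * n2 <= max_pairs
  if (!exhaustive) {
    m <- floor(sqrt(max_pairs))
    idx1 <- with_seed(seed, sample.int(n1, m, replace = TRUE, prob = w1))
    idx2 <- with_seed(seed + 1L, sample.int(n2, m, replace = TRUE, prob = w2))
    p1 <- p1[idx1, , drop = FALSE]; w1 <- rep(1 / m, m)
    p2 <- p2[idx2, , drop = FALSE]; w2 <- rep(1 / m, m)
    n1 <- n2 <- m
  }
  rs1 <- rowSums(p1^2); rs2 <- rowSums(p2^2)
  mean_R_A <- 0; mean_E <- 0
  chunk <- max(1L, floor(2e7 / n2))
  for (s in seq(1L, n1, by = chunk)) {
    e <- min(s + chunk - 1L, n1)
    d2 <- outer(rs1[s:e], rs2, "+") - 2 * p1[s:e, , drop = FALSE] %*% t(p2)
    d <- sqrt(pmax(d2, 0))
    W <- outer(w1[s:e], w2)
    mean_R_A <- mean_R_A + sum(W * d)
    mean_E <- mean_E + sum(W / (1 + (d / (10 * R0))^6))
  }
  wtot <- sum(w1) * sum(w2)
  mean_R_A <- mean_R_A / wtot; mean_E <- mean_E / wtot
  list(mean_R_nm = mean_R_A / 10, mean_E = mean_E,
       R_E_nm = R0 * (1 / mean_E - 1)^(1 / 6),
       n_pairs = as.double(n1) * n2, exhaustive = exhaustive)
}

#' Predicted distance/efficiency table for a candidate dimer form
#'
#' Computes donor and acceptor accessible volumes at the two labelling sites
#' of each protomer and tabulates the predicted mean distance, mean
#' efficiency and FRET-averaged distance for the three labelling
#' combinations H-H, T-H/H-T and T-T. The mixed T-H and H-T predictions are
#' averaged into a single entry, matching how the two experimentally
#' indistinguishable arrangements are reported.
#'
#' @param structure `structure_model` of the dimer.
#' @param protomer_chains Length-2 character: the chains carrying the label
#'   sites (one per protomer).
#' @param sites Named numeric vector `c(H = ..., T = ...)` of residue
#'   numbers.
#' @param donor_params,acceptor_params [av_parameters()] for the two dyes.
#' @param R0 Named vector of Forster radii (nm) per combination, names
#'   `"T-T"`, `"T-H/H-T"`, `"H-H"`.
#' @param form Label for the candidate assembly (e.g. `"form II"`).
#' @param ... Passed to [pair_distance_stats()].
#' @return data.frame of class `dimer_form_prediction` with columns `pair`,
#'   `mean_R_nm`, `mean_E`, `R_E_nm`; the AVs are attached as attributes.
#' @export
predict_pair_table <- function(structure, protomer_chains,
                               sites = c(H = 64, T = 280),
                               donor_params = av_dye_preset("cy3b"),
                               acceptor_params = av_dye_preset("atto647n"),
                               R0 = c("T-T" = 6.34, "T-H/H-T" = 6.34,
                                      "H-H" = 6.30),
                               form = "candidate", ...) {
  stopifnot(length(protomer_chains) == 2L, all(c("H", "T") %in% names(sites)))
  av <- list()
  for (s in c("H", "T")) {
    av[[paste0("D_", s)]] <- compute_av(structure, protomer_chains[1],
                                        sites[[s]], donor_params)
    av[[paste0("A_", s)]] <- compute_av(structure, protomer_chains[2],
                                        sites[[s]], acceptor_params)
  }
  st_tt <- pair_distance_stats(av$D_T, av$A_T, R0[["T-T"]], ...)
  st_hh <- pair_distance_stats(av$D_H, av$A_H, R0[["H-H"]], ...)
  st_th <- pair_distance_stats(av$D_T, av$A_H, R0[["T-H/H-T"]], ...)
  st_ht <- pair_distance_stats(av$D_H, av$A_T, R0[["T-H/H-T"]], ...)
  mix_E <- (st_th$mean_E + st_ht$mean_E) / 2
  mix <- list(mean_R_nm = (st_th$mean_R_nm + st_ht$mean_R_nm) / 2,
              mean_E = mix_E,
              R_E_nm = R0[["T-H/H-T"]] * (1 / mix_E - 1)^(1 / 6))
  out <- data.frame(
    pair = c("T-T", "T-H/H-T", "H-H"),
    mean_R_nm = c(st_tt$mean_R_nm, mix$mean_R_nm, st_hh$mean_R_nm),
    mean_E = c(st_tt$mean_E, mix$mean_E, st_hh$mean_E),
    R_E_nm = c(st_tt$R_E_nm, mix$R_E_nm, st_hh$R_E_nm),
    stringsAsFactors = FALSE
  )
  attr(out, "form") <- form
  attr(out, "avs") <- av
  attr(out, "unmixed") <- list(`T-H` = st_th, `H-T` = st_ht)
  class(out) <- c("dimer_form_prediction", class(out))
  out
}
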