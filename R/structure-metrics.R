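atomic_mass <- function(element) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, SE = 78.971)
  m <- tab[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Residue-range definition of the inter-domain theta angle
#'
#' The angle is defined by two vectors, each running between the centers of
#' mass of two residue ranges. The defaults describe the relative
#' orientation of the Sema and IPT1 domains of the MET ectodomain: vector 1
#' connects residues 182-200 and 464-479 (upper and lower side of the Sema
#' domain), vector 2 connects residues 561-657 and 655-657 (the two ends of
#' the IPT1 cylinder, as printed; note the two ranges overlap, which is kept
#' as published -- a warning flags any overlapping ranges).
#'
#' @param v1_a,v1_b,v2_a,v2_b Integer residue-number ranges.
#' @param chain Optional chain restriction applied to all ranges.
#' @return List of class `theta_definition`.
#' @export
theta_definition <- function(v1_a = 182:200, v1_b = 464:479,
                             v2_a = 561:657, v2_b = 655:657, chain = NULL) {
  rngs <- list(v1_a = v1_a, v1_b = v1_b, v2_a = v2_a, v2_b = v2_b)
  if (any(vapply(rngs, length, 1L) == 0L)) stop("residue ranges must be nonempty")
  if (length(intersect(v2_a, v2_b)) > 0L || length(intersect(v1_a, v1_b)) > 0L) {
    warning("theta definition has overlapping residue ranges (kept as given)")
  }
  structure(c(rngs, list(chain = chain)), class = "theta_definition")
}

range_com <- function(structure, resnos, chain, mass_weighted) {
  a <- structure$atoms
  keep <- a$resno %in% resnos
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!any(keep)) stop("residue range not resolvable in structure")
  xyz <- as.matrix(a[keep, c("x", "y", "z")])
  m <- if (mass_weighted) atomic_mass(a$elem[keep]) else rep(1, sum(keep))
  colSums(xyz * m) / sum(m)
}

#' Inter-domain angle from two center-of-mass vectors
#'
#' @param structure `structure_model`.
#' @param definition [theta_definition()].
#' @param mass_weighted Use atomic masses for the centers of mass (default);
#'   `FALSE` uses unit masses (geometric centers).
#' @return Angle in degrees, in \[0, 180\].
#' @export
theta_angle <- function(structure, definition = theta_definition(),
                        mass_weighted = TRUE) {
  stopifnot(inherits(definition, "theta_definition"))
  ch <- definition$chain
  v1 <- range_com(structure, definition$v1_b, ch, mass_weighted) -
    range_com(structure, definition$v1_a, ch, mass_weighted)
  v2 <- range_com(structure, definition$v2_b, ch, mass_weighted) -
    range_com(structure, definition$v2_a, ch, mass_weighted)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length domain vector")
  acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
}

#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}}; equal
#' masses by default (the convention for Calpha-based analyses).
#'
#' @param xyz n x 3 coordinate matrix (Angstrom) or a `structure_model`
#'   (then `...` selects atoms via [structure_coords()], default Calpha).
#' @param masses Optional atom masses.
#' @param ... Selection arguments for a `structure_model` input.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(xyz, masses = NULL, ...) {
  if (inherits(xyz, "structure_model")) {
    args <- list(...)
    if (is.null(args$elety)) args$elety <- "CA"
    xyz <- do.call(structure_coords, c(list(xyz), args))
  }
  xyz <- rbind(xyz)
  if (nrow(xyz) < 1L) stop("need at least one atom")
  if (is.null(masses)) masses <- rep(1, nrow(xyz))
  com <- colSums(xyz * masses) / sum(masses)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Classify an ectodomain conformation as extended or collapsed
#'
#' Applies the Rg threshold convention: extended strictly above the
#' threshold (default 45 Angstrom), collapsed otherwise.
#'
#' @param rg Radius of gyration in Angstrom (>= 0).
#' @param threshold Threshold in Angstrom.
#' @return List of class `conformation_call` with `rg`, `label`,
#'   `threshold`.
#' @export
classify_conformation <- function(rg, threshold = 45) {
  stopifnot(rg >= 0)
  structure(list(rg = rg,
                 label = if (rg > threshold) "extended" else "collapsed",
                 threshold = threshold), class = "conformation_call")
}

#' RMSD after optimal superposition
#'
#' Least-squares rigid-body superposition (Kabsch) of `frame` onto
#' `reference`, then the root-mean-square deviation, computed through the
#' standard bio3d fitting machinery.
#'
#' @param frame,reference n x 3 coordinate matrices with matching atom
#'   counts, or `structure_model`s (then `...` selects atoms, default
#'   Calpha).
#' @param fit Superpose before computing the deviation (default TRUE).
#' @param ... Selection arguments for `structure_model` inputs.
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(frame, reference, fit = TRUE, ...) {
  pick <- function(x) {
    if (inherits(x, "structure_model")) {
      args <- list(...)
      if (is.null(args$elety)) args$elety <- "CA"
      do.call(structure_coords, c(list(x), args))
    } else rbind(x)
  }
  a <- pick(frame); b <- pick(reference)
  if (nrow(a) != nrow(b)) stop("mismatched selections: atom counts differ")
  bio3d::rmsd(as.numeric(t(b)), as.numeric(t(a)), fit = fit)
}

# deterministic, approximately uniform unit sphere points (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Places `n_points` quadrature points on the solvent-expanded sphere of
#' each atom (van der Waals radius + probe radius) and counts the fraction
#' not buried inside any neighbouring atom's expanded sphere.
#'
#' @param structure `structure_model`, or a data.frame/matrix with columns
#'   `x, y, z` plus either a `vdw` column or an `elem` column.
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_points Quadrature points per atom (default 960).
#' @return Total SASA in Angstrom^2, with per-atom values in the
#'   `per_atom` attribute.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960L) {
  if (inherits(structure, "structure_model")) {
    a <- structure$atoms
  } else {
    a <- as.data.frame(structure)
    if (is.null(a$vdw)) {
      if (is.null(a$elem)) stop("need vdw radii or elements")
      a$vdw <- vdw_radius(a$elem)
    }
  }
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r_exp <- a$vdw + probe_radius
  sp <- sphere_points(n_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r_exp + r_exp[i])^2 & seq_len(n) != i)
    pts <- sweep(sp * r_exp[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (pts[acc, 1] - xyz[j, 1])^2 + (pts[acc, 2] - xyz[j, 2])^2 +
        (pts[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 >= r_exp[j]^2
    }
    per_atom[i] <- 4 * pi * r_exp[i]^2 * mean(acc)
  }
  out <- sum(per_atom)
  attr(out, "per_atom") <- per_atom
  out
}

#' Buried interface area between two chain groups
#'
#' PISA-style buried-surface-per-side convention:
#' \eqn{(SASA(A) + SASA(B) - SASA(A \cup B)) / 2}.
#'
#' @param structure `structure_model` of the complex.
#' @param chains_a,chains_b Disjoint, nonempty chain groups.
#' @param ... Passed to [sasa()].
#' @return Interface area in Angstrom^2.
#' @export
interface_area <- function(structure, chains_a, chains_b, ...) {
  stopifnot(length(chains_a) > 0, length(chains_b) > 0,
            length(intersect(chains_a, chains_b)) == 0L)
  a <- structure$atoms
  if (!all(c(chains_a, chains_b) %in% a$chain)) {
    stop("chain group not resolvable in structure")
  }
  sub <- function(chs) {
    s <- structure
    s$atoms <- a[a$chain %in% chs, , drop = FALSE]
    s
  }
  as.numeric(sasa(sub(chains_a), ...) + sasa(sub(chains_b), ...) -
               sasa(sub(c(chains_a, chains_b)), ...)) / 2
}
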