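#' Build an idealized B850 pigment ring
#'
#' Places `n_sites` pigments equally spaced on a circle in the xy plane and
#' assigns each a unit transition-dipole vector. The default dipole pattern is
#' tangential with alternating in-plane offsets for the two pigment types
#' (alpha/beta bacteriochlorophylls), so that adjacent dipoles point in nearly
#' opposite directions. This reproduces the exciton-band structure of the B850
#' aggregate: an optically dark lowest state and a degenerate, strongly
#' allowed second-lowest pair.
#'
#' The in-plane dipole angle of site n (0-based) relative to the local
#' tangent direction is `offset_alpha` for even (alpha) sites and
#' `offset_beta` for odd (beta) sites. The beta default of 170 degrees
#' (i.e. 180 - 10) makes adjacent dipoles antiparallel up to the tangent
#' rotation between neighbouring sites plus the small alternating tilt;
#' zero offsets give purely tangential dipoles.
#'
#' @param n_sites pigments per ring; must be even for an alternating pattern
#' @param radius radius of the pigment circle, nm
#' @param center 3-vector, ring center, nm
#' @param offset_alpha in-plane dipole offset from the tangent for even
#'   (alpha) sites, degrees
#' @param offset_beta in-plane offset from the tangent for odd (beta) sites,
#'   degrees
#' @param tilt out-of-plane dipole tilt, degrees (0 keeps dipoles in-plane)
#' @param site_energy pigment site energy, cm^-1
#' @param phase0 angular position of site 0, radians
#' @return an object of class `ring_geometry` with fields `n_sites`,
#'   `positions` (n x 3, nm), `dipoles` (n x 3, unit vectors), `ring_center`,
#'   `radius`, `site_energy`
#' @export
build_b850_ring <- function(n_sites = 16, radius = 2.3,
                            center = c(0, 0, 0),
                            offset_alpha = 10, offset_beta = 170,
                            tilt = 0, site_energy = 12500,
                            phase0 = 0) {
  if (n_sites < 2) stop("n_sites must be >= 2")
  if (radius <= 0) stop("radius must be positive")
  alternating <- (offset_alpha != 0 || offset_beta != 0 || TRUE)
  if (n_sites %% 2 != 0)
    stop("an alternating alpha/beta dipole pattern requires an even n_sites")

  n <- seq_len(n_sites) - 1L
  theta <- phase0 + 2 * pi * n / n_sites
  pos <- cbind(radius * cos(theta), radius * sin(theta), 0)
  pos <- sweep(pos, 2, center, "+")

  # tangent direction at each site
  deg <- pi / 180
  in_plane <- ifelse(n %% 2 == 0, offset_alpha * deg, offset_beta * deg)
  phi <- theta + pi / 2 + in_plane      # absolute in-plane dipole angle
  ct <- cos(tilt * deg)
  dip <- cbind(ct * cos(phi), ct * sin(phi), sin(tilt * deg))
  dip <- dip / sqrt(rowSums(dip^2))

  structure(list(n_sites = as.integer(n_sites), positions = pos,
                 dipoles = dip, ring_center = as.numeric(center),
                 radius = radius, site_energy = site_energy),
            class = "ring_geometry")
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf("B850 ring: %d pigments, radius %.3f nm, site energy %.1f cm^-1\n",
              x$n_sites, x$radius, x$site_energy))
  cat(sprintf("center (%.2f, %.2f, %.2f) nm\n", x$ring_center[1],
              x$ring_center[2], x$ring_center[3]))
  invisible(x)
}

translate_ring <- function(ring, shift) {
  ring$positions <- sweep(ring$positions, 2, shift, "+")
  ring$ring_center <- ring$ring_center + shift
  ring
}

#' Arrange B850 rings into a 1D chain or 2D hexagonal nanoarray
#'
#' Each ring is a translated copy of `ring_template`. The chain layout places
#' ring centers on the x axis at multiples of `spacing`; the hexagonal layout
#' fills `shells` concentric shells of a triangular lattice around a central
#' ring (1 shell = 7 rings), so every interior ring has six neighbours at
#' distance `spacing`.
#'
#' @param layout `"chain"` or `"hexagonal"`
#' @param n_rings number of rings for the chain layout
#' @param shells number of hexagonal shells for the 2D layout
#' @param spacing center-to-center ring distance, nm (must exceed the ring
#'   diameter)
#' @param ring_template a `ring_geometry`, typically [build_b850_ring()]
#' @return an object of class `nanoarray` with fields `rings` (list of
#'   `ring_geometry`), `layout`, `spacing`, `lattice_index` (integer vector or
#'   2-column matrix of axial coordinates), `centers` (n x 3, nm),
#'   `central_ring` (index of the ring at the origin)
#' @export
build_nanoarray <- function(layout = c("chain", "hexagonal"),
                            n_rings = 3, shells = 1, spacing = 8.0,
                            ring_template = build_b850_ring()) {
  layout <- match.arg(layout)
  if (spacing <= 2 * ring_template$radius)
    stop("spacing must exceed the ring diameter: rings would overlap")

  if (layout == "chain") {
    if (n_rings < 1) stop("n_rings must be >= 1")
    idx <- seq_len(n_rings) - 1L
    offs <- idx - idx[ceiling(n_rings / 2)]
    centers <- cbind(offs * spacing, 0, 0)
    lattice_index <- matrix(as.integer(offs), ncol = 1)
    central <- ceiling(n_rings / 2)
  } else {
    if (shells < 0) stop("shells must be >= 0")
    ax <- expand.grid(i = -shells:shells, j = -shells:shells)
    keep <- abs(ax$i + ax$j) <= shells & (abs(ax$i) + abs(ax$j) +
            abs(ax$i + ax$j)) / 2 <= shells
    ax <- ax[keep, , drop = FALSE]
    # order by shell then angle for a stable indexing; central ring first in
    # shell 0
    x <- spacing * (ax$i + ax$j / 2)
    y <- spacing * ax$j * sqrt(3) / 2
    shell <- (abs(ax$i) + abs(ax$j) + abs(ax$i + ax$j)) / 2
    ord <- order(shell, atan2(y, x))
    ax <- ax[ord, , drop = FALSE]
    x <- x[ord]; y <- y[ord]
    centers <- cbind(x, y, 0)
    lattice_index <- cbind(as.integer(ax$i), as.integer(ax$j))
    central <- which(ax$i == 0 & ax$j == 0)
  }

  rings <- lapply(seq_len(nrow(centers)), function(r)
    translate_ring(ring_template,
                   as.numeric(centers[r, ]) - ring_template$ring_center))
  structure(list(rings = rings, layout = layout, spacing = spacing,
                 lattice_index = lattice_index, centers = centers,
                 central_ring = central,
                 n_sites_per_ring = ring_template$n_sites),
            class = "nanoarray")
}

#' @export
print.nanoarray <- function(x, ...) {
  cat(sprintf("B850 nanoarray: %s layout, %d rings x %d pigments, spacing %.2f nm\n",
              x$layout, length(x$rings), x$n_sites_per_ring, x$spacing))
  cat(sprintf("central ring index: %d\n", x$central_ring))
  invisible(x)
}

#' Distances from one ring center to all ring centers
#'
#' The distance entering the mean-square displacement is the Euclidean
#' ring-center distance to the ring on which the exciton was initially
#' localized.
#'
#' @param geom a `nanoarray`
#' @param origin_ring index of the reference ring (default: central ring)
#' @return numeric vector of distances, nm, zero at `origin_ring`
#' @export
ring_center_distances <- function(geom, origin_ring = geom$central_ring) {
  n <- length(geom$rings)
  if (origin_ring < 1 || origin_ring > n) stop("invalid origin_ring index")
  d <- sweep(geom$centers, 2, geom$centers[origin_ring, ], "-")
  sqrt(rowSums(d^2))
}

#' All pigment positions of a nanoarray as one matrix
#'
#' Sites are ordered ring-major: ring 1 sites 1..Ns, then ring 2, etc.
#' @param geom a `nanoarray`
#' @return N x 3 matrix, nm
#' @export
pigment_positions <- function(geom) {
  do.call(rbind, lapply(geom$rings, `[[`, "positions"))
}

#' All pigment transition-dipole unit vectors as one matrix
#' @param geom a `nanoarray`
#' @return N x 3 matrix of unit vectors
#' @export
pigment_dipoles <- function(geom) {
  do.call(rbind, lapply(geom$rings, `[[`, "dipoles"))
}

#' Rigid transforms of a nanoarray
#'
#' Rotate about the z axis (membrane normal) through the origin, or
#' translate. Both leave all inter-pigment distances and dipole dot
#' products, and therefore the exciton Hamiltonian spectrum, unchanged.
#'
#' @param geom a `nanoarray`
#' @param angle rotation angle, radians
#' @param shift length-3 translation, nm
#' @return the transformed `nanoarray`
#' @export
rotate_geometry <- function(geom, angle) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  geom$rings <- lapply(geom$rings, function(rg) {
    rg$positions <- rg$positions %*% R
    rg$dipoles <- rg$dipoles %*% R
    rg$ring_center <- as.numeric(rg$ring_center %*% R)
    rg
  })
  geom$centers <- geom$centers %*% R
  geom
}

#' @rdname rotate_geometry
#' @export
translate_geometry <- function(geom, shift) {
  geom$rings <- lapply(geom$rings, translate_ring, shift = shift)
  geom$centers <- sweep(geom$centers, 2, shift, "+")
  geom
}

#' Write a nanoarray to a plain tabular text file
#'
#' One row per pigment: ring index, site index, position (x, y, z, nm) and
#' dipole components (dx, dy, dz).
#' @param geom a `nanoarray`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_geometry <- function(geom, path) {
  ns <- geom$n_sites_per_ring
  nr <- length(geom$rings)
  df <- data.frame(ring = rep(seq_len(nr), each = ns),
                   site = rep(seq_len(ns), nr),
                   pigment_positions(geom), pigment_dipoles(geom))
  names(df)[3:8] <- c("x", "y", "z", "dx", "dy", "dz")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a nanoarray pigment table written by [write_geometry()]
#'
#' Reconstructs per-ring geometry; layout metadata is not stored in the table,
#' so the result carries `layout = "table"` and ring centers recomputed as
#' per-ring centroids.
#' @param path tabular file from [write_geometry()]
#' @return a `nanoarray`-like object usable by the Hamiltonian builder
#' @export
read_geometry <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("ring", "site", "x", "y", "z", "dx", "dy", "dz")
  if (!all(need %in% names(df)))
    stop("geometry table must have columns: ", paste(need, collapse = ", "))
  rings <- lapply(split(df, df$ring), function(b) {
    b <- b[order(b$site), ]
    pos <- as.matrix(b[, c("x", "y", "z")])
    dip <- as.matrix(b[, c("dx", "dy", "dz")])
    dip <- dip / sqrt(rowSums(dip^2))
    structure(list(n_sites = nrow(b), positions = unname(pos),
                   dipoles = unname(dip),
                   ring_center = colMeans(pos),
                   radius = mean(sqrt(rowSums(sweep(pos, 2, colMeans(pos))^2))),
                   site_energy = NA_real_),
              class = "ring_geometry")
  })
  centers <- do.call(rbind, lapply(rings, `[[`, "ring_center"))
  structure(list(rings = rings, layout = "table", spacing = NA_real_,
                 lattice_index = matrix(seq_along(rings), ncol = 1),
                 centers = centers,
                 central_ring = which.min(rowSums(sweep(centers, 2,
                                                        colMeans(centers))^2)),
                 n_sites_per_ring = rings[[1]]$n_sites),
            class = "nanoarray")
}
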