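# Structural rupture metrics: geometric hydrogen-bond state of designed base
# pairs, denatured fraction, site-distance series, and the four-face incircle
# pore analysis of the tetrahedron.

.check_pairs <- function(pairs, n_nt, topology = NULL) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must be a 2-column matrix", call. = FALSE)
  storage.mode(pairs) <- "integer"
  if (nrow(pairs) > 0L) {
    if (any(pairs < 0L) || any(pairs >= n_nt))
      stop("pair index out of range", call. = FALSE)
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, c(2, 1)]
    if (!is.null(topology)) {
      comp <- c(A = "T", T = "A", C = "G", G = "C")
      b1 <- topology$base[pairs[, 1] + 1L]
      b2 <- topology$base[pairs[, 2] + 1L]
      if (any(comp[b1] != b2))
        stop("reference pairs must be complementary", call. = FALSE)
    }
  }
  pairs
}

#' Geometric hydrogen-bond state of designed base pairs
#'
#' A pair is counted as bound when the separation of the two hydrogen-bonding
#' sites (`position + 0.4 * base_vector`, simulation length units) is below
#' `distance_cutoff`, and — if `require_antiparallel` — the two base vectors
#' are anti-aligned (dot product < 0). This geometric criterion replaces the
#' simulator's hydrogen-bond energy readout; the cutoff is configurable.
#'
#' @param positions N x 3 matrix, simulation length units.
#' @param base_vectors N x 3 matrix of unit base vectors.
#' @param pairs 2-column matrix of 0-based nucleotide index pairs.
#' @param topology optional `oxdna_topology` used to check complementarity.
#' @param distance_cutoff bound-site separation cutoff, simulation length
#'   units (default 0.4, about 0.34 nm).
#' @param require_antiparallel logical; also require anti-aligned bases.
#' @return Logical vector, one entry per pair.
#' @export
detect_base_pairs <- function(positions, base_vectors, pairs, topology = NULL,
                              distance_cutoff = 0.4,
                              require_antiparallel = TRUE) {
  pairs <- .check_pairs(pairs, nrow(positions), topology)
  if (nrow(pairs) == 0L) return(logical(0))
  s1 <- positions[pairs[, 1] + 1L, , drop = FALSE] +
    0.4 * base_vectors[pairs[, 1] + 1L, , drop = FALSE]
  s2 <- positions[pairs[, 2] + 1L, , drop = FALSE] +
    0.4 * base_vectors[pairs[, 2] + 1L, , drop = FALSE]
  d <- sqrt(rowSums((s1 - s2)^2))
  bound <- d < distance_cutoff
  if (require_antiparallel) {
    dot <- rowSums(base_vectors[pairs[, 1] + 1L, , drop = FALSE] *
                   base_vectors[pairs[, 2] + 1L, , drop = FALSE])
    bound <- bound & dot < 0
  }
  bound
}

#' Per-frame bound mask over a trajectory
#'
#' @inheritParams detect_base_pairs
#' @param trajectory an `oxdna_trajectory`.
#' @return Logical matrix, frames x pairs.
#' @export
base_pair_mask <- function(trajectory, pairs, topology = NULL,
                           distance_cutoff = 0.4, require_antiparallel = TRUE) {
  nf <- n_frames(trajectory)
  pairs <- .check_pairs(pairs, dim(trajectory$positions)[1], topology)
  out <- matrix(FALSE, nf, nrow(pairs))
  for (f in seq_len(nf))
    out[f, ] <- detect_base_pairs(trajectory$positions[, , f],
                                  trajectory$base_vectors[, , f],
                                  pairs, NULL, distance_cutoff,
                                  require_antiparallel)
  out
}

#' Fraction of designed base pairs mechanically denatured
#'
#' `fraction = 1 - bound / reference` per frame, in `[0, 1]`; the end value
#' is taken from the final frame (the convention used when quoting a single
#' "percent denatured" number for a pulling run).
#'
#' @inheritParams base_pair_mask
#' @return Data frame with columns `frame`, `fraction`; attribute
#'   `end_fraction`.
#' @export
denatured_fraction <- function(trajectory, pairs, topology = NULL,
                               distance_cutoff = 0.4,
                               require_antiparallel = TRUE) {
  pairs <- .check_pairs(pairs, dim(trajectory$positions)[1], topology)
  if (nrow(pairs) == 0L) stop("reference pair set is empty", call. = FALSE)
  mask <- base_pair_mask(trajectory, pairs, NULL, distance_cutoff,
                         require_antiparallel)
  frac <- 1 - rowSums(mask) / ncol(mask)
  out <- data.frame(frame = seq_len(nrow(mask)), fraction = frac)
  attr(out, "end_fraction") <- frac[length(frac)]
  out
}

#' Distance between two nucleotides over a trajectory
#'
#' Euclidean distance of the two bead positions per frame, converted to nm.
#' Used for fluorophore-quencher separations and strand-release distances.
#'
#' @param trajectory an `oxdna_trajectory`.
#' @param i,j 0-based nucleotide indices.
#' @param units an [oxdna_units()] object.
#' @return Numeric vector, nm, one value per frame.
#' @export
site_distance_series <- function(trajectory, i, j, units = oxdna_units()) {
  n_nt <- dim(trajectory$positions)[1]
  if (i < 0L || i >= n_nt || j < 0L || j >= n_nt)
    stop("nucleotide index out of range", call. = FALSE)
  d <- sqrt(colSums((trajectory$positions[i + 1L, , ] -
                     trajectory$positions[j + 1L, , ])^2))
  as.numeric(d) * units$nm_per_length_unit
}

#' Incircle radius of a triangle
#'
#' `r = 2 * area / perimeter`, the radius of the largest circle inscribed in
#' the triangle — the cross-section of the largest sphere that can pass
#' through a triangular pore. Triangles with area below `degenerate_area`
#' return 0.
#'
#' @param p1,p2,p3 3-vectors (nm).
#' @param degenerate_area area threshold (nm^2) below which the triangle is
#'   treated as degenerate (default 1e-9).
#' @return Radius in the same length unit as the inputs.
#' @examples
#' incircle_radius(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))  # 1
#' @export
incircle_radius <- function(p1, p2, p3, degenerate_area = 1e-9) {
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  c <- sqrt(sum((p1 - p2)^2))
  u <- p2 - p1
  v <- p3 - p1
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  area <- 0.5 * sqrt(sum(cr^2))
  if (!is.finite(area) || area < degenerate_area) return(0)
  2 * area / (a + b + c)
}

#' Pore specification: the four hinge-vertex faces
#'
#' @param faces 4 x 3 matrix of 0-based hinge-nucleotide indices, one row per
#'   tetrahedron face.
#' @param n_nucleotides optional total nucleotide count for validation.
#' @return Object of class `pore_spec`.
#' @export
pore_spec <- function(faces, n_nucleotides = NULL) {
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (!all(dim(faces) == c(4L, 3L)))
    stop("pore spec must give 4 faces of 3 hinge indices", call. = FALSE)
  if (any(apply(faces, 1, anyDuplicated) > 0))
    stop("face hinge indices must be distinct", call. = FALSE)
  if (any(faces < 0L)) stop("negative hinge index", call. = FALSE)
  if (!is.null(n_nucleotides) && any(faces >= n_nucleotides))
    stop("hinge index out of range", call. = FALSE)
  structure(list(faces = faces), class = "pore_spec")
}

#' Per-frame incircle pore radii of the four faces
#'
#' Each face is the triangle spanned by its three hinge nucleotides; its
#' pore radius is the triangle incircle radius in nm. Per-frame maximum and
#' mean across the four faces are included (the plotting convention: show the
#' maximum, shade down to the mean).
#'
#' @param trajectory an `oxdna_trajectory`.
#' @param spec a [pore_spec()].
#' @param units an [oxdna_units()] object.
#' @return A `pore_series`: data frame with columns `frame`, `time` (s),
#'   `r1`..`r4`, `max`, `mean` (nm).
#' @export
pore_series <- function(trajectory, spec, units = oxdna_units()) {
  stopifnot(inherits(spec, "pore_spec"))
  n_nt <- dim(trajectory$positions)[1]
  if (any(spec$faces >= n_nt)) stop("hinge index out of range", call. = FALSE)
  nf <- n_frames(trajectory)
  radii <- matrix(0, nf, 4)
  for (f in seq_len(nf)) {
    pos <- trajectory$positions[, , f] * units$nm_per_length_unit
    for (k in 1:4) {
      idx <- spec$faces[k, ] + 1L
      radii[f, k] <- incircle_radius(pos[idx[1], ], pos[idx[2], ], pos[idx[3], ])
    }
  }
  out <- data.frame(frame = seq_len(nf),
                    time = convert_units(trajectory$times, "time",
                                         from = "sim", to = "si", units = units),
                    r1 = radii[, 1], r2 = radii[, 2],
                    r3 = radii[, 3], r4 = radii[, 4],
                    max = apply(radii, 1, max),
                    mean = rowMeans(radii))
  class(out) <- c("pore_series", "data.frame")
  out
}

#' Frames in which the capsule is leaky for a given cargo
#'
#' A frame is leaky when the maximum pore incircle radius strictly exceeds
#' the cargo radius (a pore exactly the size of the cargo is not leaky).
#'
#' @param series a [pore_series()].
#' @param cargo_radius cargo sphere radius, nm (> 0).
#' @return Integer vector of 1-based leaky frame indices.
#' @export
leakage_frames <- function(series, cargo_radius) {
  if (!is.finite(cargo_radius) || cargo_radius <= 0)
    stop("cargo radius must be positive", call. = FALSE)
  which(series$max > cargo_radius)
}
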