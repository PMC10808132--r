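# Simplified coarse-grained model of a DNA tetrahedron for pulling tests.
#
# Geometry: four vertices of a regular tetrahedron with edge length
# edge_bp * rise; one bead per nucleotide placed along each duplex edge, the
# two complementary strands of an edge offset toward the interiors of the two
# faces sharing that edge. Strand layout (5 oligonucleotides, mirroring the
# 5-6 strand wireframe designs): three full face strands each traversing the
# three oriented edges of a face, one truncated face strand, and a separate
# force-bearing (FB) strand occupying the first fb_bp positions of the
# remaining edge. Pulling the FB terminus shears the FB duplex against its
# complementary edge; FB release constitutes rupture.

# oriented faces: every undirected edge is traversed once in each direction
.tetra_faces <- list(c(1L, 2L, 3L), c(1L, 3L, 4L), c(1L, 4L, 2L), c(2L, 4L, 3L))

#' Design parameters of the tetrahedron analog
#'
#' @param edge_bp base pairs per edge (>= 4; default 20, giving 6.8 nm edges
#'   at the default rise).
#' @param rise axial rise per base pair, nm (default 0.34).
#' @param fb_bp number of base pairs formed by the force-bearing strand
#'   (default 4, the designed weak link; must be < `edge_bp` so the pull
#'   terminus has a
#'   single-stranded complement region, and >= 1).
#' @param strand_offset perpendicular offset of each strand from its edge
#'   axis toward its face interior, nm (default 0.59: the two strands of a
#'   duplex then sit 0.68 nm = 0.8 simulation length units apart, so the two
#'   hydrogen-bonding sites of a pair coincide and the geometric bound
#'   criterion holds with margin).
#' @return Object of class `tetra_design`.
#' @export
tetra_design <- function(edge_bp = 20L, rise = 0.34, fb_bp = 4L,
                         strand_offset = 0.59) {
  edge_bp <- as.integer(edge_bp); fb_bp <- as.integer(fb_bp)
  if (edge_bp < 4L) stop("edge_bp must be at least 4", call. = FALSE)
  if (fb_bp < 1L || fb_bp >= edge_bp)
    stop("fb_bp must lie in [1, edge_bp - 1]", call. = FALSE)
  stopifnot(rise > 0, strand_offset > 0)
  structure(list(edge_bp = edge_bp, rise = rise, fb_bp = fb_bp,
                 strand_offset = strand_offset),
            class = "tetra_design")
}

.base_complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Build the tetrahedron analog: topology, initial frame and annotations
#'
#' Constructs the 5-strand bead model described above. Base and normal
#' vectors are set from the local geometry (base vector toward the paired
#' bead, normal along the edge) so the geometric hydrogen-bond criterion of
#' [detect_base_pairs()] applies unchanged. Sequences are assigned from a
#' fixed repeating pattern with pairing complementarity enforced, so the
#' construction is fully deterministic.
#'
#' @param design a [tetra_design()].
#' @param units an [oxdna_units()] object (frame coordinates are stored in
#'   simulation units).
#' @return Object of class `dmc_model`: list with `topology`, `frame0`
#'   (1-frame `oxdna_trajectory`), `vertices` (4 x 3, nm), `positions_nm`
#'   (N x 3), `pairs` (2-column 0-based), `fb_pairs` (logical per pair),
#'   `backbone` (data frame i, j, rest), `sites` (0-based indices: `anchor`,
#'   `pull`, `fluorophore`, `quencher`), `pore` (a [pore_spec()]), `design`.
#' @export
build_tetrahedron <- function(design = tetra_design(), units = oxdna_units()) {
  stopifnot(inherits(design, "tetra_design"))
  nbp <- design$edge_bp; rise <- design$rise; fb <- design$fb_bp
  L <- nbp * rise
  s <- L / (2 * sqrt(2))
  V <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * s
  centroid_face <- function(f) colMeans(V[.tetra_faces[[f]], , drop = FALSE])

  # directed edge list per face strand; face 4 is truncated, FB covers the
  # first fb positions of its first oriented edge (2 -> 4)
  face_edges <- lapply(.tetra_faces, function(vs)
    rbind(c(vs[1], vs[2]), c(vs[2], vs[3]), c(vs[3], vs[1])))
  segs <- list()  # each: strand, a, b, face, k range
  for (f in 1:3)
    for (e in 1:3)
      segs[[length(segs) + 1L]] <- list(strand = f, a = face_edges[[f]][e, 1],
                                        b = face_edges[[f]][e, 2], face = f,
                                        ks = seq_len(nbp))
  segs[[length(segs) + 1L]] <- list(strand = 4L, a = 4L, b = 3L, face = 4L, ks = seq_len(nbp))
  segs[[length(segs) + 1L]] <- list(strand = 4L, a = 3L, b = 2L, face = 4L, ks = seq_len(nbp))
  segs[[length(segs) + 1L]] <- list(strand = 5L, a = 2L, b = 4L, face = 4L, ks = seq_len(fb))

  edge_key <- function(a, b) paste(sort(c(a, b)), collapse = "-")
  edge_ids <- unique(vapply(segs, function(sg) edge_key(sg$a, sg$b), ""))

  pos <- NULL; strand <- integer(0); face_of <- integer(0)
  edge_of <- character(0); kpos <- integer(0); dirfwd <- logical(0)
  normal <- NULL; offset_dir <- NULL
  for (sg in segs) {
    u <- (V[sg$b, ] - V[sg$a, ]); u <- u / sqrt(sum(u^2))
    mid <- (V[sg$a, ] + V[sg$b, ]) / 2
    w <- centroid_face(sg$face) - mid
    w <- w - sum(w * u) * u
    w <- w / sqrt(sum(w^2))
    ax <- outer(sg$ks - 0.5, u * rise)            # axial offsets from vertex a
    p <- sweep(ax, 2, V[sg$a, ] + design$strand_offset * w, "+")
    pos <- rbind(pos, p)
    m <- length(sg$ks)
    strand <- c(strand, rep(sg$strand, m))
    face_of <- c(face_of, rep(sg$face, m))
    edge_of <- c(edge_of, rep(edge_key(sg$a, sg$b), m))
    # axial index measured from the lower-numbered vertex of the edge
    fwd <- sg$a < sg$b
    kpos <- c(kpos, if (fwd) sg$ks else nbp + 1L - sg$ks)
    dirfwd <- c(dirfwd, rep(fwd, m))
    normal <- rbind(normal, matrix(u, m, 3, byrow = TRUE))
    offset_dir <- rbind(offset_dir, matrix(w, m, 3, byrow = TRUE))
  }
  n <- nrow(pos)

  # base pairs: same edge, same axial index, opposite traversal direction
  pair_list <- NULL
  for (ek in edge_ids) {
    idx <- which(edge_of == ek)
    for (k in unique(kpos[idx])) {
      at <- idx[kpos[idx] == k]
      if (length(at) == 2L) pair_list <- rbind(pair_list, sort(at))
    }
  }
  pair_list <- pair_list[order(pair_list[, 1]), , drop = FALSE]
  fb_pairs <- strand[pair_list[, 1]] == 5L | strand[pair_list[, 2]] == 5L

  # base vectors: toward the (possibly virtual) partner across the edge
  partner_pos <- pos - 2 * design$strand_offset * offset_dir +
    2 * design$strand_offset *
      t(vapply(seq_len(n), function(i) {
        others <- which(edge_of == edge_of[i] & dirfwd != dirfwd[i])
        if (length(others) > 0) offset_dir[others[1], ] else -offset_dir[i, ]
      }, numeric(3)))
  bvec <- partner_pos - pos
  bn <- sqrt(rowSums(bvec^2))
  bvec <- bvec / ifelse(bn > 1e-9, bn, 1)
  bvec[bn <= 1e-9, ] <- -offset_dir[bn <= 1e-9, , drop = FALSE]

  # sequences: fixed pattern indexed by edge and axial position; the forward-
  # traversing strand carries the pattern, the reverse strand its complement
  pat <- c("A", "C", "G", "T")
  base <- character(n)
  for (i in seq_len(n)) {
    e_id <- match(edge_of[i], edge_ids)
    b <- pat[(e_id * 7L + kpos[i]) %% 4L + 1L]
    base[i] <- if (dirfwd[i]) b else unname(.base_complement[b])
  }

  # topology neighbors: consecutive beads within a strand, 3' -> 5' order
  n3 <- rep(-1L, n); n5 <- rep(-1L, n)
  for (sid in 1:5) {
    at <- which(strand == sid)
    if (length(at) > 1L) {
      n5[at[-length(at)]] <- at[-1L] - 1L
      n3[at[-1L]] <- at[-length(at)] - 1L
    }
  }
  topo <- new_topology(strand = strand, base = base, neighbor3 = n3,
                       neighbor5 = n5, n_strands = 5L, path = "<built>")

  # backbone bonds with rest length = built geometry
  bb <- cbind(which(n5 >= 0L), n5[n5 >= 0L] + 1L)
  bb_rest <- sqrt(rowSums((pos[bb[, 1], , drop = FALSE] -
                           pos[bb[, 2], , drop = FALSE])^2))

  # labelled sites (0-based): pull = FB terminus near vertex 2; anchor = the
  # complementary-edge strand terminus near vertex 4; quencher = FB inner
  # terminus; fluorophore = its paired bead
  fb_idx <- which(strand == 5L)
  pull <- fb_idx[1L]
  quench <- fb_idx[length(fb_idx)]
  comp_seg <- which(edge_of == edge_key(2L, 4L) & strand == 3L)
  anchor <- comp_seg[which.min(sqrt(rowSums(sweep(pos[comp_seg, , drop = FALSE], 2, V[4L, ])^2)))]
  qpair <- pair_list[pair_list[, 1] == quench | pair_list[, 2] == quench, ]
  fluor <- setdiff(as.integer(qpair), quench)[1]

  # hinge nucleotides: per face, the face strand's bead nearest each vertex
  faces_mat <- matrix(0L, 4, 3)
  for (f in 1:4) {
    own <- which(strand == f)
    for (vi in 1:3) {
      v <- .tetra_faces[[f]][vi]
      d <- sqrt(rowSums(sweep(pos[own, , drop = FALSE], 2, V[v, ])^2))
      faces_mat[f, vi] <- own[which.min(d)] - 1L
    }
  }

  frame0 <- new_trajectory(
    times = 0,
    box = matrix(rep(ceiling(10 * L / units$nm_per_length_unit), 3), 1, 3),
    energy = matrix(0, 1, 3),
    positions = array(pos / units$nm_per_length_unit, c(n, 3, 1)),
    base_vectors = array(bvec, c(n, 3, 1)),
    normal_vectors = array(normal, c(n, 3, 1)))

  structure(
    list(topology = topo, frame0 = frame0, vertices = V, positions_nm = pos,
         pairs = pair_list - 1L, fb_pairs = fb_pairs,
         backbone = data.frame(i = bb[, 1] - 1L, j = bb[, 2] - 1L, rest = bb_rest),
         sites = list(anchor = anchor - 1L, pull = pull - 1L,
                      fluorophore = fluor - 1L, quencher = quench - 1L),
         pore = pore_spec(faces_mat, n),
         base_vectors0 = bvec, normal_vectors0 = normal,
         design = design, units = units),
    class = "dmc_model"
  )
}

#' @export
print.dmc_model <- function(x, ...) {
  cat(sprintf("DNA tetrahedron analog: %d beads, %d strands, %d bp/edge, %d FB pairs\n",
              x$topology$n_nucleotides, x$topology$n_strands,
              x$design$edge_bp, sum(x$fb_pairs)))
  invisible(x)
}

#' Simulation parameters for the pulling model
#'
#' Defaults give a structurally stiff tetrahedron whose designed weak link is
#' the FB duplex: structural base pairs are stiff with a high rupture
#' threshold (so thermal motion at 310 K never breaks them), FB pairs softer
#' with a planted threshold in the tens-of-piconewton regime
#' (`fb_k * fb_xstar` = 30 pN per bond by default).
#'
#' @param seed integer seed; fixes the full random stream (mandatory).
#' @param backbone_k backbone bond stiffness, pN/nm.
#' @param bp_k,bp_xstar structural base-pair stiffness (pN/nm) and rupture
#'   extension threshold (nm).
#' @param fb_k,fb_xstar same for force-bearing pairs.
#' @param temperature K (default 310).
#' @param gamma per-bead friction coefficient, pN s/nm.
#' @param dt timestep, s.
#' @param n_steps number of integration steps.
#' @param stride record a frame every `stride` steps (>= 1).
#' @param excluded_volume logical; soft harmonic repulsion between all bead
#'   pairs closer than `ev_cutoff` (off by default).
#' @param ev_k,ev_cutoff repulsion stiffness (pN/nm) and range (nm).
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(seed,
                       backbone_k = 300, bp_k = 50, bp_xstar = 2.0,
                       fb_k = 10, fb_xstar = 3.0,
                       temperature = 310, gamma = 1e-5, dt = 1.5e-9,
                       n_steps = 7e5, stride = 700,
                       excluded_volume = FALSE, ev_k = 50, ev_cutoff = 0.5) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(backbone_k > 0, bp_k > 0, bp_xstar > 0, fb_k > 0, fb_xstar > 0,
            temperature >= 0, gamma > 0, dt > 0, n_steps >= 1, stride >= 1)
  structure(list(seed = as.integer(seed), backbone_k = backbone_k,
                 bp_k = bp_k, bp_xstar = bp_xstar,
                 fb_k = fb_k, fb_xstar = fb_xstar,
                 temperature = temperature, gamma = gamma, dt = dt,
                 n_steps = n_steps, stride = as.integer(stride),
                 excluded_volume = excluded_volume,
                 ev_k = ev_k, ev_cutoff = ev_cutoff),
            class = "sim_params")
}

#' Default dual-trap protocol for a tetrahedron analog
#'
#' Fixed trap at the anchor bead, moving trap at the FB pull terminus,
#' pulling along the anchor-to-pull direction at the canonical converted
#' loading rate of 1.4e4 nm/s with two 11.42 pN/nm traps.
#'
#' @param model a `dmc_model`.
#' @param k trap stiffness for both traps, pN/nm.
#' @param rate trap translation rate, nm/s.
#' @return A [trap_protocol()].
#' @export
default_protocol <- function(model, k = 11.42, rate = 1.4e4) {
  pa <- model$positions_nm[model$sites$anchor + 1L, ]
  pb <- model$positions_nm[model$sites$pull + 1L, ]
  trap_protocol(model$sites$anchor, model$sites$pull, k, k,
                anchor_a = pa, start_b = pb, rate = rate,
                axis = (pb - pa) / sqrt(sum((pb - pa)^2)))
}

#' Planted rupture threshold force of the FB duplex
#'
#' The force at which a single FB bond breaks, `fb_k * fb_xstar` (pN): the
#' per-bond rupture criterion the simulator enforces.
#'
#' @param params a [sim_params()].
#' @return Force in pN.
#' @export
planted_threshold <- function(params) params$fb_k * params$fb_xstar

#' Run a dual-trap pulling simulation
#'
#' Overdamped Langevin dynamics of the bead model: backbone springs, intact
#' base-pair springs, trap forces and thermal noise. A base-pair bond breaks
#' irreversibly the first time its extension exceeds its threshold; every
#' break is logged. The same seed gives a bit-identical trajectory and event
#' log.
#'
#' @param model a `dmc_model` from [build_tetrahedron()] (or a compatible
#'   hand-built list; see [simulate_beads()] for the low-level interface).
#' @param params a [sim_params()].
#' @param protocol a [trap_protocol()] or `NULL` for no traps.
#' @return Object of class `pulling_run`: list with `trajectory`
#'   (`oxdna_trajectory`, frames every `stride` steps including step 0),
#'   `events` (data frame step, time, i, j, pair, fb), `broken` (logical per
#'   pair), `model`, `params`, `protocol`.
#' @export
run_pulling <- function(model, params, protocol = default_protocol(model)) {
  stopifnot(inherits(model, "dmc_model"), inherits(params, "sim_params"))
  pairs <- model$pairs
  p_rest <- sqrt(rowSums((model$positions_nm[pairs[, 1] + 1L, , drop = FALSE] -
                          model$positions_nm[pairs[, 2] + 1L, , drop = FALSE])^2))
  p_k <- ifelse(model$fb_pairs, params$fb_k, params$bp_k)
  p_x <- ifelse(model$fb_pairs, params$fb_xstar, params$bp_xstar)
  res <- simulate_beads(model$positions_nm,
                        backbone = cbind(model$backbone$i, model$backbone$j),
                        backbone_rest = model$backbone$rest,
                        backbone_k = rep(params$backbone_k, nrow(model$backbone)),
                        bonds = pairs, bond_rest = p_rest, bond_k = p_k,
                        bond_xstar = p_x, params = params, protocol = protocol)
  traj <- .frames_to_trajectory(res, model, params)
  ev <- data.frame(step = res$event_step,
                   time = res$event_step * params$dt,
                   i = pairs[res$event_bond, 1], j = pairs[res$event_bond, 2],
                   pair = res$event_bond,
                   fb = model$fb_pairs[res$event_bond])
  structure(list(trajectory = traj, events = ev, broken = res$broken,
                 model = model, params = params, protocol = protocol),
            class = "pulling_run")
}

#' Low-level bead-spring Langevin simulation
#'
#' Direct access to the integrator for arbitrary bead systems (used for
#' small analytic test systems as well as by [run_pulling()]). All inputs in
#' nm / s / pN; indices 0-based.
#'
#' @param positions N x 3 start positions, nm.
#' @param backbone 2-column matrix of permanent bond indices (may have 0 rows).
#' @param backbone_rest,backbone_k rest lengths (nm) and stiffnesses (pN/nm).
#' @param bonds 2-column matrix of breakable bond indices (may have 0 rows).
#' @param bond_rest,bond_k,bond_xstar rest lengths, stiffnesses and rupture
#'   extension thresholds of the breakable bonds.
#' @param params a [sim_params()].
#' @param protocol a [trap_protocol()] or `NULL`.
#' @return List with `frames` (N x 3 x n_frames, nm), `times` (s),
#'   `event_step`, `event_bond` (1-based breakable-bond index), `broken`.
#' @export
simulate_beads <- function(positions, backbone, backbone_rest, backbone_k,
                           bonds, bond_rest, bond_k, bond_xstar,
                           params, protocol = NULL) {
  stopifnot(inherits(params, "sim_params"))
  positions <- as.matrix(positions)
  backbone <- matrix(as.integer(backbone), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  kT <- 0.0138065 * params$temperature  # pN nm
  if (is.null(protocol)) {
    ia <- -1L; ib <- -1L; ka <- 0; kb <- 0
    aa <- numeric(3); sb <- numeric(3); ax <- c(1, 0, 0); rate <- 0
  } else {
    ia <- protocol$index_a; ib <- protocol$index_b
    ka <- protocol$k_a; kb <- protocol$k_b
    aa <- protocol$anchor_a; sb <- protocol$start_b
    ax <- protocol$axis; rate <- protocol$rate
  }
  max_disp <- if (nrow(backbone) > 0) min(backbone_rest) else 1.0
  set.seed(params$seed)
  res <- .sim_core(positions, backbone[, 1], backbone[, 2],
                   as.numeric(backbone_rest), as.numeric(backbone_k),
                   bonds[, 1], bonds[, 2], as.numeric(bond_rest),
                   as.numeric(bond_k), as.numeric(bond_xstar),
                   ia, ib, ka, kb, aa, sb, ax, rate,
                   params$gamma, params$dt, kT,
                   params$n_steps, params$stride, max_disp,
                   params$excluded_volume, params$ev_k, params$ev_cutoff)
  res
}

# convert raw simulator frames to an oxdna_trajectory; base vectors follow
# the paired bead per frame, normals keep the built edge direction
.frames_to_trajectory <- function(res, model, params) {
  units <- model$units
  nfr <- length(res$times)
  n <- dim(res$frames)[1]
  pos_sim <- res$frames / units$nm_per_length_unit
  bvec <- array(rep(model$base_vectors0, nfr), c(n, 3, nfr))
  prt <- rep(NA_integer_, n)
  prt[model$pairs[, 1] + 1L] <- model$pairs[, 2] + 1L
  prt[model$pairs[, 2] + 1L] <- model$pairs[, 1] + 1L
  paired <- which(!is.na(prt))
  for (f in seq_len(nfr)) {
    d <- res$frames[prt[paired], , f] - res$frames[paired, , f]
    nn <- sqrt(rowSums(d^2))
    ok <- nn > 1e-9
    bvec[paired[ok], , f] <- d[ok, , drop = FALSE] / nn[ok]
  }
  new_trajectory(
    times = res$times / units$s_per_time_unit,
    box = matrix(rep(model$frame0$box[1, ], each = nfr), nfr, 3),
    energy = matrix(0, nfr, 3),
    positions = pos_sim,
    base_vectors = bvec,
    normal_vectors = array(rep(model$normal_vectors0, nfr), c(n, 3, nfr)))
}

#' Bond-event log as CSV
#'
#' Columns: step, i, j (0-based nucleotide indices), fb flag.
#'
#' @param run a `pulling_run`.
#' @param path output path.
#' @export
write_bond_events_csv <- function(run, path) {
  utils::write.csv(run$events[, c("step", "i", "j", "fb")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Frame index of the last all-FB-intact frame
#'
#' Oracle for rupture detection: the last recorded frame at which every
#' force-bearing bond is still intact, read directly from the bond-event log.
#'
#' @param run a `pulling_run`.
#' @return 1-based frame index (number of frames if no FB bond ever broke).
#' @export
last_intact_frame <- function(run) {
  fb_ev <- run$events[run$events$fb, , drop = FALSE]
  if (nrow(fb_ev) == 0L) return(n_frames(run$trajectory))
  first_break <- min(fb_ev$step)
  max(1L, sum(run$params$stride * (seq_len(n_frames(run$trajectory)) - 1L) < first_break))
}
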