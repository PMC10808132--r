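# Readers/writers for the classic oxDNA file dialect:
#   topology:  "N_nt N_strands" header then one "strand base 3' 5'" row per
#              nucleotide (rows listed 3'->5' within a strand, -1 at ends)
#   configuration/trajectory: per frame "t = ...", "b = ...", "E = ..." then
#              one row per nucleotide with 9 or 15 whitespace-separated
#              numbers (position, base vector, normal vector[, velocity,
#              angular velocity]).
# All internal nucleotide indices are 0-based in file order.

.parse_error <- function(path, line, msg) {
  stop(sprintf("%s:%s: %s", path, line, msg), call. = FALSE)
}

#' Read an oxDNA classic topology file
#'
#' @param path path to a `.top` file.
#' @return An object of class `oxdna_topology`: a list with `n_nucleotides`,
#'   `n_strands`, `strand` (integer vector, per nucleotide), `base`
#'   (character vector over A/C/G/T), `neighbor3`, `neighbor5` (0-based
#'   indices, `-1` at chain ends) and `sequences` (per-strand strings).
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) .parse_error(path, 1L, "empty topology file")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]]))
  if (length(hdr) != 2L || anyNA(hdr))
    .parse_error(path, 1L, "header must hold two integers (N nucleotides, N strands)")
  n_nt <- hdr[1L]; n_strands <- hdr[2L]
  if (length(lines) - 1L != n_nt)
    .parse_error(path, length(lines),
                 sprintf("expected %d nucleotide rows, found %d", n_nt, length(lines) - 1L))
  fields <- strsplit(trimws(lines[-1L]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 4L))
    .parse_error(path, which(nf != 4L)[1L] + 1L, "nucleotide row must have 4 fields")
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  strand <- suppressWarnings(as.integer(m[, 1L]))
  base <- toupper(m[, 2L])
  n3 <- suppressWarnings(as.integer(m[, 3L]))
  n5 <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(strand) || anyNA(n3) || anyNA(n5))
    .parse_error(path, which(is.na(strand) | is.na(n3) | is.na(n5))[1L] + 1L,
                 "non-integer field in nucleotide row")
  topo <- new_topology(strand = strand, base = base,
                       neighbor3 = n3, neighbor5 = n5,
                       n_strands = n_strands, path = path)
  topo
}

#' Construct and validate a topology object
#'
#' @param strand integer strand id per nucleotide (contiguous, positive).
#' @param base character vector of bases (A/C/G/T).
#' @param neighbor3,neighbor5 0-based neighbor indices, -1 at ends.
#' @param n_strands declared strand count (checked).
#' @param path source path for error messages.
#' @return `oxdna_topology` object.
#' @export
new_topology <- function(strand, base, neighbor3, neighbor5,
                         n_strands = max(strand), path = "<topology>") {
  n_nt <- length(strand)
  err <- function(line, msg) .parse_error(path, line, msg)
  if (!all(base %in% c("A", "C", "G", "T")))
    err(which(!base %in% c("A", "C", "G", "T"))[1L] + 1L, "non-ACGT base")
  ids <- sort(unique(strand))
  if (!identical(ids, seq_len(max(strand))) || length(ids) != n_strands)
    err(1L, "strand ids must be contiguous 1..N_strands")
  bad <- neighbor3 < -1L | neighbor3 >= n_nt | neighbor5 < -1L | neighbor5 >= n_nt
  if (any(bad)) err(which(bad)[1L] + 1L, "neighbor index out of range")
  # symmetry: i's 5'-neighbor must name i as its 3'-neighbor, and vice versa
  for (i in seq_len(n_nt)) {
    j5 <- neighbor5[i]
    if (j5 >= 0L) {
      if (neighbor3[j5 + 1L] != i - 1L) err(i + 1L, "asymmetric neighbor link")
      if (strand[j5 + 1L] != strand[i]) err(i + 1L, "neighbor crosses strand boundary")
    }
    j3 <- neighbor3[i]
    if (j3 >= 0L && neighbor5[j3 + 1L] != i - 1L) err(i + 1L, "asymmetric neighbor link")
  }
  seqs <- vapply(ids, function(s) paste(base[strand == s], collapse = ""), "")
  structure(
    list(n_nucleotides = n_nt, n_strands = n_strands,
         strand = strand, base = base,
         neighbor3 = neighbor3, neighbor5 = neighbor5,
         sequences = seqs),
    class = "oxdna_topology"
  )
}

#' Write a topology in canonical classic format
#'
#' `write_topology()` followed by [read_topology()] is the identity; writing
#' a freshly read file reproduces it byte for byte (canonical form).
#'
#' @param topology an `oxdna_topology`.
#' @param path output path.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "oxdna_topology"))
  rows <- sprintf("%d %s %d %d", topology$strand, topology$base,
                  topology$neighbor3, topology$neighbor5)
  writeLines(c(sprintf("%d %d", topology$n_nucleotides, topology$n_strands), rows),
             path)
  invisible(path)
}

#' @export
print.oxdna_topology <- function(x, ...) {
  cat(sprintf("oxDNA topology: %d nucleotides in %d strands\n",
              x$n_nucleotides, x$n_strands))
  cat("strand lengths:", paste(nchar(x$sequences), collapse = ", "), "\n")
  invisible(x)
}

#' Read an oxDNA classic configuration/trajectory file
#'
#' Accepts both 15-column rows (with velocity and angular velocity) and
#' 9-column rows; positions are identical either way. Frame times must be
#' non-decreasing and every frame must contain exactly one row per
#' nucleotide of the topology.
#'
#' @param path path to a `.dat`/`.conf` file.
#' @param topology the matching `oxdna_topology`.
#' @return An object of class `oxdna_trajectory`: a list with `times`
#'   (simulation time units), `box` (frames x 3), `energy` (frames x 3),
#'   `positions`, `base_vectors`, `normal_vectors` (arrays N x 3 x frames,
#'   simulation length units) and `velocities` (same shape, or `NULL`).
#' @export
read_trajectory <- function(path, topology) {
  stopifnot(inherits(topology, "oxdna_topology"))
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  n_nt <- topology$n_nucleotides
  t_idx <- grep("^t\\s*=", lines)
  if (length(lines) == 0L || length(t_idx) == 0L)
    return(new_trajectory(times = numeric(0), box = matrix(0, 0, 3),
                          energy = matrix(0, 0, 3),
                          positions = array(0, c(n_nt, 3, 0)),
                          base_vectors = array(0, c(n_nt, 3, 0)),
                          normal_vectors = array(0, c(n_nt, 3, 0))))
  n_frames <- length(t_idx)
  num_after <- function(line, tag, k, lno) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(sub(".*=", "", line)), "\\s+")[[1L]]))
    if (length(v) < k || anyNA(v[seq_len(k)]))
      .parse_error(path, lno, sprintf("malformed '%s =' header", tag))
    v[seq_len(k)]
  }
  times <- numeric(n_frames)
  box <- matrix(0, n_frames, 3); energy <- matrix(0, n_frames, 3)
  pos <- array(NA_real_, c(n_nt, 3, n_frames))
  bvec <- array(NA_real_, c(n_nt, 3, n_frames))
  nvec <- array(NA_real_, c(n_nt, 3, n_frames))
  vel <- NULL
  for (f in seq_len(n_frames)) {
    i0 <- t_idx[f]
    last <- if (f < n_frames) t_idx[f + 1L] - 1L else length(lines)
    if (last - i0 < 2L + n_nt)
      .parse_error(path, last, sprintf("frame %d truncated: expected %d nucleotide rows", f, n_nt))
    times[f] <- num_after(lines[i0], "t", 1L, i0)
    if (!grepl("^b\\s*=", lines[i0 + 1L]) || !grepl("^E\\s*=", lines[i0 + 2L]))
      .parse_error(path, i0 + 1L, sprintf("frame %d: expected 'b =' and 'E =' headers", f))
    box[f, ] <- num_after(lines[i0 + 1L], "b", 3L, i0 + 1L)
    energy[f, ] <- num_after(lines[i0 + 2L], "E", 3L, i0 + 2L)
    rows <- lines[(i0 + 3L):(i0 + 2L + n_nt)]
    extra <- if (last > i0 + 2L + n_nt) lines[(i0 + 3L + n_nt):last] else character(0)
    if (any(nzchar(trimws(extra))))
      .parse_error(path, i0 + 3L + n_nt, sprintf("frame %d: row count exceeds topology", f))
    fields <- strsplit(trimws(rows), "\\s+")
    nf <- unique(lengths(fields))
    if (length(nf) != 1L || !nf %in% c(9L, 15L))
      .parse_error(path, i0 + 3L, sprintf("frame %d: rows must have 9 or 15 numeric fields", f))
    m <- suppressWarnings(matrix(as.numeric(unlist(fields)), nrow = n_nt, byrow = TRUE))
    if (anyNA(m))
      .parse_error(path, i0 + 2L + which(rowSums(is.na(m)) > 0)[1L],
                   sprintf("frame %d: non-numeric field", f))
    pos[, , f] <- m[, 1:3]
    bvec[, , f] <- m[, 4:6]
    nvec[, , f] <- m[, 7:9]
    if (nf == 15L) {
      if (is.null(vel)) vel <- array(NA_real_, c(n_nt, 3, n_frames))
      vel[, , f] <- m[, 10:12]
    }
    if (f > 1L && times[f] < times[f - 1L])
      .parse_error(path, i0, sprintf("frame %d: decreasing time", f))
  }
  new_trajectory(times = times, box = box, energy = energy,
                 positions = pos, base_vectors = bvec, normal_vectors = nvec,
                 velocities = vel)
}

#' Construct and validate a trajectory object
#'
#' @param times frame times, simulation units, non-decreasing.
#' @param box frames x 3 box lengths.
#' @param energy frames x 3 energies.
#' @param positions,base_vectors,normal_vectors arrays N x 3 x frames.
#' @param velocities optional array N x 3 x frames.
#' @return `oxdna_trajectory` object.
#' @export
new_trajectory <- function(times, box, energy, positions, base_vectors,
                           normal_vectors, velocities = NULL) {
  n_frames <- length(times)
  stopifnot(dim(positions)[3] == n_frames,
            all(dim(base_vectors) == dim(positions)),
            all(dim(normal_vectors) == dim(positions)))
  if (n_frames > 0L) {
    if (is.unsorted(times)) stop("frame times must be non-decreasing", call. = FALSE)
    if (!all(is.finite(positions))) stop("non-finite position", call. = FALSE)
    bn <- sqrt(colSums(aperm(base_vectors, c(2, 1, 3))^2))
    nn <- sqrt(colSums(aperm(normal_vectors, c(2, 1, 3))^2))
    if (any(abs(bn - 1) > 1e-3) || any(abs(nn - 1) > 1e-3))
      stop("base/normal vectors must have unit norm within 1e-3", call. = FALSE)
  }
  structure(
    list(times = times, box = box, energy = energy,
         positions = positions, base_vectors = base_vectors,
         normal_vectors = normal_vectors, velocities = velocities),
    class = "oxdna_trajectory"
  )
}

#' Number of frames in a trajectory
#' @param trajectory an `oxdna_trajectory`.
#' @export
n_frames <- function(trajectory) length(trajectory$times)

#' @export
print.oxdna_trajectory <- function(x, ...) {
  cat(sprintf("oxDNA trajectory: %d frames, %d nucleotides%s\n",
              n_frames(x), dim(x$positions)[1],
              if (is.null(x$velocities)) "" else ", with velocities"))
  invisible(x)
}

#' Write a trajectory in classic configuration format
#'
#' Output is re-readable by [read_trajectory()]; read-write-read is a fixed
#' point (positions within 1e-6 simulation length units). Frames violating
#' the unit-vector invariant are refused.
#'
#' @param trajectory an `oxdna_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "oxdna_trajectory"))
  # re-validate so a hand-modified object cannot write an invalid file
  new_trajectory(trajectory$times, trajectory$box, trajectory$energy,
                 trajectory$positions, trajectory$base_vectors,
                 trajectory$normal_vectors, trajectory$velocities)
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt_row <- function(m) do.call(sprintf, c(list(paste(rep("%.8f", ncol(m)), collapse = " ")),
                                            lapply(seq_len(ncol(m)), function(j) m[, j])))
  for (f in seq_len(n_frames(trajectory))) {
    writeLines(c(sprintf("t = %.8f", trajectory$times[f]),
                 sprintf("b = %.8f %.8f %.8f", trajectory$box[f, 1],
                         trajectory$box[f, 2], trajectory$box[f, 3]),
                 sprintf("E = %.8f %.8f %.8f", trajectory$energy[f, 1],
                         trajectory$energy[f, 2], trajectory$energy[f, 3])), con)
    m <- cbind(trajectory$positions[, , f], trajectory$base_vectors[, , f],
               trajectory$normal_vectors[, , f])
    if (!is.null(trajectory$velocities))
      m <- cbind(m, trajectory$velocities[, , f], matrix(0, nrow(m), 3))
    writeLines(fmt_row(m), con)
  }
  invisible(path)
}
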