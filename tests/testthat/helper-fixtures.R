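# Shared fixtures: all built in code at test time.

# small tetrahedron analog used in simulation tests (fast: ~90 beads)
small_model <- function(fb_bp = 3L, edge_bp = 8L) {
  build_tetrahedron(tetra_design(edge_bp = edge_bp, fb_bp = fb_bp))
}

# fast pulling parameters for the small analog
small_params <- function(seed, ...) {
  args <- list(seed = seed, n_steps = 2e5, stride = 500)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_params, args)
}

run_small <- function(fb_bp = 3L, seed = 1L, rate = 7e4, ...) {
  m <- small_model(fb_bp)
  pr <- default_protocol(m, rate = rate)
  run <- run_pulling(m, small_params(seed, ...), pr)
  run$curve <- force_extension_curve(run$trajectory, pr)
  run
}

# hand-built trajectory from a positions array (nm), static orientations
make_trajectory <- function(pos_nm, times_s = seq_len(dim(pos_nm)[3]) - 1,
                            base = NULL, units = oxdna_units()) {
  n <- dim(pos_nm)[1]; nf <- dim(pos_nm)[3]
  if (is.null(base)) base <- matrix(rep(c(0, 1, 0), each = n), n, 3)
  new_trajectory(times = times_s / units$s_per_time_unit,
                 box = matrix(100, nf, 3), energy = matrix(0, nf, 3),
                 positions = pos_nm / units$nm_per_length_unit,
                 base_vectors = array(rep(base, nf), c(n, 3, nf)),
                 normal_vectors = array(rep(c(0, 0, 1), each = n), c(n, 3, nf)))
}

# canonical 8-nt duplex topology fixture, written to a temp dir
duplex_fixture_dir <- function() {
  dir <- tempfile("fixtures")
  write_demo_fixtures(dir)
  dir
}
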