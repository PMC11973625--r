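# Shared fixture builders. All fixtures are constructed in code with fixed
# seeds; nothing is read from disk.

# small all-water grid with a single delivery-depth layer
tiny_grid <- function(nx = 40, ny = 40, n_steps = 31, depths = 3.6,
                      time_step = 720) {
  grid_spec(nx = nx, ny = ny, cell_size = 50, depth_layers = depths,
            time_step = time_step, n_steps = n_steps)
}

# spatially uniform steady field
uniform_field <- function(u = 0.1, v = 0, grid = tiny_grid(), mask = NULL) {
  build_tidal_field(grid, tidal_amp = 0, mean_flow = c(u, v), mask = mask)
}

# square release polygon centred at (cx, cy)
square_poly <- function(cx, cy, half = 100) {
  cbind(c(cx - half, cx + half, cx + half, cx - half),
        c(cy - half, cy - half, cy + half, cy + half))
}

# hand-built track ensemble (unit under test for counting code): positions
# given as nT x np matrices
manual_ensemble <- function(x, y, dt = 720, t_release = NULL,
                            status = NULL) {
  nT <- nrow(x); np <- ncol(x)
  if (is.null(status)) status <- matrix(0L, nT, np)
  if (is.null(t_release)) t_release <- rep(0, np)
  structure(list(times = (seq_len(nT) - 1) * dt, x = x, y = y,
                 status = status, depth = 3.6,
                 config = tracking_config(duration_h = max(nT - 1, 1) * dt / 3600,
                                          release_depth = 3.6,
                                          n_particles = max(np, 1L),
                                          release_jitter = FALSE),
                 polygon_id = "manual", t_release = t_release,
                 release_complete_step = 1L,
                 excluded_from_step = NA_integer_),
            class = "track_ensemble")
}

# piecewise-constant speed series with Gaussian noise
stepped_series <- function(levels, lengths, sd = 0.005, seed = 1) {
  set.seed(seed)
  rep(levels, lengths) + stats::rnorm(sum(lengths), 0, sd)
}
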