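# Shared fixtures: a desk-scale acquisition (same 200-degree short-scan
# span and 4 s breathing cycle as the full setup, quarter-resolution
# detector, 50 views) so unit tests stay fast. Stacks are generated once
# per test run and cached.

small_detector <- function() {
  detector_spec(nu = 160L, nv = 120L, spacing_u = 2.464, spacing_v = 2.464)
}

small_geom <- function(n_views = 50L, increment = 4.0, scan_time = 4,
                       detector = small_detector()) {
  circular_trajectory(n_views, increment = increment, scan_time = scan_time,
                      detector = detector)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_stack <- function() {
  cached("stack_moving", forward_project(phantom_spec(), small_geom()))
}

small_stack_static <- function() {
  cached("stack_static",
         forward_project(phantom_spec(amplitude_mm = 0), small_geom()))
}

# exact detector trajectory of the diaphragm apex (perfect tracking)
apex_vertices <- function(spec, geom) {
  truth <- diaphragm_top_truth(spec, geom$timestamps)
  t(vapply(seq_len(geom$n_views), function(i)
    project_point(geom$matrices[[i]], truth[i, ]), numeric(2)))
}
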