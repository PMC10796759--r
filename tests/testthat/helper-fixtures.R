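# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# Mid-sized clean phantom shared across pathway/profile tests.
std_phantom <- function() {
  cached("std", make_phantom(shape = c(96, 96, 96),
                             spacing = c(0.5, 0.5, 0.5), seed = 401))
}

# Same geometry carved with zero misalignment and no noise: post equals the
# carved pre exactly.
std_phantom_nomis <- function() {
  cached("nomis", make_phantom(shape = c(96, 96, 96),
                               spacing = c(0.5, 0.5, 0.5), seed = 401,
                               misalignment = rigid_transform(),
                               noise = list(hu_sd = 0, force_sd = 0,
                                            ar1 = 0)))
}

# Smooth band-limited test volume for interpolation-error bounds.
smooth_volume <- function(n = 40, spacing = c(1, 1, 1)) {
  xs <- (seq_len(n) - 1) * spacing[1]
  f <- function(x, y, z)
    500 + 200 * sin(x / 7) * cos(y / 9) + 150 * sin(z / 8 + 1)
  g <- expand.grid(x = xs, y = xs, z = xs)
  ct_volume(array(f(g$x, g$y, g$z), c(n, n, n)), spacing = spacing)
}

axis_angle_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b)))) * 180 / pi
}
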