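# small in-code fixtures shared across test files

# flat 4-vertex, 2-face strip in the z = 0 plane (unit right triangles)
flat_quad_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               rbind(c(1, 2, 3), c(2, 4, 3)))
}

# series with the same vector replicated on every face at each time sample;
# `vecs` is a T x 3 matrix (or list of length-3 vectors)
uniform_series <- function(vecs, mesh = flat_quad_mesh(), times = NULL,
                           period = NULL) {
  if (is.list(vecs)) vecs <- do.call(rbind, vecs)
  nt <- nrow(vecs)
  if (is.null(times)) times <- (seq_len(nt) - 1) / nt
  if (is.null(period)) period <- 1
  m <- nrow(mesh$faces)
  wss <- array(0, c(nt, m, 3))
  for (k in 1:3) wss[, , k] <- matrix(vecs[, k], nt, m)
  wall_field_series(mesh, times, wss, period = period)
}

all_sac <- function(mesh) sac_mask(rep(TRUE, nrow(mesh$faces)), mesh)

# independent cyclic trapezoid oracle: explicit sum over segments,
# including the closing segment pairing the last sample with the first
trapz_cyclic_oracle <- function(times, values, period) {
  nt <- length(times)
  total <- 0
  for (i in seq_len(nt - 1))
    total <- total + 0.5 * (values[i] + values[i + 1]) *
      (times[i + 1] - times[i])
  dt_close <- period - (times[nt] - times[1])
  total + 0.5 * (values[nt] + values[1]) * dt_close
}

# brute-force two-sided Mann-Whitney U by enumeration of group assignments
mwu_brute_force <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(utils::combn(length(pooled), n1), 2,
                 function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  p <- min(1, 2 * min(mean(u_all <= u_obs + 1e-9),
                      mean(u_all >= u_obs - 1e-9)))
  list(statistic = u_obs, p_value = p)
}

# the 19 frozen published CIEDE2000 verification pairs (Lab1, Lab2, dE00)
ciede2000_reference_pairs <- function() {
  m <- matrix(c(
    50.0000,  2.6772, -79.7751, 50.0000,  0.0000, -82.7485, 2.0425,
    50.0000,  3.1571, -77.2803, 50.0000,  0.0000, -82.7485, 2.8615,
    50.0000,  2.8361, -74.0200, 50.0000,  0.0000, -82.7485, 3.4412,
    50.0000, -1.3802, -84.2814, 50.0000,  0.0000, -82.7485, 1.0000,
    50.0000, -1.1848, -84.8006, 50.0000,  0.0000, -82.7485, 1.0000,
    50.0000, -0.9009, -85.5211, 50.0000,  0.0000, -82.7485, 1.0000,
    50.0000,  0.0000,   0.0000, 50.0000, -1.0000,   2.0000, 2.3669,
    50.0000, -1.0000,   2.0000, 50.0000,  0.0000,   0.0000, 2.3669,
    50.0000,  2.4900,  -0.0010, 50.0000, -2.4900,   0.0009, 7.1792,
    50.0000,  2.4900,  -0.0010, 50.0000, -2.4900,   0.0010, 7.1792,
    60.2574, -34.0099,  36.2677, 60.4626, -34.1751,  39.4387, 1.2644,
    63.0109, -31.0961,  -5.8663, 62.8187, -29.7946,  -4.0864, 1.2630,
    35.0831, -44.1164,   3.7933, 35.0232, -40.0716,   1.5901, 1.8645,
    22.7233,  20.0904, -46.6940, 23.0331,  14.9730, -42.5619, 2.0373,
    36.4612,  47.8580,  18.3852, 36.2715,  50.5065,  21.2231, 1.4146,
    90.8027,  -2.0831,   1.4410, 91.1528,  -1.6435,   0.0447, 1.4441,
    90.9257,  -0.5406,  -0.9208, 88.6381,  -0.8985,  -0.7239, 1.5381,
     6.7747,  -0.2908,  -2.4247,  5.8714,  -0.0985,  -2.2286, 0.6377,
     2.0776,   0.0795,  -1.1350,  0.9033,  -0.0636,  -0.5514, 0.9082),
    ncol = 7, byrow = TRUE)
  list(lab_a = m[, 1:3], lab_b = m[, 4:6], de = m[, 7])
}
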