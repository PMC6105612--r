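# Shared fixtures: the calibrated illumination model and a small,
# fast-rendering study design (same 51.2 x 51.2 mm field as the default,
# at coarser pixel pitch).

calibrated_model <- function(...) {
  calibrate_distance_exponent(rbind(c(20, 25.2), c(35, 4.7)), ...)
}

small_design <- function(n_specimens = 2, seed = 1,
                         cameras = list(external = external_camera()), ...) {
  study_design(n_specimens = n_specimens, shape = c(128, 128),
               pitch_mm = 0.4, roi_radius_px = 12, cameras = cameras,
               seed = seed, ...)
}

# The published 9-standard x 4-observer score matrix, built in code so
# agreement tests do not depend on the packaged CSV.
score_matrix <- function() {
  rating_table(rbind(
    c(4, 4, 4, 4), c(4, 4, 4, 4), c(3, 4, 3, 4),
    c(3, 4, 3, 3), c(3, 3, 3, 3), c(2, 2, 2, 2),
    c(2, 2, 2, 2), c(1, 1, 2, 1), c(1, 1, 1, 1)), k = 5)
}

# Brute-force pairwise agreement: explicit loop over all rater pairs.
pairwise_agreement_bruteforce <- function(m) {
  m <- as.matrix(m)
  agree <- 0L; total <- 0L
  for (i in seq_len(nrow(m))) {
    for (a in seq_len(ncol(m) - 1L)) {
      for (b in (a + 1L):ncol(m)) {
        agree <- agree + (m[i, a] == m[i, b])
        total <- total + 1L
      }
    }
  }
  agree / total
}

# Brute-force Fleiss kappa from explicit tallies.
fleiss_kappa_bruteforce <- function(m, k) {
  m <- as.matrix(m)
  po <- pairwise_agreement_bruteforce(m)
  counts <- integer(k)
  for (v in as.integer(m)) counts[v + 1L] <- counts[v + 1L] + 1L
  pe <- sum((counts / sum(counts))^2)
  (po - pe) / (1 - pe)
}
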