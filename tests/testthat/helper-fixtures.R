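# Shared test fixtures, built in code.

# small deterministic cube with distinct values everywhere
make_test_cube <- function(lines = 4, samples = 4, bands = 10, unit = "DN",
                           interleave = "BIL") {
  vals <- array(seq_len(lines * samples * bands) %% 977 + 1,
                c(lines, samples, bands))
  hypercube(vals, wavelengths_nm = seq(400, by = 10, length.out = bands),
            unit = unit, camera_id = "test", interleave = interleave)
}

# best label agreement over all cluster -> class bijections (brute force,
# independent of the package's labeling rules)
best_label_agreement <- function(labels, truth_map, k) {
  classes <- sort(unique(as.vector(truth_map)))
  stopifnot(length(classes) <= k)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  lab_v <- as.vector(labels)
  truth_v <- as.vector(truth_map)
  conf <- table(factor(lab_v, levels = seq_len(k)),
                factor(truth_v, levels = classes))
  best <- 0
  for (pm in perms(seq_len(k))) {
    # pm[c] = cluster assigned to class index c
    agree <- sum(conf[cbind(pm[seq_along(classes)], seq_along(classes))])
    best <- max(best, agree / length(lab_v))
  }
  best
}

# leaf-clip spectroradiometer wavelength grid fixture (3 nm step)
asd_grid <- function() seq(400, 2500, by = 3)
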