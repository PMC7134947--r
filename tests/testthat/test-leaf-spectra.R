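smooth_leaf <- function(wl = asd_grid()) {
  spectrum(wl, leaf_reflectance_default(wl))
}

test_that("splice correction leaves continuous spectra essentially unchanged", {
  wl <- asd_grid()
  # locally linear spectrum: the extrapolation is exact, offsets vanish
  lin <- spectrum(wl, 0.1 + 2e-4 * wl)
  out <- splice_correct(lin)
  expect_equal(out$values, lin$values, tolerance = 1e-9)
  # smooth curved spectrum: offsets stay far below any real detector step
  s <- smooth_leaf()
  expect_lt(max(abs(splice_correct(s)$values - s$values)), 2e-3)
})

test_that("splice correction removes an injected detector step", {
  wl <- asd_grid()
  base <- 0.1 + 2e-4 * wl  # linear: the extrapolation is exact
  v <- base
  v[wl <= 1000] <- v[wl <= 1000] + 0.05
  stepped <- spectrum(wl, v)
  fixed <- splice_correct(stepped)
  i <- max(which(wl <= 1000))
  jump_before <- abs(diff(stepped$values[i:(i + 1)]) - diff(base[i:(i + 1)]))
  jump_after <- abs(diff(fixed$values[i:(i + 1)]) - diff(base[i:(i + 1)]))
  expect_gt(jump_before, 0.049)
  expect_lt(jump_after, 1e-6)
  expect_equal(fixed$values, base, tolerance = 1e-9)  # step fully removed
  # the reference (central) segment is untouched
  mid <- wl > 1000 & wl <= 1800
  expect_identical(fixed$values[mid], stepped$values[mid])
  # steps on the SWIR side are corrected against the central segment too
  v2 <- base
  v2[wl > 1800] <- v2[wl > 1800] - 0.04
  fixed2 <- splice_correct(spectrum(wl, v2))
  j <- min(which(wl > 1800))
  expect_lt(abs(diff(fixed2$values[(j - 1):j]) - diff(base[(j - 1):j])), 1e-6)
  expect_equal(fixed2$values, base, tolerance = 1e-9)
})

test_that("splice correction is idempotent", {
  s <- smooth_leaf()
  v <- s$values + ifelse(s$wavelengths_nm <= 1000, 0.03, 0)
  once <- splice_correct(spectrum(s$wavelengths_nm, v))
  twice <- splice_correct(once)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
  expect_error(splice_correct(s, junctions_nm = c(100)), "interior")
})

test_that("replicate QC: identical replicates all survive and average to
           themselves", {
  s <- smooth_leaf()
  reps <- replicate(6, s, simplify = FALSE)
  out <- qc_replicates(leaf_sample("L1", "P1", reps))
  expect_true(all(out$viable))
  expect_true(out$accepted)
  expect_equal(out$mean_spectrum$values, s$values)
})

test_that("a single strongly deviant replicate is eliminated, leaf accepted", {
  s <- smooth_leaf()
  # offset confined above 600 nm so the 450 nm seal check stays silent
  shift <- 0.10 * (s$wavelengths_nm > 600)
  bad <- spectrum(s$wavelengths_nm, s$values + shift)
  reps <- c(replicate(5, s, simplify = FALSE), list(bad))
  out <- qc_replicates(leaf_sample("L2", "P1", reps))
  # hand oracle: the replicate mean shifts by shift/6 (band-average 0.015 <
  # 0.02, clean replicates kept); the outlier deviates by 5*shift/6
  # (band-average 0.075 > 0.02, dropped)
  expect_identical(out$viable, c(rep(TRUE, 5), FALSE))
  expect_identical(out$reasons[6], "deviation_gt_threshold")
  expect_true(out$accepted)
  expect_equal(out$mean_spectrum$values, s$values)
})

test_that("three replicates offset by +0.05 reject the whole leaf", {
  s <- smooth_leaf()
  off <- spectrum(s$wavelengths_nm, s$values + 0.05)
  reps <- c(replicate(3, s, simplify = FALSE), replicate(3, off, simplify = FALSE))
  out <- qc_replicates(leaf_sample("L3", "P1", reps))
  # hand oracle: the replicate mean sits 0.025 from BOTH groups, so every
  # replicate exceeds the 0.02 deviation bound; fewer than 4 survive
  expect_false(any(out$viable))
  expect_false(out$accepted)
  expect_null(out$mean_spectrum)
})

test_that("the 450 nm seal check removes light-leak replicates first", {
  s <- smooth_leaf()
  leak <- s
  leak$values[which.min(abs(s$wavelengths_nm - 450))] <- 0.5
  reps <- c(replicate(5, s, simplify = FALSE), list(leak))
  out <- qc_replicates(leaf_sample("L4", "P1", reps))
  expect_identical(out$viable, c(rep(TRUE, 5), FALSE))
  expect_identical(out$reasons[6], "seal_check_450nm")
  expect_true(out$accepted)
})

test_that("QC flags but never modifies replicate spectra", {
  s <- smooth_leaf()
  bad <- spectrum(s$wavelengths_nm, s$values + 0.10)
  samp <- leaf_sample("L5", "P1", list(s, s, s, s, bad))
  out <- qc_replicates(samp)
  for (i in seq_along(samp$replicates)) {
    expect_identical(out$replicates[[i]]$values, samp$replicates[[i]]$values)
  }
})

test_that("rejection is monotone in added deviant replicates", {
  s <- smooth_leaf()
  bad <- spectrum(s$wavelengths_nm, s$values + 0.10)
  base <- replicate(5, s, simplify = FALSE)
  v0 <- sum(qc_replicates(leaf_sample("L", "P", base))$viable)
  v1 <- sum(qc_replicates(leaf_sample("L", "P", c(base, list(bad))))$viable)
  expect_lte(v1, v0 + 1L)
  expect_gte(v0, v1)  # adding a deviant never increases the viable count
})

test_that("leaf-to-plot averaging is the unweighted mean of accepted leaves", {
  s <- smooth_leaf()
  mk <- function(offset) {
    qc_replicates(leaf_sample(paste0("L", offset), "P",
                              replicate(4, spectrum(s$wavelengths_nm,
                                                    s$values + offset),
                                        simplify = FALSE)))
  }
  leaves <- lapply(c(0, 0.01, 0.02, -0.01, 0.03), mk)
  avg <- average_leaves_to_plot(leaves)
  expect_equal(avg$values, s$values + mean(c(0, 0.01, 0.02, -0.01, 0.03)),
               tolerance = 1e-12)
  one <- average_leaves_to_plot(leaves[1])
  expect_equal(one$values, s$values)
  two <- average_leaves_to_plot(leaves[1:2])
  expect_equal(two$values, (leaves[[1]]$mean_spectrum$values +
                              leaves[[2]]$mean_spectrum$values) / 2)
  rejected <- qc_replicates(leaf_sample("R", "P", replicate(3, s, simplify = FALSE)))
  expect_error(average_leaves_to_plot(list(rejected)), "empty plot")
  expect_equal(average_traits(c(1, 2, NA, 3)), 2)
})
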