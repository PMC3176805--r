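test_that("pearson_r: self, sign flip, direct formula oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- c(1, 2, 3, 5)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero-variance")
})

test_that("partial_r reduces to pearson_r and matches the recursive formula", {
  set.seed(12)
  x <- rnorm(50); y <- rnorm(50); z <- rnorm(50)
  expect_equal(partial_r(x, y, NULL), pearson_r(x, y))

  rxy <- cor(x, y); rxz <- cor(x, z); rzy <- cor(z, y)
  oracle <- (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
  expect_equal(partial_r(x, y, cbind(z)), oracle, tolerance = 1e-10)

  # a covariate that generated x explains the shared part away
  c1 <- rnorm(50)
  xx <- c1
  yy <- c1 + rnorm(50, sd = 0.5)
  expect_lt(abs(partial_r(xx, yy, cbind(c1))), 0.3)
})

test_that("seed FC: own series gives r = 1; Fisher z of 0 is 0; clipping", {
  vol <- random_vol4d(c(4, 4, 2, 40), seed = 13)
  seed_tc <- vol$data[2, 2, 1, ]
  res <- seed_fc_map(vol, seed_tc, fisher_z = TRUE)
  expect_equal(res$r$data[2, 2, 1], 1, tolerance = 1e-12)
  expect_true(all(abs(res$r$data) <= 1))
  expect_true(all(is.finite(res$z$data)))
  expect_equal(res$z$data[2, 2, 1], atanh(1 - 1e-7), tolerance = 1e-9)
  expect_gte(res$z$qc$clipped_voxels, 1L)
  expect_equal(atanh(0), 0)
  # constant voxel -> r = 0 and a QC count, never NaN
  vol$data[1, 1, 1, ] <- 5
  res2 <- seed_fc_map(vol, seed_tc)
  expect_equal(res2$r$data[1, 1, 1], 0)
  expect_equal(res2$r$qc$constant_voxels, 1L)
})

test_that("partial seed FC equals voxel-wise partial_r", {
  vol <- random_vol4d(c(3, 3, 1, 30), seed = 14)
  seed_tc <- rnorm(30)
  covs <- cbind(rnorm(30), rnorm(30))
  res <- seed_fc_map(vol, seed_tc, covs = covs)
  expect_equal(res$r$data[3, 2, 1],
               partial_r(vol$data[3, 2, 1, ], seed_tc, covs),
               tolerance = 1e-10)
})

test_that("roi_wise_fc is a symmetric unit-diagonal matrix matching pearson_r", {
  set.seed(15)
  tcs <- list(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  m <- roi_wise_fc(tcs)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_identical(m, t(m))
  expect_equal(m["a", "b"], pearson_r(tcs$a, tcs$b), tolerance = 1e-12)
  expect_equal(m["b", "c"], pearson_r(tcs$b, tcs$c), tolerance = 1e-12)

  two <- roi_wise_fc(list(tcs$a, tcs$a))
  expect_equal(two[1, 2], 1)
})

test_that("kcc attains 1 for identical monotone series and matches brute force", {
  perfect <- matrix(rep(seq_len(100), 27), 100, 27)
  expect_identical(kcc(perfect), 1)

  set.seed(16)
  small <- matrix(sample(12), 4, 3)
  expect_identical(kcc(small), kcc_bruteforce(small))
})

test_that("kcc equals brute force on 500 random instances (with ties)", {
  set.seed(17)
  for (i in seq_len(500)) {
    k <- sample(2:27, 1)
    n <- sample(3:30, 1)
    m <- matrix(sample(seq_len(n), n * k, replace = TRUE), n, k)
    expect_identical(kcc(m), kcc_bruteforce(m))
  }
})

test_that("neighbourhood stencils enumerate 6/18/26 offsets correctly", {
  s6 <- restkit:::stencil_offsets(6)
  expect_equal(nrow(s6), 6L)
  hand6 <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                 c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  expect_setequal(apply(s6, 1, paste, collapse = ","),
                  apply(hand6, 1, paste, collapse = ","))
  expect_equal(nrow(restkit:::stencil_offsets(18)), 18L)
  s26 <- restkit:::stencil_offsets(26)
  expect_equal(nrow(s26), 26L)
  expect_false(any(rowSums(abs(s26)) == 0))
})

test_that("reho is 1 when all voxels share one series; bounded otherwise", {
  tt <- 20
  shared <- rnorm(tt)
  arr <- array(rep(shared, each = 4 * 4 * 4), dim = c(4, 4, 4, tt))
  vol <- volume4d(arr, diag(4), 2)
  m <- reho_map(vol, neighbors = 26)
  expect_equal(max(abs(m$data - 1)), 0, tolerance = 1e-10)

  vol2 <- random_vol4d(c(5, 5, 5, 30), seed = 18)
  for (nb in c(6L, 26L)) {
    m2 <- reho_map(vol2, neighbors = nb)
    expect_true(all(m2$data >= 0 & m2$data <= 1))
  }
})

test_that("white-noise ReHo sits at the Kendall-W null, per permutation oracle", {
  set.seed(19)
  tt <- 100
  vol <- random_vol4d(c(6, 6, 6, tt), seed = 19)
  m <- reho_map(vol, neighbors = 26)
  inner <- m$data[2:5, 2:5, 2:5]                 # full K = 27 voxels
  # permutation oracle for E[W] under independence at K = 27
  perm_w <- replicate(300, kcc(replicate(27, sample(tt))))
  expect_lt(abs(mean(inner) - mean(perm_w)), 3 * sd(perm_w) / sqrt(300) + 0.01)
  # three sampled voxels individually near the null
  expect_true(all(abs(c(m$data[3, 3, 3], m$data[2, 4, 5], m$data[5, 2, 3]) -
                        mean(perm_w)) < 5 * sd(perm_w)))
})

test_that("ALFF: constant gives 0, amplitude is linear, oracle agreement", {
  tt <- 200; tr <- 2
  const <- volume4d(array(7, dim = c(2, 2, 1, tt)), diag(4), tr)
  expect_equal(max(abs(alff_map(const, 0.01, 0.08)$data)), 0, tolerance = 1e-12)

  f <- 20 / (good_fft_length(tt) * tr)
  a1 <- array(0, dim = c(2, 1, 1, tt))
  a1[1, 1, 1, ] <- centred_sinusoid(f, tt, tr, 1)
  a1[2, 1, 1, ] <- centred_sinusoid(f, tt, tr, 2)
  vol <- volume4d(a1 + 100, diag(4), tr)
  m <- alff_map(vol, 0.01, 0.08)
  expect_equal(m$data[2, 1, 1] / m$data[1, 1, 1], 2, tolerance = 1e-8)

  # white noise against a direct periodogram oracle
  set.seed(20)
  x <- rnorm(tt)
  vol2 <- volume4d(array(x, dim = c(1, 1, 1, tt)), diag(4), tr)
  m2 <- alff_map(vol2, 0.01, 0.08)
  npad <- good_fft_length(tt)
  ft <- fft(c(x - mean(x), numeric(npad - tt)))
  freqs <- seq_len(npad %/% 2) / (npad * tr)
  amp <- Mod(ft[seq_len(npad %/% 2) + 1]) / sqrt(npad)
  oracle <- mean(amp[freqs >= 0.01 & freqs <= 0.08])
  expect_equal(m2$data[1, 1, 1], oracle, tolerance = 1e-10)
})

test_that("ALFF is invariant to adding a constant; errors without in-band bins", {
  vol <- random_vol4d(c(3, 3, 1, 64), seed = 21)
  shifted <- volume4d(vol$data + 500, vol$affine, vol$tr)
  expect_equal(alff_map(vol)$data, alff_map(shifted)$data, tolerance = 1e-9)
  expect_error(alff_map(vol, 0.2491, 0.2499), "resolution")
  expect_error(alff_map(vol, 0.01, 0.3), "Nyquist")
})

test_that("fALFF: band-limited signal near 1, out-of-band near 0, ratio oracle", {
  tt <- 160; tr <- 2
  npad <- good_fft_length(tt)
  fin <- 16 / (npad * tr)                        # exact bin inside the band
  fout <- 64 / (npad * tr)                       # 0.2 Hz
  mk <- function(x) volume4d(array(x, dim = c(1, 1, 1, tt)), diag(4), tr)
  pure <- falff_map(mk(100 + centred_sinusoid(fin, tt, tr)), 0.01, 0.08)
  expect_gte(pure$data[1, 1, 1], 0.99)
  off <- falff_map(mk(100 + centred_sinusoid(fout, tt, tr)), 0.01, 0.08)
  expect_lte(off$data[1, 1, 1], 0.01)

  set.seed(22)
  x <- rnorm(tt)
  got <- falff_map(mk(x), 0.01, 0.08)$data[1, 1, 1]
  ft <- fft(c(x - mean(x), numeric(npad - tt)))
  amp <- Mod(ft[seq_len(npad %/% 2) + 1]) / sqrt(npad)
  freqs <- seq_len(npad %/% 2) / (npad * tr)
  oracle <- sum(amp[freqs >= 0.01 & freqs <= 0.08]) / sum(amp)
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_true(got >= 0 && got <= 1)

  const <- falff_map(mk(rep(3, tt)), 0.01, 0.08)
  expect_equal(const$data[1, 1, 1], 0)
  expect_equal(const$qc$zero_amplitude_voxels, 1L)
})

test_that("mask-mean standardization yields in-mask mean 1", {
  affine <- diag(4)
  uni <- volume3d(array(5, dim = c(3, 3, 3)), affine)
  mask <- brain_mask(array(TRUE, dim = c(3, 3, 3)), affine)
  expect_equal(standardize_by_mask_mean(uni, mask)$data,
               array(1, dim = c(3, 3, 3)))

  set.seed(23)
  m <- volume3d(array(runif(27, 1, 9), dim = c(3, 3, 3)), affine)
  s <- standardize_by_mask_mean(m, mask)
  expect_equal(mean(s$data[mask$data]), 1, tolerance = 1e-12)

  two <- array(0, dim = c(3, 3, 3)); two[1, 1, 1] <- 2; two[2, 1, 1] <- 4
  msk <- array(FALSE, dim = c(3, 3, 3)); msk[1:2, 1, 1] <- TRUE
  got <- standardize_by_mask_mean(volume3d(two, affine),
                                  brain_mask(msk, affine))
  expect_equal(got$data[1:2, 1, 1], c(2 / 3, 4 / 3), tolerance = 1e-12)

  zero <- volume3d(array(0, dim = c(3, 3, 3)), affine)
  expect_error(standardize_by_mask_mean(zero, mask), "mean is zero")
})

test_that("power spectrum: dominant bin, trend leakage, Parseval identity", {
  tr <- 2; tt <- 128
  f <- 16 / (tt * tr)
  x <- centred_sinusoid(f, tt, tr, 3)
  ps <- power_spectrum(x, tr)
  expect_equal(ps$frequency[which.max(ps$power)], f, tolerance = 1e-12)

  set.seed(24)
  drifty <- 5 * seq_len(tt) / tt + rnorm(tt, sd = 0.2)
  raw <- power_spectrum(drifty, tr, detrend_first = FALSE)
  det <- power_spectrum(drifty, tr, detrend_first = TRUE)
  lowest <- which(raw$frequency > 0)[1]
  expect_lt(det$power[lowest], raw$power[lowest])

  y <- rnorm(100)                               # pads to 100 (5-smooth)
  psy <- power_spectrum(y, tr)
  expect_equal(sum(psy$power), sum((y - mean(y))^2), tolerance = 1e-8)
})
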