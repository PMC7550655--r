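test_that("addNoise respects the noise model contract", {
  s <- c(0, 10, 100, 1000)
  expect_identical(addNoise(s, noiseSpec("none", 0)), s)
  expect_identical(addNoise(s, noiseSpec("rician", 0)), s)
  expect_error(addNoise(c(-1, 2), noiseSpec("rician", 5)), "non-negative")

  # reproducible for a fixed seed
  n1 <- addNoise(s, noiseSpec("rician", 5, seed = 42L))
  n2 <- addNoise(s, noiseSpec("rician", 5, seed = 42L))
  expect_identical(n1, n2)
})

test_that("Rician noise has the Rayleigh floor and the high-SNR limit", {
  set.seed(11)
  sigma <- 3
  draws <- addNoise(rep(0, 1e5), noiseSpec("rician", sigma))
  expect_lt(abs(mean(draws) - sigma * sqrt(pi / 2)) / (sigma * sqrt(pi / 2)),
            0.01)
  expect_lt(abs(var(draws) - (2 - pi / 2) * sigma^2) / ((2 - pi / 2) * sigma^2),
            0.02)

  # s/sigma = 50 (Gaussian limit): sample mean within Monte-Carlo error of s
  # plus the first-order Rician bias sigma^2 / (2 s)
  s <- 150; sigma <- 3; n <- 1e5
  hs <- addNoise(rep(s, n), noiseSpec("rician", sigma))
  expect_lt(abs(mean(hs) - s), 3.5 * sigma / sqrt(n) + sigma^2 / (2 * s))
})

test_that("noiseless phantom volumes equal the forward model exactly", {
  spec <- small_phantom(tumor = constant_region())
  prot <- defaultDiffusionProtocol()
  ph <- generateIvimVolume(spec, prot, no_noise(), seed = 1)
  expect_identical(dim(ph$volume), c(10L, 10L, 6L, 13L))
  want <- ivimSignal(base_tumor_truth(), prot)
  i <- which(ph$mask, arr.ind = TRUE)[1L, ]
  expect_equal(ph$volume[i[1L], i[2L], i[3L], ], want, tolerance = 1e-12)

  gprot <- defaultRelaxometryProtocol()
  gv <- generateGreVolume(spec, gprot, no_noise(), seed = 1)
  j <- which(gv$mask)
  mat <- matrix(gv$volume, nrow = prod(dim(gv$mask)))
  # ln(signal) exactly affine in TE for every voxel
  x <- echoTimes(gprot) / 1000
  for (v in j[c(1L, length(j) %/% 2L, length(j))]) {
    r <- lm(log(mat[v, ]) ~ x)
    expect_lt(max(abs(residuals(r))), 1e-10)
  }
})

test_that("generators are pure functions of (spec, protocol, noise, seed)", {
  spec <- small_phantom()
  prot <- defaultDiffusionProtocol()
  a <- generateIvimVolume(spec, prot, noiseSpec("rician", 20), seed = 9)
  b <- generateIvimVolume(spec, prot, noiseSpec("rician", 20), seed = 9)
  expect_identical(a$volume, b$volume)
  expect_identical(a$truth, b$truth)
  c <- generateIvimVolume(spec, prot, noiseSpec("rician", 20), seed = 10)
  expect_false(identical(a$volume, c$volume))
})

test_that("mask matches a brute-force voxel-by-voxel ellipsoid test", {
  spec <- phantomSpec(grid = c(9L, 7L, 5L), center = c(4, 3, 2),
                      semi_axes = c(3.2, 2.1, 1.6))
  mask <- ellipsoidMask(spec)
  count <- 0L
  for (i in 0:8) for (j in 0:6) for (k in 0:4) {
    inside <- (i - 4)^2 / 3.2^2 + (j - 3)^2 / 2.1^2 + (k - 2)^2 / 1.6^2 <= 1
    expect_identical(mask[i + 1L, j + 1L, k + 1L], inside)
    count <- count + inside
  }
  expect_identical(sum(mask), count)
  expect_error(phantomSpec(semi_axes = c(0, 3, 2)), "positive|fit")
  expect_error(phantomSpec(grid = c(6L, 6L, 6L), semi_axes = c(6, 2, 2)),
               "fit")
})

test_that("truth maps satisfy the tissue invariants and target the region means", {
  spec <- small_phantom()
  ph <- generateIvimVolume(spec, defaultDiffusionProtocol(), no_noise(),
                           seed = 3)
  idx <- which(ph$mask)
  expect_true(all(ph$truth$D[idx] > 0))
  expect_true(all(ph$truth$Dstar[idx] > ph$truth$D[idx]))
  expect_true(all(ph$truth$f[idx] >= 0 & ph$truth$f[idx] <= 1))
  # sample mean of the truth field close to the design mean (SE-scaled)
  n <- length(idx)
  se <- 0.024e-3 / sqrt(n)
  expect_lt(abs(mean(ph$truth$D[idx]) - 0.556e-3), 4 * se)
})

test_that("generateStudy has the designed cardinality and cell structure", {
  des <- studyDesign()
  rec <- generateStudy(des, seed = 5)
  expect_setequal(unique(rec$group), c("A", "B", "C", "D"))
  # one record per animal x timepoint after widening
  wide <- widenStudy(rec)
  expect_identical(nrow(wide), 4L * 4L * 8L)
  # pathology drawn only at the final time point
  expect_identical(sort(unique(rec$timepoint[rec$quantity == "PTEN"])),
                   "week3")
  # SD = 0 design reproduces the cell means exactly
  ct <- referenceCellTargets()
  ct$sd <- 0
  des0 <- studyDesign(cell_targets = ct)
  rec0 <- generateStudy(des0, seed = 1)
  cells <- longitudinalSummary(rec0)
  expect_equal(cells$sd, rep(0, nrow(cells)))
  merged <- merge(cells, ct, by = c("quantity", "group", "timepoint"))
  expect_equal(merged$mean.x, merged$mean.y, tolerance = 1e-12)
})

test_that("replicated studies concentrate around the table targets", {
  des <- studyDesign()
  set.seed(123)
  means <- replicate(200, {
    rec <- generateStudy(des, seed = sample.int(1e6, 1))
    v <- rec$value[rec$quantity == "volume" & rec$group == "A" &
                   rec$timepoint == "week3"]
    mean(v)
  })
  # grand mean within 3 SE of the week-3 control volume target 1039.8
  se <- 93.9 / sqrt(8 * 200)
  expect_lt(abs(mean(means) - 1039.8), 3 * se)
})

test_that("unknown cells and noise models are rejected by name", {
  des <- studyDesign()
  ct <- des@cell_targets
  ct$group[1L] <- "Z"
  expect_error(generateStudy(studyDesign(cell_targets = ct)), "Z")
  expect_error(noiseSpec("poisson", 3), "arg")
})
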