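test_that("SUV conversion is the dose/weight fixed point and is linear", {
  act <- volume3d(array(5.18, c(4, 4, 4)), modality = "PET-activity")
  # 70 kg patient dosed at 5.18 MBq/kg: uniform 5.18 kBq/mL is SUV 1.0
  suv <- suv_convert(act, dose_mbq = 5.18 * 70, weight_kg = 70)
  expect_true(all(abs(suv$data - 1) < 1e-12))
  expect_equal(suv$modality, "PET-SUV")

  act2 <- act; act2$data <- act$data * 2
  suv2 <- suv_convert(act2, dose_mbq = 5.18 * 70, weight_kg = 70)
  expect_equal(suv2$data, 2 * suv$data)
  # inverse-linear in dose
  suv_half <- suv_convert(act, dose_mbq = 5.18 * 35, weight_kg = 70)
  expect_equal(suv_half$data, 2 * suv$data)

  expect_error(suv_convert(act, dose_mbq = 0, weight_kg = 70), "dose")
  expect_error(suv_convert(suv, 10, 70), "PET-activity")
})

test_that("normalization clips to the documented ranges", {
  ct <- volume3d(array(c(-2000, 0, 500, 2000), c(4, 4, 4)) * 1, modality = "CT-HU")
  pet <- volume3d(array(runif(64, 0, 8), c(4, 4, 4)), modality = "PET-SUV")
  out <- normalize_and_resample(pet, ct, target_spacing = 1)
  expect_equal(min(out$ct$data), 0)
  expect_equal(max(out$ct$data), 1)
  expect_true(all(out$pet$data >= 0 & out$pet$data <= 1))
})

test_that("resampling at the native spacing is the identity", {
  set.seed(1)
  v <- volume3d(array(rnorm(6 * 5 * 4), c(6, 5, 4)), spacing = c(2, 2, 2))
  r <- resample_volume(v, c(2, 2, 2))
  expect_equal(r$data, v$data, tolerance = 1e-10)

  const <- volume3d(array(3, c(8, 8, 8)), spacing = c(1, 1, 1))
  half <- resample_volume(const, 2)
  expect_equal(dim(half$data), c(4L, 4L, 4L))
  expect_true(all(abs(half$data - 3) < 1e-12))

  thin <- volume3d(array(0, c(1, 8, 8)))
  expect_error(resample_volume(thin, 2), "degenerate")
})

test_that("the percent-of-SUVmax VOI follows the hand-evaluated rule", {
  a <- array(1, c(5, 5, 5)); a[3, 3, 3] <- 10
  a[c(2, 4), 3, 3] <- 5; a[3, c(2, 4), 3] <- 5; a[3, 3, c(2, 4)] <- 5
  pet <- volume3d(a, modality = "PET-SUV")
  voi <- threshold_voi(pet, frac = 0.41)
  expect_equal(voi$threshold, 4.1)
  expect_equal(sum(voi$mask), 7L)          # centre + six 5-valued neighbours
  expect_true(voi$mask[3, 3, 3])

  only_max <- threshold_voi(pet, frac = 1.0)
  expect_equal(sum(only_max$mask), 1L)

  zero <- volume3d(array(0, c(3, 3, 3)), modality = "PET-SUV")
  expect_error(threshold_voi(zero), "no uptake")
})

test_that("VOI masks shrink monotonically as the threshold fraction grows", {
  ph <- generate_phantom(c(16, 16, 16),
                         list(list(center = c(8, 8, 8), radius = 8, peak = 12)))
  prev <- NULL
  for (f in c(0.3, 0.41, 0.6, 0.8)) {
    m <- threshold_voi(ph$pet, frac = f)$mask
    if (!is.null(prev)) expect_true(all(!m | prev))  # m subset of prev
    prev <- m
  }
})

test_that("a second lesion below threshold stays out of the VOI", {
  ph <- generate_phantom(c(24, 24, 24),
                         list(list(center = c(7, 7, 7), radius = 6, peak = 10),
                              list(center = c(18, 18, 18), radius = 6, peak = 6)))
  voi <- threshold_voi(ph$pet,
                       seed_box = list(z = c(1, 12), y = c(1, 12), x = c(1, 12)))
  expect_equal(voi$suvmax_seed, 10)
  expect_false(voi$mask[18, 18, 18])       # 6 > 4.1 but disconnected
  expect_true(voi$mask[7, 7, 7])
})

test_that("metabolic metrics follow their definitions and are additive", {
  a <- array(0, c(10, 10, 10))
  a[1:4, 1:5, 1:5] <- 2                     # 100 voxels of SUV 2
  pet <- volume3d(a, spacing = c(2, 2, 2), modality = "PET-SUV")
  m <- metabolic_metrics(pet, a > 0)
  expect_equal(m$tmtv_cm3, 100 * 0.008)     # 0.8 cm^3
  expect_equal(m$tlg, m$suvmean * m$tmtv_cm3)
  expect_equal(m$suvmax, 2)

  # additivity over two disjoint components
  b <- array(0, c(10, 10, 10))
  b[1:4, 1:5, 1:5] <- 5                     # comp 1: TMTV 0.8, TLG 4.0
  b[8:9, 1:5, 1:5] <- 3                     # comp 2: TMTV 0.4, TLG 1.2
  petb <- volume3d(b, spacing = c(2, 2, 2), modality = "PET-SUV")
  m1 <- metabolic_metrics(petb, (b == 5))
  m2 <- metabolic_metrics(petb, (b == 3))
  mall <- metabolic_metrics(petb, (b > 0))
  expect_equal(mall$tmtv_cm3, m1$tmtv_cm3 + m2$tmtv_cm3)
  expect_equal(mall$tlg, m1$tlg + m2$tlg)

  expect_error(metabolic_metrics(pet, a > 99), "empty")
})

test_that("NMI registration recovers a known translation", {
  set.seed(5)
  base <- generate_phantom(c(20, 20, 20),
                           list(list(center = c(8, 10, 12), radius = 8, peak = 9),
                                list(center = c(14, 6, 6), radius = 6, peak = 5)),
                           spacing = c(2, 2, 2))
  fixed <- base$pet
  fixed$data <- fixed$data + array(rnorm(length(fixed$data), sd = 0.02),
                                   dim(fixed$data))
  # moving = fixed shifted by a known world translation
  shift <- c(6, -4, 2)
  moving <- apply_transform(fixed, fixed,
                            rigid_transform(translation = -shift), fill = NA)
  moving$valid <- NULL

  self_nmi <- ns$nmi_score(fixed$data, fixed$data)
  noise <- array(rnorm(length(fixed$data)), dim(fixed$data))
  expect_gt(self_nmi, ns$nmi_score(fixed$data, noise))

  tr <- rigid_register(moving, fixed, dof = "translation", seed = 2)
  expect_lt(max(abs(tr$translation - shift)), 1)  # within half a 2 mm voxel
  expect_gte(attr(tr, "nmi"), attr(tr, "nmi_identity"))
})

test_that("volumes survive a NIfTI round trip", {
  set.seed(8)
  v <- volume3d(array(rnorm(4 * 5 * 6), c(4, 5, 6)), spacing = c(2, 1.5, 1),
                modality = "PET-SUV")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  back <- read_volume(f, modality = "PET-SUV")
  expect_equal(back$data, v$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$spacing, v$spacing, tolerance = 1e-6)
})
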