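test_that("report segmentation tracks sections and drops boilerplate", {
  b <- segment_report("Impression: Lesion present. No recurrence.")
  expect_equal(nrow(b), 2L)
  expect_equal(b$section, c("Impression", "Impression"))

  plain <- segment_report("One sentence. Another one.")
  expect_equal(plain$section, c("body", "body"))

  bp <- segment_report("Findings: Mass in spleen.\nElectronically signed by Dr X\nImpression: Stable.")
  expect_false(any(grepl("signed", bp$text, ignore.case = TRUE)))
  expect_equal(bp$section, c("Findings", "Impression"))

  expect_error(segment_report(""), "non-empty")
})

test_that("negation tagging respects word boundaries", {
  b <- segment_report(paste("No evidence of splenomegaly.",
                            "Splenomegaly is present.",
                            "The nostril appears normal."))
  b <- tag_negation(b)
  expect_equal(b$negated, c(TRUE, FALSE, FALSE))
})

test_that("radiomics handles degenerate and hand-computable textures", {
  const <- matrix(5, 6, 6)
  f <- radiomics_features(const, matrix(TRUE, 6, 6), bin_count = 8)
  expect_equal(unname(f["fo_variance"]), 0)
  expect_equal(unname(f["fo_entropy"]), 0)
  expect_equal(unname(f["glcm_asm"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)

  # checkerboard of two levels: horizontal pairs always differ by one level
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2 + 1)
  fcb <- radiomics_features(cb, matrix(TRUE, 6, 6), bin_count = 2,
                            offsets = list(c(0, 1)))
  expect_equal(unname(fcb["glcm_contrast"]), 1)

  fs <- radiomics_features(matrix(3, 2, 2), rbind(c(TRUE, FALSE), c(FALSE, FALSE)))
  expect_equal(unname(fs["glcm_entropy"]), 0)
  expect_equal(unname(fs["glcm_correlation"]), 0)
  expect_true(all(is.finite(fs)))
})

test_that("quantized texture features are invariant to intensity scaling", {
  set.seed(3)
  img <- matrix(rexp(64), 8, 8)
  mask <- matrix(TRUE, 8, 8)
  f1 <- radiomics_features(img, mask, bin_count = 16)
  f2 <- radiomics_features(img * 37.5, mask, bin_count = 16)
  glcm <- grep("^glcm|^fo_entropy", names(f1))
  expect_equal(f1[glcm], f2[glcm], tolerance = 1e-12)
})

test_that("radiomics vectors are fixed-length, named and finite", {
  set.seed(4)
  for (k in 1:5) {
    img <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
    mask <- array(runif(120) > 0.4, c(4, 5, 6))
    if (!any(mask)) next
    f <- radiomics_features(img, mask)
    expect_length(f, 19L)
    expect_true(all(is.finite(f)))
    expect_identical(names(f), ns$radiomics_feature_names())
  }
})

test_that("projection layers are affine", {
  set.seed(6)
  pl <- projection_layer(8, 5, seed = 2)
  x <- matrix(rnorm(8), 1, 8)
  d1 <- apply_projection(2 * x, pl) - apply_projection(x, pl)
  expect_equal(as.vector(d1), as.vector(x %*% pl$W), tolerance = 1e-12)
  id <- projection_layer(4, 4, identity = TRUE)
  z <- matrix(rnorm(12), 3, 4)
  expect_equal(apply_projection(z, id), z)
  expect_error(projection_layer(4, 5, identity = TRUE), "identity")
})

test_that("a full patient yields exactly seven well-formed groups", {
  ph <- generate_phantom(c(12, 12, 12),
                         list(list(center = c(6, 6, 6), radius = 6, peak = 8)))
  voi <- threshold_voi(ph$pet)
  sent <- tag_negation(segment_report(
    "Findings: FDG-avid mass. No splenomegaly. Impression: Lymphoma involvement."))
  groups <- build_patient_groups(ph$pet, ph$ct, voi, sent, embed_dim = 12,
                                 seed = 5)
  expect_length(groups, 7L)
  expect_identical(vapply(groups, function(g) g$group_id, integer(1)), 1:7)
  # vision groups: one token per axial slice
  for (g in 1:4) expect_equal(nrow(groups[[g]]$tokens), 12L)
  # text group: one token per sentence
  expect_equal(nrow(groups[[7]]$tokens), nrow(sent))
  # all at the shared dimension
  for (g in groups) expect_equal(ncol(g$tokens), 12L)
  # deterministic
  groups2 <- build_patient_groups(ph$pet, ph$ct, voi, sent, embed_dim = 12,
                                  seed = 5)
  expect_identical(groups, groups2)
})

test_that("identity encoders plus identity projection pass features through", {
  # native dim = embed dim = 19 (the radiomics vector length) so identity
  # projections are admissible for every group
  ph <- generate_phantom(c(6, 6, 6),
                         list(list(center = c(3, 3, 3), radius = 4, peak = 8)))
  voi <- threshold_voi(ph$pet)
  sent <- segment_report("Impression: mass.")
  sent$negated <- FALSE
  picker <- encoder_plugin("first-voxels", 19L,
                           function(slice) as.numeric(slice)[1:19])
  txt <- encoder_plugin("len", 19L, function(s) rep(nchar(s), 19))
  enc <- list(vision_semantic_pet = picker, vision_semantic_ct = picker,
              vision_morphology_pet = picker, vision_morphology_ct = picker,
              text = txt)
  groups_id <- build_patient_groups(ph$pet, ph$ct, voi, sent, embed_dim = 19,
                                    encoders = enc,
                                    identity_projections = TRUE, seed = 1)
  expect_equal(groups_id[[1]]$tokens[2, ],
               as.numeric(ph$pet$data[2, , ])[1:19])
  expect_equal(groups_id[[7]]$tokens[1, ], rep(nchar(sent$text[1]), 19))
  # radiomics tokens equal the raw feature vector under the identity map
  expect_equal(groups_id[[5]]$tokens[1, ],
               as.numeric(radiomics_features(ph$pet$data, voi$mask,
                                             spacing = ph$pet$spacing)))
})

test_that("sentence bundles round-trip through JSONL", {
  b <- tag_negation(segment_report("Findings: Mass. No effusion."))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_sentences_jsonl(b, f)
  back <- read_sentences_jsonl(f)
  expect_equal(back$text, b$text)
  expect_equal(back$negated, b$negated)
})
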