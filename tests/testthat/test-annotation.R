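test_that("ppm error is signed relative deviation", {
  expect_equal(ppm_error(823.3022, 823.301906), 0.357, tolerance = 0.01)
  expect_equal(ppm_error(500, 500), 0)
  expect_equal(ppm_error(927.4931, 927.495889), -3.01, tolerance = 0.01)
})

test_that("worked flavonoid ion is matched to its library compound", {
  lib <- tibble::tibble(compound = c("baohuoside VI", "akebiasaponin D"),
                        formula = c("C39H50O19", "C47H76O18"),
                        herb = c("h1", "h2"))
  feats <- tibble::tibble(mz = c(823.3022, 830.0000, 927.4931),
                          polarity = c("+", "+", "-"))
  ann <- match_features(feats, lib)
  hit1 <- ann[ann$feature_id == 1 & ann$adduct == "[M+H]+", ]
  expect_identical(hit1$compound, "baohuoside VI")
  expect_equal(hit1$error_mda, 0.294, tolerance = 0.01)
  expect_false(2 %in% ann$feature_id) # 830 is outside every tolerance
  hit3 <- ann[ann$feature_id == 3 & ann$adduct == "[M-H]-", ]
  expect_identical(hit3$compound, "akebiasaponin D")
  expect_lt(abs(hit3$error_ppm), 10)
})

test_that("tolerance is an inclusive disjunction of 5 mDa and 10 ppm", {
  lib <- tibble::tibble(compound = "small", formula = "C4H4O4") # M+H ~ 117
  theo <- adduct_mz(monoisotopic_mass("C4H4O4"), "[M+H]+")
  # exactly 5.000 mDa off: ~43 ppm, admitted by the inclusive mDa bound
  ann <- match_features(tibble::tibble(mz = theo + 0.005, polarity = "+"), lib)
  expect_true("[M+H]+" %in% ann$adduct)
  # just beyond both bounds: rejected
  ann2 <- match_features(tibble::tibble(mz = theo + 0.0051, polarity = "+"), lib)
  expect_false("[M+H]+" %in% ann2$adduct)
  # heavy dimer: 10 mDa off but only ~6 ppm, admitted by the ppm bound
  lib2 <- tibble::tibble(compound = "big", formula = "C39H50O19")
  theo2 <- adduct_mz(monoisotopic_mass("C39H50O19"), "[2M+H]+")
  ann3 <- match_features(tibble::tibble(mz = theo2 + 0.010, polarity = "+"), lib2)
  expect_true("[2M+H]+" %in% ann3$adduct)
})

test_that("empty library warns and returns an empty annotation table", {
  expect_warning(
    ann <- match_features(tibble::tibble(mz = 500, polarity = "+"),
                          tibble::tibble(compound = character(0),
                                         formula = character(0))),
    "empty"
  )
  expect_identical(nrow(ann), 0L)
})

test_that("every emitted match satisfies the tolerance invariant", {
  for (s in 1:3) {
    g <- gen_library_and_features(tiny_config(seed = s, mz_sigma_mda = 3))
    ann <- match_features(g$features, g$library)
    expect_true(all(abs(ann$error_mda) <= 5 | abs(ann$error_ppm) <= 10))
    # sorted by absolute error, compound as tie-breaker
    expect_true(!is.unsorted(abs(ann$error_mda)))
  }
})

test_that("matching is invariant under library permutation", {
  g <- gen_library_and_features(tiny_config(seed = 4))
  ann1 <- match_features(g$features, g$library)
  set.seed(1)
  ann2 <- match_features(g$features, g$library[sample(nrow(g$library)), ])
  expect_equal(as.data.frame(ann1), as.data.frame(ann2))
})

test_that("fragments of the worked spectra are assigned their losses", {
  mh <- adduct_mz(monoisotopic_mass("C39H50O19"), "[M+H]+")
  fr <- annotate_fragments(mh, c(677.2438, 531.1860, 369.1328, 500.0000))
  expect_identical(fr$loss_label[1], "-rha")
  expect_identical(fr$loss_label[2], "-2rha")
  expect_identical(fr$loss_label[3], "-2rha-Glc")
  expect_true(is.na(fr$loss_label[4]))
  expect_true(all(abs(fr$error_mda[1:3]) <= 5))

  mneg <- adduct_mz(monoisotopic_mass("C47H76O18"), "[M-H]-")
  fr2 <- annotate_fragments(mneg, 603.3904)
  expect_identical(fr2$loss_label, "-2Glc")
  expect_lt(abs(fr2$error_ppm), 10)
})

test_that("loss search respects the multiset caps", {
  # a loss of 4x rha cannot be explained when each loss is capped at 3
  mh <- 1000
  fr <- annotate_fragments(mh, mh - 4 * 146.0579088,
                           losses = neutral_losses()[1, ],
                           max_losses = 4L, max_per_loss = 3L)
  expect_true(is.na(fr$loss_label))
  fr2 <- annotate_fragments(mh, mh - 4 * 146.0579088,
                            losses = neutral_losses()[1, ],
                            max_losses = 4L, max_per_loss = 4L)
  expect_identical(fr2$loss_label, "-4rha")
})
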