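test_that("spectra are per-class fractions of single-label records", {
  sch <- seven_class_scheme()
  tab <- single_label_table(stats::setNames(
    rep(c("nucleus", "cytoplasm"), each = 5), sprintf("P%02d", 1:10)))
  sp <- compute_spectrum(tab, sch, "human")
  expect_equal(unname(sp$values), c(0, .5, .5, 0, 0, 0, 0))
  expect_equal(sp$n_proteins, 10L)
  expect_false(sp$corrected)

  counts <- c(3, 6, 6, 3, 1, 1, 1)
  tab21 <- single_label_table(stats::setNames(
    rep(sch$classes, counts), sprintf("Q%02d", 1:21)))
  expect_equal(unname(compute_spectrum(tab21, sch)$values), counts / 21)

  one <- single_label_table(c(A = "secreted", B = "secreted"))
  expect_equal(unname(compute_spectrum(one, sch)$values),
               c(1, 0, 0, 0, 0, 0, 0))

  expect_error(compute_spectrum(annotation_table(character(), list()), sch),
               "empty")
  multi <- annotation_table("P1", list(c("nucleus", "cytoplasm")), "x")
  expect_error(compute_spectrum(multi, sch), "single-label")
})

test_that("confusion matrices tally predicted x observed over shared proteins", {
  sch <- mini_scheme()
  pred <- single_label_table(c(P1 = "nucleus", P2 = "nucleus",
                               P3 = "cytoplasm", P4 = "cytoplasm",
                               extra = "nucleus"), "pred")
  obs <- single_label_table(c(P1 = "nucleus", P2 = "cytoplasm",
                              P3 = "cytoplasm", P4 = "cytoplasm"), "obs")
  m <- build_confusion(pred, obs, sch)
  expect_equal(unclass(m)[, ], matrix(c(1L, 0L, 1L, 2L), 2,
                                      dimnames = dimnames(m))[, ])
  # perfect predictor -> diagonal
  md <- build_confusion(obs, obs, sch)
  expect_equal(unname(diag(md)), c(1L, 3L))
  expect_equal(sum(md) - sum(diag(md)), 0L)
  expect_error(build_confusion(pred, single_label_table(c(Z = "nucleus")), sch),
               "no shared")
})

test_that("row normalization gives M'(p,o) = M(p,o)/row sum, identity for empty rows", {
  sch <- mini_scheme()
  pred <- single_label_table(c(P1 = "nucleus", P2 = "nucleus",
                               P3 = "cytoplasm", P4 = "cytoplasm"), "pred")
  obs <- single_label_table(c(P1 = "nucleus", P2 = "cytoplasm",
                              P3 = "cytoplasm", P4 = "cytoplasm"), "obs")
  mp <- row_normalize(build_confusion(pred, obs, sch))
  expect_equal(unname(mp[1, ]), c(0.5, 0.5))
  expect_equal(unname(mp[2, ]), c(0, 1))

  # a class never predicted -> identity row with a warning
  pred2 <- single_label_table(c(P1 = "nucleus", P2 = "nucleus",
                                P3 = "nucleus", P4 = "nucleus"), "pred")
  m2 <- build_confusion(pred2, obs, sch)
  expect_warning(mp2 <- row_normalize(m2), "never predicted")
  expect_equal(unname(mp2[2, ]), c(0, 1))
  expect_equal(rowSums(mp2), stats::setNames(c(1, 1), sch$classes))
})

test_that("the correction applies c_x = sum_i M'(i,x) p_i", {
  sch <- mini_scheme()
  mk_mprime <- function(m) {
    structure(matrix(m, 2, 2, byrow = TRUE,
                     dimnames = list(predicted = sch$classes,
                                     observed = sch$classes)),
              class = c("normalized_confusion", "matrix", "array"))
  }
  p <- location_spectrum(c(0.5, 0.5), sch, "org")
  corr <- correct_spectrum(p, mk_mprime(c(0.8, 0.2, 0.3, 0.7)))
  expect_equal(unname(corr$values), c(0.55, 0.45))
  expect_true(corr$corrected)

  # identity channel leaves the spectrum unchanged
  ident <- mk_mprime(c(1, 0, 0, 1))
  expect_equal(unname(correct_spectrum(p, ident)$values), c(0.5, 0.5))

  # an indicator spectrum picks out a row of M'
  mp <- mk_mprime(c(0.6, 0.4, 0.1, 0.9))
  ind <- location_spectrum(c(1, 0), sch, "org")
  expect_equal(unname(correct_spectrum(ind, mp)$values), unname(mp[1, ]))

  expect_error(correct_spectrum(corr, mp), "already corrected")
})

test_that("correction conserves total mass and is linear in the spectrum", {
  sch <- seven_class_scheme()
  k <- 7
  set.seed(11)
  for (i in 1:50) {
    mp <- structure(random_stochastic(k),
                    class = c("normalized_confusion", "matrix", "array"),
                    dimnames = list(predicted = sch$classes,
                                    observed = sch$classes))
    p1 <- random_simplex(k); p2 <- random_simplex(k)
    c1 <- correct_spectrum(location_spectrum(p1, sch), mp)
    c2 <- correct_spectrum(location_spectrum(p2, sch), mp)
    expect_lt(abs(sum(c1$values) - 1), 1e-9)
    # linearity: correcting a mixture equals mixing the corrections
    w <- stats::runif(1)
    mix <- correct_spectrum(location_spectrum(w * p1 + (1 - w) * p2, sch), mp)
    expect_equal(unname(mix$values),
                 w * unname(c1$values) + (1 - w) * unname(c2$values),
                 tolerance = 1e-12)
  }
})

test_that("spectra and confusion matrices round-trip through TSV", {
  sch <- seven_class_scheme()
  sp <- location_spectrum(c(.12, .24, .22, .14, .10, .10, .08), sch,
                          "human", n_proteins = 500L)
  path <- tempfile(fileext = ".tsv")
  write_spectra(list(sp), path)
  back <- read_spectra(path, sch)[[1]]
  expect_equal(back$values, sp$values, tolerance = 1e-12)
  expect_equal(back$n_proteins, 500L)

  pred <- single_label_table(stats::setNames(
    sample(sch$classes, 60, replace = TRUE), sprintf("P%02d", 1:60)), "pred")
  obs <- single_label_table(stats::setNames(
    sample(sch$classes, 60, replace = TRUE), sprintf("P%02d", 1:60)), "obs")
  m <- build_confusion(pred, obs, sch)
  cpath <- tempfile(fileext = ".tsv")
  write_confusion(m, cpath)
  m2 <- read_confusion(cpath, sch)
  expect_equal(unclass(m2)[, ], unclass(m)[, ])
  rpath <- tempfile(fileext = ".tsv")
  mp <- suppressWarnings(row_normalize(m))
  write_confusion(mp, rpath)
  mp2 <- read_confusion(rpath, sch, ratios = TRUE)
  expect_equal(unclass(mp2)[, ], unclass(mp)[, ], tolerance = 1e-12)
})
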