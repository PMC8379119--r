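test_that("annotation TSVs parse into records with split, trimmed label sets", {
  path <- tmp_tsv(c("protein_id\tsource\treliability\tlabels",
                    "P1\tHPA\tValidated\tcytoplasm; mitochondria",
                    "P2\tHPA\t\tnucleus"))
  tab <- read_annotation_table(path)
  expect_s3_class(tab, "annotation_table")
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$labels[[1]], c("cytoplasm", "mitochondria"))
  expect_true(is.na(tab$reliability[2]))

  empty <- read_annotation_table(tmp_tsv("protein_id\tsource\treliability\tlabels"))
  expect_equal(nrow(empty), 0L)

  expect_error(read_annotation_table(tempfile()), "not found")
  expect_error(
    read_annotation_table(tmp_tsv(c("protein_id\tsource\treliability\tlabels",
                                    "P1\tHPA\tValidated\tnucleus",
                                    "P1\tHPA\tValidated\tcytoplasm"))),
    "P1, HPA")
  expect_error(
    read_annotation_table(tmp_tsv(c("protein_id\tsource\treliability\tlabels",
                                    "P1\tHPA\tValidated\t"))),
    "empty labels")
})

test_that("annotation tables round-trip through write/read", {
  tab <- annotation_table(c("P1", "P2"),
                          list(c("nucleus", "cytoplasm"), "secreted"),
                          source = c("db", "pred"),
                          reliability = c("Validated", NA))
  path <- tempfile(fileext = ".tsv")
  write_annotation_table(tab, path)
  back <- read_annotation_table(path)
  expect_equal(back$protein_id, tab$protein_id)
  expect_equal(back$labels, tab$labels)
  expect_equal(back$reliability, tab$reliability)
})

test_that("projection maps synonyms, drops unmappables, removes emptied records", {
  sch <- seven_class_scheme()
  tab <- annotation_table(
    c("P1", "P2", "P3"),
    list("ER membrane", "vesicles", c("nucleoplasm", "vesicles")),
    source = "db")
  out <- project_to_scheme(tab, sch)
  expect_equal(out$protein_id, c("P1", "P3"))
  expect_equal(out$labels[[1]], "endoplasmic reticulum")
  expect_equal(out$labels[[2]], "nucleus")
})

test_that("projection matching is case-insensitive but unknown labels are a hard error", {
  sch <- mini_scheme()
  tab <- annotation_table("P1", list(c("  NUCLEAR ", "Cytosol")), "db")
  out <- project_to_scheme(tab, sch)
  expect_setequal(out$labels[[1]], c("nucleus", "cytoplasm"))
  bad <- annotation_table("P2", list("golgi"), "db")
  expect_error(project_to_scheme(bad, sch), "golgi")
})

test_that("projection and single-label filtering are idempotent and never add records", {
  sch <- seven_class_scheme()
  set.seed(42)
  raw <- c("nucleus", "cytosol", "vesicles", "ER", "golgi",
           "extracellular", "mitochondria", "cell membrane")
  for (i in 1:20) {
    n <- sample(1:12, 1)
    tab <- annotation_table(sprintf("P%02d", seq_len(n)),
                            lapply(seq_len(n), function(.)
                              sample(raw, sample(1:3, 1))),
                            source = "db")
    p1 <- project_to_scheme(tab, sch)
    expect_identical(project_to_scheme(p1, sch), p1)
    expect_lte(nrow(p1), nrow(tab))
    f1 <- filter_single_label(p1)
    expect_identical(filter_single_label(f1), f1)
    expect_lte(nrow(f1), nrow(p1))
    expect_true(all(lengths(f1$labels) == 1L))
  }
})

test_that("single-label filtering keeps exactly the one-label records", {
  tab <- annotation_table(sprintf("P%d", 1:8),
                          c(lapply(1:5, function(i) "nucleus"),
                            lapply(1:3, function(i) c("nucleus", "cytoplasm"))),
                          source = "db")
  kept <- filter_single_label(tab)
  expect_equal(nrow(kept), 5L)
  all_multi <- annotation_table(c("A", "B"),
                                list(c("x", "y"), c("y", "z")), "db")
  expect_equal(nrow(filter_single_label(all_multi)), 0L)
})

test_that("scheme config files round-trip and validate", {
  sch <- seven_class_scheme()
  expect_identical(sch$classes,
                   c("secreted", "nucleus", "cytoplasm", "plasma membrane",
                     "mitochondrion", "endoplasmic reticulum",
                     "Golgi apparatus"))
  path <- tempfile(fileext = ".txt")
  write_scheme(sch, path)
  back <- read_scheme(path)
  expect_identical(back$classes, sch$classes)
  expect_identical(sort(names(back$synonyms)), sort(names(sch$synonyms)))

  expect_error(location_scheme(c("a", "a")), "unique")
  expect_error(location_scheme("a", c(foo = "b")), "not in scheme")
})

test_that("reliability levels merge via the map and unmapped levels fail", {
  tab <- annotation_table(sprintf("P%d", 1:4), rep("nucleus", 4), "HPA",
                          reliability = c("Validated", "Supportive",
                                          "Uncertain", "Unreliable"))
  merged <- merge_reliability_levels(tab)
  expect_equal(merged$reliability,
               c("reliable", "reliable", "speculative", "speculative"))
  ident <- merge_reliability_levels(tab, stats::setNames(
    c("Validated", "Supportive", "Uncertain", "Unreliable"),
    c("Validated", "Supportive", "Uncertain", "Unreliable")))
  expect_identical(ident, tab)
  expect_error(merge_reliability_levels(tab, c(Validated = "reliable")),
               "Supportive")
})
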