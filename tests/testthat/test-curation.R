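test_that("pIC50 transform follows -log10 of the molar concentration", {
  expect_equal(compute_pic50(1, "uM"), 6.0)
  expect_equal(compute_pic50(10, "nM"), 8.0)
  expect_equal(compute_pic50(100, "nM"), 7.0)
  expect_equal(compute_pic50(50, "nM"), 7.30103, tolerance = 1e-6)
  # round trip over the whole assay-relevant range
  x <- seq(0, 12, by = 0.25)
  expect_equal(compute_pic50(10^(-x), "M"), x)
  expect_error(compute_pic50(0, "nM"), "positive")
  expect_error(compute_pic50(-5, "uM"), "positive")
})

test_that("potency classes bin pIC50 with boundaries in the upper class", {
  cls <- assign_activity_class(c(8.0, 7.0, 6.0, 5.99, 8.7, 6.5))
  expect_equal(as.character(cls),
               c("potent", "active", "intermediate", "inactive", "potent",
                 "intermediate"))
  expect_error(activity_class_scheme(thresholds = c(6, 7, 8)))
  expect_error(activity_class_scheme(labels = c("a", "b")))
})

test_that("salt stripping keeps the largest organic fragment, idempotently", {
  expect_equal(strip_salts_and_canonicalize("CCO.Cl"),
               canonical_smiles("CCO"))
  expect_equal(strip_salts_and_canonicalize("[Na+].CC(=O)[O-]"),
               canonical_smiles("CC(=O)[O-]"))
  expect_equal(strip_salts_and_canonicalize("c1ccccc1"),
               canonical_smiles("c1ccccc1"))
  smis <- fixture_clean()$records$smiles[seq(1, 276, by = 3)]
  once <- strip_salts_and_canonicalize(smis)
  expect_identical(strip_salts_and_canonicalize(once), once)
})

test_that("CSV loading rejects bad rows with reasons and keeps the rest", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,smiles,ic50,ic50_unit",
               "a,c1ccccc1,100,nM",
               "b,CCO,1,uM",
               "c,not_a_smiles,5,nM"), path)
  expect_message(d <- load_dataset(path, format = "csv"), "rejected")
  expect_equal(nrow(d), 2)
  expect_equal(d$pic50, c(7, 6))
  expect_equal(as.character(d$activity_class), c("active", "intermediate"))
  rej <- attr(d, "rejected")
  expect_equal(rej$compound_id, "c")
  expect_match(rej$reason, "SMILES")
})

test_that("duplicate ids and duplicate structures keep the first occurrence", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,smiles,pic50",
               "a,c1ccccc1,8.1",
               "a,CCO,6.1",
               "b,C1=CC=CC=C1,5.0"), path)  # same structure as row 1
  expect_message(d <- load_dataset(path, format = "csv"))
  expect_equal(nrow(d), 1)
  expect_equal(d$compound_id, "a")
  expect_setequal(attr(d, "rejected")$reason,
                  c("duplicate compound_id", "duplicate structure"))
})

test_that("missing columns and empty data raise configuration errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,ic50", "a,5"), path)
  expect_error(load_dataset(path, format = "csv"), "SMILES")
  writeLines(c("compound_id,smiles", "a,CCO"), path)
  expect_error(load_dataset(path, format = "csv"), "IC50 or a pIC50")
  writeLines(c("compound_id,smiles,pic50", "a,not_a_smiles,7"), path)
  expect_error(suppressMessages(load_dataset(path, format = "csv")),
               "empty dataset")
})

test_that("SDF input with pIC50 properties is ingested", {
  path <- withr::local_tempfile(fileext = ".sdf")
  sdf_block <- function(title, smiles, pic50) {
    mol <- ChemmineOB::convertFormat("SMI", "SDF", smiles)
    mol <- sub("^\n", paste0(title, "\n"), mol)
    mol <- sub("\\$\\$\\$\\$\n$", "", mol)
    paste0(mol, ">  <pic50>\n", pic50, "\n\n$$$$\n")
  }
  writeLines(paste0(sdf_block("m1", "c1ccccc1O", 8.2),
                    sdf_block("m2", "CCN", 6.4)), sep = "", path)
  d <- load_dataset(path, format = "sdf")
  expect_equal(nrow(d), 2)
  expect_equal(d$pic50, c(8.2, 6.4))
  expect_equal(as.character(d$activity_class), c("potent", "intermediate"))
})

test_that("oversampling equalizes every class at the majority count", {
  d <- dummy_records(c(A = 4, B = 2, C = 1))
  b <- balance_by_oversampling(d, seed = 1)
  expect_equal(as.vector(table(b$activity_class)), c(4, 4, 4))
  expect_equal(nrow(b), 12)
  expect_true(all(d$compound_id %in% b$compound_id))
  # four classes with majority 112 -> 448 total
  d4 <- dummy_records(c(potent = 112, active = 43, intermediate = 60,
                        inactive = 35))
  expect_equal(nrow(balance_by_oversampling(d4, seed = 42)), 448)
  # already balanced input passes through unchanged
  d0 <- dummy_records(c(A = 3, B = 3))
  expect_identical(balance_by_oversampling(d0, seed = 9), d0)
  expect_identical(balance_by_oversampling(d, seed = 7),
                   balance_by_oversampling(d, seed = 7))
  expect_error(balance_by_oversampling(d[0, ]), "empty")
})

test_that("train/test split is exact, disjoint and reproducible", {
  d <- dummy_records(c(potent = 112, active = 112, intermediate = 112,
                       inactive = 112))
  sp <- split_train_test(d, test_fraction = 0.2, seed = 42)
  expect_equal(nrow(sp$test), 90)
  expect_equal(nrow(sp$train), 358)
  expect_length(intersect(sp$train$compound_id, sp$test$compound_id), 0)
  expect_setequal(c(sp$train$compound_id, sp$test$compound_id),
                  d$compound_id)
  # stratification keeps class balance in the test set
  expect_true(all(abs(table(sp$test$activity_class) - 22.5) <= 0.5))
  sp2 <- split_train_test(d, test_fraction = 0.2, seed = 42)
  expect_identical(sp$test$compound_id, sp2$test$compound_id)
  d10 <- dummy_records(c(A = 5, B = 5))
  sp3 <- split_train_test(d10, test_fraction = 0.5, seed = 1)
  expect_equal(nrow(sp3$test), 5)
  expect_error(split_train_test(d, test_fraction = 1.2), "test_fraction")
  expect_error(split_train_test(d, test_fraction = 0), "test_fraction")
})
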