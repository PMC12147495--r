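test_that("long-format tables group into one sample per material", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(material_id = "m1", measurement = c(10, 20, 30),
                       temp = 900, dose = 1.5),
            path, row.names = FALSE)
  ds <- load_dataset(path)
  expect_length(ds$samples, 1L)
  expect_equal(ds$samples[[1]]$measurements, c(10, 20, 30))
  expect_equal(ds$feature_names, c("temp", "dose"))
})

test_that("a feature varying within a material is a consistency error", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(material_id = "m1", measurement = c(10, 20),
                       temp = c(900, 950)),
            path, row.names = FALSE)
  expect_error(load_dataset(path), class = "bonevar_consistency_error")
  expect_error(load_dataset(withr::local_tempfile(fileext = ".csv")),
               class = "bonevar_input_error")
})

test_that("missing required columns raise a format error", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = "m1", value = 10), path, row.names = FALSE)
  expect_error(load_dataset(path), class = "bonevar_format_error")
})

test_that("write/load round trip preserves ids, features, measurements and spectra", {
  gen <- generate_synthetic_dataset(small_config(seed = 5))
  dir <- withr::local_tempdir()
  write_dataset(gen$dataset, file.path(dir, "materials.csv"),
                spectra_dir = file.path(dir, "spectra"),
                image_dir = file.path(dir, "images"))
  back <- load_dataset(file.path(dir, "materials.csv"),
                       spectra_dir = file.path(dir, "spectra"),
                       image_dir = file.path(dir, "images"))
  expect_equal(summarize_measurements(back), summarize_measurements(gen$dataset))
  for (i in seq_along(back$samples)) {
    expect_equal(back$samples[[i]]$measurements,
                 gen$dataset$samples[[i]]$measurements)
    expect_equal(back$samples[[i]]$base_features,
                 gen$dataset$samples[[i]]$base_features)
  }
  id <- back$samples[[1]]$material_id
  expect_equal(back$spectra[[id]]$ftir$intensity,
               gen$dataset$spectra[[id]]$ftir$intensity)
  # images survive up to 8-bit PNG quantisation
  expect_lt(max(abs(back$images[[id]] - gen$dataset$images[[id]])), 1 / 254)
})

test_that("measurement counts summarise correctly, including the empty dataset", {
  ds <- tiny_dataset()
  counts <- summarize_measurements(ds)
  expect_equal(unname(counts), c(3L, 4L, 3L, 2L, 1L))
  expect_equal(names(counts), c("a", "b", "c", "d", "e"))
  expect_length(summarize_measurements(material_dataset(list())), 0L)
})

test_that("the eight combo labels map bijectively onto the block-flag cube", {
  tab <- combo_table()
  keys <- paste(tab$use_ftir, tab$use_xrd, tab$use_sem)
  expect_equal(sort(tab$label), LETTERS[1:8])
  expect_equal(anyDuplicated(keys), 0L)
  a <- method_combo("A"); h <- method_combo("H")
  expect_false(a$use_ftir || a$use_xrd || a$use_sem)
  expect_true(h$use_ftir && h$use_xrd && h$use_sem)
  expect_error(method_combo("Z"), class = "bonevar_input_error")
})

test_that("feature matrices contain the right blocks in deterministic order", {
  gen <- generate_synthetic_dataset(small_config(seed = 3))
  fa <- assemble_feature_matrix(gen$dataset, method_combo("A"))
  expect_equal(fa$column_names, gen$dataset$feature_names)

  fh <- assemble_feature_matrix(gen$dataset, method_combo("H"),
                                ftir_bands = gen$bands$ftir,
                                xrd_bands = gen$bands$xrd)
  expect_equal(sum(startsWith(fh$column_names, "lbp_")), 256L)
  expect_true(all(gen$dataset$feature_names %in% fh$column_names))
  # band columns ascend by position within each block
  ftir_cols <- grep("^ftir_", fh$column_names, value = TRUE)
  expect_equal(ftir_cols, ftir_cols[order(as.numeric(sub("ftir_", "", ftir_cols)))])

  # monotone block inclusion: every combo's columns nest into H's
  for (lab in LETTERS[1:8]) {
    fl <- assemble_feature_matrix(gen$dataset, method_combo(lab),
                                  ftir_bands = gen$bands$ftir,
                                  xrd_bands = gen$bands$xrd)
    expect_true(all(fl$column_names %in% fh$column_names), label = lab)
  }
  fe <- assemble_feature_matrix(gen$dataset, method_combo("E"),
                                ftir_bands = gen$bands$ftir,
                                xrd_bands = gen$bands$xrd)
  expect_true(all(fa$column_names %in% fe$column_names))
  expect_gt(ncol(fe$matrix), ncol(fa$matrix))

  # determinism
  fe2 <- assemble_feature_matrix(gen$dataset, method_combo("E"),
                                 ftir_bands = gen$bands$ftir,
                                 xrd_bands = gen$bands$xrd)
  expect_identical(fe$matrix, fe2$matrix)
})

test_that("a switched-on block that is absent raises a missing-block error", {
  ds <- tiny_dataset()
  expect_error(assemble_feature_matrix(ds, method_combo("B"),
                                       ftir_bands = band_list(1000, 10)),
               class = "bonevar_missing_block_error")
  expect_error(assemble_feature_matrix(ds, method_combo("D")),
               class = "bonevar_missing_block_error")
})
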