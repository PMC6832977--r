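test_that("octa_image validates geometry, range and metadata", {
  img <- make_image(matrix(c(0L, 255L, 255L, 0L), 2, 2), extent_mm = 1)
  expect_identical(img$pixels, matrix(c(0L, 255L, 255L, 0L), 2, 2))
  expect_equal(scale_mm_per_px(img) * ncol(img$pixels), img$extent_mm,
               tolerance = 1e-12)

  expect_error(make_image(matrix(0L, 320, 240)), class = "octava_validation_error")
  expect_error(make_image(matrix(300, 4, 4)), class = "octava_validation_error")
  expect_error(make_image(matrix(0.5, 4, 4)), class = "octava_validation_error")
  expect_error(octa_image(matrix(0L, 4, 4), -3, "SCP", "OD", "v"),
               class = "octava_validation_error")
  expect_error(octa_image(matrix(0L, 4, 4), 3, "XXX", "OD", "v"),
               class = "octava_validation_error")
  expect_error(octa_image(matrix(0L, 4, 4), 3, "SCP", "OD", ""),
               class = "octava_validation_error")
})

test_that("scale bookkeeping matches metadata arithmetic", {
  img <- make_image(matrix(0L, 320, 320), extent_mm = 3)
  expect_equal(scale_mm_per_px(img), 3 / 320, tolerance = 1e-15)
})

test_that("PNG and TIFF round trips are bit-exact for 8-bit grayscale", {
  set.seed(11)
  pix <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
  img <- make_image(pix)
  for (ext in c("png", "tif")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_octa_image(img, path)
    back <- read_octa_image(path, extent_mm = 3, plexus = "SCP",
                            laterality = "OD", visit_id = "t")
    expect_identical(back$pixels, img$pixels)
    unlink(path)
  }
})

test_that("metadata sidecars are honored and missing metadata rejected", {
  pix <- matrix(7L, 16, 16)
  path <- tempfile(fileext = ".png")
  write_octa_image(make_image(pix), path)
  jsonlite::write_json(
    list(extent_mm = 6, plexus = "DCP", laterality = "OS", visit_id = "v9"),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  img <- read_octa_image(path)
  expect_equal(img$extent_mm, 6)
  expect_equal(img$plexus, "DCP")
  expect_equal(img$laterality, "OS")
  expect_equal(img$visit_id, "v9")
  unlink(paste0(path, ".json"))
  expect_error(read_octa_image(path), class = "octava_validation_error")
  expect_error(read_octa_image(tempfile(fileext = ".png"), 3, "SCP", "OD", "v"),
               class = "octava_io_error")
  unlink(path)
})

test_that("equal-channel RGB collapses; colored images are rejected", {
  gray <- matrix(runif(64), 8, 8)
  rgb_equal <- array(rep(gray, 3), c(8, 8, 3))
  p1 <- tempfile(fileext = ".png")
  png::writePNG(rgb_equal, p1)
  img <- read_octa_image(p1, 3, "SCP", "OD", "v")
  expect_identical(img$pixels, matrix(as.integer(round(round(gray * 255) / 255 * 255)), 8, 8))
  colored <- rgb_equal
  colored[, , 2] <- 1 - colored[, , 2]
  p2 <- tempfile(fileext = ".png")
  png::writePNG(colored, p2)
  expect_error(read_octa_image(p2, 3, "SCP", "OD", "v"),
               class = "octava_validation_error")
  unlink(c(p1, p2))
})

test_that("cohort tables are validated row by row", {
  df <- data.frame(
    visit_id = c("a", "b", "c"), va_decimal = c(0.2, 0.8, 1.0),
    laterality = c("OD", "OS", "OD"),
    path_scp3 = "x.png", path_scp6 = "x.png",
    path_dcp3 = "x.png", path_dcp6 = "x.png",
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  tab <- read_cohort(path)
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$visit_id, c("a", "b", "c")) # order preserved

  bad_va <- df
  bad_va$va_decimal[2] <- 1.3
  write.csv(bad_va, path, row.names = FALSE)
  err <- expect_error(read_cohort(path), class = "octava_validation_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "b")

  dup <- df
  dup$visit_id[3] <- "a"
  write.csv(dup, path, row.names = FALSE)
  expect_error(read_cohort(path), class = "octava_validation_error")

  writeLines(character(0), path)
  expect_error(read_cohort(path), class = "octava_validation_error")
  unlink(path)
})
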