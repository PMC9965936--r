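test_that("zero-noise phantom equals its template and rendering is deterministic", {
  spec <- phantom_spec(noise_sigma = 0, salt_pepper = 0, seed = 3)
  ph <- generate_phantom(spec)
  expect_identical(ph$image, hhocnn:::phantom_template(spec)$image)
  expect_lte(length(unique(as.vector(ph$image))), 3L)
  expect_identical(ph$label, 1L)

  noisy <- phantom_spec(noise_sigma = 5, salt_pepper = 0.02, seed = 17)
  expect_identical(generate_phantom(noisy), generate_phantom(noisy))
  # a different seed gives a different noise realization
  other <- noisy; other$seed <- 18L
  expect_false(identical(generate_phantom(noisy)$image,
                         generate_phantom(other)$image))
})

test_that("tumor mask matches a brute-force point-in-disk scan", {
  for (r in c(4, 6, 8)) {
    spec <- phantom_spec(tumor_radius = r, noise_sigma = 0, salt_pepper = 0)
    ph <- generate_phantom(spec)
    cnt <- 0
    for (rr in seq_len(spec$size)) {
      for (cc in seq_len(spec$size)) {
        if ((rr - spec$tumor_center[1])^2 + (cc - spec$tumor_center[2])^2 <= r^2)
          cnt <- cnt + 1
      }
    }
    expect_equal(sum(ph$mask), cnt)
    expect_equal(sort(unique(ph$image[ph$mask])), spec$tumor_intensity)
  }
})

test_that("phantom specs reject invalid geometry and intensities", {
  expect_error(phantom_spec(tumor_center = c(5, 5)), "inside the brain")
  expect_error(phantom_spec(tumor_radius = 30), "inside the brain")
  expect_error(phantom_spec(tumor_intensity = 300), "intensities")
  expect_error(phantom_spec(salt_pepper = 0.7), "salt_pepper")
})

test_that("generated datasets honor class balance, determinism and mask/label consistency", {
  ds <- generate_dataset(10, 0.5, seed = 5)
  expect_equal(sum(ds$labels == 1L), 5L)
  expect_equal(sum(ds$labels == 0L), 5L)

  big <- generate_dataset(253, 0.6, seed = 5)
  expect_length(big$images, 253L)
  expect_equal(sum(big$labels == 1L), round(253 * 0.6))

  expect_identical(generate_dataset(8, 0.5, seed = 9),
                   generate_dataset(8, 0.5, seed = 9))
  for (i in seq_along(ds$images)) {
    if (ds$labels[i] == 1L) {
      expect_gt(sum(ds$masks[[i]]), 0)
    } else {
      expect_null(ds$masks[[i]])
    }
  }
  expect_error(generate_dataset(10, 0), "balance")
  expect_error(generate_dataset(10, 1), "balance")
})

test_that("dataset export and re-import round-trips pixels, labels and split", {
  ds <- split_dataset(generate_dataset(8, 0.5, seed = 2), 0.75, seed = 3)
  dir <- tempfile("ds")
  write_dataset(ds, dir)
  back <- read_image_folder(dir)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$split, ds$split)
  for (i in seq_along(ds$images)) {
    expect_equal(back$images[[i]], ds$images[[i]])
    if (ds$labels[i] == 1L) expect_equal(back$masks[[i]], ds$masks[[i]])
  }
  unlink(dir, recursive = TRUE)
})

test_that("two-folder layout is read with yes-then-no labels", {
  dir <- tempfile("folder")
  dir.create(file.path(dir, "yes"), recursive = TRUE)
  dir.create(file.path(dir, "no"), recursive = TRUE)
  set.seed(4)
  imgs <- replicate(5, random_gray_image(6, 6), simplify = FALSE)
  for (i in 1:3) write_gray_image(imgs[[i]], file.path(dir, "yes", sprintf("a%d.png", i)))
  for (i in 4:5) write_gray_image(imgs[[i]], file.path(dir, "no", sprintf("b%d.png", i)))
  ds <- read_image_folder(dir)
  expect_identical(ds$labels, c(1L, 1L, 1L, 0L, 0L))
  # 8-bit PNG is read back bit-exactly
  expect_equal(ds$images[[1]], imgs[[1]])
  unlink(dir, recursive = TRUE)
  expect_error(read_image_folder(tempfile()), "directory")
})

test_that("16-bit input is linearly rescaled so full scale maps to 255", {
  raw <- c(0, 1000, 32768, 65535)
  v16 <- matrix(raw / 65535, 2, 2)
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(v16, path, bits.per.sample = 16L)
  img <- read_gray_image(path)
  expect_equal(as.vector(img), round(raw / 65535 * 255))
  expect_equal(max(img), 255)
  unlink(path)
})

test_that("unreadable image files raise an error naming the file", {
  dir <- tempfile("badset")
  dir.create(file.path(dir, "yes"), recursive = TRUE)
  dir.create(file.path(dir, "no"), recursive = TRUE)
  writeLines("not a png", file.path(dir, "yes", "broken.png"))
  expect_error(read_image_folder(dir), "broken.png")
  unlink(dir, recursive = TRUE)
})

test_that("color inputs collapse to the documented luminance rule", {
  arr <- array(0, c(3, 3, 3))
  arr[, , 1] <- 1  # pure red
  path <- tempfile(fileext = ".png")
  png::writePNG(arr, path)
  img <- read_gray_image(path)
  expect_true(all(img == round(0.299 * 255)))
  unlink(path)
})
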