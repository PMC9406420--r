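# Phantom generator: determinism, mask geometry, dataset manifests.

test_that("no lesions means an empty mask; pairs are dimension-consistent", {
  pair <- generate_phantom(phantom_spec(seed = 3, size = 64, n_lesions = 0))
  expect_identical(dim(pair$image), dim(pair$mask))
  expect_true(all(pair$mask == 0))
  expect_true(all(pair$image >= 0 & pair$image <= 1))

  pair1 <- generate_phantom(phantom_spec(seed = 4, size = 64, n_lesions = 1))
  expect_true(sum(pair1$mask) >= 1)
  expect_true(all(pair1$mask %in% c(0, 1)))
})

test_that("the same spec reproduces bit-identical output", {
  sp <- phantom_spec(seed = 1, size = 64)
  expect_identical(generate_phantom(sp), generate_phantom(sp))
})

test_that("single-lesion mask area stays within the disk-area bounds", {
  # radial profile r * (1 + irr * s) with zero-mean s keeps the enclosed
  # area between pi r_min^2 and pi (r_max (1 + irr))^2 < 4 pi r_max^2
  for (seed in 1:15) {
    pair <- generate_phantom(phantom_spec(seed = seed, size = 64,
                                          n_lesions = 1,
                                          lesion_radius_range = c(8, 12)))
    area <- sum(pair$mask)
    expect_gte(area, pi * 8^2)
    expect_lte(area, 4 * pi * 12^2)
  }
})

test_that("lesion pixels exceed the background by at least half the contrast", {
  sp <- phantom_spec(seed = 11, size = 64, lesion_contrast = 0.3,
                     noise_sd = 0)
  pair <- generate_phantom(sp)
  les <- pair$mask == 1
  expect_gte(mean(pair$image[les]) - mean(pair$image[!les]),
             sp$lesion_contrast / 2)
})

test_that("foreground fraction is monotone nondecreasing in n_lesions", {
  areas <- vapply(0:4, function(k)
    sum(generate_phantom(phantom_spec(seed = 5, size = 64,
                                      n_lesions = k))$mask), 0)
  expect_true(all(diff(areas) >= 0))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_spec(lesion_radius_range = c(1, 5)), class = "csn_config_error")
  expect_error(phantom_spec(lesion_radius_range = c(10, 5)), class = "csn_config_error")
  expect_error(phantom_spec(dynamic_range = c(0.7, 0.3)), class = "csn_config_error")
  expect_error(phantom_spec(lesion_contrast = 0.9), class = "csn_config_error")
})

test_that("generate_dataset writes n pairs with a deterministic manifest", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sp <- phantom_spec(size = 32)
  man <- generate_dataset(9, base_seed = 100, sp, dir = d1,
                          split = "train", dataset_tag = "phantom")$manifest
  expect_equal(nrow(man), 9)
  expect_named(man, c("image_path", "mask_path", "split", "dataset_tag"))
  expect_true(all(file.exists(file.path(d1, man$image_path))))

  generate_dataset(9, base_seed = 100, sp, dir = d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "manifest.csv"))),
                   unname(tools::md5sum(file.path(d2, "manifest.csv"))))
  expect_identical(unname(tools::md5sum(file.path(d1, man$image_path))),
                   unname(tools::md5sum(file.path(d2, man$image_path))))

  # PNG round trip: mask read back binary, image within quantization error
  img <- read_gray_image(file.path(d1, man$image_path[1]))
  msk <- read_gray_image(file.path(d1, man$mask_path[1]), binarize = TRUE)
  pair <- generate_phantom(phantom_spec(seed = 100, size = 32))
  expect_lt(max(abs(img - pair$image)), 1 / 255)
  expect_identical(msk, pair$mask)
})

test_that("in-memory generation uses per-item seeds base_seed + i", {
  res <- generate_dataset(3, base_seed = 50, phantom_spec(size = 32))
  expect_length(res$pairs, 3)
  expect_identical(res$pairs[[2]],
                   generate_phantom(phantom_spec(seed = 51, size = 32)))
})
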