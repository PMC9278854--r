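test_that("image generation is deterministic and correctly structured", {
  a <- generate_images(2, 1, size = c(16, 16), seed = 0)
  b <- generate_images(2, 1, size = c(16, 16), seed = 0)
  expect_identical(a$images, b$images)
  expect_identical(a$labels, b$labels)

  s <- generate_images(5, 7, size = c(16, 16), seed = 3)
  expect_equal(dim(s$images), c(35, 16, 16, 3))
  expect_equal(as.integer(table(s$labels)), rep(7L, 5))
  expect_true(all(s$images >= 0 & s$images <= 1))
  expect_true(all(s$labels >= 1 & s$labels <= 5))

  d <- generate_images(2, 1, size = c(16, 16), seed = 1)
  expect_false(identical(d$images, a$images))
})

test_that("degenerate image requests fail loudly", {
  expect_error(generate_images(2, 1, size = c(8, 8)), "too small")
  expect_error(generate_images(1, 5), "two classes")
  expect_error(generate_images(3, 0), "at least one image")
})

test_that("image subsetting keeps alignment", {
  s <- tiny_images()
  idx <- c(5, 1, 80)
  sub <- s[idx]
  expect_equal(sub$labels, s$labels[idx])
  expect_equal(sub$images[2, , , ], s$images[1, , , ])
})
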