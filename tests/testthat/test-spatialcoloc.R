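course8 <- c(0.06, 0.37, 0.33, 0.25, 0.24, 0.28, 0.07, 0.06)

small_series <- function(seed = 1) {
  generate_sections(synth_config(
    n_celltypes = 2, cells_per_type = 50, n_genes = 40,
    n_modules_shared = 1, n_modules_regen_only = 0, module_size = 8,
    marker_fraction_course = course8, seed = seed))
}

test_that("positive-cell fractions recover the configured course exactly", {
  sim <- small_series()
  course <- positive_fraction_course(sim$sections, "TRH")
  expect_equal(course$positive_fraction, course8)
  # time-course shape: injury peak, then below-peak decay to control level
  expect_identical(which.max(course$positive_fraction), 2L)
  expect_true(all(course$positive_fraction[3:8] <
                    course$positive_fraction[2]))
  expect_lte(course$positive_fraction[8],
             course$positive_fraction[1] + 0.01)
})

test_that("positive_cell_fraction handles edge genes and errors", {
  s <- tiny_section()
  expect_equal(positive_cell_fraction(s, "GA"), 0.5)
  expect_equal(positive_cell_fraction(s, "GC"), 4 / 6)
  expect_error(positive_cell_fraction(s, "nope"), "unknown gene")
  z <- s
  z$expr[, "GA"] <- 0
  expect_equal(positive_cell_fraction(z, "GA"), 0)
  z$expr[, "GA"] <- 1
  expect_equal(positive_cell_fraction(z, "GA"), 1)
})

test_that("annotation overlap follows the radius rule", {
  s <- tiny_section()
  # positive GA cells are exactly the T1 cells
  res <- annotation_overlap(s, "GA", "T1", radius = 0)
  expect_equal(res$colocalized_fraction, 1)
  # T2 cells are ~14 units away from T1 positives
  res2 <- annotation_overlap(s, "GA", "T2", radius = 5)
  expect_equal(res2$colocalized_fraction, 0)
  res3 <- annotation_overlap(s, "GA", "T2", radius = 20)
  expect_equal(res3$colocalized_fraction, 1)
  expect_error(annotation_overlap(s, "GA", "T1", radius = -1), "radius")
  expect_error(annotation_overlap(s, "GA", "T9", 1), "absent")
})

test_that("annotation overlap matches a brute-force distance oracle", {
  sim <- small_series(4)
  s <- sim$sections[["2dpi"]]
  radius <- 60
  res <- annotation_overlap(s, "TRH", "CT01", radius)
  pos <- which(s$expr[, "TRH"] > 0)
  ann <- which(s$cells$celltype == "CT01")
  hits <- 0L
  for (p in pos) {
    d <- sqrt((s$cells$x[p] - s$cells$x[ann])^2 +
                (s$cells$y[p] - s$cells$y[ann])^2)
    if (min(d) <= radius) hits <- hits + 1L
  }
  expect_identical(res$n_colocalized, hits)
  expect_equal(res$colocalized_fraction, hits / length(pos))
})

test_that("RGB thresholding applies all clause bounds", {
  black <- new_raster_image(array(c(rep(0L, 10 * 10 * 3),
                                    rep(255L, 10 * 10)), c(10, 10, 4)))
  expect_identical(sum(threshold_rgb(black, "R>=10")), 0L)
  # pure red disk on black
  px <- array(0L, c(40, 40, 4)); px[, , 4] <- 255L
  disk <- outer(0:39, 0:39, function(y, x) (x - 20)^2 + (y - 20)^2 <= 64)
  ch <- px[, , 1]; ch[disk] <- 200L; px[, , 1] <- ch
  img <- new_raster_image(px)
  mask <- threshold_rgb(img, "R>=128,G<=50,B<=50")
  expect_identical(unclass(mask), disk)
  # list form and alpha-on-demand
  mask2 <- threshold_rgb(img, list(R = c(128, 255)))
  expect_identical(unclass(mask2), disk)
  expect_error(threshold_rgb(img, "R>=200,R<=100"), "contradictory")
  expect_error(threshold_rgb(img, "Q>=1"), "parse")
  # generated marker fixture: mask contains the disk interior
  fix <- generate_coloc_image(60, 60,
                              list(list(center = c(30, 30), radius = 12,
                                        intensity = 0.8)),
                              list(), seed = 3)
  m <- threshold_rgb(fix$marker, "R>=64,G<=80,B<=80")
  interior <- outer(0:59, 0:59, function(y, x)
    (x - 30)^2 + (y - 30)^2 <= 11^2)
  expect_true(all(m[interior]))
})

test_that("dilation matches its oracle and is extensive and monotone", {
  # single pixel, square element radius 1 -> 3x3 block
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  d <- dilate(new_binary_mask(m), 1, shape = "square")
  expect_identical(sum(d), 9L)
  # radius 0 is the identity
  expect_identical(unclass(dilate(new_binary_mask(m), 0)), m)
  # random mask vs brute-force neighborhood-max oracle
  set.seed(8)
  rm <- matrix(runif(20 * 15) < 0.1, 20, 15)
  for (r in c(1, 2)) {
    expect_identical(unclass(dilate(new_binary_mask(rm), r)),
                     oracle_dilate(rm, r))
  }
  # extensivity chain
  prev <- new_binary_mask(rm)
  for (r in 0:3) {
    cur <- dilate(new_binary_mask(rm), r)
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("composites count overlap and encode the documented colors", {
  fix <- generate_coloc_image(100, 80,
                              list(list(center = c(40, 40), radius = 15,
                                        intensity = 1)),
                              list(list(center = c(55, 40), radius = 15)),
                              seed = 2)
  marker_mask <- threshold_rgb(fix$marker, "R>=128,G<=80,B<=80")
  pop_mask <- threshold_rgb(fix$population, "R>=200,G>=200,B<=80")
  out <- compose(fix$marker, marker_mask, pop_mask)
  res <- out$result
  expect_identical(res$marker_pixels, sum(marker_mask))
  expect_identical(res$population_pixels, sum(pop_mask))
  expect_identical(res$overlap_pixels, sum(marker_mask & pop_mask))
  expect_lte(res$overlap_pixels, min(res$marker_pixels,
                                     res$population_pixels))
  # pixel-count conservation against the generator truth (lens area)
  expect_lt(abs(res$overlap_pixels - sum(fix$truth_overlap)),
            2 * pi * 15 * 2 + 20)
  # population-only pixels are yellow, marker pixels red-channel only
  px <- out$image$pixels
  pop_only <- unclass(pop_mask) & !unclass(marker_mask)
  expect_true(all(px[, , 1][pop_only] == 255L))
  expect_true(all(px[, , 2][pop_only] == 255L))
  expect_true(all(px[, , 3][pop_only] == 0L))
  mm <- unclass(marker_mask)
  expect_true(all(px[, , 2][mm] == 0L))
  expect_true(all(px[, , 1][mm] >= 120L))
  # disjoint masks
  m1 <- new_binary_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  m2 <- new_binary_mask(matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2))
  img <- new_raster_image(array(rep(c(100L, 100L, 100L, 255L),
                                    each = 4), c(2, 2, 4)))
  r <- compose(img, m1, m2)$result
  expect_identical(r$overlap_pixels, 0L)
  # identical masks
  r2 <- compose(img, m1, m1)$result
  expect_identical(r2$overlap_pixels, r2$marker_pixels)
  expect_error(compose(img, m1, new_binary_mask(matrix(FALSE, 3, 3))),
               "shapes")
})

test_that("raster images round-trip through PNG", {
  fix <- generate_coloc_image(30, 20,
                              list(list(center = c(10, 10), radius = 5,
                                        intensity = 0.7)),
                              list(list(center = c(20, 10), radius = 5)),
                              seed = 6)
  path <- withr::local_tempfile(fileext = ".png")
  write_png_raster(fix$marker, path)
  back <- read_png_raster(path)
  expect_identical(back$pixels, fix$marker$pixels)
})
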