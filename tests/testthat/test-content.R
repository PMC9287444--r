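# descriptors operate on decoded rasters in [0, 1]; helpers build rasters
# with exactly known histograms
gray_raster <- function(values255, n = 256) {
  matrix(values255 / 255, nrow = n)
}

test_that("entropy matches closed-form values on constructed histograms", {
  # uniform image: single-bin histogram
  expect_equal(image_entropy(gray_raster(rep(128, 256 * 256))), 0.0,
               tolerance = 1e-9)
  # two equal bins: exactly 1 bit
  expect_equal(image_entropy(gray_raster(rep(c(0, 255), each = 128 * 256))),
               1.0, tolerance = 1e-9)
  # four equal bins: exactly 2 bits
  expect_equal(image_entropy(gray_raster(rep(c(64, 128, 192, 255),
                                             each = 64 * 256))),
               2.0, tolerance = 1e-9)
})

test_that("entropy is invariant under pixel permutation", {
  set.seed(41)
  v <- sample(0:255, 4096, replace = TRUE)
  e1 <- image_entropy(matrix(v / 255, 64))
  e2 <- image_entropy(matrix(sample(v) / 255, 64))
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_gte(e1, 0); expect_lte(e1, 8)
})

test_that("luma conversion uses BT.601 weights with half-up rounding", {
  # a colour image whose luma is known exactly:
  # 0.299*255 = 76.245 -> 76 for pure red
  img <- array(0, dim = c(2, 2, 3)); img[, , 1] <- 1
  e <- image_entropy(img)
  expect_equal(e, 0, tolerance = 1e-12)  # all pixels identical luma
  # mixed red/green image: two distinct luma bins, 1 bit
  img2 <- array(0, dim = c(2, 2, 3))
  img2[1, , 1] <- 1  # red row
  img2[2, , 2] <- 1  # green row
  expect_equal(image_entropy(img2), 1.0, tolerance = 1e-12)
})

test_that("average colour is the per-channel mean on the 0-255 scale", {
  img <- array(0, dim = c(4, 4, 3))
  img[, , 1] <- 10 / 255; img[, , 2] <- 20 / 255; img[, , 3] <- 30 / 255
  expect_equal(average_colour(img), c(10, 20, 30))
  half <- matrix(rep(c(0, 1), each = 8), nrow = 4)
  expect_equal(average_colour(half), rep(127.5, 3))
  # brute-force pixel-loop oracle on a random image
  set.seed(42)
  rnd <- array(runif(4 * 5 * 3), dim = c(4, 5, 3))
  oracle <- numeric(3)
  for (k in 1:3) {
    s <- 0
    for (i in 1:4) for (j in 1:5) s <- s + rnd[i, j, k]
    oracle[k] <- s / 20 * 255
  }
  expect_equal(average_colour(rnd), round(oracle, 2), tolerance = 1e-9)
})

test_that("particle counting finds exactly the generated disks", {
  f <- tempfile(fileext = ".png")
  gt <- make_image(f, seed = 43, particles = 7)
  expect_identical(particle_count(f, min_area = 10), 7L)
  # min_area beyond the disk area suppresses everything
  expect_identical(particle_count(f, min_area = 1000), 0L)
  # blank image: zero foreground
  gt0 <- make_image(f, seed = 44, particles = 0)
  expect_identical(particle_count(f, min_area = 10), 0L)
})

test_that("particle counting is invariant under in-frame translation", {
  f <- tempfile(fileext = ".png")
  make_image(f, seed = 45, particles = 5)
  img <- png::readPNG(f)
  n0 <- particle_count(img)
  background <- 64 / 255
  shifted <- matrix(background, nrow(img), ncol(img))
  shifted[4:nrow(img), 4:ncol(img)] <- img[1:(nrow(img) - 3),
                                           1:(ncol(img) - 3)]
  # generator keeps disks off the border, so the shift keeps all in frame
  expect_identical(particle_count(shifted), n0)
})

test_that("8-connected labeling joins diagonal pixels", {
  m <- matrix(0, 8, 8)
  m[2, 2] <- 1; m[3, 3] <- 1; m[4, 4] <- 1   # a diagonal line: 1 component
  m[7, 7] <- 1                               # plus an isolated pixel
  expect_identical(particle_count(m, min_area = 1, threshold = 0.5), 2L)
  expect_identical(particle_count(m, min_area = 2, threshold = 0.5), 1L)
})

test_that("annotation geometry classes follow the coordinate rules", {
  a_whole <- ifdo_annotation(list(), "lbl", "ann")
  expect_identical(annotation_geometry(a_whole), "whole-image")
  a_pt <- ifdo_annotation(list(c(10, 20)), "lbl", "ann", confidence = 0.9)
  expect_identical(annotation_geometry(a_pt), "point")
  a_box <- ifdo_annotation(list(c(5, 5), c(20, 30)), "lbl", "ann",
                           kind = "bbox")
  expect_identical(annotation_geometry(a_box), "bounding-box")
  a_poly <- ifdo_annotation(list(c(0, 0), c(10, 0), c(5, 8), c(0, 0)),
                            "lbl", "ann")
  expect_identical(annotation_geometry(a_poly), "polygon")
  expect_error(ifdo_annotation(list(c(0, 0), c(10, 0), c(5, 8)),
                               "lbl", "ann"), "closed")
  expect_error(ifdo_annotation(list(c(5, 5), c(20, 30)), "lbl", "ann"),
               "bbox")
  expect_error(ifdo_annotation(list(c(1, 2)), "lbl", "ann",
                               confidence = 1.5), "confidence")
})

test_that("annotation encoding and decoding are inverse bijections", {
  labels <- list(list(id = "l1", name = "coral"),
                 list(id = "l2", name = "sponge"))
  creators <- list(list(id = "c1", name = "A Human", kind = "human"),
                   list(id = "c2", name = "detector-v2", kind = "machine"))
  set.seed(46)
  anns <- lapply(1:50, function(i) {
    geom <- sample(c("whole", "point", "bbox", "poly"), 1)
    co <- switch(geom,
      whole = list(),
      point = list(round(runif(2, 0, 512), 1)),
      bbox = { p <- sort(round(runif(2, 0, 512), 1))
               q <- sort(round(runif(2, 0, 512), 1))
               list(c(p[1], q[1]), c(p[2], q[2])) },
      poly = { pts <- lapply(1:3, function(j) round(runif(2, 0, 512), 1))
               c(pts, pts[1]) })
    ifdo_annotation(co,
                    labels = sample(c("l1", "l2"), sample(1:2, 1)),
                    annotators = sample(c("c1", "c2"), 1),
                    confidence = if (runif(1) < 0.5) round(runif(1), 3),
                    kind = if (geom == "bbox") "bbox")
  })
  enc <- encode_annotations(labels, creators, anns)
  dec <- decode_annotations(enc)
  expect_identical(dec$labels, labels)
  expect_identical(dec$creators, creators)
  expect_identical(dec$annotations, anns)
  # and encode(decode(enc)) is enc
  enc2 <- encode_annotations(dec$labels, dec$creators, dec$annotations)
  expect_identical(enc2, enc)
})

test_that("dangling ids and bad confidence are refused by name", {
  labels <- list(list(id = "l1", name = "coral"))
  creators <- list(list(id = "c1", name = "A", kind = "human"))
  a <- ifdo_annotation(list(c(1, 2)), "l9", "c1")
  expect_error(encode_annotations(labels, creators, list(a)), "l9")
  b <- ifdo_annotation(list(c(1, 2)), "l1", "c9")
  expect_error(encode_annotations(labels, creators, list(b)), "c9")
})

test_that("annotations round-trip through a full document", {
  set.seed(47)
  doc <- minimal_valid_doc()
  labels <- list(list(id = "l1", name = "coral"))
  creators <- list(list(id = "c1", name = "A", kind = "human"))
  a <- ifdo_annotation(list(c(10, 20)), "l1", "c1", confidence = 0.9)
  fields <- encode_annotations(labels, creators, list(a))
  doc$items[[1]] <- c(doc$items[[1]], fields)
  doc2 <- parse_ifdo(write_ifdo(doc))
  rep <- validate_ifdo(doc2)
  expect_true(rep$is_fair)
  got <- decode_annotations(resolve_item(doc2, names(doc2$items)[1]))
  expect_identical(length(got$annotations), 1L)
  expect_identical(got$annotations[[1]]$coordinates, list(c(10, 20)))
  expect_identical(got$annotations[[1]]$confidence, 0.9)
  # a dangling reference surfaces as a validation error
  doc$items[[1]]$annotations[[1]]$labels <- list("ghost")
  rep2 <- validate_ifdo(doc)
  expect_false(rep2$is_fair)
})
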