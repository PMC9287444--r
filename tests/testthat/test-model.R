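test_that("parse and write round-trip preserves semantic content", {
  set.seed(42)
  for (i in 1:20) {
    doc <- random_doc()
    txt <- write_ifdo(doc)
    doc2 <- parse_ifdo(txt)
    expect_true(ifdo_equal(doc, doc2))
    # canonical text is a fixed point
    expect_identical(write_ifdo(doc2), txt)
  }
})

test_that("serialization is deterministic and canonically keyed", {
  set.seed(7)
  doc <- minimal_valid_doc()
  t1 <- write_ifdo(doc)
  t2 <- write_ifdo(doc)
  expect_identical(t1, t2)
  expect_match(t1, "image-set-uuid", fixed = TRUE)
  # set fields come first in the header
  lines <- strsplit(t1, "\n")[[1]]
  expect_match(lines[1], "^image-set-header:")
  expect_match(lines[2], "image-set-name", fixed = TRUE)
  expect_match(lines[3], "image-set-uuid", fixed = TRUE)
  expect_match(lines[4], "image-set-handle", fixed = TRUE)
  # a complete single-item document stays small
  expect_lt(nchar(t1, type = "bytes"), 10 * 1024)
})

test_that("header-only documents parse to zero items", {
  set.seed(1)
  doc <- ifdo_document("empty set", generate_uuid(),
                       "https://hdl.handle.net/20.500.12085/x")
  doc2 <- parse_ifdo(write_ifdo(doc))
  expect_length(doc2$items, 0)
})

test_that("malformed input is rejected with a diagnosable error", {
  expect_error(parse_ifdo("a: [1, 2"), "parse error")
  expect_error(parse_ifdo("just-a-key: 1"), "structure error")
  expect_error(parse_ifdo("image-set-header:\n  a: 1"), "structure error")
})

test_that("unknown fields are preserved verbatim through a round trip", {
  set.seed(3)
  doc <- minimal_valid_doc()
  doc$items[[1]][["x-institute-internal"]] <- "ABC-123"
  doc$header$defaults[["x-cruise-wiki"]] <- "https://wiki.example.org"
  doc2 <- parse_ifdo(write_ifdo(doc))
  expect_identical(resolve_item(doc2, names(doc2$items)[1])[["x-institute-internal"]],
                   "ABC-123")
  expect_identical(doc2$header$defaults[["x-cruise-wiki"]],
                   "https://wiki.example.org")
})

test_that("serialization refuses invariant violations by name", {
  set.seed(4)
  doc <- minimal_valid_doc()
  doc$header$set_uuid <- "not-a-uuid"
  expect_error(write_ifdo(doc), "image-set-uuid")
  doc <- minimal_valid_doc()
  doc$header$set_handle <- "hdl.handle.net/no-scheme"
  expect_error(write_ifdo(doc), "image-set-handle")
  doc <- minimal_valid_doc()
  doc$items[[1]]$set_name <- "sneaky override"
  expect_error(write_ifdo(doc), "set-level")
  doc <- minimal_valid_doc()
  doc$items[["vid.mov"]] <- list(
    list(sensor = "camB"),
    list(datetime = "2022-07-15T10:00:02.000Z", depth = 5),
    list(datetime = "2022-07-15T10:00:01.000Z", depth = 6))
  expect_error(write_ifdo(doc), "non-decreasing")
})

test_that("item resolution overlays header defaults, item winning", {
  set.seed(5)
  doc <- minimal_valid_doc()
  doc$header$defaults$sensor <- "camA"
  nm <- names(doc$items)[1]
  expect_identical(resolve_item(doc, nm)$sensor, "camA")
  doc$items[[nm]]$sensor <- "camB"
  expect_identical(resolve_item(doc, nm)$sensor, "camB")
  doc$header$defaults$latitude <- 10.0
  doc$items[[nm]]$latitude <- 11.0
  expect_identical(resolve_item(doc, nm)$latitude, 11.0)
  expect_error(resolve_item(doc, "no-such-item"), "unknown item")
  # re-overlaying an empty layer is the identity
  m <- resolve_item(doc, nm)
  expect_identical(naive_merge(m, list()), naive_merge(m))
})

test_that("video timepoints layer defaults, entry 0 and the timepoint", {
  set.seed(6)
  doc <- minimal_valid_doc()
  doc$header$defaults$sensor <- "camA"
  doc$items[["vid.mov"]] <- list(
    list(depth = 100, license = "CC-0"),
    list(datetime = "2022-07-15T10:00:01.000Z"),
    list(datetime = "2022-07-15T10:00:02.000Z", depth = 105))
  tp1 <- resolve_timepoint(doc, "vid.mov", 1)
  tp2 <- resolve_timepoint(doc, "vid.mov", 2)
  expect_identical(tp1$depth, 100)
  expect_identical(tp2$depth, 105)
  expect_identical(tp1$license, "CC-0")  # video-wide default
  expect_identical(tp2$license, "CC-0")
  expect_identical(tp1$sensor, "camA")   # set-wide default
  expect_error(resolve_timepoint(doc, "vid.mov", 0), "defaults entry")
  expect_error(resolve_timepoint(doc, "vid.mov", 3), "out of range")
})

test_that("three-layer overlay matches the brute-force merge oracle", {
  set.seed(8)
  for (i in 1:25) {
    pool <- full_item_meta()
    l1 <- pool[sample(names(pool), sample(3:10, 1))]
    l2 <- pool[sample(names(pool), sample(0:8, 1))]
    l2 <- lapply(l2, function(v) "overridden-by-video")
    l3 <- pool[sample(names(pool), sample(0:8, 1))]
    l3 <- lapply(l3, function(v) "overridden-by-timepoint")
    doc <- ifdo_document("s", generate_uuid(),
                         "https://hdl.handle.net/p/x", defaults = l1,
                         items = list(v.mov = list(
                           l2,
                           c(list(datetime = "2022-07-15T10:00:01.000Z"), l3))))
    got <- resolve_timepoint(doc, "v.mov", 1)
    want <- naive_merge(l1, l2,
                        c(list(datetime = "2022-07-15T10:00:01.000Z"), l3))
    expect_identical(got[order(names(got))], want[order(names(want))])
  }
})

test_that("one-element photo lists normalize to a single object", {
  txt <- paste(
    "image-set-header:",
    "  image-set-name: s",
    "  image-set-uuid: 9a1f8a29-2552-4c11-895b-051f7424d2d2",
    "  image-set-handle: https://hdl.handle.net/p/x",
    "image-set-items:",
    "  a.png:",
    "    - image-latitude: 1.5",
    sep = "\n")
  doc <- parse_ifdo(txt)
  expect_false(is.null(names(doc$items[["a.png"]])))  # a plain mapping now
  expect_identical(doc$items[["a.png"]]$latitude, 1.5)
})
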