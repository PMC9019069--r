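# Septum geometry: convex hull rasterisation against a brute-force
# half-plane oracle (see helper-geometry.R), septum extraction, candidate
# filtering, and the image/case decision rules.

test_that("convex hull mask equals the half-plane oracle on small masks", {
  # singletons and fixed-point rectangles
  single <- mask_from_points(23L)
  expect_identical(convex_hull_mask(single), single)
  rect <- matrix(FALSE, 8, 8); rect[3:6, 2:7] <- TRUE
  expect_identical(convex_hull_mask(rect), rect)
  expect_error(convex_hull_mask(matrix(FALSE, 8, 8)), "empty")

  # right triangle from the three pixels (0,0), (0,8), (8,0) on a 9x9 grid
  tri <- matrix(FALSE, 9, 9)
  tri[1, 1] <- tri[9, 1] <- tri[1, 9] <- TRUE
  got <- convex_hull_mask(tri)
  pts <- pts_of_mask(tri)
  oracle <- hull_oracle(pts, 9, 9)
  expect_identical(got, oracle)
  expect_true(all(got[cbind(c(1, 9, 1), c(1, 1, 9))]))

  # exhaustive: all 1- and 2-point masks, all 3-point masks
  for (i in 1:64) {
    m <- mask_from_points(i)
    expect_identical(convex_hull_mask(m), hull_oracle(pts_of_mask(m)))
  }
  pairs <- utils::combn(64, 2)
  for (p in seq_len(ncol(pairs))) {
    m <- mask_from_points(pairs[, p])
    if (!identical(convex_hull_mask(m), hull_oracle(pts_of_mask(m)))) {
      fail(sprintf("2-point mismatch at %s", paste(pairs[, p],
                                                   collapse = ",")))
    }
  }
  triples <- utils::combn(64, 3)
  bad <- 0
  for (p in seq_len(ncol(triples))) {
    m <- mask_from_points(triples[, p])
    if (!identical(convex_hull_mask(m), hull_oracle(pts_of_mask(m)))) {
      bad <- bad + 1
    }
  }
  expect_identical(bad, 0)
  # 4-point masks: fixed-seed sample of the 635,376-mask space
  set.seed(99)
  for (trial in 1:20000) {
    m <- mask_from_points(sample.int(64, 4))
    if (!identical(convex_hull_mask(m), hull_oracle(pts_of_mask(m)))) {
      bad <- bad + 1
    }
  }
  expect_identical(bad, 0)
})

test_that("hull output is always a superset of its input", {
  set.seed(17)
  for (trial in 1:50) {
    m <- matrix(runif(16 * 16) < 0.1, 16, 16)
    if (!any(m)) next
    h <- convex_hull_mask(m)
    expect_true(all(h[m]))
  }
})

test_that("septum extraction: rectangle fixture, monotonicity, disjointness", {
  m <- matrix(0L, 10, 40)
  m[1:10, 1:10] <- 1L   # LA = [0,10) x [0,10)
  m[1:10, 21:30] <- 2L  # RA = [20,30) x [0,10)
  s0 <- extract_septum(m, 0)
  expect_identical(sum(s0$mask), 100L) # the [10,20) x [0,10) gap
  expect_true(all(which(s0$mask, arr.ind = TRUE)[, 2] %in% 11:20))
  # disjoint from the chambers at radius 0
  expect_false(any(s0$mask & (m == 1L | m == 2L)))
  # dilation is monotone in the radius
  a_prev <- sum(s0$mask)
  for (r in c(1, 3, 6)) {
    a <- sum(extract_septum(m, r)$mask)
    expect_gte(a, a_prev)
    a_prev <- a
  }
  # missing chambers produce errors naming the chamber
  la_only <- m; la_only[la_only == 2L] <- 0L
  expect_error(extract_septum(la_only), "RA")
  ra_only <- m; ra_only[ra_only == 1L] <- 0L
  expect_error(extract_septum(ra_only), "LA")
})

test_that("candidate filtering matches the per-box pixel-count oracle", {
  m <- matrix(0L, 40, 40)
  m[11:30, 1:10] <- 1L
  m[11:30, 31:40] <- 2L
  septum <- extract_septum(m, 0) # band [10,30) x [10,30)
  boxes <- tibble::tibble(
    x0 = c(12, 0, 25, 8, 35), y0 = c(12, 0, 15, 18, 35),
    x1 = c(20, 6, 34, 13, 40), y1 = c(20, 6, 23, 23, 40),
    confidence = c(0.9, 0.8, 0.7, 0.6, 0.5))
  for (thr in c(0, 0.2, 0.5, 1)) {
    kept <- filter_candidates(boxes, septum, thr)
    want <- vapply(seq_len(nrow(boxes)), function(i)
      box_mask_overlap(boxes[i, ], septum$mask) >= thr, logical(1))
    expect_identical(kept$confidence, boxes$confidence[want])
  }
  # fully inside: retained for any threshold <= 1; disjoint: removed
  inside <- boxes[1, ]
  expect_identical(nrow(filter_candidates(inside, septum, 1)), 1L)
  disjoint <- boxes[5, ]
  expect_identical(nrow(filter_candidates(disjoint, septum, 0.01)), 0L)
  # empty candidate list passes through
  expect_identical(nrow(filter_candidates(boxes[0, ], septum, 0.2)), 0L)
})

test_that("image and case calls implement the >= cutoff decision rule", {
  empty <- tibble::tibble(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                          y1 = numeric(), confidence = numeric())
  expect_false(image_call(empty, 0.95)$positive)
  low <- tibble::tibble(x0 = 1, y0 = 1, x1 = 2, y1 = 2, confidence = 0.9432)
  expect_false(image_call(low, 0.95)$positive)
  at <- low; at$confidence <- 0.95
  expect_true(image_call(at, 0.95)$positive)

  mk_call <- function(pos) structure(list(positive = pos),
                                     class = "asd_image_call")
  expect_true(case_call(lapply(rep(TRUE, 4), mk_call), 0.6)$positive)
  expect_false(case_call(lapply(rep(FALSE, 4), mk_call), 0.6)$positive)
  # 3 of 5 positive at threshold 0.6: 0.6 >= 0.6 is positive
  calls <- lapply(c(TRUE, TRUE, TRUE, FALSE, FALSE), mk_call)
  expect_true(case_call(calls, 0.6)$positive)
  expect_error(case_call(list()), "at least one")
})
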