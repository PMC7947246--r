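test_that("find_extrema matches hand-derived examples", {
  # triangle on a zero baseline: prominence = amplitude = h, width = w/2
  x <- c(rep(0, 5), seq(0.25, 1, by = 0.25), seq(0.75, 0, by = -0.25), rep(0, 5))
  ex <- find_extrema(x)
  pk <- ex[ex$kind == "peak", ]
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$prominence, 1)
  expect_equal(pk$amplitude, 1)
  expect_equal(pk$contour_height, 0)
  expect_equal(pk$width_half_prom, pk$span / 2)

  ex2 <- find_extrema(c(0, 2, 1, 3, 0))
  expect_equal(ex2$kind, c("peak", "valley", "peak"))
  expect_equal(ex2$amplitude, c(2, -1, 3))
  expect_equal(ex2$prominence, c(1, 1, 3))

  expect_equal(nrow(find_extrema(seq_len(50))), 0L)

  # valley mirror of a peak: identical magnitudes, kind flips
  up <- c(0, 0.5, 2, 0.4, 0.1, 0)
  down <- -up
  p <- find_extrema(up); v <- find_extrema(down)
  expect_equal(p$kind, "peak"); expect_equal(v$kind, "valley")
  expect_equal(p[, -1], v[, -1])
})

test_that("plateau extrema locate at the first plateau sample", {
  x <- c(0, 1, 2, 2, 2, 1, 0)
  ex <- find_extrema(x)
  expect_equal(ex$location, 2)  # 0-based
  expect_equal(ex$prominence, 2)
})

test_that("measurements equal the brute-force contour oracle on random signals", {
  set.seed(21)
  got <- list(); want <- list()
  widths_impl <- c(); widths_oracle <- c(); spans <- c()
  for (trial in 1:200) {
    x <- round(rnorm(sample(10:60, 1)), 3)
    ex <- find_extrema(x)
    for (r in seq_len(nrow(ex))) {
      row <- ex[r, ]
      sig <- if (row$kind == "valley") -x else x
      i <- row$location + 1L
      o <- oracle_prominence(sig, i)
      got[[length(got) + 1L]] <- c(row$prominence, row$dist_left,
                                   row$dist_right, row$span)
      want[[length(want) + 1L]] <- c(o$prominence, i - o$left_base,
                                     o$right_base - i,
                                     o$right_base - o$left_base)
      if (trial <= 40) {
        widths_impl <- c(widths_impl, row$width_half_prom)
        widths_oracle <- c(widths_oracle, oracle_width(sig, i))
      }
      spans <- c(spans, row$span - row$width_half_prom)
    }
  }
  expect_gt(length(got), 500L)
  expect_equal(do.call(rbind, got), do.call(rbind, want))
  expect_equal(widths_impl, widths_oracle, tolerance = 5e-3)
  expect_true(all(spans >= -1e-9))
})

test_that("two-peak interaction bounds the smaller peak's base", {
  x <- c(0, 1, 0.5, 2, 0)
  ex <- find_extrema(x)
  small <- ex[ex$kind == "peak" & ex$amplitude == 1, ]
  expect_equal(small$dist_right, 1)        # P4 stopped by the higher peak side
  expect_equal(small$prominence, 0.5)      # down to the 0.5 saddle
})

test_that("select_eight follows the 3-before / 4-after rule with zero padding", {
  ex <- find_extrema(c(0, rep(c(1, 0), 10)))  # peaks at odd 0-based locations
  pk <- ex[ex$kind == "peak", ]
  expect_gte(nrow(pk), 8L)
  sel <- select_eight(ex, ref_offset = ex$location[7])
  expect_equal(sel$location, ex$location[4:11])

  one <- find_extrema(c(0, 1, 0))
  sel1 <- select_eight(one, ref_offset = 1)
  expect_equal(sel1$kind, c(rep("pad", 3), "peak", rep("pad", 4)))
  expect_true(all(as.matrix(sel1[sel1$kind == "pad", -1]) == 0))

  sel0 <- select_eight(find_extrema(1:10), ref_offset = 5)
  expect_equal(sel0$kind, rep("pad", 8))
})

test_that("feature matrix has the documented shape, order and determinism", {
  sp <- synth_params("RVOT", seed = 5)
  rec <- generate_record(sp)$record
  w <- cut_beats(denoise_record(rec))
  m <- build_feature_matrix(w$sr, w$pvc)
  expect_equal(dim(m), c(192L, 8L))
  expect_equal(rownames(m), auto_row_keys())
  expect_equal(colnames(m),
               c("location", "prominence", "dist_left", "dist_right",
                 "width_half_prom", "span", "amplitude", "contour_height"))
  expect_identical(m, build_feature_matrix(w$sr, w$pvc))

  zero <- make_window(list(), "SR")
  zero_pvc <- make_window(list(), "PVC")
  zero_pvc$beat_class <- "PVC"
  mz <- build_feature_matrix(zero, zero_pvc)
  expect_true(all(mz == 0))
})

test_that("span equals dist_left + dist_right for every non-pad descriptor", {
  sp <- synth_params("LVOT", seed = 9)
  rec <- generate_record(sp)$record
  w <- cut_beats(denoise_record(rec))
  m <- build_feature_matrix(w$sr, w$pvc)
  nonpad <- m[, "prominence"] > 0
  expect_true(any(nonpad))
  expect_equal(m[nonpad, "span"],
               m[nonpad, "dist_left"] + m[nonpad, "dist_right"])
})

test_that("the 2x2 toy expansion matches the hand enumeration", {
  m <- matrix(c(1, 3, 2, 4), nrow = 2,
              dimnames = list(c("r1", "r2"), c("a", "b")))
  v <- expand_ratio_features(m, parts = c("raw", "row_ratio", "col_ratio",
                                          "col_diff"), with_names = TRUE)
  expect_equal(unname(v[c("raw(r1.a)", "raw(r1.b)", "raw(r2.a)", "raw(r2.b)")]),
               c(1, 2, 3, 4))
  expect_equal(unname(v[c("ratio(r1.a, r1.b)", "ratio(r1.b, r1.a)",
                          "ratio(r2.a, r2.b)", "ratio(r2.b, r2.a)")]),
               c(1/2, 2/1, 3/4, 4/3))
  expect_equal(unname(v[c("ratio(r1.a, r2.a)", "ratio(r2.a, r1.a)",
                          "ratio(r1.b, r2.b)", "ratio(r2.b, r1.b)")]),
               c(1/3, 3/1, 2/4, 4/2))
  expect_equal(unname(v[c("diff(r1.a, r2.a)", "diff(r2.a, r1.a)",
                          "diff(r1.b, r2.b)", "diff(r2.b, r1.b)")]),
               c(-2, 2, -2, 2))
  expect_equal(length(v), 4 + 4 + 4 + 4)
})

test_that("zero denominators yield zero ratios, never non-finite values", {
  m <- matrix(c(1, 0, 2, 5), nrow = 2,
              dimnames = list(c("r1", "r2"), c("a", "b")))
  v <- expand_ratio_features(m, parts = c("raw", "row_ratio", "col_ratio"),
                             with_names = TRUE)
  expect_equal(unname(v["ratio(r1.a, r2.a)"]), 0)  # 1/0 -> 0
  expect_true(all(is.finite(v)))
})

test_that("full expansion has the documented constant length and grammar", {
  sp <- synth_params("RVOT", seed = 2)
  rec <- generate_record(sp)$record
  w <- cut_beats(denoise_record(rec))
  m <- build_feature_matrix(w$sr, w$pvc)
  v <- expand_ratio_features(m)
  expect_equal(length(v), 604416L)
  expect_true(all(is.finite(v)))
  nms <- expand_feature_names()
  expect_equal(length(nms), 604416L)
  # the study's reported top automated feature exists under the grammar
  expect_true("ratio(SR.V1.5.location, PVC.V1.5.dist_right)" %in% nms)
  expect_true("ratio(PVC.V1.5.prominence, PVC.V3.5.prominence)" %in% nms)
  expect_true("diff(PVC.V1.5.dist_left, SR.V1.5.dist_left)" %in% nms)
  # names are unique
  expect_false(anyDuplicated(nms) > 0)
})

test_that("feature extraction is location-equivariant", {
  set.seed(31)
  beat <- c(numeric(60), 0.2 * sin(seq(0, 3 * pi, length.out = 80)),
            1.5 * exp(-((seq_len(40) - 20) / 6)^2), numeric(250))
  shift <- 10L
  shifted <- c(numeric(shift), beat)[seq_along(beat)]
  a <- find_extrema(beat)
  b <- find_extrema(shifted)
  keep <- a$location < length(beat) - shift - 1
  expect_equal(b$location, a$location[keep] + shift)
  for (col in c("prominence", "dist_left", "dist_right", "width_half_prom",
                "span", "amplitude", "contour_height")) {
    expect_equal(b[[col]], a[[col]][keep], info = col)
  }
})
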