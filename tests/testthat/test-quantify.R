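test_that("microtubule density divides counts by cell width", {
  d <- microtubule_density(c(`2` = 30, `4` = 20, `6` = 10), cell_width = 5)
  expect_equal(unname(d), c(6, 4, 2))
  expect_equal(unname(microtubule_density(c(`2` = 0, `4` = 0, `6` = 0), 3)),
               c(0, 0, 0))
  expect_error(microtubule_density(c(`2` = 5), 0), "positive")
  expect_error(microtubule_density(c(`3` = 5), 2), "depth")
  # homogeneity of degree -1 in width
  expect_equal(microtubule_density(c(`2` = 12), 2),
               3 * microtubule_density(c(`2` = 12), 6))
})

test_that("aspect ratio is width over length", {
  expect_equal(aspect_ratio(5, 20), 0.25)
  expect_equal(aspect_ratio(7, 7), 1)
  expect_error(aspect_ratio(5, 0), "positive")
  expect_error(aspect_ratio(-1, 2), "positive")
  # homogeneity of degree -1 in length
  expect_equal(aspect_ratio(4, 10), 2 * aspect_ratio(4, 20))
})

test_that("line-scan intensity averages pixels inside a 2-um window", {
  img <- matrix(987, nrow = 40, ncol = 60)   # 4 x 6 um at 0.1 um/px
  expect_equal(line_scan_intensity(img, c(1, 3, 0, 4), 0.1), 987)
  # window half over a 100 region, half over a 300 region
  img2 <- cbind(matrix(100, 40, 30), matrix(300, 40, 30))
  expect_equal(line_scan_intensity(img2, c(2, 4, 0, 4), 0.1), 200)
  expect_error(line_scan_intensity(img, c(5, 7, 0, 4), 0.1), "outside")
  expect_error(line_scan_intensity(img, c(1, 2.5, 0, 4), 0.1), "2 um")
})

test_that("relative density is a background-free band-area ratio", {
  # identical bands over identical background
  x <- 0:499
  gauss <- function(c0, s, a) a / (s * sqrt(2 * pi)) * exp(-(x - c0)^2 / (2 * s^2))
  bg <- 20 + 0.05 * x
  y <- bg + gauss(120, 10, 800) + gauss(350, 10, 800)
  prof <- lane_profile(x, y, list(b1 = c(60, 180), b2 = c(290, 410)))
  expect_equal(lane_relative_density(lane_band(prof, "b1"),
                                     lane_band(prof, "b2")),
               1, tolerance = 1e-6)
  # doubled amplitude doubles the ratio
  y2 <- bg + gauss(120, 10, 1600) + gauss(350, 10, 800)
  prof2 <- lane_profile(x, y2, list(b1 = c(60, 180), b2 = c(290, 410)))
  expect_equal(lane_relative_density(lane_band(prof2, "b1"),
                                     lane_band(prof2, "b2")),
               2, tolerance = 1e-6)
  # analytic Gaussian areas: ratio of specified areas, any background
  y3 <- 100 + 0.2 * x + gauss(120, 8, 500) + gauss(350, 14, 1700)
  prof3 <- lane_profile(x, y3, list(t = c(60, 180), r = c(280, 420)))
  expect_equal(lane_relative_density(lane_band(prof3, "t"),
                                     lane_band(prof3, "r")),
               500 / 1700, tolerance = 1e-3)
  # global rescaling cancels
  prof4 <- lane_profile(x, 3.7 * y3, list(t = c(60, 180), r = c(280, 420)))
  expect_equal(lane_relative_density(lane_band(prof4, "t"),
                                     lane_band(prof4, "r")),
               lane_relative_density(lane_band(prof3, "t"),
                                     lane_band(prof3, "r")),
               tolerance = 1e-12)
})

test_that("lane profiles validate their band windows", {
  expect_error(lane_profile(0:9, rep(1, 10), list(a = c(2, 8), b = c(5, 9))),
               "overlap")
  expect_error(lane_profile(0:9, rep(1, 10), list(a = c(8, 2))), "range|invert")
  expect_error(lane_profile(0:9, rep(-1, 10)), "non-negative")
  expect_error(lane_relative_density(
    list(positions = 0:9, intensity = rep(1, 10), window = c(0, 9)),
    list(positions = 0:9, intensity = rep(1, 10), window = c(0, 9))),
    "reference")
})

test_that("delta-delta-Ct fold change inverts cycle differences", {
  rows <- expand.grid(sample_id = paste0("s", 1:6),
                      gene = c("GAPDH", "Fgfr1"),
                      stringsAsFactors = FALSE)
  rows$condition <- ifelse(rows$sample_id %in% paste0("s", 1:3),
                           "control", "treated")
  # identical Ct everywhere -> fold 1
  rows$ct <- 20
  tb <- ct_table(rows)
  expect_equal(ddct_fold_change(tb, "Fgfr1", "treated", "control"), 1)
  # treated dCt one cycle higher -> fold 0.5
  rows2 <- rows
  rows2$ct[rows2$gene == "Fgfr1" & rows2$condition == "treated"] <- 21
  tb2 <- ct_table(rows2)
  expect_equal(ddct_fold_change(tb2, "Fgfr1", "treated", "control"), 0.5)
  # treated dCt lower by log2(6) cycles -> fold 6
  rows3 <- rows
  rows3$ct[rows3$gene == "Fgfr1" & rows3$condition == "treated"] <- 20 - log2(6)
  tb3 <- ct_table(rows3)
  expect_equal(ddct_fold_change(tb3, "Fgfr1", "treated", "control"), 6,
               tolerance = 1e-12)
  # reciprocal property
  expect_equal(ddct_fold_change(tb3, "Fgfr1", "treated", "control") *
                 ddct_fold_change(tb3, "Fgfr1", "control", "treated"), 1,
               tolerance = 1e-12)
  expect_error(ddct_fold_change(tb3, "Nope", "treated", "control"), "Nope")
  expect_error(ddct_fold_change(tb3, "Fgfr1", "T3", "control"), "absent")
})

test_that("Ct tables require the reference gene in every sample", {
  rows <- data.frame(sample_id = c("s1", "s1", "s2"),
                     condition = "control",
                     gene = c("GAPDH", "Fgfr1", "Fgfr1"),
                     ct = c(20, 22, 22))
  expect_error(ct_table(rows), "missing for sample")
  rows$ct[1] <- 50
  expect_error(ct_table(rows), "0, 45")
})
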