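test_that("projected area is the pixel count scaled to cm2", {
  expect_equal(projected_area(root_mask(matrix(TRUE, 10, 10), 1)), 1.0)
  expect_equal(projected_area(root_mask(matrix(FALSE, 4, 4), 1)), 0)
  for (seed in 1:5) {
    m <- random_mask(seed, 20, 30, p = 0.3, pixel_size = 0.5)
    expect_equal(projected_area(m), sum(m$grid) * 0.5^2 / 100)
  }
})

test_that("span is half the maximum caliper width between pixel centres", {
  g <- matrix(FALSE, 3, 120)
  g[2, c(10, 110)] <- TRUE # two pixels 100 columns apart
  expect_equal(root_span(root_mask(g, 1)), 5.0)

  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_equal(root_span(root_mask(single, 1)), 0)

  expect_warning(s <- root_span(root_mask(matrix(FALSE, 3, 3), 1)))
  expect_true(is.na(s))
})

test_that("span equals the all-pairs brute-force oracle on random masks", {
  cases <- expand.grid(seed = 1:8, p = c(0.05, 0.3, 0.7))
  for (i in seq_len(nrow(cases))) {
    m <- random_mask(cases$seed[i] + 100 * i, 24, 24, p = cases$p[i],
                     pixel_size = 0.5)
    if (sum(m$grid) < 2) next
    expect_equal(root_span(m), oracle_max_feret(m) / 2 / 10)
  }
  # a dense case around 500 root pixels
  m <- random_mask(999, 36, 36, p = 0.4)
  expect_equal(root_span(m), oracle_max_feret(m) / 2 / 10)
})

test_that("symmetry matches its definition against brute-force extents", {
  for (seed in c(1:8, 21:24)) {
    m <- random_mask(seed, 24, 24, p = 0.25)
    if (sum(m$grid) < 3) next
    sym <- root_symmetry(m)
    # d1 must be the true maximum pairwise distance; the defining pair may
    # be tied on a pixel grid, so the reported symmetry must equal the
    # perpendicular-extent ratio of one of the maximizing pairs
    d1 <- oracle_max_feret(m)
    idx <- which(m$grid, arr.ind = TRUE)
    pts <- cbind((idx[, 2] - 1) * m$pixel_size, (idx[, 1] - 1) * m$pixel_size)
    d2mat <- as.matrix(stats::dist(pts))
    ties <- which(d2mat >= max(d2mat) - 1e-9, arr.ind = TRUE)
    valid_syms <- apply(ties, 1, function(k) {
      theta <- atan2(pts[k[2], 2] - pts[k[1], 2], pts[k[2], 1] - pts[k[1], 1])
      max(oracle_extent(m, theta + pi / 2), m$pixel_size) / max(d1, m$pixel_size)
    })
    expect_true(any(abs(sym - valid_syms) < 1e-10))
    # dense angle scan recovers the same maximum extent (to scan resolution)
    scan <- oracle_angle_scan(m, 3600)
    expect_equal(scan$d_max, d1, tolerance = 1e-5)
  }
})

test_that("symmetry hits its limiting values on canonical shapes", {
  # pixels on a circle: isotropic, symmetry ~ 1
  n <- 200
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  g <- matrix(FALSE, 81, 81)
  g[cbind(round(41 + 35 * sin(th)), round(41 + 35 * cos(th)))] <- TRUE
  expect_equal(root_symmetry(root_mask(g, 1)), 1, tolerance = 0.05)

  # collinear horizontal run of 100 pixels: one-pixel perpendicular extent
  g <- matrix(FALSE, 3, 102)
  g[2, 2:101] <- TRUE
  expect_equal(root_symmetry(root_mask(g, 1)), 1 / 99, tolerance = 1e-12)

  expect_warning(s <- root_symmetry(root_mask(matrix(c(TRUE, FALSE), 1, 2), 1)))
  expect_true(is.na(s))
})

test_that("phenotypes scale correctly with pixel size and tolerate rotation", {
  m1 <- random_mask(7, 30, 30, p = 0.3, pixel_size = 1)
  m2 <- root_mask(m1$grid, pixel_size = 2)
  expect_equal(root_span(m2), 2 * root_span(m1))
  expect_equal(projected_area(m2), 4 * projected_area(m1))
  expect_equal(root_symmetry(m2), root_symmetry(m1))

  rot <- root_mask(t(m1$grid)[ncol(m1$grid):1, ], pixel_size = 1)
  expect_equal(root_span(rot), root_span(m1), tolerance = 0.02)
  expect_equal(root_symmetry(rot), root_symmetry(m1), tolerance = 0.02)
})

test_that("phenotype_batch joins biomass by source id and validates inputs", {
  masks <- lapply(1:3, function(i) random_mask(i, 12, 12, p = 0.4))
  rec <- phenotype_batch(masks)
  expect_equal(nrow(rec), 3)
  expect_false("root_biomass_mg" %in% names(rec))

  biomass <- data.frame(source_id = "rand-2", root_biomass_mg = 31.5,
                        rh_condition = "75%")
  rec2 <- phenotype_batch(masks, biomass)
  expect_equal(sum(!is.na(rec2$root_biomass_mg)), 1)
  expect_equal(rec2$root_biomass_mg[rec2$source_id == "rand-2"], 31.5)

  expect_error(phenotype_batch(list(masks[[1]], masks[[1]])), "duplicate")
  expect_warning(
    phenotype_batch(masks, data.frame(source_id = "ghost", root_biomass_mg = 1)),
    "no mask"
  )
})

test_that("batch phenotypes recover the synthetic generator's ground truth", {
  specs <- lapply(c(5, 6), function(s) root_spec(seed = s, image_size = c(128, 128)))
  roots <- lapply(specs, generate_root_mask)
  rec <- phenotype_batch(lapply(roots, `[[`, "mask"))
  diag_cm <- sqrt(2) * 0.25 / 10
  for (i in seq_along(roots)) {
    expect_lt(abs(rec$span_cm[i] - roots[[i]]$true_span_cm), diag_cm)
    expect_equal(rec$projected_area_cm2[i], projected_area(roots[[i]]$mask))
  }
})
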