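test_that("centroid size matches the closed form and scales linearly", {
  # unit tetrahedron: centroid (1/4,1/4,1/4); sum of squared distances
  # = 3/16*3 + (9/16 + 1/16 + 1/16)*3 = 2.25, so CS = 1.5
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(centroid_size(tet), 1.5)
  set.seed(3)
  m <- matrix(rnorm(30), 10, 3)
  expect_equal(centroid_size(2 * m), 2 * centroid_size(m))
  expect_warning(cs0 <- centroid_size(matrix(1, 5, 3)), "degenerate")
  expect_equal(cs0, 0)
  cfg <- landmark_config("s", "sp", rbind(c(0, 0, 0), c(NA, NA, NA), c(1, 1, 1)))
  expect_error(centroid_size(cfg), "missing")
})

test_that("gpa is invariant to similarity transforms of its inputs", {
  arr <- noisy_array(seed = 11L)
  g1 <- gpa(arr)
  set.seed(12)
  arr2 <- arr
  for (i in seq_len(dim(arr)[3L])) arr2[, , i] <- similarity_transform(arr[, , i])
  g2 <- gpa(arr2)
  d1 <- dist(flatten_coords(g1))
  d2 <- dist(flatten_coords(g2))
  expect_lt(max(abs(d1 - d2)), 1e-8)
  # two identical configs under arbitrary similarity transforms align exactly
  set.seed(13)
  base <- matrix(rnorm(24), 8, 3)
  pair <- array(c(base, similarity_transform(base)), c(8, 3, 2))
  gp <- gpa(pair)
  expect_lt(procrustes_distance(gp$coords[, , 1L], gp$coords[, , 2L]), 1e-9)
})

test_that("gpa output satisfies its structural invariants", {
  arr <- noisy_array(n = 8L, seed = 21L)
  g <- gpa(arr)
  for (i in seq_len(8L)) {
    expect_lt(max(abs(colMeans(g$coords[, , i]))), 1e-9)
    expect_equal(sum(g$coords[, , i]^2), 1, tolerance = 1e-9)
  }
  expect_equal(g$consensus / sqrt(sum(g$consensus^2)),
               {
                 cm <- apply(g$coords, c(1, 2), mean)
                 cm <- scale(cm, scale = FALSE)
                 cm / sqrt(sum(cm^2))
               }, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(g$converged)
  # log centroid size is computed before scaling, from the raw coordinates
  expect_equal(g$log_centroid_size,
               log(apply(arr, 3L, centroid_size)), tolerance = 1e-12)
})

test_that("procrustes residual sum of squares descends across gpa iterations", {
  arr <- noisy_array(n = 10L, sd = 0.5, seed = 31L)
  total_ss <- function(maxit) {
    g <- suppressWarnings(gpa(arr, max_iter = maxit))
    sum(apply(g$coords, 3L, function(m) sum((m - g$consensus)^2)))
  }
  ss <- vapply(1:4, total_ss, 0)
  expect_true(all(diff(ss) <= 1e-12))
})

test_that("planar triangle alignment matches a brute-force rotation search", {
  # 2D triangles embedded in 3D: the optimal rotation minimizing squared
  # distance to a reference is found by a fine grid over the in-plane angle
  set.seed(41)
  ref <- cbind(matrix(rnorm(6), 3, 2), 0)
  ref <- scale(ref, scale = FALSE); ref <- ref / sqrt(sum(ref^2))
  target <- cbind(matrix(rnorm(6), 3, 2), 0)
  target <- scale(target, scale = FALSE); target <- target / sqrt(sum(target^2))
  rot2 <- function(th) rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  grid <- seq(0, 2 * pi, length.out = 100000L)
  # a 3D rotation can also realize an in-plane mirror (rotation by pi about
  # an in-plane axis), so the brute force searches both sheets
  mirrored <- target %*% diag(c(1, -1, -1))
  ssd <- vapply(grid, function(th)
    min(sum((target %*% rot2(th) - ref)^2),
        sum((mirrored %*% rot2(th) - ref)^2)), 0)
  best <- min(ssd)
  aligned <- target %*% craniomorph:::rotation_onto(target, ref)
  expect_equal(sum((aligned - ref)^2), best, tolerance = 1e-3)
})

test_that("procrustes distance is a metric on aligned shapes", {
  arr <- noisy_array(n = 9L, seed = 51L)
  g <- gpa(arr)
  Y <- flatten_coords(g)
  expect_equal(procrustes_distance(Y[1L, ], Y[1L, ]), 0)
  set.seed(52)
  for (r in 1:100) {
    ijk <- sample(9L, 3L)
    dij <- procrustes_distance(Y[ijk[1L], ], Y[ijk[2L], ])
    dji <- procrustes_distance(Y[ijk[2L], ], Y[ijk[1L], ])
    dik <- procrustes_distance(Y[ijk[1L], ], Y[ijk[3L], ])
    dkj <- procrustes_distance(Y[ijk[3L], ], Y[ijk[2L], ])
    expect_equal(dij, dji)
    expect_lte(dij, dik + dkj + 1e-12)
  }
  expect_error(procrustes_distance(Y[1L, ], Y[1L, 1:6]), "mismatch")
})

test_that("thin-plate spline estimation reproduces affine maps exactly", {
  tpl <- cranium_template()
  A <- matrix(c(1.2, 0.1, 0, -0.05, 0.9, 0.02, 0, 0.1, 1.1), 3L, 3L)
  ref <- landmark_config("ref", "sp", tpl$coords, tpl$labels)
  warped <- tpl$coords %*% A + matrix(c(5, -3, 2), 53L, 3L, byrow = TRUE)
  target <- landmark_config("t", "sp", warped, tpl$labels)
  target$coords[c(7L, 30L), ] <- NA_real_
  target$missing[c(7L, 30L)] <- TRUE
  est <- estimate_missing_tps(target, ref)
  expect_false(any(est$missing))
  expect_equal(est$estimated, c(7L, 30L))
  expect_equal(est$coords[c(7L, 30L), ], warped[c(7L, 30L), ], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("tps recovery error is of the order of the added noise", {
  tpl <- cranium_template()
  set.seed(61)
  sigma <- 0.5  # mm
  errs <- vapply(1:20, function(r) {
    noisy <- tpl$coords + matrix(rnorm(159L, sd = sigma), 53L, 3L)
    cfg <- landmark_config(paste0("s", r), "sp", noisy, tpl$labels)
    truth <- cfg$coords[25L, ]
    cfg$coords[25L, ] <- NA_real_; cfg$missing[25L] <- TRUE
    est <- estimate_missing_tps(cfg, landmark_config("ref", "sp", tpl$coords, tpl$labels))
    sqrt(sum((est$coords[25L, ] - truth)^2))
  }, 0)
  expect_lt(mean(errs), 10 * sigma)
  expect_gt(mean(errs), 0.1 * sigma)
})

test_that("tps requires enough non-coplanar anchors", {
  expect_error(tps3d(matrix(rnorm(9), 3L, 3L), matrix(rnorm(9), 3L, 3L)),
               "at least 4")
  flat <- cbind(matrix(rnorm(10), 5L, 2L), 0)
  expect_error(tps3d(flat, flat + 1), "coplanar")
})

test_that("symmetric subset drops landmarks 23-44 and keeps order", {
  tpl <- cranium_template()
  cfg <- landmark_config("s", "sp", tpl$coords, tpl$labels)
  sub <- symmetric_subset(cfg)
  expect_equal(nrow(sub$coords), 31L)
  expect_identical(sub$landmark_labels, tpl$labels[c(1:22, 45:53)])
  expect_false(any(grepl("_l$", sub$landmark_labels)))
  small <- landmark_config("s", "sp", tpl$coords[1:10, ], tpl$labels[1:10])
  expect_error(symmetric_subset(small), "53")
})

test_that("facial length is the 5-13 over 5-52 distance ratio, scale-free", {
  m <- matrix(0, 53L, 3L)
  m[, 1L] <- seq_len(53L)  # collinear but distinct
  m[5L, ] <- c(0, 0, 0); m[13L, ] <- c(30, 0, 0); m[52L, ] <- c(0, 60, 0)
  cfg <- landmark_config("s", "sp", m)
  expect_equal(facial_length(cfg), 0.5)
  cfg3 <- landmark_config("s", "sp", 3 * m)
  expect_equal(facial_length(cfg3), 0.5)
  cfg$coords[13L, ] <- NA_real_; cfg$missing[13L] <- TRUE
  expect_error(facial_length(cfg), "missing")
})
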