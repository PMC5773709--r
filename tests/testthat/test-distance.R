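test_that("weighted distance matches hand-evaluated cases", {
  a <- make_summary("a", c(0, 0, 0), c(1, 1, 1))
  expect_equal(weighted_distance(a, a), 0)

  b <- make_summary("b", c(2, 0, 0), c(1, 1, 1))
  expect_equal(weighted_distance(a, b), 2)
  expect_equal(weighted_distance(b, a), 2)

  # Weight is the geometric mean of the spreads: sqrt(sqrt(4*4) * 2^2) = 4.
  a4 <- make_summary("a", c(0, 0, 0), c(4, 1, 1))
  b4 <- make_summary("b", c(2, 0, 0), c(4, 1, 1))
  expect_equal(weighted_distance(a4, b4), 4)

  # Zero spread on an axis drops that axis's term.
  az <- make_summary("a", c(0, 0, 0), c(0, 1, 1))
  bz <- make_summary("b", c(5, 0, 3), c(2, 1, 1))
  expect_equal(weighted_distance(az, bz), 3)
})

test_that("eigen-angle factor uses rank matching and absolute cosines", {
  a <- make_summary("a", c(0, 0, 0), c(1, 1, 1))
  expect_equal(angle_factor(a, a)$Theta, 0)

  # Eigenbases differing by a 45-degree rotation about the third eigenvector.
  b <- make_summary("b", c(0, 0, 0), c(1, 1, 1), eigvecs = rot_z(pi / 4))
  af <- angle_factor(a, b)
  expect_equal(af$theta, c(pi / 4, pi / 4, 0))
  expect_equal(af$Theta, pi / 2)
  expect_equal(angle_factor(b, a)$Theta, af$Theta)

  # Sign flips are immaterial.
  flip <- make_summary("f", c(0, 0, 0), c(1, 1, 1), eigvecs = -diag(3))
  expect_equal(angle_factor(a, flip)$Theta, 0)

  # Degenerate flat cloud: defined as zero, with a warning.
  z <- make_summary("z", c(0, 0, 0), c(0, 0, 0))
  expect_warning(th <- angle_factor(a, z)$Theta, "zero-variance")
  expect_equal(th, 0)
})

test_that("combined distance is the literal product d * Theta", {
  a <- make_summary("a", c(0, 0, 0), c(1, 1, 1))
  expect_equal(combined_distance(a, a), 0)

  b <- make_summary("b", c(2, 0, 0), c(1, 1, 1), eigvecs = rot_z(pi / 4))
  expect_equal(combined_distance(a, b), 2 * pi / 2)

  # Documented degeneracy: distinct centroids, identical orientation -> D = 0.
  cooriented <- make_summary("c", c(9, 9, 9), c(1, 1, 1))
  expect_gt(weighted_distance(a, cooriented), 0)
  expect_equal(combined_distance(a, cooriented), 0)
})

test_that("matrix assembly matches a brute-force pairwise loop", {
  set.seed(30)
  sums <- lapply(1:3, function(i) {
    make_summary(paste0("g", i), rnorm(3), runif(3, 0.5, 2),
                 eigvecs = qr.Q(qr(matrix(rnorm(9), 3))))
  })
  dm <- build_distance_matrix(sums, mode = "D")
  for (i in 1:3) for (j in 1:3) {
    expected <- if (i == j) 0 else combined_distance(sums[[i]], sums[[j]])
    expect_equal(dm$values[i, j], expected)
  }

  two <- build_distance_matrix(list(sums[[1]],
                                    make_summary("g2", sums[[1]]$centroid,
                                                 sums[[1]]$sigma,
                                                 sums[[1]]$eigvecs)))
  expect_equal(unname(two$values), matrix(0, 2, 2))

  expect_error(build_distance_matrix(list(sums[[1]], sums[[1]])), "duplicate")

  # mode d keeps centroid separation that mode D collapses for co-oriented clouds.
  a <- make_summary("a", c(0, 0, 0), c(1, 1, 1))
  b <- make_summary("b", c(3, 0, 0), c(1, 1, 1))
  expect_gt(build_distance_matrix(list(a, b), mode = "d")$values[1, 2], 0)
  expect_equal(build_distance_matrix(list(a, b), mode = "D")$values[1, 2], 0)
})

test_that("matrices are symmetric with zero diagonal and Theta is bounded", {
  set.seed(77)
  for (rep in 1:5) {
    sums <- lapply(1:4, function(i) {
      make_summary(paste0("g", i), rnorm(3, sd = 10), runif(3, 0, 3),
                   eigvecs = qr.Q(qr(matrix(rnorm(9), 3))))
    })
    dm <- build_distance_matrix(sums, mode = sample(c("d", "D"), 1))
    expect_equal(dm$values, t(dm$values))
    expect_equal(unname(diag(dm$values)), rep(0, 4))
    expect_true(all(dm$values >= 0))
    for (i in 1:3) for (j in (i + 1):4) {
      th <- angle_factor(sums[[i]], sums[[j]])$Theta
      expect_gte(th, 0)
      expect_lte(th, 3 * pi / 2 + 1e-12)
    }
  }
})

test_that("d grows monotonically with centroid displacement at fixed spread", {
  base <- make_summary("a", c(0, 0, 0), c(1.5, 1, 2))
  deltas <- c(0.5, 1, 2, 5, 10)
  ds <- vapply(deltas, function(dx) {
    weighted_distance(base, make_summary("b", c(dx, 0, 0), c(1.5, 1, 2)))
  }, 0)
  expect_true(all(diff(ds) > 0))
})

test_that("PHYLIP files round-trip in both dialects", {
  set.seed(41)
  sums <- lapply(1:5, function(i) {
    make_summary(paste0("taxon_", i), rnorm(3, sd = 5), runif(3, 0.5, 2),
                 eigvecs = qr.Q(qr(matrix(rnorm(9), 3))))
  })
  dm <- build_distance_matrix(sums, mode = "D")
  for (dialect in c("strict", "relaxed")) {
    p <- tempfile(fileext = ".phy")
    write_phylip(dm, p, dialect = dialect)
    back <- read_phylip(p)
    expect_equal(back$labels, dm$labels)
    expect_equal(back$values, dm$values, tolerance = 1e-5, ignore_attr = TRUE)
  }
  # Strict dialect: first line is the taxon count, names padded to 10 chars.
  p <- tempfile(fileext = ".phy")
  write_phylip(dm, p, dialect = "strict")
  lines <- readLines(p)
  expect_equal(as.integer(trimws(lines[1])), 5L)
  expect_equal(substr(lines[2], 1, 10), formatC("taxon_1", width = 10, flag = "-"))

  clash <- dm
  clash$labels <- paste0("longsharedprefix_", 1:5)
  dimnames(clash$values) <- list(clash$labels, clash$labels)
  expect_error(write_phylip(clash, p, dialect = "strict"), "collision")
})

test_that("exported matrices drive an independent tree builder", {
  set.seed(52)
  sums <- lapply(1:5, function(i) {
    make_summary(paste0("t", i), rnorm(3, sd = 5), runif(3, 0.5, 2),
                 eigvecs = qr.Q(qr(matrix(rnorm(9), 3))))
  })
  dm <- build_distance_matrix(sums, mode = "d")
  p <- tempfile(fileext = ".phy")
  write_phylip(dm, p, dialect = "relaxed")
  back <- read_phylip(p)
  ref <- ape::nj(as.dist(as.matrix(back)))
  expect_s3_class(ref, "phylo")
  expect_setequal(ref$tip.label, dm$labels)
})
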