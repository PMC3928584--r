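test_that("branch length sums 3D segment lengths", {
  expect_equal(branchLength(makeBranch(c(0, 3), c(0, 4), c(0, 0))), 5)
  stair <- makeBranch(c(0, 1, 1, 2, 2), c(0, 0, 1, 1, 2), rep(0, 5))
  expect_equal(branchLength(stair), 4)
  # brute-force per-segment recomputation on a random branch
  set.seed(42)
  pts <- matrix(rnorm(30), ncol = 3)
  b <- makeBranch(pts[, 1], pts[, 2], pts[, 3])
  expect_equal(branchLength(b),
               sum(sqrt(rowSums((pts[-1, ] - pts[-10, ])^2))))
})

test_that("DM tortuosity is path over chord and >= 1", {
  expect_equal(dmTortuosity(makeBranch(c(0, 1, 2), c(0, 0, 0), c(0, 0, 0))), 1)
  expect_equal(dmTortuosity(makeBranch(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0))),
               2 / sqrt(2))
  for (seed in 1:20) {
    set.seed(seed)
    pts <- matrix(rnorm(24), ncol = 3)
    expect_gte(dmTortuosity(makeBranch(pts[, 1], pts[, 2], pts[, 3])), 1)
  }
  loop <- makeBranch(c(0, 1, 0), c(0, 1, 0), c(0, 0, 0))
  expect_warning(v <- dmTortuosity(loop), "coincide")
  expect_true(is.na(v))
})

test_that("SOAM matches hand-derived closed forms", {
  # collinear: zero total curvature
  col <- makeBranch(0:5, rep(0, 6), rep(0, 6))
  expect_equal(as.numeric(soamTortuosity(col)), 0, tolerance = 1e-8)

  # planar U-shape: one combined angle with IP = pi/2, TP = 0, length 3
  u <- makeBranch(c(0, 1, 1, 0), c(0, 0, 1, 1), rep(0, 4))
  s <- soamTortuosity(u, details = TRUE)
  expect_equal(attr(s, "IP"), pi / 2)
  expect_equal(attr(s, "TP"), 0)
  expect_equal(as.numeric(s), pi / 6)

  # uniform x2 scaling halves SOAM (angles invariant, length doubles)
  u2 <- makeBranch(2 * c(0, 1, 1, 0), 2 * c(0, 0, 1, 1), rep(0, 4))
  expect_equal(as.numeric(soamTortuosity(u2)), pi / 12)

  # fewer than 4 points: no combined angle is defined
  short <- makeBranch(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0))
  expect_identical(as.numeric(soamTortuosity(short)), 0)
  expect_true(attr(soamTortuosity(short), "tooShort"))
})

test_that("SOAM angle domains and rigid-motion invariance hold", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:12, 1)
    pts <- apply(matrix(rnorm(3 * n), ncol = 3), 2, cumsum)
    b <- makeBranch(pts[, 1], pts[, 2], pts[, 3])
    s <- soamTortuosity(b, details = TRUE)
    expect_true(all(attr(s, "IP") >= 0 & attr(s, "IP") <= pi))
    expect_true(all(attr(s, "TP") >= 0 & attr(s, "TP") <= pi))
    expect_gte(as.numeric(s), 0)

    # random rotation + translation leaves SOAM unchanged
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    rot <- pts %*% q + matrix(rnorm(3), n, 3, byrow = TRUE)
    br <- makeBranch(rot[, 1], rot[, 2], rot[, 3])
    expect_equal(as.numeric(soamTortuosity(br)), as.numeric(s),
                 tolerance = 1e-9)
    # inverse proportionality to uniform scale
    b3 <- makeBranch(3 * pts[, 1], 3 * pts[, 2], 3 * pts[, 3])
    expect_equal(as.numeric(soamTortuosity(b3)), as.numeric(s) / 3,
                 tolerance = 1e-9)
  }
})

test_that("tapering is the OLS slope of diameter on arc length", {
  const <- makeBranch(0:10, rep(0, 11), rep(0, 11), radius = rep(0.5, 11))
  tp <- tapering(const)
  expect_equal(tp$taperSlope, 0)
  expect_equal(tp$meanDiameter, 1)
  expect_equal(tp$diameterSEM, 0)

  # diameter falling linearly 2 -> 1 over 10 um at 11 uniform points
  lin <- makeBranch(0:10, rep(0, 11), rep(0, 11),
                    radius = (2 - 0.1 * (0:10)) / 2)
  tp <- tapering(lin)
  expect_equal(tp$taperSlope, -0.1)
  expect_equal(tp$meanDiameter, 1.5)

  # brute-force normal equations oracle on random diameters
  for (seed in 1:10) {
    set.seed(seed)
    r <- runif(8, 0.2, 1.5)
    x <- cumsum(runif(8, 0.5, 2)); x[1] <- 0
    b <- makeBranch(cumsum(c(0, diff(x))), rep(0, 8), rep(0, 8), radius = r)
    s <- cumsum(c(0, abs(diff(x))))
    X <- cbind(1, s)
    beta <- solve(t(X) %*% X, t(X) %*% (2 * r))
    expect_equal(tapering(b)$taperSlope, beta[2], tolerance = 1e-10)
  }
})

test_that("soma distances obey path >= Euclidean with exact Y-tree values", {
  forest <- branchForest(makeFixture(fixtureSpec("ytree", branchLength = 50)))
  root <- getBranch(forest, 1L)
  d <- somaDistances(root, forest)
  expect_equal(d$euclideanToSoma, 0)
  expect_equal(d$pathToSoma, 0)
  for (k in 2:3) {
    d <- somaDistances(getBranch(forest, k), forest)
    expect_equal(d$euclideanToSoma, 50)  # straight stem of 50 um
    expect_equal(d$pathToSoma, 50)
  }
  # meandering stem: path exceeds Euclidean on every branch
  forest <- branchForest(makeFixture(fixtureSpec("btree", depth = 3,
                                                 wiggle = 4)))
  met <- branchMetrics(forest)
  expect_true(all(met$pathToSoma >= met$euclideanToSoma - 1e-9))
})

test_that("branchMetrics assembles one coherent row per branch", {
  forest <- branchForest(makeFixture(fixtureSpec("btree", depth = 3L)))
  met <- branchMetrics(forest)
  expect_identical(nrow(met), 7L)
  expect_identical(met$firstName, 1:7)
  expect_true(all(met$length > 0))
  expect_true(all(met$dm >= 1))
  expect_true(all(met$soam >= 0))
  expect_equal(met$length, rep(50, 7), tolerance = 1e-9)
})
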