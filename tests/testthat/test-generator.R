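test_that("fixture factory realizes the planned topology exactly", {
  chain <- makeFixture(fixtureSpec("chain", branchLength = 100))
  fc <- branchForest(chain)
  expect_length(branches(fc), 1L)
  met <- branchMetrics(fc)
  expect_equal(met$length, 100)
  expect_equal(met$dm, 1)
  expect_equal(met$soam, 0, tolerance = 1e-6)

  bt <- branchForest(makeFixture(fixtureSpec("btree", depth = 3)))
  expect_length(branches(bt), 7L)
  expect_identical(max(vapply(branches(bt), slot, integer(1),
                              "strahlerOrder")), 3L)
  # identical specs give identical reconstructions; the znoise = 0 spec is
  # the exact noise-free twin
  a <- makeFixture(fixtureSpec("btree", depth = 3, znoise = 2, seed = 4))
  b <- makeFixture(fixtureSpec("btree", depth = 3, znoise = 2, seed = 4))
  expect_identical(records(a), records(b))
  tw <- makeFixture(fixtureSpec("btree", depth = 3, znoise = 0, seed = 4))
  expect_identical(records(a)[c("x", "y", "radius")],
                   records(tw)[c("x", "y", "radius")])
})

test_that("model fitting records per-order distributions and branch probabilities", {
  tab <- verticalCompress(branchForest(makeFixture(fixtureSpec("ytree"))))
  mod <- fitMorphometryModel(tab)
  expect_identical(mod@maxOrder, 2L)
  expect_identical(mod@nBranches, 3L)
  expect_equal(mod@orders[[1]]$branchProb, 1)
  expect_equal(mod@orders[[2]]$branchProb, 0)

  single <- verticalCompress(branchForest(makeFixture(fixtureSpec("chain"))))
  m1 <- fitMorphometryModel(single)
  expect_identical(m1@maxOrder, 1L)
  expect_error(fitMorphometryModel(list()), "no branch tables")
})

test_that("virtual neurons are valid, deterministic, and respect the cap", {
  tabs <- lapply(1:3, function(i) verticalCompress(branchForest(
    makeFixture(fixtureSpec("btree", depth = 4, wiggle = 2,
                            branchLength = 35 + 5 * i, seed = i)))))
  mod <- fitMorphometryModel(tabs)

  vn <- generateVirtualNeuron(mod, growthConfig(seed = 5))
  expect_identical(nrow(validateReconstruction(vn)), 0L)
  vn2 <- generateVirtualNeuron(mod, growthConfig(seed = 5))
  expect_identical(records(vn), records(vn2))
  # ... and byte-identical after writing
  f1 <- tempfile(); f2 <- tempfile()
  writeSWC(vn, f1); writeSWC(vn2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # branching probability zero at order 1 forces single-branch trees
  m0 <- mod
  m0@orders[[1]]$branchProb <- 0
  solo <- generateVirtualNeuron(m0, growthConfig(seed = 1, nTrees = 2))
  expect_length(branches(branchForest(solo)), 2L)

  expect_warning(
    generateVirtualNeuron(mod, growthConfig(seed = 2, maxBranches = 3L)),
    "truncated")
})

test_that("generated populations recover the model's length distributions", {
  tabs <- lapply(1:3, function(i) verticalCompress(branchForest(
    makeFixture(fixtureSpec("btree", depth = 4, wiggle = 2,
                            branchLength = 35 + 5 * i, seed = i)))))
  mod <- fitMorphometryModel(tabs)
  pop <- lapply(1:100, function(i)
    generateVirtualNeuron(mod, growthConfig(seed = 1000L + i)))
  expect_true(all(vapply(pop, function(v)
    nrow(validateReconstruction(v)) == 0L, logical(1))))

  met <- do.call(rbind, lapply(pop, function(v) {
    m <- branchMetrics(branchForest(v))
    m[c("centrifugalOrder", "length")]
  }))
  for (o in seq_len(mod@maxOrder)) {
    ref <- mod@orders[[o]]$length
    got <- met$length[met$centrifugalOrder == o]
    expect_gt(length(got), 20L)
    D <- ksStat(ref, got)
    expect_lt(D, ksCrit01(length(ref), length(got)))
    # cross-check the hand-rolled KS statistic against stats::ks.test
    expect_equal(D, unname(suppressWarnings(
      stats::ks.test(ref, got)$statistic)), tolerance = 1e-12)
  }
})

test_that("model JSON round-trips through write/read", {
  tabs <- verticalCompress(branchForest(makeFixture(
    fixtureSpec("btree", depth = 3, wiggle = 1))))
  mod <- fitMorphometryModel(tabs)
  tf <- tempfile(fileext = ".json")
  writeMorphometryModel(mod, tf)
  back <- readMorphometryModel(tf)
  expect_identical(back@maxOrder, mod@maxOrder)
  expect_identical(back@nBranches, mod@nBranches)
  for (o in seq_len(mod@maxOrder))
    expect_equal(back@orders[[o]], mod@orders[[o]])
  # the restored model drives the generator to the same neuron (equal to
  # the JSON serialization precision)
  g1 <- generateVirtualNeuron(mod, growthConfig(seed = 3))
  g2 <- generateVirtualNeuron(back, growthConfig(seed = 3))
  expect_equal(records(g1), records(g2), tolerance = 1e-12)
})
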