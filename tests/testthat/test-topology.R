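test_that("an unbranched chain is a single branch", {
  rec <- readSWC(writeSWCText(c("1 1 0 0 0 1 -1", "2 3 1 0 0 0.5 1",
                                "3 3 2 0 0 0.5 2", "4 3 3 0 0 0.5 3")))
  forest <- branchForest(rec)
  expect_length(branches(forest), 1L)
  b <- getBranch(forest, 1L)
  expect_identical(nrow(b@points) - 1L, 3L)
  expect_identical(b@fullName, 1L)
  expect_identical(b@centrifugalOrder, 1L)
  expect_identical(b@strahlerOrder, 1L)
})

test_that("a Y-tree decomposes into stem and two daughters", {
  # root soma, stem of 2 segments, then a bifurcation into 2 single-segment
  # daughters (hand enumeration of the three chain rules)
  rec <- readSWC(writeSWCText(c(
    "1 1 0 0 0 1 -1", "2 3 0 1 0 0.5 1", "3 3 0 2 0 0.5 2",
    "4 3 -1 3 0 0.4 3", "5 3 1 3 0 0.4 3")))
  forest <- branchForest(rec)
  expect_length(branches(forest), 3L)
  segs <- vapply(branches(forest), function(b) nrow(b@points) - 1L, integer(1))
  expect_identical(sort(segs), c(1L, 1L, 2L))
  stem <- getBranch(forest, 1L)
  expect_identical(stem@daughterBranches, c(2L, 3L))
  expect_identical(getBranch(forest, 2L)@fullName, c(1L, 2L))
  expect_identical(getBranch(forest, 3L)@fullName, c(1L, 3L))
  expect_identical(vapply(branches(forest), slot, integer(1), "strahlerOrder"),
                   c(2L, 1L, 1L))
  expect_identical(vapply(branches(forest), slot, integer(1), "centrifugalOrder"),
                   c(1L, 2L, 2L))
})

test_that("a structure-flag change forces a branch boundary", {
  rec <- readSWC(writeSWCText(c(
    "1 1 0 0 0 1 -1", "2 3 0 1 0 0.5 1", "3 3 0 2 0 0.5 2",
    "4 4 0 3 0 0.5 3", "5 4 0 4 0 0.5 4")))
  forest <- branchForest(rec)
  expect_length(branches(forest), 2L)
  expect_identical(vapply(branches(forest), slot, integer(1), "flag"),
                   c(3L, 4L))
  # the apical continuation is a daughter of the basal branch
  expect_identical(getBranch(forest, 2L)@parentBranch, 1L)
})

test_that("branch identification refuses inconsistent reconstructions", {
  bad <- SWCReconstruction(data.frame(index = c(1L, 2L), flag = c(1L, 3L),
                                      x = c(0, 0), y = c(0, 0), z = c(0, 0),
                                      radius = 0.5, parent = c(-1L, 1L)))
  expect_error(identifyBranches(bad), "validation findings")
})

test_that("full names have the prefix property and match depth", {
  forest <- branchForest(makeFixture(fixtureSpec("btree", depth = 4L)))
  expect_length(branches(forest), 15L)
  for (b in branches(forest)) {
    expect_identical(b@centrifugalOrder, length(b@fullName))
    if (!is.na(b@parentBranch)) {
      parent <- getBranch(forest, b@parentBranch)
      expect_identical(b@fullName, c(parent@fullName, b@firstName))
    } else {
      expect_identical(b@fullName, b@firstName)
    }
  }
  expect_identical(max(vapply(branches(forest), slot, integer(1),
                              "centrifugalOrder")), 4L)
})

test_that("Strahler continuation rule keeps the larger daughter order", {
  # stem -> (leaf, sub-Y): daughters have orders {1, 2}, stem continues at 2
  lines <- c("1 1 0 0 0 1 -1", "2 3 0 1 0 0.5 1",
             "3 3 -1 2 0 0.5 2",                    # leaf daughter
             "4 3 1 2 0 0.5 2",                     # sub-Y stem
             "5 3 0.5 3 0 0.5 4", "6 3 1.5 3 0 0.5 4")
  forest <- branchForest(readSWC(writeSWCText(lines)))
  ord <- vapply(branches(forest), slot, integer(1), "strahlerOrder")
  names(ord) <- vapply(branches(forest), function(b)
    paste(sort(b@pointIndices[-1L]), collapse = ","), character(1))
  expect_identical(unname(ord[names(ord) == "2"]), 2L)  # stem
  expect_identical(unname(ord[names(ord) == "4"]), 2L)  # sub-Y stem
  expect_identical(max(ord), 2L)
})

test_that("assignFullNames detects cycles in corrupt genealogies", {
  b1 <- makeBranch(c(0, 1), c(0, 0), c(0, 0))
  b2 <- makeBranch(c(1, 2), c(0, 0), c(0, 0))
  b1@parentBranch <- 2L
  b2@firstName <- 2L; b2@parentBranch <- 1L
  forest <- new("BranchForest", branches = list(b1, b2), roots = integer(),
                somaPoint = c(0, 0, 0))
  expect_error(assignFullNames(forest), "cycle")
})

test_that("decomposition and Strahler orders match the brute-force oracle", {
  for (seed in 1:200) {
    rec <- randomReconstruction(5L + (seed * 13L) %% 96L, seed = seed)
    forest <- branchForest(rec)
    keys <- forestKeys(forest)
    oracle <- oracleBranches(rec)
    expect_setequal(keys, names(oracle))
    oStr <- oracleStrahler(rec)
    pStr <- stats::setNames(vapply(branches(forest), slot, integer(1),
                                   "strahlerOrder"), keys)
    expect_identical(pStr[names(oStr)], oStr)

    # partition property: every non-soma segment in exactly one branch
    segTotal <- sum(vapply(branches(forest), function(b)
      nrow(b@points) - 1L, integer(1)))
    df <- records(rec)
    expect_identical(segTotal, sum(df$parent != -1L & df$flag != 1L))

    # Strahler monotonicity and terminal-count bound
    ords <- vapply(branches(forest), slot, integer(1), "strahlerOrder")
    for (b in branches(forest))
      if (length(b@daughterBranches))
        expect_true(b@strahlerOrder >= max(ords[b@daughterBranches]))
    nTerm <- sum(vapply(branches(forest), function(b)
      length(b@daughterBranches) == 0L, logical(1)))
    expect_lte(max(ords), ceiling(log2(nTerm)) + 1L)
  }
})
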