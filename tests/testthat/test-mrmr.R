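test_that("relevance dominates and exact duplicates are penalised", {
  set.seed(1)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(8 * n), 8, n,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:n)))
  X["f3", ] <- y * 2 + rnorm(n, 0, 0.3)
  ord <- mrmrRank(X, y, listLength = 8)
  expect_equal(ord[1], "f3")

  # a duplicate of the winner carries maximal redundancy, so a comparably
  # relevant but independent feature overtakes it at the second pick
  X["f3", ] <- y * 1.6 + rnorm(n, 0, 1.0)
  X["f4", ] <- y * 1.4 + rnorm(n, 0, 1.0)
  top <- mrmrRank(X, y, listLength = 1)
  Xd <- rbind(X, zdup = X[top, ])
  ord2 <- mrmrRank(Xd, y, listLength = 9)
  expect_equal(ord2[1], top)
  expect_false(ord2[2] == "zdup")

  Xc <- X; Xc["f1", ] <- 5          # constant feature never ranks first
  expect_false(mrmrRank(Xc, y, listLength = 8)[1] == "f1")
  Xall <- matrix(1, 3, n, dimnames = list(paste0("c", 1:3), colnames(X)))
  expect_error(mrmrRank(Xall, y), "constant")
})

test_that("the greedy ordering equals an exhaustive recomputation oracle", {
  set.seed(2)
  seeds <- 1:100
  for (sd in seeds) {
    set.seed(sd)
    n <- 30
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(rnorm(12 * n), 12, n,
                dimnames = list(sprintf("f%02d", 1:12), paste0("s", 1:n)))
    X[1, ] <- X[1, ] + y            # ensure some signal
    expect_identical(mrmrRank(X, y, listLength = 12), oracle_mrmr(X, y))
  }
})

test_that("ensemble scoring follows the L+1-p / absent-is-0 rule", {
  # two hand-written lists of length 3 over 4 features
  lists <- list(c("a", "b", "c"), c("c", "d", "a"))
  fr <- BloodBiasAudit:::aggregate_rank_lists(lists, c("a", "b", "c", "d"), 3)
  s <- rankScores(fr)
  # a: positions 1 and 3 -> (3 + 1)/2 = 2 ; b: (2 + 0)/2 = 1
  expect_equal(unname(s["a"]), 2)
  expect_equal(unname(s["b"]), 1)
  expect_equal(unname(s["c"]), (1 + 3) / 2)
  expect_equal(unname(s["d"]), (0 + 2) / 2)
  expect_equal(names(s)[1], "a")   # descending with lexical tie-break (a>c)

  # absent from every list -> 0
  fr2 <- BloodBiasAudit:::aggregate_rank_lists(lists, c("a", "b", "c", "d", "e"), 3)
  expect_equal(unname(rankScores(fr2)["e"]), 0)
})

test_that("a single full-sample repeat collapses to the plain mRMR order", {
  coh <- smallCohort(seed = 6, n = 40, genes = 60, reps = 0)
  X <- exprMatrix(coh)
  md <- sampleInfo(coh)
  fr <- ensembleRank(X, md$diagnosis, md$sex, nRepeats = 1, subsample = 1,
                     listLength = 20, seed = 1)
  direct <- mrmrRank(X, md$diagnosis, listLength = 20)
  expect_identical(names(rankScores(fr))[1:20], direct)
  expect_identical(fr@perRepeat[[1]], direct)
})

test_that("ensemble ranking is deterministic and elevates planted signal", {
  set.seed(9)
  n <- 80
  y <- rep(c(1, 0), each = n / 2)
  sex <- rep(rep(c("F", "M"), each = n / 4), 2)
  X <- matrix(rnorm(100 * n), 100, n,
              dimnames = list(sprintf("f%03d", 1:100), paste0("s", 1:n)))
  X[1:10, y == 1] <- X[1:10, y == 1] + 1      # planted block
  r1 <- ensembleRank(X, y, sex, nRepeats = 10, listLength = 40, seed = 5)
  r2 <- ensembleRank(X, y, sex, nRepeats = 10, listLength = 40, seed = 5)
  expect_identical(rankScores(r1), rankScores(r2))
  planted <- sprintf("f%03d", 1:10)
  expect_gte(mean(names(rankScores(r1))[1:15] %in% planted), 0.6)

  idx <- c(1, 2, 41)                    # one stratum of size 1
  expect_error(ensembleRank(X[, idx], y[idx], sex[idx], nRepeats = 2,
                            listLength = 5, seed = 1), "stratum")
})

test_that("feature-count scan and subset selection follow the protocol rules", {
  set.seed(10)
  n <- 120
  y <- rep(c(1, 0), each = n / 2)
  X <- matrix(rnorm(120 * n), 120, n,
              dimnames = list(sprintf("f%03d", 1:120), paste0("s", 1:n)))
  X[1:60, y == 1] <- X[1:60, y == 1] + 0.8    # exactly 60 informative
  tr <- c(1:40, 61:100); te <- setdiff(1:n, tr)
  ranking <- BloodBiasAudit:::aggregate_rank_lists(
    list(sprintf("f%03d", 1:120)), sprintf("f%03d", 1:120), 120)
  scan <- scanFeatureCounts(list(x = X[, tr], y = y[tr]),
                            list(x = X[, te], y = y[te]),
                            ranking, grid = seq(20, 120, 20))
  expect_equal(dim(scan$auc), c(6, 1))
  # signal saturates once the 60 planted features are in
  expect_gte(scan$auc["60", 1], scan$auc["20", 1])
  expect_gte(scan$auc["60", 1], max(scan$auc[c("80", "100", "120"), 1]) - 0.05)

  # leakage and grid validation
  expect_error(scanFeatureCounts(list(x = X[, tr], y = y[tr]),
                                 list(x = X[, tr], y = y[tr]),
                                 ranking, grid = c(20, 40)), "leakage")
  expect_error(scanFeatureCounts(list(x = X[, tr], y = y[tr]),
                                 list(x = X[, te], y = y[te]),
                                 ranking, grid = c(40, 20)), "increasing")

  single <- scanFeatureCounts(list(x = X[, tr], y = y[tr]),
                              list(x = X[, te], y = y[te]),
                              ranking, grid = 30)
  expect_equal(length(single$auc), 1)
})

test_that("best-subset selection caps size and breaks AUC ties downward", {
  mk <- function(grid, aucs) {
    structure(list(grid = grid,
                   auc = matrix(aucs, length(grid), 1,
                                dimnames = list(as.character(grid), "lr")),
                   featureOrder = sprintf("f%03d", 1:500)),
              class = "ScanResult")
  }
  sel <- selectBestSubset(mk(c(100, 150, 300), c(0.80, 0.80, 0.95)))
  expect_equal(sel$lr$count, 100)             # 300 ineligible; tie -> smaller
  expect_length(sel$lr$features, 100)

  sel2 <- selectBestSubset(mk(150, 0.7))
  expect_equal(sel2$lr$count, 150)
  expect_error(selectBestSubset(mk(c(300, 400), c(0.9, 0.9))), "cap")

  # brute-force argmax-with-tiebreak oracle on random tables
  set.seed(11)
  for (i in 1:100) {
    grid <- seq(50, 500, 50)
    aucs <- round(runif(length(grid), 0.5, 0.9), 2)
    sc <- mk(grid, aucs)
    got <- selectBestSubset(sc, 200)$lr$count
    elig <- grid <= 200
    best <- max(aucs[elig])
    expect_equal(got, min(grid[elig][aucs[elig] == best]))
  }
})
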