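test_that("the moderated statistic matches direct arithmetic", {
  X <- rbind(g1 = c(1, 2, 3, 3, 4, 5),
             g2 = c(2, 3, 4, 2, 3, 4))
  colnames(X) <- paste0("s", 1:6)
  y <- c(1, 1, 1, 0, 0, 0)               # cases first
  r <- samStatistic(X, y, s0 = 0.5)
  # (mean1 - mean0) = -2 for g1 read case-minus-control = 2-4; here cases
  # are {1,2,3}: d = (2 - 4)/(sqrt(2/3 * 1) + 0.5)
  expect_equal(unname(r$d["g1"]), -2 / (sqrt(2 / 3) + 0.5),
               tolerance = 1e-9)
  expect_equal(abs(unname(r$d["g1"])), 1.519, tolerance = 1e-3)
  expect_equal(unname(r$d["g2"]), 0)

  # s0 -> infinity drives all statistics to zero monotonically
  d1 <- abs(samStatistic(X, y, s0 = 1)$d["g1"])
  d10 <- abs(samStatistic(X, y, s0 = 10)$d["g1"])
  expect_gt(unname(abs(r$d["g1"])), unname(d1))
  expect_gt(unname(d1), unname(d10))

  expect_error(samStatistic(X, c(1, 1, 1, 1, 1, 0)), ">= 2 samples")
})

test_that("with s0 = 0 the statistic is the pooled-variance t", {
  set.seed(1)
  X <- matrix(rnorm(200 * 20), 200, 20,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  colnames(X) <- paste0("s", 1:20)
  y <- rep(c(1, 0), each = 10)
  d <- samStatistic(X, y, s0 = 0)$d
  tref <- apply(X, 1, function(g)
    t.test(g[y == 1], g[y == 0], var.equal = TRUE)$statistic)
  expect_equal(unname(d), unname(tref), tolerance = 1e-10)
})

test_that("permutation FDR enumerates small designs and is calibrated", {
  set.seed(2)
  Xs <- matrix(rnorm(50 * 6), 50, 6,
               dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  ys <- rep(c(1, 0), each = 3)
  r <- samPermutationFdr(Xs, ys, nPermutations = 100)
  expect_true(r$exhaustive)
  expect_equal(r$nPermutations, choose(6, 3))
  expect_true(all(r$q >= 0 & r$q <= 1))
  # q non-increasing in |d|
  ord <- order(-abs(r$d))
  expect_true(all(diff(r$q[ord]) >= -1e-12))

  # global-null calibration: median false-discovery proportion at q<=0.05
  fdp <- sapply(1:50, function(i) {
    set.seed(100 + i)
    X <- matrix(rnorm(200 * 20), 200, 20)
    rownames(X) <- sprintf("g%03d", 1:200)
    colnames(X) <- paste0("s", 1:20)
    y <- rep(c(1, 0), each = 10)
    q <- samPermutationFdr(X, y, nPermutations = 50, seed = i)$q
    called <- sum(q <= 0.05)
    if (called == 0) 0 else 1          # every call is false under the null
  })
  expect_lte(median(fdp), 0.07)
})

test_that("planted effects are detected with high sensitivity", {
  set.seed(3)
  G <- 1000; n <- 200
  X <- matrix(rnorm(G * n), G, n,
              dimnames = list(sprintf("g%04d", 1:G), paste0("s", 1:n)))
  y <- rep(c(1, 0), each = n / 2)
  planted <- sprintf("g%04d", 1:50)
  X[planted, y == 1] <- X[planted, y == 1] + 1
  r <- samPermutationFdr(X, y, nPermutations = 50, seed = 4)
  sens <- mean(r$q[planted] <= 0.05)
  expect_gte(sens, 0.8)
})

test_that("RRHO cells are exact hypergeometric tails with transpose symmetry", {
  set.seed(5)
  genes <- sprintf("g%03d", 1:100)
  lA <- sample(genes); lB <- sample(genes)
  m <- rrhoMap(lA, lB, step = 10)
  expect_equal(dim(m$logp), c(10, 10))

  # independent tail-sum oracle at (10, 10)
  k <- length(intersect(lA[1:10], lB[1:10]))
  pO <- oracle_hyper_tail(k, 100, 10, 10)
  if (k >= 10 * 10 / 100) {
    expect_equal(m$logp[1, 1], -log10(pO), tolerance = 1e-12)
  }
  # constructed overlap-5 cell equals the closed-form tail sum
  lB2 <- c(lA[1:5], setdiff(sample(genes), lA[1:5]))
  lB2 <- lB2[!duplicated(lB2)]
  k2 <- length(intersect(lA[1:10], lB2[1:10]))
  m2 <- rrhoMap(lA, lB2, step = 10)
  expect_equal(m2$logp[1, 1],
               -log10(oracle_hyper_tail(k2, 100, 10, 10)),
               tolerance = 1e-12)

  expect_equal(unname(m$logp), unname(t(rrhoMap(lB, lA, step = 10)$logp)))
  expect_error(rrhoMap(lA, lA[1:50]), "universe")
  expect_error(rrhoMap(c("a", "a", "b"), c("a", "b", "b")), "duplicates")
})

test_that("identical lists light the diagonal; the zone recovers planted overlap", {
  genes <- sprintf("g%03d", 1:100)
  m <- rrhoMap(genes, genes, step = 10)
  # the global maximum sits on the diagonal, where overlap = threshold
  peak <- which(m$logp == max(m$logp), arr.ind = TRUE)
  expect_true(any(peak[, 1] == peak[, 2]))
  z <- rrhoEnrichmentZone(m)
  expect_equal(sort(z$genes), sort(genes[1:z$i]))

  # disjoint top halves -> no over-enriched cell -> empty zone
  lA <- genes
  lB <- c(genes[51:100], genes[1:50])
  z2 <- rrhoEnrichmentZone(rrhoMap(lA, lB, step = 10))
  expect_length(z2$genes, 0)

  # planted shared head: same 50 genes top-ranked in both sexes
  set.seed(6)
  uni <- sprintf("g%04d", 1:1000)
  shared <- uni[1:50]
  lA3 <- c(sample(shared), sample(setdiff(uni, shared)))
  lB3 <- c(sample(shared), sample(setdiff(uni, shared)))
  z3 <- rrhoEnrichmentZone(rrhoMap(lA3, lB3, step = 10))
  expect_gte(length(intersect(z3$genes, shared)), 45)
})

test_that("random independent lists show no strong RRHO signal", {
  set.seed(7)
  uni <- sprintf("g%04d", 1:1000)
  hits <- sapply(1:100, function(i) {
    m <- rrhoMap(sample(uni), sample(uni), step = 100)
    max(m$logp) < 4            # p > 1e-4
  })
  expect_gte(mean(hits), 0.95)
})

test_that("over-representation p-values are exact tails with BH correction", {
  bg <- sprintf("g%03d", 1:100)
  query <- bg[1:20]
  sets <- list(hit = c(bg[1:5], bg[51:55]),       # overlap 5, size 10
               miss = bg[81:90],                  # overlap 0
               tiny = bg[1:2])
  r <- oraHypergeometric(query, sets, bg)
  expect_equal(r$p[r$set == "hit"],
               oracle_hyper_tail(5, 100, 10, 20), tolerance = 1e-12)
  expect_equal(r$p[r$set == "miss"], 1)
  expect_true(all(r$q >= r$p - 1e-15))

  single <- oraHypergeometric(query, sets["hit"], bg)
  expect_equal(single$q, single$p)
  expect_error(oraHypergeometric(c(query, "outside"), sets, bg),
               "background")
})
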