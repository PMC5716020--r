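# hand-built reference table helper
toyTable <- function(models, params, stats, scale = NULL) {
  if (is.null(scale))
    scale <- apply(do.call(rbind, stats), 2, function(x) max(mad(x), 1e-12))
  new("ReferenceTable", models = models, params = params, stats = stats,
      scale = scale)
}

test_that("summary statistics match direct formula evaluation on a toy", {
  b1 <- SequenceBlock(c(x1 = "AAAA", x2 = "AAGA", x3 = "AAGA"), c(1L, 4L))
  b2 <- SequenceBlock(c(y1 = "GGAA", y2 = "GGAA"), c(1L, 4L))
  st <- summaryStats(list(P = b1, Q = b2))
  expect_equal(unname(st["K_P"]), 2)
  expect_equal(unname(st["K_Q"]), 1)
  # haplotype diversity P: n/(n-1) * (1 - (1/3)^2 - (2/3)^2) = 2/3
  expect_equal(unname(st["H_P"]), 2 / 3)
  expect_equal(unname(st["S_P"]), 1)
  expect_equal(unname(st["S_Q"]), 0)
  # mean pairwise differences in P: pairs (0,1),(0,1),(1,1)->diffs 1,1,0
  expect_equal(unname(st["pi_P"]), 2 / 3)
  expect_equal(unname(st["pi_Q"]), 0)
  expect_equal(unname(st["TajD_Q"]), 0)
  expect_equal(unname(st["shared_P_Q"]), 0)
  # PhiST entry equals the brute-force decomposition
  all5 <- SequenceBlock(c(x1 = "AAAA", x2 = "AAGA", x3 = "AAGA",
                          y1 = "GGAA", y2 = "GGAA"), c(1L, 4L))
  D <- pairDiff(all5)
  expect_equal(unname(st["phist_P_Q"]),
               bruteForcePhiST(D, c("P", "P", "P", "Q", "Q")))
})

test_that("monomorphic and identical-population inputs give null stats", {
  b <- SequenceBlock(c(a = "AAAA", b = "AAAA"), c(1L, 4L))
  st <- summaryStats(list(P = b, Q = b))
  expect_equal(unname(st[c("S_P", "pi_P", "TajD_P")]), c(0, 0, 0))
  expect_equal(unname(st["K_P"]), 1)
  expect_equal(unname(st["phist_P_Q"]), 0)
  expect_equal(unname(st["shared_P_Q"]), 1)
})

test_that("rejection keeps the nearest replicates deterministically", {
  set.seed(23)
  S <- matrix(rnorm(200), ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  P <- matrix(runif(100), ncol = 1, dimnames = list(NULL, "p"))
  tab <- toyTable("m", list(m = P), list(m = S))
  obs <- S[17, ]
  r <- abcReject(obs, tab, eps = 0.2)
  expect_equal(r@accepted$index[1], 17)
  expect_equal(r@accepted$distance[1], 0)
  expect_equal(nrow(r@accepted), ceiling(0.2 * 100))
  expect_warning(abcReject(obs, tab, eps = 0.05), "fewer than 10")
  expect_error(abcReject(obs, tab, eps = 0), "eps")
})

test_that("AR shares of two identical simulators are symmetric", {
  set.seed(24)
  n <- 4000
  tab <- toyTable(c("m1", "m2"),
                  list(m1 = matrix(rnorm(n), ncol = 1,
                                   dimnames = list(NULL, "p")),
                       m2 = matrix(rnorm(n), ncol = 1,
                                   dimnames = list(NULL, "p"))),
                  list(m1 = matrix(rnorm(n), ncol = 1,
                                   dimnames = list(NULL, "s")),
                       m2 = matrix(rnorm(n), ncol = 1,
                                   dimnames = list(NULL, "s"))))
  mc <- abcModelChoice(c(s = 0.2), tab, eps = 0.05)
  pr <- modelProbabilities(mc)
  nacc <- ceiling(0.05 * 2 * n)
  se <- sqrt(0.25 / nacc)
  expect_lt(abs(pr["AR", "m1"] - 0.5), 3 * se)
  expect_equal(sum(pr["AR", ]), 1)
  expect_equal(sum(pr["LR", ]), 1)
  expect_lt(abs(pr["LR", "m1"] - 0.5), 0.15)
})

test_that("fully separable models are identified near-certainly and
           label permutation permutes the probabilities", {
  set.seed(25)
  n <- 2000
  s1 <- matrix(rnorm(n, -5), ncol = 1, dimnames = list(NULL, "s"))
  s2 <- matrix(rnorm(n, 5), ncol = 1, dimnames = list(NULL, "s"))
  p1 <- matrix(runif(n), ncol = 1, dimnames = list(NULL, "p"))
  tabA <- toyTable(c("m1", "m2"), list(m1 = p1, m2 = p1),
                   list(m1 = s1, m2 = s2))
  prA <- modelProbabilities(abcModelChoice(c(s = -5), tabA, eps = 0.05))
  expect_gt(prA["LR", "m1"], 0.99)
  # permute the labels
  tabB <- toyTable(c("m1", "m2"), list(m1 = p1, m2 = p1),
                   list(m1 = s2, m2 = s1))
  prB <- modelProbabilities(abcModelChoice(c(s = -5), tabB, eps = 0.05))
  expect_equal(unname(prA["LR", "m1"]), unname(prB["LR", "m2"]),
               tolerance = 1e-6)
})

test_that("the Gaussian toy posterior matches the conjugate solution", {
  set.seed(26)
  m <- 40000; sig2n <- 0.25
  theta <- rnorm(m)
  xbar <- rnorm(m, theta, sqrt(sig2n))
  tab <- toyTable("toy",
                  list(toy = matrix(theta, ncol = 1,
                                    dimnames = list(NULL, "theta"))),
                  list(toy = matrix(xbar, ncol = 1,
                                    dimnames = list(NULL, "xbar"))))
  obs <- c(xbar = 0.8)
  postVar <- 1 / (1 + 1 / sig2n)
  postMean <- postVar * obs / sig2n
  # rejection posterior, small eps
  r <- abcReject(obs, tab, eps = 0.002)
  x <- r@posterior$toy$raw[, 1]
  seM <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - postMean), 3 * seM)
  seV <- sd((x - mean(x))^2) / sqrt(length(x))
  expect_lt(abs(var(x) - postVar), 3 * seV)
  # regression adjustment gets closer on average than plain rejection at a
  # larger eps (squared error of mean and variance as the KL proxy)
  errAdj <- errRej <- numeric(60)
  for (k in 1:60) {
    o <- c(xbar = rnorm(1, 0, 1))
    pv <- 1 / (1 + 1 / sig2n); pm <- pv * o / sig2n
    ad <- abcAdjust(o, tab, "toy", eps = 0.05)
    xa <- ad$adjusted[, 1]; w <- ad$weights
    mu <- sum(xa * w) / sum(w)
    va <- sum(w * (xa - mu)^2) / sum(w)
    errAdj[k] <- (mu - pm)^2 + (va - pv)^2
    xr <- ad$raw[, 1]
    errRej[k] <- (mean(xr) - pm)^2 + (var(xr) - pv)^2
  }
  expect_lt(mean(errAdj), mean(errRej))
})

test_that("95% HPD of a uniform posterior sample has length about 0.95", {
  set.seed(27)
  u <- runif(20000)
  h <- weightedHPD(u)
  expect_lt(abs((h[2] - h[1]) - 0.95), 0.02)
  # weighted degenerate case
  expect_equal(weightedHPD(rep(2, 5)), c(2, 2))
})

test_that("adjustment is near the identity at the accepted-set mean", {
  set.seed(28)
  n <- 5000
  th <- runif(n, 0, 10)
  st <- th + rnorm(n, 0, 0.5)
  tab <- toyTable("m", list(m = matrix(th, ncol = 1,
                                       dimnames = list(NULL, "th"))),
                  list(m = matrix(st, ncol = 1,
                                  dimnames = list(NULL, "s"))))
  r <- abcReject(c(s = 5), tab, eps = 0.05)
  accMean <- mean(tab@stats$m[r@accepted$index, 1])
  ad <- abcAdjust(c(s = accMean), tab, "m", eps = 0.05)
  shift <- abs(mean(ad$adjusted[, 1]) - mean(ad$raw[, 1]))
  expect_lt(shift / 10, 0.02)
})

test_that("the rejection posterior converges to the prior as eps -> 1", {
  set.seed(29)
  n <- 20000
  th <- runif(n, 0, 1)
  st <- rnorm(n, th, 5)  # nearly uninformative
  tab <- toyTable("m", list(m = matrix(th, ncol = 1,
                                       dimnames = list(NULL, "th"))),
                  list(m = matrix(st, ncol = 1,
                                  dimnames = list(NULL, "s"))))
  r <- abcReject(c(s = 0.5), tab, eps = 1)
  x <- r@posterior$m$raw[, 1]
  expect_lt(abs(mean(x) - 0.5), 3 * sd(x) / sqrt(length(x)))
})

test_that("results are invariant to affine rescaling of a statistic", {
  set.seed(30)
  n <- 3000
  P <- matrix(runif(n), ncol = 1, dimnames = list(NULL, "p"))
  S <- cbind(s1 = rnorm(n), s2 = rnorm(n, 2, 3))
  tab1 <- toyTable("m", list(m = P), list(m = S))
  S2 <- S; S2[, 2] <- 100 * S2[, 2] + 7
  tab2 <- toyTable("m", list(m = P), list(m = S2))
  obs1 <- c(s1 = 0.3, s2 = 1)
  obs2 <- c(s1 = 0.3, s2 = 100 * 1 + 7)
  r1 <- abcReject(obs1, tab1, eps = 0.01)
  r2 <- abcReject(obs2, tab2, eps = 0.01)
  expect_equal(r1@accepted$index, r2@accepted$index)
  expect_equal(r1@accepted$distance, r2@accepted$distance, tolerance = 1e-9)
})

test_that("duplicating every replicate leaves model probabilities stable", {
  set.seed(31)
  n <- 1500
  S <- list(m1 = matrix(rnorm(n, -1), ncol = 1,
                        dimnames = list(NULL, "s")),
            m2 = matrix(rnorm(n, 1), ncol = 1, dimnames = list(NULL, "s")))
  P <- list(m1 = matrix(runif(n), ncol = 1, dimnames = list(NULL, "p")),
            m2 = matrix(runif(n), ncol = 1, dimnames = list(NULL, "p")))
  tab <- toyTable(c("m1", "m2"), P, S)
  tab2 <- toyTable(c("m1", "m2"),
                   lapply(P, function(x) rbind(x, x)),
                   lapply(S, function(x) rbind(x, x)),
                   scale = tab@scale)
  pr1 <- modelProbabilities(abcModelChoice(c(s = -0.5), tab, 0.02))
  pr2 <- modelProbabilities(abcModelChoice(c(s = -0.5), tab2, 0.02))
  expect_equal(pr1["AR", ], pr2["AR", ], tolerance = 0.02)
})

test_that("validation refuses meaningless pseudo-observed counts", {
  reg <- modelRegistry(sampleSizes = c(4L, 4L, 4L))
  tab <- toyTable("model1",
                  list(model1 = matrix(runif(50), ncol = 1,
                                       dimnames = list(NULL, "a"))),
                  list(model1 = matrix(rnorm(50), ncol = 1,
                                       dimnames = list(NULL, "s"))))
  expect_error(abcValidate(tab, reg["model1"], q = 5), "q < 20")
})

test_that("reference tables round-trip through the delimited writer", {
  set.seed(32)
  reg <- modelRegistry(sampleSizes = c(4L, 4L, 6L))
  tab <- buildReferenceTable(reg["model3"], nrep = 30, seed = 5)
  d <- tempfile()
  writeReferenceTable(tab, d)
  back <- readReferenceTable(d)
  expect_equal(back@models, tab@models)
  expect_equal(back@params$model3, tab@params$model3, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(back@scale), unname(tab@scale), tolerance = 1e-12)
})
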