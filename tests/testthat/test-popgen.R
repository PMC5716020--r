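test_that("kinship correction collapses within-grave haplotype sharing", {
  d <- loadMogouHaplotypes()
  u <- kinshipCorrect(d)
  expect_equal(sum(u$weight), 46)
  expect_equal(nrow(u), 46)
  expect_true(all(u$weight >= 1 & u$weight <= u$n_carriers))

  # all-unique haplotypes: unit count equals sample count
  s <- data.frame(sample_id = paste0("s", 1:5), population = "P",
                  grave_id = paste0("g", 1:5), age_bp = 0, sex = "unknown",
                  haplotype_id = paste0("h", 1:5), haplogroup = "A",
                  stringsAsFactors = FALSE)
  expect_equal(sum(kinshipCorrect(s)$weight), 5)

  # one haplotype in two distinct graves contributes two units
  s2 <- data.frame(sample_id = c("x1", "x2", "x3"), population = "P",
                   grave_id = c("g1", "g1", "g2"), age_bp = 0,
                   sex = "unknown", haplotype_id = "h1", haplogroup = "A",
                   stringsAsFactors = FALSE)
  u2 <- kinshipCorrect(s2)
  expect_equal(nrow(u2), 1)
  expect_equal(u2$weight, 2)

  # idempotence: one representative per unit re-corrects to the same units
  rep1 <- s2[c(1, 3), ]
  expect_equal(sum(kinshipCorrect(rep1)$weight), sum(u2$weight))

  # missing haplotype IDs are excluded with a warning
  s3 <- rbind(s, data.frame(sample_id = "s6", population = "P",
                            grave_id = "g6", age_bp = 0, sex = "unknown",
                            haplotype_id = "", haplogroup = ""))
  expect_warning(u3 <- kinshipCorrect(s3), "excluded")
  expect_equal(sum(u3$weight), 5)
})

test_that("kinship-corrected frequencies reproduce the published values", {
  u <- kinshipCorrect(loadMogouHaplotypes())
  f <- haplogroupFrequencies(u)
  expect_equal(f$percent[f$haplogroup == "D"], 34.78)
  expect_equal(f$percent[f$haplogroup == "C"], 10.87)
  expect_equal(f$percent[f$haplogroup == "F"], 8.70)
  expect_equal(f$percent[f$haplogroup == "A"], 8.70)
  expect_equal(sum(f$frequency), 1)

  one <- data.frame(haplotype_id = "h1", haplogroup = "Z",
                    carriers = "x", n_carriers = 1L, weight = 1L)
  expect_equal(haplogroupFrequencies(one)$percent, 100)
  expect_error(haplogroupFrequencies(one[0, ]), "empty")
})

test_that("PhiST matches a brute-force decomposition and its bounds", {
  b <- toyBlock()
  pop <- rep(c("A", "B"), each = 4)
  res <- pairwisePhiST(b, pop, nperm = 199, seed = 1)
  D <- pairDiff(b)
  expect_equal(res$raw["A", "B"], bruteForcePhiST(D, pop))

  # identical populations: PhiST = 0
  sameSeqs <- c(a1 = "AACA", a2 = "ATAA", b1 = "AACA", b2 = "ATAA")
  same <- SequenceBlock(sameSeqs, c(1L, 4L))
  r0 <- pairwisePhiST(same, c("A", "A", "B", "B"), nperm = 99, seed = 2)
  expect_equal(unname(r0$dist["A", "B"]), 0)

  # fixed differences: PhiST = 1
  fixed <- SequenceBlock(c(a1 = "AAAA", a2 = "AAAA",
                           b1 = "TTTT", b2 = "TTTT"), c(1L, 4L))
  r1 <- pairwisePhiST(fixed, c("A", "A", "B", "B"), nperm = 99, seed = 3)
  expect_equal(unname(r1$dist["A", "B"]), 1)

  # errors name the offending population
  expect_error(pairwisePhiST(b, c("A", rep("B", 7)), nperm = 9), "A")
})

test_that("PhiST is invariant to within-population relabeling and site
           order", {
  set.seed(21)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "G"), 20, TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("s", 1:10)
  pop <- rep(c("A", "B"), each = 5)
  b <- SequenceBlock(seqs, c(1L, 20L))
  base <- pairwisePhiST(b, pop, nperm = 9, seed = 1)$raw[1, 2]
  # permute sequences within populations
  ord <- c(sample(1:5), sample(6:10))
  b2 <- SequenceBlock(seqs[ord], c(1L, 20L))
  expect_equal(pairwisePhiST(b2, pop, nperm = 9, seed = 1)$raw[1, 2], base)
  # permute site order globally
  perm <- sample(20)
  seqs3 <- vapply(seqs, function(s)
    paste(strsplit(s, "")[[1]][perm], collapse = ""), character(1))
  b3 <- SequenceBlock(seqs3, c(1L, 20L))
  expect_equal(pairwisePhiST(b3, pop, nperm = 9, seed = 1)$raw[1, 2], base)
})

test_that("AMOVA matches hand-computed sums of squares and sums to 100%", {
  b <- toyBlock()
  pops <- rep(c("p1", "p2", "p3", "p4"), each = 2)
  grp <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2")
  am <- amova(b, pops, grp, nperm = 99, seed = 4)
  tab <- amovaTable(am)
  expect_equal(sum(tab$percent), 100, tolerance = 1e-9)
  expect_equal(tab$df, c(1, 2, 4))
  D <- pairDiff(b)
  # hand oracle: total and within sums of squares from first principles
  ssdT <- sum(D[lower.tri(D)]) / 8
  ssdWP <- sum(vapply(unique(pops), function(p) {
    sub <- D[pops == p, pops == p]
    sum(sub[lower.tri(sub)]) / 2
  }, numeric(1)))
  expect_equal(sum(tab$SSD), ssdT, tolerance = 1e-12)
  expect_equal(tab$SSD[3], ssdWP, tolerance = 1e-12)
  expect_true(all(amovaPvalues(am) >= 0 & amovaPvalues(am) <= 1))
  # two-population AMOVA PhiST equals pairwisePhiST on the same input
  pop2 <- rep(c("A", "B"), each = 4)
  am2 <- amova(b, pop2, c(A = "gA", B = "gB"), nperm = 9, seed = 5)
  pp <- pairwisePhiST(b, pop2, nperm = 9, seed = 5)
  expect_equal(unname(amovaPhi(am2)["PhiST"]), unname(pp$raw["A", "B"]))
})

test_that("AMOVA on identically composed groups has a null among-group
           component", {
  set.seed(31)
  seqs <- vapply(1:16, function(i)
    paste(sample(c("A", "G"), 12, TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("s", 1:16)
  b <- SequenceBlock(seqs, c(1L, 12L))
  pops <- rep(c("p1", "p2", "p3", "p4"), each = 4)
  am <- amova(b, pops, c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2"),
              nperm = 99, seed = 6)
  expect_lt(abs(amovaTable(am)$percent[1]), 25)
  expect_gt(amovaPvalues(am)["PhiCT"], 0.05)
})

test_that("degenerate single-group AMOVA reduces with a notice", {
  b <- toyBlock()
  pops <- rep(c("p1", "p2"), each = 4)
  expect_message(am <- amova(b, pops, c(p1 = "g", p2 = "g"), nperm = 9),
                 "one-level")
  expect_equal(amovaTable(am)$sigma[1], 0)
})

test_that("metric MDS recovers embeddable configurations", {
  X <- matrix(c(0, 0, 3, 0, 0, 4, 5, 6), ncol = 2, byrow = TRUE)
  D <- as.matrix(dist(X))
  fit <- mdsEmbed(D, 2)
  expect_lt(fit$stress, 1e-8)
  expect_equal(as.matrix(dist(fit$points)), D, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(colSums(fit$points), c(Dim1 = 0, Dim2 = 0), tolerance = 1e-8)

  # 3-point metric: closed-form triangle placement (side lengths preserved)
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3)
  f3 <- mdsEmbed(D3, 2)
  expect_equal(as.matrix(dist(f3$points)), D3, tolerance = 1e-6,
               ignore_attr = TRUE)

  # adding a constant to off-diagonal entries breaks embeddability
  D4 <- D + 2; diag(D4) <- 0
  f4 <- mdsEmbed(D4, 2)
  expect_gt(f4$stress, fit$stress)
  expect_error(mdsEmbed(D3, 3), "dims")
})

test_that("frequency PCA matches a brute-force eigendecomposition", {
  f <- matrix(c(.5, .5, 0,
                .4, .6, 0,
                .3, .3, .4,
                .2, .4, .4), nrow = 4, byrow = TRUE)
  p <- pcaFrequencies(f)
  C <- stats::cov(f)
  ev <- eigen(C)$values
  expect_equal(p$explained, (ev / sum(ev))[seq_along(p$explained)],
               tolerance = 1e-9)
  sc <- scale(f, center = TRUE, scale = FALSE) %*% eigen(C)$vectors
  expect_equal(abs(p$scores[, 1]), abs(sc[, 1]), tolerance = 1e-9,
               ignore_attr = TRUE)

  # identical populations collapse to the origin of PC1
  f2 <- rbind(c(.5, .5), c(.5, .5), c(.2, .8))
  p2 <- pcaFrequencies(f2)
  expect_equal(p2$scores[1, 1], p2$scores[2, 1], tolerance = 1e-12)

  # a rank-1 perturbation loads 100% on PC1
  base <- c(.3, .3, .4)
  f3 <- rbind(base, base + c(.1, -.1, 0), base + c(.2, -.2, 0))
  p3 <- pcaFrequencies(f3)
  expect_equal(p3$explained[1], 1, tolerance = 1e-9)

  expect_message(pcaFrequencies(rbind(c(.5, .5), c(.5, .5))), "constant")
})
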