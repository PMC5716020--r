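chainSeqs <- function() c(h1 = "AAAAAAAAAA", h2 = "GAAAAAAAAA",
                          h3 = "GGAAAAAAAA", h4 = "GGGAAAAAAA",
                          h5 = "GGGGAAAAAA")

# exhaustive Kruskal oracle: the minimum spanning network is the union of
# all minimum spanning trees; an edge belongs to it iff its weight is
# minimal over every path between its endpoints restricted to edges of
# smaller weight (cycle property), checked here by brute force over
# connectivity at lower weights
msnOracle <- function(D) {
  n <- nrow(D)
  keep <- NULL
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    w <- D[i, j]
    # connectivity using only edges strictly lighter than w
    adj <- D < w & upper.tri(D) | t(D < w & upper.tri(D))
    reach <- logical(n); reach[i] <- TRUE
    repeat {
      nxt <- reach | apply(adj[, reach, drop = FALSE], 1, any)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    if (!reach[j]) keep <- rbind(keep, c(i, j, w))
  }
  keep
}

test_that("layers with identical haplotype sets are fully cross-linked", {
  s <- chainSeqs()
  b1 <- SequenceBlock(s, c(1L, 10L))
  b2 <- SequenceBlock(setNames(s, paste0("x", 1:5)), c(1L, 10L))
  net <- buildTempNet(list(old = b1, new = b2), ages = c(4000, 0))
  expect_equal(nrow(tempnetCrossEdges(net)), 5)
  rep <- sharedHaplotypeReport(net)
  expect_true(all(rep$n_layers == 2))
})

test_that("disjoint layers have no cross-layer edges", {
  b1 <- SequenceBlock(c(a = "AAAA", b = "AAAT"), c(1L, 4L))
  b2 <- SequenceBlock(c(c = "GGGG", d = "GGGA"), c(1L, 4L))
  net <- buildTempNet(list(L1 = b1, L2 = b2), ages = c(1000, 0))
  expect_equal(nrow(tempnetCrossEdges(net)), 0)
})

test_that("within-layer topology equals the brute-force spanning network", {
  # 1-step mutation chain: the MSN is exactly the chain
  b <- SequenceBlock(chainSeqs(), c(1L, 10L))
  b2 <- SequenceBlock(chainSeqs()[c(1, 5)] |> setNames(c("y1", "y2")),
                      c(1L, 10L))
  net <- buildTempNet(list(main = b, other = b2), ages = c(100, 0))
  e <- tempnetEdges(net)
  within <- e[grepl("^main", e$from), ]
  expect_equal(nrow(within), 4)
  expect_true(all(within$weight == 1))

  # randomized sets against the exhaustive oracle
  set.seed(13)
  for (rep in 1:5) {
    seqs <- unique(vapply(1:7, function(i)
      paste(sample(c("A", "G"), 8, TRUE), collapse = ""), character(1)))
    names(seqs) <- paste0("s", seq_along(seqs))
    bb <- SequenceBlock(seqs, c(1L, 8L))
    dummy <- SequenceBlock(setNames(seqs[1], "z"), c(1L, 8L))
    nn <- buildTempNet(list(A = bb, B = dummy), ages = c(10, 0))
    got <- tempnetEdges(nn)
    got <- got[grepl("^A", got$from), c("from", "to", "weight")]
    D <- pairDiff(bb)
    want <- msnOracle(D)
    expect_equal(nrow(got), nrow(want))
    gotPairs <- sort(paste(got$from, got$to, got$weight))
    wantPairs <- sort(paste(paste0("A.h", want[, 1]),
                            paste0("A.h", want[, 2]), want[, 3]))
    expect_equal(gotPairs, wantPairs)
  }
})

test_that("carrier counts are conserved per layer", {
  set.seed(14)
  mk <- function(n, lab) {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "G"), 6, TRUE), collapse = ""), character(1))
    names(seqs) <- paste0(lab, seq_len(n))
    SequenceBlock(seqs, c(1L, 6L))
  }
  blocks <- list(p1 = mk(12, "a"), p2 = mk(9, "b"), p3 = mk(15, "c"))
  net <- buildTempNet(blocks, ages = c(4000, 3000, 0))
  nd <- tempnetNodes(net)
  for (l in names(blocks))
    expect_equal(sum(nd$count[nd$layer == l]),
                 length(blockLabels(blocks[[l]])))
})

test_that("the network is invariant to sequence input order", {
  set.seed(15)
  seqs <- vapply(1:8, function(i)
    paste(sample(c("A", "G", "T"), 6, TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("s", 1:8)
  ref <- SequenceBlock(setNames(seqs[1], "r"), c(1L, 6L))
  n1 <- buildTempNet(list(A = SequenceBlock(seqs, c(1L, 6L)), B = ref),
                     ages = c(10, 0))
  ord <- sample(8)
  n2 <- buildTempNet(list(A = SequenceBlock(seqs[ord], c(1L, 6L)), B = ref),
                     ages = c(10, 0))
  # same multiset of (sorted) node sequences and same edge weights
  expect_setequal(tempnetNodes(n1)$sequence, tempnetNodes(n2)$sequence)
  key <- function(net) {
    nd <- tempnetNodes(net); e <- tempnetEdges(net)
    sort(paste(pmin(nd$sequence[match(e$from, nd$node)],
                    nd$sequence[match(e$to, nd$node)]),
               pmax(nd$sequence[match(e$from, nd$node)],
                    nd$sequence[match(e$to, nd$node)]), e$weight))
  }
  expect_equal(key(n1), key(n2))
})

test_that("shared-haplotype report matches brute-force set intersections", {
  set.seed(16)
  pool <- unique(vapply(1:10, function(i)
    paste(sample(c("A", "G"), 5, TRUE), collapse = ""), character(1)))
  mkLayer <- function(k, lab) {
    pick <- sample(pool, k, replace = TRUE)
    names(pick) <- paste0(lab, seq_len(k))
    SequenceBlock(pick, c(1L, 5L))
  }
  blocks <- list(L1 = mkLayer(6, "a"), L2 = mkLayer(7, "b"),
                 L3 = mkLayer(5, "c"))
  net <- buildTempNet(blocks, ages = c(2, 1, 0))
  rep <- sharedHaplotypeReport(net)
  seqSets <- lapply(blocks, function(b) unique(blockSequences(b)))
  for (r in seq_len(nrow(rep))) {
    nd <- tempnetNodes(net)
    sq <- nd$sequence[nd$node == rep$haplotype[r]]
    inLayers <- names(seqSets)[vapply(seqSets, function(ss) sq %in% ss,
                                      logical(1))]
    expect_setequal(strsplit(rep$layers[r], ",")[[1]], inLayers)
  }
  # sanity: one haplotype forced into all layers is reported once with 3
  forced <- pool[1]
  blocks2 <- lapply(blocks, function(b) {
    s <- blockSequences(b); s[1] <- forced
    SequenceBlock(setNames(s, blockLabels(b)), c(1L, 5L))
  })
  net2 <- buildTempNet(blocks2, ages = c(2, 1, 0))
  rep2 <- sharedHaplotypeReport(net2)
  expect_gte(sum(rep2$n_layers == 3), 1)
})

test_that("mismatched windows across layers are an alignment error", {
  b1 <- SequenceBlock(c(a = "AAAA"), c(1L, 4L))
  b2 <- SequenceBlock(c(b = "AAAAA"), c(1L, 5L))
  expect_error(buildTempNet(list(b1, b2), ages = c(1, 0)), "window")
})

test_that("DOT export writes a parseable graph", {
  b1 <- SequenceBlock(chainSeqs(), c(1L, 10L))
  b2 <- SequenceBlock(setNames(chainSeqs()[1], "x"), c(1L, 10L))
  net <- buildTempNet(list(A = b1, B = b2), ages = c(1, 0))
  f <- tempfile(fileext = ".dot")
  writeTempNetDot(net, f)
  txt <- readLines(f)
  expect_true(any(grepl("graph", txt)))
  g <- tempnetGraph(net)
  expect_equal(igraph::vcount(g), nrow(tempnetNodes(net)))
})
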