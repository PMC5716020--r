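# Small in-code fixtures shared across test files.

toyBlock <- function() {
  SequenceBlock(c(a1 = "AAAA", a2 = "AAAT", a3 = "AATA", a4 = "AAAA",
                  b1 = "TTAA", b2 = "TTAT", b3 = "TTAA", b4 = "TTTA"),
                window = c(1L, 4L))
}

# brute-force one-level AMOVA PhiST, written directly from the sums of
# squares of the molecular-variance decomposition (independent of the
# package's C++ path)
bruteForcePhiST <- function(D, pop) {
  N <- nrow(D)
  pops <- unique(pop)
  P <- length(pops)
  ssdT <- sum(D[lower.tri(D)]) / N
  ssdW <- 0
  np <- numeric(P)
  for (k in seq_len(P)) {
    sel <- pop == pops[k]
    np[k] <- sum(sel)
    sub <- D[sel, sel, drop = FALSE]
    ssdW <- ssdW + sum(sub[lower.tri(sub)]) / np[k]
  }
  sc <- ssdW / (N - P)
  nprime <- (N - sum(np^2) / N) / (P - 1)
  sa <- ((ssdT - ssdW) / (P - 1) - sc) / nprime
  if (sa + sc <= 0) 0 else sa / (sa + sc)
}

# random substitution-only motif of k transitions at distinct HVS-I sites
randomTransitionMotif <- function(k) {
  pos <- sample(16051:16384, k)
  HapMotif(data.frame(pos = pos, kind = "transition",
                      base = NA_character_, span = 1L,
                      stringsAsFactors = FALSE))
}

# single-deme model helper
oneDemeModel <- function(N, n, ages = 0, g = 25) {
  DemographicModel(c(d = N),
                   data.frame(deme = "d", age = ages,
                              n = as.integer(rep(n, length.out =
                                                   length(ages)))),
                   generationTime = g)
}

# cached desk-scale reference table + registry shared by the acceptance
# tests (built once per test run)
deskScaleFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      reg <- modelRegistry(sampleSizes = c(20L, 20L, 60L))
      tab <- buildReferenceTable(reg, nrep = 20000, seed = 424241)
      cache <<- list(registry = reg, table = tab)
    }
    cache
  }
})
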