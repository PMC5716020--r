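test_that("the model registry encodes the four candidate histories", {
  reg <- modelRegistry()
  expect_length(reg, 4)
  expect_named(reg, c("model1", "model2", "model3", "model4"))
  # sampling scheme: 46/64/521 at 4000/3000/0 BP
  se <- reg$model1@samplingEvents
  expect_equal(se$n[match(c("Mogou", "Hengbei", "NorthernHan"), se$deme)],
               c(46L, 64L, 521L))
  expect_equal(se$age[match(c("Mogou", "Hengbei", "NorthernHan"), se$deme)],
               c(4000, 3000, 0))
  # model 1: exactly one pulse, Mogou -> Northern Han
  expect_equal(nrow(reg$model1@pulses), 1)
  expect_equal(reg$model1@pulses$source, "Mogou")
  expect_equal(reg$model1@pulses$sink, "NorthernHan")
  # model 2 is the mirror
  expect_equal(reg$model2@pulses$source, "Hengbei")
  # models 3 and 4 have no admixture
  expect_equal(nrow(reg$model3@pulses), 0)
  expect_equal(nrow(reg$model4@pulses), 0)
  for (m in reg) expect_true(validObject(m))
})

test_that("prior draws honour bounds, moments and order constraints", {
  reg <- modelRegistry()
  pr <- modelPrior(reg$model1)
  expect_setequal(pr@params$name,
                  c("Ne_Mogou", "Ne_Hengbei", "Ne_NorthernHan",
                    "T1", "T2", "a"))
  expect_equal(pr@params$lower[pr@params$name == "a"], 0.01)
  expect_equal(pr@params$upper[pr@params$name == "a"], 1)

  set.seed(17)
  draws <- t(replicate(2000, drawFromPrior(pr, reg$model1)$params))
  expect_true(all(draws[, "T2"] < draws[, "T1"]))
  # mean of a over U[0.01, 1] = 0.505 within 3 SE
  se <- sd(draws[, "a"]) / sqrt(nrow(draws))
  expect_lt(abs(mean(draws[, "a"]) - 0.505), 3 * se)

  # degenerate prior yields a constant
  dg <- PriorSpec(data.frame(name = "Ne_Mogou", lower = 5, upper = 5))
  d <- drawFromPrior(dg, reg$model1)
  expect_equal(unname(d$params["Ne_Mogou"]), 5)
  expect_equal(unname(d$model@demes["Mogou"]), 5)

  # unsatisfiable constraint is a configuration error
  bad <- PriorSpec(data.frame(name = c("T1", "T2"),
                              lower = c(1, 10), upper = c(5, 20)),
                   constraints = "T2<T1")
  expect_error(drawFromPrior(bad, reg$model1, maxTries = 50),
               "configuration")
})

test_that("single-deme expectations match coalescent closed forms", {
  set.seed(18)
  N <- 400; g <- 25; mu <- 9.883e-8; L <- 334
  mut <- MutationModel(mu = mu, L = L)
  nrep <- 800
  m <- oneDemeModel(N, 2)
  diffs <- replicate(nrep, {
    s <- simulateSequences(m, mut, reference = NULL)
    sum(s$states[1, ] != s$states[2, ])
  })
  expected <- 2 * N * g * mu * L
  se <- sd(diffs) / sqrt(nrep)
  expect_lt(abs(mean(diffs) - expected), 3 * se)

  # serial pair sampled Delta years apart
  Delta <- 6000
  m2 <- oneDemeModel(N, 1, ages = c(0, Delta))
  diffs2 <- replicate(nrep, {
    s <- simulateSequences(m2, mut, reference = NULL)
    sum(s$states[1, ] != s$states[2, ])
  })
  expected2 <- mu * L * (Delta + 2 * N * g)
  se2 <- sd(diffs2) / sqrt(nrep)
  expect_lt(abs(mean(diffs2) - expected2), 3 * se2)
})

test_that("a zero-proportion pulse collapses model 1 onto model 3", {
  set.seed(19)
  reg <- modelRegistry(sampleSizes = c(8L, 8L, 12L))
  pars <- c(Ne_Mogou = 600, Ne_Hengbei = 900, Ne_NorthernHan = 700,
            T1 = 6000, T2 = 3500, a = 0.01)
  m1 <- applyParams(reg$model1, pars)
  m1@pulses$prop <- 0
  m3 <- applyParams(reg$model3, pars[names(pars) != "a"])
  mut <- MutationModel()
  a1 <- paleomito:::.modelArgs(m1, mut); a3 <- paleomito:::.modelArgs(m3, mut)
  nrep <- 600
  s1 <- t(replicate(nrep, as.numeric(paleomito:::.simStatsFromArgs(a1))))
  s3 <- t(replicate(nrep, as.numeric(paleomito:::.simStatsFromArgs(a3))))
  # two-sample tests across informative statistics: none should reject at
  # p < 0.01 after accounting for multiplicity (Bonferroni within run)
  pvals <- vapply(seq_len(ncol(s1)), function(k) {
    if (sd(c(s1[, k], s3[, k])) == 0) return(1)
    suppressWarnings(stats::ks.test(s1[, k], s3[, k])$p.value)
  }, numeric(1))
  expect_gt(min(pvals) * length(pvals), 0.01)
})

test_that("summary distributions are exchangeable within demes", {
  set.seed(20)
  # permuting sample labels within a deme leaves statistics unchanged --
  # statistics are computed from unordered population membership, so a
  # direct check: recompute stats after permuting rows within populations
  reg <- modelRegistry(sampleSizes = c(6L, 6L, 8L))
  m <- applyParams(reg$model3, c(Ne_Mogou = 500, Ne_Hengbei = 500,
                                 Ne_NorthernHan = 500, T1 = 8000,
                                 T2 = 3500))
  sim <- simulateSequences(m, MutationModel(), seed = 99)
  pop <- sim$pop
  st1 <- paleomito:::.statsFromStates(sim$states, pop)
  ord <- unlist(lapply(unique(pop), function(p) sample(which(pop == p))))
  st2 <- paleomito:::.statsFromStates(sim$states[ord, ], pop[ord],
                                      pops = unique(pop))
  expect_equal(st1, st2)
})

test_that("invalid models are rejected at validation", {
  expect_error(DemographicModel(c(A = 100),
                                data.frame(deme = "B", age = 0, n = 2L)) |>
                 validObject(), "unknown deme")
  expect_error(
    DemographicModel(c(A = 100, B = 100),
                     data.frame(deme = "A", age = 0, n = 2L),
                     pulses = data.frame(age = 10, source = "A",
                                         sink = "B", prop = 1.5)) |>
      validObject(), "proportion")
})

test_that("per-model summary means match the independent msprime oracle", {
  reg <- modelRegistry(sampleSizes = c(10L, 10L, 10L))
  mut <- MutationModel()
  pars <- c(Ne_Mogou = 799, Ne_Hengbei = 1489, Ne_NorthernHan = 657,
            T1 = 5472, T2 = 3505, a = 0.146)
  nrep <- 400
  for (lab in c("model1", "model4")) {
    m <- applyParams(reg[[lab]], pars)
    a <- paleomito:::.modelArgs(m, mut)
    set.seed(4242)
    stats <- t(replicate(nrep,
                         as.numeric(paleomito:::.simStatsFromArgs(a))))
    colnames(stats) <- summaryStatNames(a$popNames)
    # oracle input
    g <- m@generationTime
    ev <- c(lapply(seq_len(nrow(m@pulses)), function(i)
      list(m@pulses$age[i] / g, "pulse", m@pulses$sink[i],
           m@pulses$source[i], m@pulses$prop[i])),
      lapply(seq_len(nrow(m@divergences)), function(i)
        list(m@divergences$age[i] / g, "merge", m@divergences$child[i],
             m@divergences$parent[i])))
    cfg <- list(ne = as.list(m@demes),
                samples = lapply(seq_len(nrow(m@samplingEvents)),
                                 function(i)
                  list(m@samplingEvents$deme[i],
                       m@samplingEvents$age[i] / g,
                       m@samplingEvents$n[i])),
                events = ev, mu_site_gen = mut@mu * g, L = mut@L,
                nrep = nrep, seed = 777)
    script <- system.file("oracle", "msprime_oracle.py",
                          package = "paleomito")
    json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
    out <- system2("python", script, input = as.character(json),
                   stdout = TRUE)
    oracle <- jsonlite::fromJSON(paste(out, collapse = ""))
    for (p in names(m@demes)) {
      myPi <- stats[, paste0("pi_", p)]
      myS <- stats[, paste0("S_", p)]
      sePi <- sqrt(var(myPi) / nrep + oracle$pi[[p]][2]^2)
      seS <- sqrt(var(myS) / nrep + oracle$S[[p]][2]^2)
      expect_lt(abs(mean(myPi) - oracle$pi[[p]][1]), 3 * sePi)
      expect_lt(abs(mean(myS) - oracle$S[[p]][1]), 3 * seS)
    }
  }
})
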