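## Synthetic-data scenarios: fully simulated multi-population HVS-I
## datasets that exercise every stage of the pipeline without external
## downloads, plus panmictic null pairs for permutation-test calibration.
## Sequences are anchored on the packaged reference so motif notation,
## callers and networks operate identically on real and simulated data.

#' Construct a scenario configuration
#'
#' Defaults are the posterior means of the best-supported demographic
#' history (model 1: Ne 799/1489/657, T1 = 5472, T2 = 3505, a = 0.146),
#' used here as a realistic operating point, not as ground truth.
#'
#' @param model registry model label ("model1".."model4").
#' @param params named true parameter vector.
#' @param sampleSizes per-population sample sizes (Mogou, Hengbei,
#'   NorthernHan).
#' @param mutation a \linkS4class{MutationModel}.
#' @param seed integer seed.
#' @return list of class "scenarioConfig".
#' @export
scenarioConfig <- function(model = "model1",
                           params = c(Ne_Mogou = 799, Ne_Hengbei = 1489,
                                      Ne_NorthernHan = 657, T1 = 5472,
                                      T2 = 3505, a = 0.146),
                           sampleSizes = c(46L, 64L, 521L),
                           mutation = MutationModel(), seed = 1L) {
  structure(list(model = model, params = params,
                 sampleSizes = as.integer(sampleSizes),
                 mutation = mutation, seed = as.integer(seed)),
            class = "scenarioConfig")
}

#' Simulate a full scenario dataset
#'
#' Simulates under the configured model, converts the sequences to motifs
#' relative to the packaged reference, assigns synthetic sample IDs and
#' per-sample graves, and returns a truth manifest for recovery tests.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @return list with \code{dataset} (a \linkS4class{PopulationDataset}),
#'   \code{blocks} (per-population \linkS4class{SequenceBlock}s) and
#'   \code{truth} (model, params, seed).
#' @export
makeScenario <- function(config) {
  stopifnot(inherits(config, "scenarioConfig"))
  reg <- modelRegistry(sampleSizes = config$sampleSizes)
  if (!config$model %in% names(reg))
    stop("unknown model: ", config$model, call. = FALSE)
  template <- reg[[config$model]]
  prior <- modelPrior(template)
  pp <- prior@params
  have <- intersect(pp$name, names(config$params))
  bad <- have[config$params[have] < pp$lower[match(have, pp$name)] |
                config$params[have] > pp$upper[match(have, pp$name)]]
  if (length(bad))
    stop("parameter(s) outside prior support: ",
         paste(bad, collapse = ", "), call. = FALSE)
  model <- applyParams(template, config$params)
  sim <- simulateSequences(model, config$mutation, seed = config$seed)
  rows <- list(); motifs <- list()
  for (p in names(sim$blocks)) {
    b <- sim$blocks[[p]]
    labs <- blockLabels(b)
    seqs <- blockSequences(b)
    age <- model@samplingEvents$age[model@samplingEvents$deme == p]
    for (i in seq_along(labs)) {
      motifs[[labs[i]]] <- sequenceToMotif(seqs[i])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = labs[i], population = p,
        grave_id = paste0("g_", labs[i]), age_bp = as.integer(age),
        sex = "unknown", haplotype_id = "", haplogroup = "",
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)
  ages <- setNames(model@samplingEvents$age, model@samplingEvents$deme)
  dataset <- new("PopulationDataset", samples = samples, motifs = motifs,
                 populations = ages[unique(samples$population)])
  list(dataset = dataset, blocks = sim$blocks,
       truth = list(model = config$model,
                    params = as.list(config$params),
                    sampleSizes = config$sampleSizes,
                    mu = config$mutation@mu, L = config$mutation@L,
                    seed = config$seed))
}

#' Write / read a truth manifest
#'
#' @param truth the \code{truth} element of \code{\link{makeScenario}}.
#' @param file path to a JSON file.
#' @return \code{writeTruthManifest}: the path, invisibly;
#'   \code{readTruthManifest}: the manifest list.
#' @export
writeTruthManifest <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeTruthManifest
#' @export
readTruthManifest <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}

#' Simulate a panmictic null pair
#'
#' One deme, one sampling time; the sample is split arbitrarily into two
#' labeled populations, so the true PhiST is 0 by construction. Used for
#' permutation-test calibration.
#'
#' @param n sequences per labeled population (>= 2).
#' @param L sequence length.
#' @param theta population-scaled mutation rate 2*Ne*g*mu*L (expected
#'   pairwise differences).
#' @param seed optional integer seed.
#' @return list with \code{block} (a \linkS4class{SequenceBlock} over a
#'   synthetic window), \code{pop} (labels "A"/"B") and \code{states}.
#' @export
makeNullPair <- function(n, L = 334L, theta = 5, seed = NULL) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  ne <- 1000
  g <- 25
  mu <- theta / (2 * ne * g * L)
  model <- DemographicModel(c(pop = ne),
                            data.frame(deme = "pop", age = 0,
                                       n = as.integer(2 * n)),
                            generationTime = g, label = "null")
  mut <- MutationModel(mu = mu, L = L)
  ref <- if (L == HVS1_LEN) hvs1Reference() else NULL
  sim <- simulateSequences(model, mut, reference = ref)
  pop <- rep(c("A", "B"), each = n)
  if (!is.null(ref)) {
    block <- sim$blocks[[1]]
  } else {
    chars <- c("A", "G")
    seqs <- apply(sim$states, 1, function(r)
      paste(chars[r + 1L], collapse = ""))
    names(seqs) <- sprintf("s%03d", seq_along(seqs))
    block <- SequenceBlock(seqs, window = c(1L, L))
  }
  list(block = block, pop = pop, states = sim$states)
}
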