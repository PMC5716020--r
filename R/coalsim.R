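#' Construct a DemographicModel
#'
#' @param demes named numeric vector of constant effective haploid sizes.
#' @param samplingEvents data.frame (deme, age, n) in yr BP.
#' @param divergences data.frame (age, child, parent): backward in time the
#'   child deme's lineages join the parent at \code{age}.
#' @param pulses data.frame (age, source, sink, prop): a one-generation
#'   admixture pulse, forward in time a fraction \code{prop} of the sink
#'   derives from the source.
#' @param generationTime years per generation (default 25).
#' @param label model label.
#' @return A \linkS4class{DemographicModel}.
#' @export
DemographicModel <- function(demes, samplingEvents,
                             divergences = data.frame(age = numeric(0),
                                                      child = character(0),
                                                      parent = character(0)),
                             pulses = data.frame(age = numeric(0),
                                                 source = character(0),
                                                 sink = character(0),
                                                 prop = numeric(0)),
                             generationTime = 25, label = "model") {
  new("DemographicModel", demes = demes, samplingEvents = samplingEvents,
      divergences = divergences, pulses = pulses,
      generationTime = generationTime, label = label)
}

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel '", object@label, "': ",
      length(object@demes), " demes (",
      paste(names(object@demes), round(object@demes), sep = "=",
            collapse = ", "), ")\n", sep = "")
  cat("  sampling:", paste(object@samplingEvents$deme, "n=",
                           object@samplingEvents$n, "@",
                           object@samplingEvents$age, "BP",
                           collapse = "; "), "\n")
  if (nrow(object@divergences))
    cat("  divergences:", paste(object@divergences$child, "->",
                                object@divergences$parent, "@",
                                round(object@divergences$age), "BP",
                                collapse = "; "), "\n")
  if (nrow(object@pulses))
    cat("  pulses:", paste(object@pulses$source, "->", object@pulses$sink,
                           "prop", signif(object@pulses$prop, 3), "@",
                           round(object@pulses$age), "BP",
                           collapse = "; "), "\n")
})

#' Construct a MutationModel
#'
#' Defaults are the ancient-DNA-calibrated control-region rate 9.883e-8
#' substitutions per site per year over the 334-bp HVS-I window, with a
#' two-state transition-only finite-sites scheme (transitions dominate
#' HVS-I hypermutability; per-site multiple hits are allowed).
#'
#' @param mu substitution rate per site per year.
#' @param L sequence length (bp).
#' @param scheme "transition" (default) or "jc".
#' @return A \linkS4class{MutationModel}.
#' @export
MutationModel <- function(mu = 9.883e-8, L = 334L, scheme = "transition") {
  new("MutationModel", mu = mu, L = as.integer(L), scheme = scheme)
}

# Pack a model into the argument list of the C++ simulator (times converted
# from years BP to generations).
.modelArgs <- function(model, mutation) {
  g <- model@generationTime
  dn <- names(model@demes)
  se <- model@samplingEvents
  se <- se[order(se$age), , drop = FALSE]
  dv <- model@divergences
  pu <- model@pulses
  ev <- rbind(
    if (nrow(pu)) data.frame(t = pu$age / g, type = 1L,
                             a = match(pu$sink, dn) - 1L,
                             b = match(pu$source, dn) - 1L, p = pu$prop)
    else NULL,
    if (nrow(dv)) data.frame(t = dv$age / g, type = 2L,
                             a = match(dv$child, dn) - 1L,
                             b = match(dv$parent, dn) - 1L, p = 0)
    else NULL)
  if (is.null(ev)) ev <- data.frame(t = numeric(0), type = integer(0),
                                    a = integer(0), b = integer(0),
                                    p = numeric(0))
  list(ne = unname(model@demes),
       samp_deme = match(se$deme, dn) - 1L,
       samp_time = se$age / g,
       samp_n = as.integer(se$n),
       ev_time = ev$t, ev_type = ev$type, ev_a = ev$a, ev_b = ev$b,
       ev_p = ev$p,
       mu_seq_gen = mutation@mu * g * mutation@L,
       L = mutation@L,
       scheme = if (mutation@scheme == "jc") 1L else 0L,
       popNames = se$deme)
}

#' Simulate sequences under a demographic model
#'
#' Backward-in-time serial-sampling structured coalescent: within a deme of
#' haploid size Ne each lineage pair coalesces at rate 1/Ne per generation;
#' serial samples enter the genealogy at their age; at an admixture pulse
#' each sink lineage moves to the source deme with the pulse probability; at
#' a divergence the child deme's lineages move to the parent. Mutations are
#' dropped on branches as a Poisson process with rate mu*L per year.
#'
#' @param model a \linkS4class{DemographicModel}.
#' @param mutation a \linkS4class{MutationModel}.
#' @param seed optional integer seed.
#' @param reference reference \linkS4class{SequenceBlock} used to express
#'   the simulated states as nucleotides (its width must equal the mutation
#'   model's L for sequence output; pass NULL for raw states).
#' @return list with \code{blocks} (named list of
#'   \linkS4class{SequenceBlock}, one per sampled population),
#'   \code{states} (integer matrix of raw site states) and \code{pop}
#'   (population label per row).
#' @export
simulateSequences <- function(model, mutation = MutationModel(),
                              seed = NULL, reference = hvs1Reference()) {
  if (!is.null(seed)) set.seed(seed)
  validObject(model)
  a <- .modelArgs(model, mutation)
  X <- cpp_sim_serial(a$ne, a$samp_deme, a$samp_time, a$samp_n, a$ev_time,
                      a$ev_type, a$ev_a, a$ev_b, a$ev_p, a$mu_seq_gen, a$L,
                      a$scheme)
  pop <- rep(a$popNames, a$samp_n)
  blocks <- NULL
  if (!is.null(reference)) {
    refchars <- strsplit(blockSequences(reference)[1], "")[[1]]
    if (length(refchars) != a$L)
      stop("reference width does not match mutation model L", call. = FALSE)
    flip <- .TRANSIT[refchars]
    blocks <- lapply(unique(pop), function(p) {
      rows <- which(pop == p)
      seqs <- vapply(rows, function(i) {
        s <- refchars
        hit <- X[i, ] == 1L
        s[hit] <- flip[hit]
        if (a$scheme == 1L) {  # four-state: map states 2,3 to transversions
          tv <- X[i, ] >= 2L
          s[tv] <- c("A", "C")[X[i, tv] - 1L]
        }
        paste(s, collapse = "")
      }, character(1))
      names(seqs) <- sprintf("%s_%03d", p, seq_along(rows))
      SequenceBlock(seqs, blockWindow(reference))
    })
    names(blocks) <- unique(pop)
  }
  list(blocks = blocks, states = X, pop = pop)
}

## ---- model registry ------------------------------------------------------

.SAMPLE_DEFAULTS <- data.frame(
  deme = c("Mogou", "Hengbei", "NorthernHan"),
  age = c(4000, 3000, 0),
  n = c(46L, 64L, 521L), stringsAsFactors = FALSE)

#' The four candidate demographic models
#'
#' Three demes (Mogou, sampled ~4000 yr BP; Hengbei, ~3000 yr BP; Northern
#' Han, present day) under four topologies: Model 1 — Mogou and Hengbei
#' diverge at T1; Northern Han forms from the Hengbei lineage at T2 with an
#' admixture pulse of proportion a from Mogou. Model 2 — the mirror image
#' (Han from the Mogou lineage, pulse from Hengbei). Model 3 — Han from the
#' Hengbei lineage at T2, no admixture. Model 4 — Mogou and Hengbei are a
#' sister pair splitting at T2 whose common ancestor split from Han at T1,
#' no admixture. Models are data: edit the returned objects to change
#' topologies.
#'
#' @param sampleSizes integer vector of sample sizes for
#'   Mogou/Hengbei/NorthernHan (default 46/64/521).
#' @param demes named sizes used as template values (overwritten when
#'   simulating from a prior draw).
#' @param generationTime years per generation.
#' @param T1,T2,a template event parameters (defaults near the posterior
#'   means: T1=5472, T2=3505, a=0.146).
#' @return Named list of four \linkS4class{DemographicModel} templates.
#' @export
modelRegistry <- function(sampleSizes = c(46L, 64L, 521L),
                          demes = c(Mogou = 799, Hengbei = 1489,
                                    NorthernHan = 657),
                          generationTime = 25,
                          T1 = 5472, T2 = 3505, a = 0.146) {
  se <- .SAMPLE_DEFAULTS
  se$n <- as.integer(sampleSizes)
  div <- function(...) {
    d <- data.frame(...)
    names(d) <- c("age", "child", "parent"); d
  }
  pul <- function(...) {
    d <- data.frame(...)
    names(d) <- c("age", "source", "sink", "prop"); d
  }
  list(
    model1 = DemographicModel(
      demes, se,
      divergences = div(c(T2, T1), c("NorthernHan", "Mogou"),
                        c("Hengbei", "Hengbei")),
      pulses = pul(T2, "Mogou", "NorthernHan", a),
      generationTime = generationTime, label = "model1"),
    model2 = DemographicModel(
      demes, se,
      divergences = div(c(T2, T1), c("NorthernHan", "Hengbei"),
                        c("Mogou", "Mogou")),
      pulses = pul(T2, "Hengbei", "NorthernHan", a),
      generationTime = generationTime, label = "model2"),
    model3 = DemographicModel(
      demes, se,
      divergences = div(c(T2, T1), c("NorthernHan", "Mogou"),
                        c("Hengbei", "Hengbei")),
      generationTime = generationTime, label = "model3"),
    model4 = DemographicModel(
      demes, se,
      divergences = div(c(T2, T1), c("Mogou", "Hengbei"),
                        c("Hengbei", "NorthernHan")),
      generationTime = generationTime, label = "model4"))
}

#' Construct a PriorSpec
#'
#' @param params data.frame with columns name, lower, upper.
#' @param constraints character vector of "a<b" order constraints.
#' @return A \linkS4class{PriorSpec}.
#' @export
PriorSpec <- function(params, constraints = character(0)) {
  new("PriorSpec", params = params, constraints = constraints)
}

#' The default prior for a registry model
#'
#' Uniform priors: effective haploid sizes in [1, 1e5]; event times T1, T2
#' in [1, 2e4] yr BP with T2 < T1; admixture proportion a in [0.01, 1]
#' (models with a pulse only).
#'
#' @param model a \linkS4class{DemographicModel} (registry template).
#' @return A \linkS4class{PriorSpec}.
#' @export
modelPrior <- function(model) {
  p <- data.frame(
    name = c(paste0("Ne_", names(model@demes)), "T1", "T2"),
    lower = c(rep(1, length(model@demes)), 1, 1),
    upper = c(rep(1e5, length(model@demes)), 2e4, 2e4),
    stringsAsFactors = FALSE)
  if (nrow(model@pulses))
    p <- rbind(p, data.frame(name = "a", lower = 0.01, upper = 1))
  PriorSpec(p, constraints = "T2<T1")
}

#' Draw a parameter vector from a prior and instantiate a model template
#'
#' Independent uniform draws; order constraints are honoured by rejection.
#'
#' @param prior a \linkS4class{PriorSpec}.
#' @param template a \linkS4class{DemographicModel} whose deme sizes, event
#'   times and pulse proportions are replaced by the draw (parameter names
#'   "Ne_<deme>", "T1", "T2", "a").
#' @param maxTries rejection cap; exceeding it is a configuration error.
#' @return list with \code{model} (instantiated) and \code{params} (named
#'   numeric vector).
#' @export
drawFromPrior <- function(prior, template, maxTries = 1000) {
  p <- prior@params
  for (i in seq_len(maxTries)) {
    x <- setNames(runif(nrow(p), p$lower, p$upper), p$name)
    ok <- all(vapply(prior@constraints, function(cn) {
      ab <- strsplit(cn, "<", fixed = TRUE)[[1]]
      x[[ab[1]]] < x[[ab[2]]]
    }, logical(1)))
    if (ok) return(list(model = applyParams(template, x), params = x))
  }
  stop("prior constraint rejection rate too high (configuration error)",
       call. = FALSE)
}

#' Instantiate a model template with a named parameter vector
#'
#' @param template a \linkS4class{DemographicModel}.
#' @param params named numeric vector ("Ne_<deme>", "T1", "T2", "a").
#' @return A \linkS4class{DemographicModel}.
#' @export
applyParams <- function(template, params) {
  m <- template
  for (d in names(m@demes)) {
    key <- paste0("Ne_", d)
    if (key %in% names(params)) m@demes[[d]] <- params[[key]]
  }
  # registry convention: the younger divergence is T2, the older is T1
  if (nrow(m@divergences)) {
    iT2 <- which.min(m@divergences$age)
    iT1 <- which.max(m@divergences$age)
    if ("T2" %in% names(params)) m@divergences$age[iT2] <- params[["T2"]]
    if ("T1" %in% names(params)) m@divergences$age[iT1] <- params[["T1"]]
  }
  if (nrow(m@pulses) && "T2" %in% names(params))
    m@pulses$age <- params[["T2"]]
  if (nrow(m@pulses) && "a" %in% names(params))
    m@pulses$prop <- params[["a"]]
  m
}
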