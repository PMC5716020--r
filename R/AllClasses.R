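#' @title Core S4 classes
#' @description S4 containers used across the package. Variants are stored as
#'   data.frames with columns \code{pos} (1-based rCRS coordinate),
#'   \code{kind} (\code{"transition"}, \code{"transversion"},
#'   \code{"deletion"}, \code{"insertion"}), \code{base} (derived base or
#'   \code{NA}) and \code{span} (bp, for deletions).
#' @name paleomito-classes
NULL

.emptyVariants <- function() {
  data.frame(pos = integer(0), kind = character(0), base = character(0),
             span = integer(0), stringsAsFactors = FALSE)
}

.validVariants <- function(v) {
  if (!is.data.frame(v) ||
      !all(c("pos", "kind", "base", "span") %in% names(v)))
    return("variant table must have columns pos, kind, base, span")
  if (nrow(v) == 0) return(TRUE)
  if (any(v$pos < 1L | v$pos > 16569L))
    return("variant position outside [1, 16569]")
  if (!all(v$kind %in% c("transition", "transversion", "deletion",
                         "insertion")))
    return("unknown variant kind")
  need <- v$kind %in% c("transversion", "insertion")
  if (any(need & (is.na(v$base) | !v$base %in% c("A", "C", "G", "T"))))
    return("transversion/insertion without a derived base in {A,C,G,T}")
  if (any(v$span < 1L)) return("variant span must be >= 1")
  if (anyDuplicated(v$pos)) return("duplicate positions in a variant set")
  TRUE
}

#' HapMotif: a sample's variant set
#'
#' Holds the HVS-I variants (within [16051, 16384]), diagnostic coding-region
#' variants (outside that window) and special markers such as the 9-bp
#' COII/tRNA-Lys deletion (\code{"9bp_del"}).
#'
#' @slot hvs1 data.frame of HVS-I variants.
#' @slot coding data.frame of coding-region variants.
#' @slot markers character vector of special marker labels.
#' @exportClass HapMotif
setClass("HapMotif", representation(hvs1 = "data.frame",
                                    coding = "data.frame",
                                    markers = "character"))

setValidity("HapMotif", function(object) {
  ok <- .validVariants(object@hvs1)
  if (!isTRUE(ok)) return(ok)
  ok <- .validVariants(object@coding)
  if (!isTRUE(ok)) return(ok)
  if (nrow(object@hvs1) &&
      any(object@hvs1$pos < HVS1_START | object@hvs1$pos > HVS1_END))
    return("hvs1 slot contains variants outside the HVS-I window")
  if (nrow(object@coding) &&
      any(object@coding$pos >= HVS1_START & object@coding$pos <= HVS1_END))
    return("coding slot contains variants inside the HVS-I window")
  TRUE
})

#' PopulationDataset: samples grouped into populations
#'
#' @slot samples data.frame with columns sample_id, population, grave_id,
#'   age_bp, sex, haplotype_id, haplogroup.
#' @slot motifs named list of \linkS4class{HapMotif}, one per sample.
#' @slot populations named numeric vector of sampling ages (yr BP).
#' @exportClass PopulationDataset
setClass("PopulationDataset", representation(samples = "data.frame",
                                             motifs = "list",
                                             populations = "numeric"))

setValidity("PopulationDataset", function(object) {
  s <- object@samples
  need <- c("sample_id", "population", "grave_id", "age_bp", "sex",
            "haplotype_id", "haplogroup")
  if (!all(need %in% names(s)))
    return(paste("samples table must have columns:",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(s$sample_id)) return("duplicated sample_id")
  if (nrow(s) && !setequal(names(object@motifs), s$sample_id))
    return("motif list names must match sample_id")
  if (nrow(s) && !all(s$population %in% names(object@populations)))
    return("every sample's population must appear in the population map")
  if (nrow(s) && !all(s$sex %in% c("male", "female", "unknown")))
    return("sex must be male, female or unknown")
  TRUE
})

#' SequenceBlock: aligned sequences over a coordinate window
#'
#' @slot seqs named \code{DNAStringSet}; all sequences have equal width.
#' @slot window integer vector (start, end) in rCRS coordinates.
#' @exportClass SequenceBlock
setClass("SequenceBlock", representation(seqs = "ANY", window = "integer"))

setValidity("SequenceBlock", function(object) {
  if (!is(object@seqs, "DNAStringSet")) return("seqs must be a DNAStringSet")
  if (length(object@window) != 2L || object@window[2] < object@window[1])
    return("window must be (start, end) with start <= end")
  w <- Biostrings::width(object@seqs)
  if (length(w) && length(unique(w)) != 1L)
    return("all sequences must have identical length")
  if (length(w) && w[1] != diff(object@window) + 1L)
    return("sequence length must equal the window span")
  if (length(w) && is.null(names(object@seqs)))
    return("sequences must be named by sample_id")
  TRUE
})

#' HaplogroupTree: rooted rule tree of diagnostic variants
#'
#' @slot nodes data.frame with columns label, parent.
#' @slot defs named list of character token vectors (defining variants).
#' @slot root root label.
#' @exportClass HaplogroupTree
setClass("HaplogroupTree", representation(nodes = "data.frame",
                                          defs = "list",
                                          root = "character"))

setValidity("HaplogroupTree", function(object) {
  n <- object@nodes
  if (!all(c("label", "parent") %in% names(n)))
    return("nodes must have columns label, parent")
  if (anyDuplicated(n$label)) return("duplicated node labels")
  if (!all(n$parent %in% c(object@root, n$label)))
    return("every parent must be the root or another node")
  # acyclicity: walking up from each node must reach the root
  for (lab in n$label) {
    seen <- character(0); cur <- lab
    while (cur != object@root) {
      if (cur %in% seen) return(paste("cycle at node", lab))
      seen <- c(seen, cur)
      cur <- n$parent[match(cur, n$label)]
      if (is.na(cur)) return(paste("broken parent link at", lab))
    }
  }
  TRUE
})

#' YSnpPanel: ordered SNP markers on a haplogroup tree
#'
#' @slot markers data.frame with columns node, parent, marker, ancestral,
#'   derived.
#' @slot tree \linkS4class{HaplogroupTree} over the panel's nodes.
#' @exportClass YSnpPanel
setClass("YSnpPanel", representation(markers = "data.frame",
                                     tree = "HaplogroupTree"))

#' HaplogroupCall: result of a rule-tree call
#'
#' @slot label called haplogroup (or \code{"unassigned"}).
#' @slot path node labels root to call.
#' @slot evidence named list, matched tokens per path node.
#' @slot conflicts character vector describing contradictory diagnostics.
#' @slot lowConfidence logical; TRUE for motif-only exact-match calls.
#' @exportClass HaplogroupCall
setClass("HaplogroupCall", representation(label = "character",
                                          path = "character",
                                          evidence = "list",
                                          conflicts = "character",
                                          lowConfidence = "logical"))

#' DemographicModel: demes, sizes, events and sampling scheme
#'
#' Times are in years BP at the interface; they are converted to generations
#' internally using \code{generationTime}.
#'
#' @slot demes named numeric vector of constant effective haploid sizes.
#' @slot samplingEvents data.frame (deme, age, n).
#' @slot divergences data.frame (age, child, parent): looking backward in
#'   time, at \code{age} the child deme's lineages join the parent deme.
#' @slot pulses data.frame (age, source, sink, prop): forward in time a
#'   fraction \code{prop} of the sink deme derives from the source at
#'   \code{age}; backward, each sink lineage moves to the source with
#'   probability \code{prop}.
#' @slot generationTime generation time in years.
#' @slot label model label.
#' @exportClass DemographicModel
setClass("DemographicModel", representation(demes = "numeric",
                                            samplingEvents = "data.frame",
                                            divergences = "data.frame",
                                            pulses = "data.frame",
                                            generationTime = "numeric",
                                            label = "character"))

setValidity("DemographicModel", function(object) {
  if (is.null(names(object@demes)) || any(object@demes <= 0))
    return("demes must be a named vector of positive sizes")
  dn <- names(object@demes)
  se <- object@samplingEvents
  if (nrow(se) && !all(se$deme %in% dn)) return("sampling in unknown deme")
  dv <- object@divergences
  if (nrow(dv) && !all(c(dv$child, dv$parent) %in% dn))
    return("divergence references unknown deme")
  pu <- object@pulses
  if (nrow(pu)) {
    if (!all(c(pu$source, pu$sink) %in% dn))
      return("pulse references unknown deme")
    if (any(pu$prop < 0 | pu$prop > 1))
      return("pulse proportion outside [0, 1]")
    # a pulse must predate (be younger than) the divergence that removes
    # either involved deme
    for (i in seq_len(nrow(pu))) {
      gone <- dv$age[dv$child %in% c(pu$source[i], pu$sink[i])]
      if (length(gone) && any(gone < pu$age[i]))
        return("admixture pulse older than a divergence removing its deme")
    }
  }
  if (object@generationTime <= 0) return("generationTime must be positive")
  TRUE
})

#' MutationModel: substitution process for HVS-I sequences
#'
#' @slot mu substitution rate per site per year.
#' @slot L sequence length (bp).
#' @slot scheme \code{"transition"} (two-state toggling, default) or
#'   \code{"jc"} (equal-rates four-state).
#' @exportClass MutationModel
setClass("MutationModel", representation(mu = "numeric", L = "integer",
                                         scheme = "character"))

setValidity("MutationModel", function(object) {
  if (object@mu <= 0) return("mu must be positive")
  if (object@L < 1L) return("L must be >= 1")
  if (!object@scheme %in% c("transition", "jc")) return("unknown scheme")
  TRUE
})

#' PriorSpec: independent uniform priors with order constraints
#'
#' @slot params data.frame with columns name, lower, upper.
#' @slot constraints character vector of \code{"a<b"} order constraints.
#' @exportClass PriorSpec
setClass("PriorSpec", representation(params = "data.frame",
                                     constraints = "character"))

setValidity("PriorSpec", function(object) {
  p <- object@params
  if (!all(c("name", "lower", "upper") %in% names(p)))
    return("params must have columns name, lower, upper")
  if (any(!is.finite(p$lower)) || any(!is.finite(p$upper)))
    return("prior bounds must be finite")
  if (any(p$upper < p$lower)) return("upper < lower in prior")
  TRUE
})

#' ReferenceTable: simulated parameters and summary statistics per model
#'
#' @slot models model labels.
#' @slot params named list of parameter matrices (one per model).
#' @slot stats named list of summary-statistic matrices (one per model,
#'   identical columns).
#' @slot scale named numeric vector of pooled per-statistic MADs used for
#'   standardization.
#' @exportClass ReferenceTable
setClass("ReferenceTable", representation(models = "character",
                                          params = "list",
                                          stats = "list",
                                          scale = "numeric"))

setValidity("ReferenceTable", function(object) {
  if (!setequal(object@models, names(object@stats)) ||
      !setequal(object@models, names(object@params)))
    return("params/stats must be named by model")
  for (m in object@models)
    if (nrow(object@params[[m]]) != nrow(object@stats[[m]]))
      return("params and stats row counts differ")
  TRUE
})

#' AbcResult: output of the rejection/regression ABC machinery
#'
#' @slot modelProb matrix of model probabilities (rows "AR", "LR").
#' @slot accepted data.frame (model, index, distance) of accepted replicates.
#' @slot posterior named list per model: list(raw, adjusted, weights) of
#'   parameter draws.
#' @slot estimates named list per model: data.frame with mean, mode, hpd_lo,
#'   hpd_hi per parameter.
#' @slot eps accepted fraction used.
#' @slot notes character log (e.g. LR fallback).
#' @exportClass AbcResult
setClass("AbcResult", representation(modelProb = "matrix",
                                     accepted = "data.frame",
                                     posterior = "list",
                                     estimates = "list",
                                     eps = "numeric",
                                     notes = "character"))

#' AmovaResult: hierarchical analysis of molecular variance
#'
#' @slot table data.frame with df, SSD, variance components and percentages.
#' @slot phi named numeric (PhiCT, PhiSC, PhiST as applicable).
#' @slot pvalues named numeric permutation p-values.
#' @slot nperm permutations used.
#' @exportClass AmovaResult
setClass("AmovaResult", representation(table = "data.frame",
                                       phi = "numeric",
                                       pvalues = "numeric",
                                       nperm = "integer"))

#' TemporalNetwork: layered haplotype network
#'
#' @slot layers data.frame (layer, age_bp, n).
#' @slot nodes data.frame (node, layer, count, sequence, members).
#' @slot edges data.frame (from, to, weight): within-layer minimum spanning
#'   network edges (weights in nucleotide differences).
#' @slot crossEdges data.frame (from, to): identity links across layers.
#' @exportClass TemporalNetwork
setClass("TemporalNetwork", representation(layers = "data.frame",
                                           nodes = "data.frame",
                                           edges = "data.frame",
                                           crossEdges = "data.frame"))
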