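## Temporal haplotype networks: each time layer collapses its sequences to
## distinct haplotypes; within a layer the topology is the minimum spanning
## network (union of all minimum spanning trees, keeping every co-minimal
## edge); identical haplotypes in different layers are linked by cross-layer
## identity edges.

# Collapse sequences to haplotype classes. Sequences are identical-modulo-N
# when they agree at all non-N sites and the N-poorer profile has <= 2 Ns
# on the candidate partner (conservative sharing). When haplotype ids are
# supplied they define the classes directly.
.collapseLayer <- function(seqs, ids = NULL) {
  n <- length(seqs)
  if (!is.null(ids)) {
    cls <- match(ids, unique(ids))
  } else {
    cls <- integer(n)
    reps <- character(0)
    for (i in seq_len(n)) {
      hit <- 0L
      for (r in seq_along(reps)) {
        if (.seqIdentical(seqs[i], reps[r])) { hit <- r; break }
      }
      if (hit == 0L) { reps <- c(reps, seqs[i]); hit <- length(reps) }
      cls[i] <- hit
    }
  }
  split(seq_len(n), cls)
}

.seqIdentical <- function(a, b) {
  if (a == b) return(TRUE)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  nA <- ca == "N"; nB <- cb == "N"
  if (sum(nA) > 2 && sum(nB) > 2) return(FALSE)
  mask <- !(nA | nB)
  all(ca[mask] == cb[mask])
}

# Minimum spanning network over a distance matrix: process edge-weight
# classes in increasing order; within a class admit every edge joining two
# components as they stood before the class, then merge.
.msnEdges <- function(D) {
  n <- nrow(D)
  if (n < 2) return(data.frame(from = integer(0), to = integer(0),
                               weight = numeric(0)))
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  edges <- data.frame(from = integer(0), to = integer(0),
                      weight = numeric(0))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[upper.tri(D)]
  for (wc in sort(unique(w))) {
    sel <- which(w == wc)
    pre <- vapply(seq_len(n), function(i) find(i), integer(1))
    keep <- sel[pre[pairs[sel, 1]] != pre[pairs[sel, 2]]]
    for (e in keep)
      edges <- rbind(edges, data.frame(from = pairs[e, 1], to = pairs[e, 2],
                                       weight = wc))
    for (e in keep) {
      ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
      if (ra != rb) comp[ra] <- rb
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) == 1L) break
  }
  edges
}

#' Build a temporal haplotype network
#'
#' @param blocks named list of \linkS4class{SequenceBlock}, one per time
#'   layer, all aligned to the same window; list order is layer order.
#' @param ages numeric vector of layer ages (yr BP), same length.
#' @param ids optional list of haplotype-id vectors (per layer) used instead
#'   of sequence identity for collapsing (distinguishing-token support).
#' @return A \linkS4class{TemporalNetwork}.
#' @export
buildTempNet <- function(blocks, ages, ids = NULL) {
  stopifnot(length(blocks) >= 2, length(ages) == length(blocks))
  if (is.null(names(blocks)))
    names(blocks) <- paste0("layer", seq_along(blocks))
  win <- blockWindow(blocks[[1]])
  for (b in blocks)
    if (!identical(blockWindow(b), win))
      stop("layers aligned to different windows", call. = FALSE)
  layers <- data.frame(layer = names(blocks), age_bp = ages,
                       n = vapply(blocks, function(b)
                         length(blockLabels(b)), integer(1)),
                       stringsAsFactors = FALSE)
  nodes <- data.frame(node = character(0), layer = character(0),
                      count = integer(0), sequence = character(0),
                      members = character(0), stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  nodeSeqs <- list()
  for (li in seq_along(blocks)) {
    b <- blocks[[li]]
    seqs <- blockSequences(b)
    labs <- blockLabels(b)
    groups <- .collapseLayer(seqs, if (!is.null(ids)) ids[[li]] else NULL)
    nm <- paste0(names(blocks)[li], ".h", seq_along(groups))
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      nodes <- rbind(nodes, data.frame(
        node = nm[gi], layer = names(blocks)[li], count = length(g),
        sequence = seqs[g[1]], members = paste(labs[g], collapse = ","),
        stringsAsFactors = FALSE))
      nodeSeqs[[nm[gi]]] <- seqs[g[1]]
    }
    if (length(groups) > 1) {
      reps <- vapply(groups, function(g) seqs[g[1]], character(1))
      Dl <- cpp_seq_diff(reps)
      me <- .msnEdges(Dl)
      if (nrow(me))
        edges <- rbind(edges, data.frame(from = nm[me$from], to = nm[me$to],
                                         weight = me$weight,
                                         stringsAsFactors = FALSE))
    }
  }
  cross <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  nd <- nodes
  for (i in seq_len(nrow(nd) - 1)) for (j in seq(i + 1, nrow(nd))) {
    if (nd$layer[i] != nd$layer[j] &&
        .seqIdentical(nd$sequence[i], nd$sequence[j]))
      cross <- rbind(cross, data.frame(from = nd$node[i], to = nd$node[j],
                                       stringsAsFactors = FALSE))
  }
  new("TemporalNetwork", layers = layers, nodes = nodes, edges = edges,
      crossEdges = cross)
}

setMethod("show", "TemporalNetwork", function(object) {
  cat("TemporalNetwork:", nrow(object@layers), "layers,",
      nrow(object@nodes), "haplotype nodes,", nrow(object@edges),
      "within-layer edges,", nrow(object@crossEdges), "cross-layer links\n")
  print(object@layers, row.names = FALSE)
})

#' @describeIn buildTempNet Layer table accessor.
#' @param net a \linkS4class{TemporalNetwork}.
#' @export
tempnetLayers <- function(net) net@layers

#' @describeIn buildTempNet Node table accessor.
#' @export
tempnetNodes <- function(net) net@nodes

#' @describeIn buildTempNet Within-layer edge table accessor.
#' @export
tempnetEdges <- function(net) net@edges

#' @describeIn buildTempNet Cross-layer identity link accessor.
#' @export
tempnetCrossEdges <- function(net) net@crossEdges

#' Haplotype sharing report across layers
#'
#' One row per haplotype class (sequence identity across layers), listing
#' presence and carrier counts per layer, sorted by decreasing number of
#' layers then node ID.
#'
#' @param net a \linkS4class{TemporalNetwork}.
#' @return data.frame with columns haplotype, n_layers, layers, plus one
#'   count column per layer.
#' @export
sharedHaplotypeReport <- function(net) {
  nd <- net@nodes
  # union-find over cross-layer identity links
  cls <- seq_len(nrow(nd))
  find <- function(i) { while (cls[i] != i) i <- cls[i]; i }
  for (r in seq_len(nrow(net@crossEdges))) {
    i <- match(net@crossEdges$from[r], nd$node)
    j <- match(net@crossEdges$to[r], nd$node)
    cls[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(nrow(nd)), find, integer(1))
  layerNames <- net@layers$layer
  rows <- lapply(split(seq_len(nrow(nd)), roots), function(i) {
    cnt <- setNames(integer(length(layerNames)), layerNames)
    for (k in i) cnt[nd$layer[k]] <- cnt[nd$layer[k]] + nd$count[k]
    present <- layerNames[cnt > 0]
    c(list(haplotype = nd$node[min(i)], n_layers = length(present),
           layers = paste(present, collapse = ",")), as.list(cnt))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- out[order(-out$n_layers, out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a temporal network to igraph / DOT
#'
#' @param net a \linkS4class{TemporalNetwork}.
#' @return An \code{igraph} object with node attributes layer, age_bp and
#'   count; cross-layer identity links carry edge attribute
#'   \code{kind = "identity"}.
#' @export
tempnetGraph <- function(net) {
  nd <- net@nodes
  e1 <- net@edges
  e2 <- net@crossEdges
  el <- rbind(data.frame(from = e1$from, to = e1$to, weight = e1$weight,
                         kind = "mutation", stringsAsFactors = FALSE),
              data.frame(from = e2$from, to = e2$to, weight = 0,
                         kind = "identity", stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(name = nd$node, layer = nd$layer,
                          age_bp = net@layers$age_bp[match(nd$layer,
                                                           net@layers$layer)],
                          count = nd$count, stringsAsFactors = FALSE))
  g
}

#' @describeIn tempnetGraph Write the network in DOT format.
#' @param file output path.
#' @export
writeTempNetDot <- function(net, file) {
  igraph::write_graph(tempnetGraph(net), file, format = "dot")
  invisible(file)
}
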