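## Rule-tree haplogroup assignment.
##
## mtDNA: a node is supported when at least one of its defining tokens is
## satisfied by the sample's typed variants. Coding diagnostics are
## presence/absence semantics (the APLP-style typing the source data use);
## explicit alleles are matched only where the rule states one (e.g. 15487T).
## Star labels (D*, N*) are fallback children taken when the parent holds but
## no typed sibling diagnostic is present. Extra private HVS-I variants never
## veto a call; only support for two mutually exclusive branches does.

#' Read a haplogroup rule tree from its plain-text definition
#'
#' Format: one node per line, tab separated: label, parent label, a
#' comma-separated list of defining tokens. Lines starting with "#" are
#' comments. See the packaged \code{mt_haplogroup_tree.txt} for the token
#' grammar.
#'
#' @param file path to a tree definition file.
#' @param root root label (default "ROOT").
#' @return A \linkS4class{HaplogroupTree}.
#' @export
readHaplogroupTree <- function(file, root = "ROOT") {
  ln <- readLines(file)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  nodes <- data.frame(label = vapply(parts, `[[`, "", 1),
                      parent = vapply(parts, `[[`, "", 2),
                      stringsAsFactors = FALSE)
  defs <- lapply(parts, function(p)
    if (length(p) >= 3) trimws(strsplit(p[3], ",", fixed = TRUE)[[1]])
    else character(0))
  names(defs) <- nodes$label
  new("HaplogroupTree", nodes = nodes, defs = defs, root = root)
}

#' The packaged East Asian mtDNA rule tree
#' @return A \linkS4class{HaplogroupTree}.
#' @export
mtHaplogroupTree <- function() {
  if (is.null(.pmEnv$mtTree))
    .pmEnv$mtTree <- readHaplogroupTree(
      system.file("extdata", "mt_haplogroup_tree.txt", package = "paleomito"))
  .pmEnv$mtTree
}

#' The packaged Y-chromosome SNP panel
#' @return A \linkS4class{YSnpPanel}.
#' @export
ySnpPanel <- function() {
  if (is.null(.pmEnv$yPanel)) {
    f <- system.file("extdata", "y_snp_panel.txt", package = "paleomito")
    ln <- readLines(f)
    ln <- ln[!grepl("^\\s*(#|$)", ln)]
    parts <- strsplit(ln, "\t", fixed = TRUE)
    mk <- data.frame(node = vapply(parts, `[[`, "", 1),
                     parent = vapply(parts, `[[`, "", 2),
                     marker = vapply(parts, `[[`, "", 3),
                     ancestral = vapply(parts, `[[`, "", 4),
                     derived = vapply(parts, `[[`, "", 5),
                     stringsAsFactors = FALSE)
    tree <- new("HaplogroupTree",
                nodes = mk[, c("node", "parent")] |>
                  setNames(c("label", "parent")),
                defs = setNames(as.list(mk$marker), mk$node),
                root = "ROOT")
    .pmEnv$yPanel <- new("YSnpPanel", markers = mk, tree = tree)
  }
  .pmEnv$yPanel
}

setMethod("show", "HaplogroupTree", function(object) {
  cat("HaplogroupTree:", nrow(object@nodes), "nodes, root =", object@root,
      "\n")
})

setMethod("show", "YSnpPanel", function(object) {
  cat("YSnpPanel:", nrow(object@markers), "markers over nodes",
      paste(object@markers$node, collapse = " > "), "\n")
})

setMethod("show", "HaplogroupCall", function(object) {
  cat("HaplogroupCall:", object@label,
      if (object@lowConfidence) "(low confidence)" else "", "\n")
  if (length(object@path))
    cat("  path:", paste(object@path, collapse = " > "), "\n")
  if (length(object@conflicts))
    cat("  conflicts:", paste(object@conflicts, collapse = "; "), "\n")
})

#' @describeIn callMtHaplogroup Called label of a HaplogroupCall.
#' @export
callLabel <- function(call) call@label

#' @describeIn callMtHaplogroup Conflict descriptions of a HaplogroupCall.
#' @export
callConflicts <- function(call) call@conflicts

# Does a defining token hold for this motif? Returns FALSE/TRUE, with
# attribute "kind" = coding/marker/hvs recording the evidence class.
.tokenHolds <- function(token, motif) {
  codingTyped <- nrow(motif@coding) > 0L || length(motif@markers) > 0L
  hvsTrans <- motif@hvs1$pos[motif@hvs1$kind == "transition"]
  res <- FALSE; kind <- "coding"
  if (grepl("^del:", token)) {
    res <- sub("^del:", "", token) == "9bp" && "9bp_del" %in% motif@markers
    kind <- "marker"
  } else if (grepl("^!", token)) {
    pos <- as.integer(sub("^!", "", token))
    res <- codingTyped && !pos %in% motif@coding$pos
  } else if (grepl("^hvs\\*", token)) {
    pp <- as.integer(strsplit(sub("^hvs\\*", "", token), "+",
                              fixed = TRUE)[[1]])
    res <- all(pp %in% motif@hvs1$pos); kind <- "hvs"
  } else if (grepl("^hvs=", token)) {
    pp <- as.integer(strsplit(sub("^hvs=", "", token), "+",
                              fixed = TRUE)[[1]])
    res <- setequal(hvsTrans, pp) && nrow(motif@hvs1) == length(pp)
    kind <- "hvs"
  } else {
    m <- regmatches(token, regexec("^([0-9]+)([ACGT]?)$", token))[[1]]
    if (length(m) == 0L) stop("bad tree token: ", token, call. = FALSE)
    pos <- as.integer(m[2])
    hit <- motif@coding[motif@coding$pos == pos, , drop = FALSE]
    res <- nrow(hit) == 1L &&
      (m[3] == "" || (!is.na(hit$base[1]) && hit$base[1] == m[3]) ||
         is.na(hit$base[1]))
  }
  attr(res, "kind") <- kind
  res
}

.nodeSupport <- function(label, tree, motif) {
  toks <- tree@defs[[label]]
  toks <- toks[toks != "*"]
  hits <- character(0); kinds <- character(0)
  for (tk in toks) {
    if (tk == "child") {
      kids <- tree@nodes$label[tree@nodes$parent == label]
      kids <- kids[!vapply(kids, function(k) "*" %in% tree@defs[[k]],
                           logical(1))]
      sup <- vapply(kids, function(k)
        .nodeSupport(k, tree, motif)$ok, logical(1))
      if (any(sup)) { hits <- c(hits, tk); kinds <- c(kinds, "coding") }
      next
    }
    h <- .tokenHolds(tk, motif)
    if (h) { hits <- c(hits, tk); kinds <- c(kinds, attr(h, "kind")) }
  }
  list(ok = length(hits) > 0L, hits = hits, kinds = kinds)
}

# depth of the deepest supported descendant chain below a node (0 = none)
.supportDepth <- function(label, tree, motif) {
  kids <- tree@nodes$label[tree@nodes$parent == label]
  kids <- kids[!vapply(kids, function(k) "*" %in% tree@defs[[k]],
                       logical(1))]
  best <- 0L
  for (k in kids)
    if (.nodeSupport(k, tree, motif)$ok)
      best <- max(best, 1L + .supportDepth(k, tree, motif))
  best
}

#' Call the mtDNA haplogroup of a motif
#'
#' Walks the rule tree from the root, descending into children with at least
#' one satisfied defining token. Coding/marker diagnostics take priority over
#' motif-only (HVS-I) rules when several children are supported; support for
#' two mutually exclusive coding-diagnosed branches yields an ambiguous call
#' carrying both candidates rather than a silent pick. Star children
#' (defining token \code{"*"}) are taken when the parent holds but no typed
#' sibling does.
#'
#' @param motif a \linkS4class{HapMotif}.
#' @param tree a \linkS4class{HaplogroupTree} (default the packaged East
#'   Asian tree).
#' @return A \linkS4class{HaplogroupCall}. An empty motif yields label
#'   \code{"unassigned"}.
#' @examples
#' m <- mergeMotifs(parseMotif("223-298-327"), parseCodingSnps("10400;14318"))
#' callLabel(callMtHaplogroup(m))
#' @export
callMtHaplogroup <- function(motif, tree = mtHaplogroupTree()) {
  if (isEmptyMotif(motif))
    return(new("HaplogroupCall", label = "unassigned", path = character(0),
               evidence = list(), conflicts = character(0),
               lowConfidence = FALSE))
  cur <- tree@root
  path <- character(0); evid <- list(); lowConf <- FALSE
  conflicts <- character(0)
  repeat {
    kids <- tree@nodes$label[tree@nodes$parent == cur]
    if (!length(kids)) break
    star <- kids[vapply(kids, function(k) "*" %in% tree@defs[[k]],
                        logical(1))]
    kids <- setdiff(kids, star)
    sup <- lapply(kids, .nodeSupport, tree = tree, motif = motif)
    ok <- vapply(sup, `[[`, logical(1), "ok")
    hitKids <- kids[ok]
    if (length(hitKids) > 1L) {
      # deeper specific support wins (a subclade diagnostic outranks a
      # bare branch marker); then coding/marker evidence outranks
      # motif-only rules
      depth <- vapply(hitKids, .supportDepth, integer(1), tree = tree,
                      motif = motif)
      hitKids2 <- hitKids[depth == max(depth)]
      sup2 <- sup[ok][depth == max(depth)]
      codingBacked <- vapply(sup2, function(s)
        any(s$kinds %in% c("coding", "marker")), logical(1))
      if (length(hitKids2) == 1L) {
        hitKids <- hitKids2
      } else if (sum(codingBacked) == 1L) {
        hitKids <- hitKids2[codingBacked]
      } else {
        hitKids <- hitKids2
        conflicts <- paste0("mutually exclusive branches supported: ",
                            paste(hitKids, collapse = " vs "))
        return(new("HaplogroupCall", label = "ambiguous",
                   path = c(path, cur), evidence = evid,
                   conflicts = conflicts, lowConfidence = FALSE))
      }
    }
    if (length(hitKids) == 0L) {
      if (length(star) && length(path)) {
        # parent supported, no deeper diagnostic: emit the star label
        path <- c(path, cur); cur <- star[1]
        evid[[cur]] <- "*"
      }
      break
    }
    nxt <- hitKids[1]
    s <- sup[[match(nxt, kids)]]
    path <- c(path, cur)
    evid[[nxt]] <- s$hits
    if (all(s$kinds == "hvs")) lowConf <- TRUE
    cur <- nxt
  }
  if (cur == tree@root)
    return(new("HaplogroupCall", label = "unassigned", path = character(0),
               evidence = list(), conflicts = character(0),
               lowConfidence = FALSE))
  new("HaplogroupCall", label = cur, path = c(path, cur), evidence = evid,
      conflicts = conflicts, lowConfidence = lowConf)
}

#' Call a Y-chromosome haplogroup from a SNP genotype vector
#'
#' The call is the deepest panel node whose marker is derived and whose
#' ancestors are derived wherever typed; an ancestral genotype at a node
#' blocks its whole subtree, while untyped markers do not block but cap the
#' call depth. A derived child under a typed-ancestral parent is reported in
#' the conflicts field.
#'
#' @param genotypes named character vector (marker -> observed allele;
#'   literal keywords "derived"/"ancestral" are also accepted). Missing
#'   markers are allowed.
#' @param panel a \linkS4class{YSnpPanel}.
#' @return A \linkS4class{HaplogroupCall}.
#' @export
callYHaplogroup <- function(genotypes, panel = ySnpPanel()) {
  mk <- panel@markers
  norm <- function(x) gsub("−", "-", gsub("\\s", "", x))
  genotypes <- as.list(genotypes)
  state <- vapply(seq_len(nrow(mk)), function(i) {
    if (!mk$marker[i] %in% names(genotypes)) return("missing")
    g <- genotypes[[mk$marker[i]]]
    if (is.null(g) || is.na(g) || g == "") return("missing")
    g <- norm(g)
    if (tolower(g) == "derived") return("derived")
    if (tolower(g) == "ancestral") return("ancestral")
    if (mk$derived[i] != "." && g == norm(mk$derived[i])) return("derived")
    if (mk$ancestral[i] != "." && g == norm(mk$ancestral[i]))
      return("ancestral")
    "missing"
  }, character(1))
  names(state) <- mk$node
  conflicts <- character(0)
  # depth-first: deepest node with derived state and no typed-ancestral
  # ancestor; ancestors may be missing
  best <- character(0)
  for (i in seq_len(nrow(mk))) {
    if (state[i] != "derived") next
    cur <- mk$parent[i]; blocked <- FALSE
    while (cur != panel@tree@root) {
      j <- match(cur, mk$node)
      if (state[j] == "ancestral") {
        blocked <- TRUE
        conflicts <- c(conflicts, paste0(mk$node[i], " derived under ",
                                         cur, " ancestral"))
      }
      cur <- mk$parent[j]
    }
    if (!blocked) {
      cand <- mk$node[i]
      if (!length(best) || .yDepth(cand, panel) > .yDepth(best, panel))
        best <- cand
    }
  }
  if (!length(best))
    return(new("HaplogroupCall", label = "unassigned", path = character(0),
               evidence = list(), conflicts = unique(conflicts),
               lowConfidence = FALSE))
  path <- best
  cur <- mk$parent[match(best, mk$node)]
  while (cur != panel@tree@root) {
    path <- c(cur, path)
    cur <- mk$parent[match(cur, mk$node)]
  }
  evid <- lapply(path, function(nd) {
    j <- match(nd, mk$node)
    paste0(mk$marker[j], "=", state[j])
  })
  names(evid) <- path
  new("HaplogroupCall", label = best, path = path, evidence = evid,
      conflicts = unique(conflicts), lowConfidence = FALSE)
}

.yDepth <- function(node, panel) {
  d <- 0L; cur <- node
  while (cur != panel@tree@root) {
    d <- d + 1L
    cur <- panel@markers$parent[match(cur, panel@markers$node)]
  }
  d
}

#' Annotate every sample of a dataset with haplogroup calls
#'
#' Runs the mtDNA caller on each sample motif and, where Y genotypes are
#' supplied, the Y caller on each genotyped male. Returns the dataset with
#' the haplogroup column filled from the calls, plus a per-label summary.
#'
#' @param dataset a \linkS4class{PopulationDataset}.
#' @param tree mtDNA rule tree.
#' @param yGenotypes optional data.frame of Y genotypes (rows = sample ids).
#' @param panel Y SNP panel.
#' @return A list with elements \code{dataset} (annotated), \code{mtCalls}
#'   (named character), \code{yCalls} (named character or NULL) and
#'   \code{summary} (table of call counts).
#' @export
callDataset <- function(dataset, tree = mtHaplogroupTree(),
                        yGenotypes = NULL, panel = ySnpPanel()) {
  ids <- dataset@samples$sample_id
  mtCalls <- vapply(ids, function(id)
    callLabel(callMtHaplogroup(dataset@motifs[[id]], tree)), character(1))
  out <- dataset
  out@samples$haplogroup <- unname(mtCalls)
  yCalls <- NULL
  if (!is.null(yGenotypes)) {
    yCalls <- vapply(rownames(yGenotypes), function(id)
      callLabel(callYHaplogroup(unlist(yGenotypes[id, , drop = TRUE]),
                                panel)), character(1))
  }
  list(dataset = out, mtCalls = mtCalls, yCalls = yCalls,
       summary = table(mtCalls))
}
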