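#' Kinship correction of haplotype counts
#'
#' Collapses carriers of the same haplotype buried in the same grave to a
#' single counting unit (matrilineal relatives share both haplotype and
#' grave), while the same haplotype observed in distinct graves contributes
#' one unit per grave. Samples without a haplotype ID are excluded with a
#' warning; samples with unknown grave are treated as singleton graves.
#'
#' @param x a \linkS4class{PopulationDataset} or its samples data.frame.
#' @return data.frame with one row per haplotype: haplotype_id, haplogroup,
#'   carriers (comma-separated sample ids), n_carriers, weight (units after
#'   correction). Ordered by haplotype ID. \code{sum(weight)} is the
#'   kinship-corrected unit count.
#' @export
kinshipCorrect <- function(x) {
  s <- if (is(x, "PopulationDataset")) x@samples else x
  drop <- s$haplotype_id == "" | is.na(s$haplotype_id)
  if (any(drop)) {
    warning(sum(drop), " sample(s) without haplotype ID excluded")
    s <- s[!drop, , drop = FALSE]
  }
  if (!nrow(s))
    return(data.frame(haplotype_id = character(0), haplogroup = character(0),
                      carriers = character(0), n_carriers = integer(0),
                      weight = integer(0)))
  grave <- s$grave_id
  unk <- grave == "" | is.na(grave)
  grave[unk] <- paste0(".solo.", s$sample_id[unk])
  out <- do.call(rbind, lapply(split(seq_len(nrow(s)), s$haplotype_id),
    function(i) {
      data.frame(haplotype_id = s$haplotype_id[i[1]],
                 haplogroup = s$haplogroup[i[1]],
                 carriers = paste(s$sample_id[i], collapse = ","),
                 n_carriers = length(i),
                 weight = length(unique(grave[i])),
                 stringsAsFactors = FALSE)
    }))
  out <- out[order(out$haplotype_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Macro-haplogroup collapse map folding D sublineages
#'
#' @return Named character vector mapping sublineage labels to their macro
#'   label (D*, D4, D5 -> D).
#' @export
macroHaplogroupMap <- function() c("D*" = "D", "D4" = "D", "D5" = "D")

.roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Haplogroup frequencies over kinship-corrected units
#'
#' Frequencies are unit counts divided by total units, reported as
#' percentages rounded half-up to two decimals.
#'
#' @param units data.frame from \code{\link{kinshipCorrect}}.
#' @param collapse named character map folding sublineages into macro
#'   groups (default folds D*, D4, D5 into D); NULL for no folding.
#' @return data.frame with haplogroup, units, frequency (proportion) and
#'   percent columns, sorted by decreasing frequency.
#' @export
haplogroupFrequencies <- function(units, collapse = macroHaplogroupMap()) {
  if (!nrow(units)) stop("empty unit list", call. = FALSE)
  hg <- units$haplogroup
  if (!is.null(collapse)) {
    hit <- hg %in% names(collapse)
    hg[hit] <- collapse[hg[hit]]
  }
  cnt <- tapply(units$weight, hg, sum)
  tot <- sum(units$weight)
  out <- data.frame(haplogroup = names(cnt), units = as.integer(cnt),
                    frequency = as.numeric(cnt) / tot,
                    stringsAsFactors = FALSE)
  out$percent <- .roundHalfUp(100 * out$frequency, 2)
  out <- out[order(-out$frequency, out$haplogroup), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- PhiST / AMOVA -------------------------------------------------------

#' Pairwise difference matrix of a SequenceBlock
#'
#' Number of differing sites between each pair; a run of gap characters on
#' one side counts as a single event (so the 9-bp deletion is one
#' difference) and 'N' matches anything.
#'
#' @param block a \linkS4class{SequenceBlock}.
#' @return Symmetric numeric matrix with sample labels.
#' @export
pairDiff <- function(block) {
  D <- cpp_seq_diff(blockSequences(block))
  dimnames(D) <- list(blockLabels(block), blockLabels(block))
  D
}

#' Pairwise PhiST between populations with permutation tests
#'
#' PhiST is computed from the two-population AMOVA decomposition of the
#' pairwise-difference matrix. Permutation p-values use the (b+1)/(m+1)
#' estimator over label permutations. Negative estimates are truncated to 0
#' in the distance matrix; the raw values are retained.
#'
#' @param block a \linkS4class{SequenceBlock}.
#' @param populations character/factor of population labels, one per
#'   sequence (in block order).
#' @param nperm permutations per pair (default 1000).
#' @param seed optional integer seed.
#' @return list with elements \code{dist} (PhiST matrix, negatives floored
#'   at 0), \code{raw} (untruncated estimates) and \code{p} (p-value
#'   matrix).
#' @export
pairwisePhiST <- function(block, populations, nperm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  populations <- as.character(populations)
  stopifnot(length(populations) == length(blockLabels(block)))
  tab <- table(populations)
  if (length(tab) < 2) stop("need at least two populations", call. = FALSE)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("population(s) with fewer than 2 sequences: ",
         paste(small, collapse = ", "), call. = FALSE)
  D <- pairDiff(block)
  pops <- names(tab)
  k <- length(pops)
  raw <- p <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    sel <- populations %in% c(pops[i], pops[j])
    lab <- as.integer(populations[sel] == pops[j])
    res <- cpp_phist_perm(D[sel, sel, drop = FALSE], lab, 2L,
                          as.integer(nperm))
    raw[i, j] <- raw[j, i] <- res[1]
    p[i, j] <- p[j, i] <- (res[2] + 1) / (nperm + 1)
  }
  diag(p) <- NA_real_
  list(dist = pmax(raw, 0), raw = raw, p = p)
}

# Three-level AMOVA variance components from a pairwise (squared-)distance
# matrix, population labels and group labels (per individual).
.amovaComponents <- function(D, pop, grp) {
  N <- nrow(D)
  pops <- unique(pop)
  grps <- unique(grp)
  P <- length(pops); G <- length(grps)
  lt <- lower.tri(D)
  ssdSet <- function(sel) sum(D[sel, sel][lower.tri(D[sel, sel])]) / sum(sel)
  ssdTot <- sum(D[lt]) / N
  np <- vapply(pops, function(pp) sum(pop == pp), numeric(1))
  ng <- vapply(grps, function(g) sum(grp == g), numeric(1))
  ssdWP <- sum(vapply(pops, function(pp) ssdSet(pop == pp), numeric(1)))
  ssdWG <- sum(vapply(grps, function(g) ssdSet(grp == g), numeric(1)))
  ssdAPWG <- ssdWG - ssdWP
  ssdAG <- ssdTot - ssdWG
  grpOf <- vapply(pops, function(pp) grp[match(pp, pop)], character(1))
  A <- sum(vapply(grps, function(g)
    sum(np[grpOf == g]^2) / ng[grps == g], numeric(1)))
  B <- sum(np^2) / N
  C <- sum(ng^2) / N
  sc <- ssdWP / (N - P)
  if (G > 1 && P > G) {
    ncoef <- (N - A) / (P - G)
    sb <- (ssdAPWG / (P - G) - sc) / ncoef
    np1 <- (A - B) / (G - 1)
    np2 <- (N - C) / (G - 1)
    sa <- (ssdAG / (G - 1) - sc - np1 * sb) / np2
  } else if (G > 1) {  # one population per group: no within-group level
    sb <- 0
    np2 <- (N - C) / (G - 1)
    sa <- (ssdAG / (G - 1) - sc) / np2
  } else {
    sb <- if (P > 1) (ssdAPWG / (P - 1) - sc) / ((N - B) / (P - 1)) else 0
    sa <- 0
  }
  tot <- sa + sb + sc
  list(ssd = c(among_groups = ssdAG, among_pops_within = ssdAPWG,
               within_pops = ssdWP),
       df = c(G - 1, P - G, N - P),
       sigma = c(sa, sb, sc),
       phi = c(PhiCT = if (tot != 0) sa / tot else 0,
               PhiSC = if ((sb + sc) != 0) sb / (sb + sc) else 0,
               PhiST = if (tot != 0) (sa + sb) / tot else 0))
}

#' Hierarchical AMOVA with permutation tests
#'
#' Two-level analysis of molecular variance on the pairwise-difference
#' matrix: among groups, among populations within groups, within
#' populations, with Phi statistics and permutation p-values (PhiCT by
#' permuting populations among groups; PhiSC by permuting individuals among
#' populations within groups; PhiST by permuting individuals among
#' populations). Negative variance components are reported as estimated.
#'
#' @param block a \linkS4class{SequenceBlock} (or a precomputed symmetric
#'   difference matrix).
#' @param populations population label per sequence.
#' @param groups named character map population -> group; with a single
#'   group the analysis reduces to one level with a notice.
#' @param nperm permutations (default 1000).
#' @param seed optional integer seed.
#' @return An \linkS4class{AmovaResult}.
#' @export
amova <- function(block, populations, groups, nperm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- if (is(block, "SequenceBlock")) pairDiff(block) else as.matrix(block)
  pop <- as.character(populations)
  stopifnot(length(pop) == nrow(D))
  if (!all(pop %in% names(groups)))
    stop("every population needs a group assignment", call. = FALSE)
  grp <- unname(groups[pop])
  G <- length(unique(grp))
  if (G == 1) message("single group: reducing to one-level AMOVA")
  obs <- .amovaComponents(D, pop, grp)
  tot <- sum(obs$sigma)
  pct <- if (tot != 0) 100 * obs$sigma / tot else rep(NA_real_, 3)
  # permutation tests
  ge <- c(PhiCT = 0, PhiSC = 0, PhiST = 0)
  pops <- unique(pop)
  grpOfPop <- vapply(pops, function(pp) grp[match(pp, pop)], character(1))
  for (r in seq_len(nperm)) {
    # PhiCT: permute populations among groups
    g1 <- setNames(sample(grpOfPop), pops)
    c1 <- .amovaComponents(D, pop, unname(g1[pop]))
    if (c1$phi["PhiCT"] >= obs$phi["PhiCT"] - 1e-12)
      ge["PhiCT"] <- ge["PhiCT"] + 1
    # PhiSC: permute individuals among populations within groups
    pop2 <- pop
    for (g in unique(grp)) {
      sel <- grp == g
      pop2[sel] <- sample(pop[sel])
    }
    c2 <- .amovaComponents(D, pop2, grp)
    if (c2$phi["PhiSC"] >= obs$phi["PhiSC"] - 1e-12)
      ge["PhiSC"] <- ge["PhiSC"] + 1
    # PhiST: permute individuals among populations
    ord <- sample(length(pop))
    c3 <- .amovaComponents(D, pop[ord], grp[ord])
    if (c3$phi["PhiST"] >= obs$phi["PhiST"] - 1e-12)
      ge["PhiST"] <- ge["PhiST"] + 1
  }
  pv <- (ge + 1) / (nperm + 1)
  tab <- data.frame(source = c("among_groups", "among_pops_within_groups",
                               "within_pops"),
                    df = obs$df, SSD = obs$ssd, sigma = obs$sigma,
                    percent = pct, stringsAsFactors = FALSE)
  new("AmovaResult", table = tab, phi = obs$phi, pvalues = pv,
      nperm = as.integer(nperm))
}

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (", object@nperm, "permutations )\n")
  print(object@table, row.names = FALSE)
  cat("Phi:", paste(names(object@phi),
                    sprintf("%.4f", object@phi), collapse = "  "), "\n")
  cat("p:  ", paste(names(object@pvalues),
                    sprintf("%.4f", object@pvalues), collapse = "  "), "\n")
})

#' @describeIn amova AMOVA table accessor.
#' @param x an \linkS4class{AmovaResult}.
#' @export
amovaTable <- function(x) x@table

#' @describeIn amova Phi statistics accessor.
#' @export
amovaPhi <- function(x) x@phi

#' @describeIn amova Permutation p-values accessor.
#' @export
amovaPvalues <- function(x) x@pvalues

## ---- ordination ----------------------------------------------------------

#' Metric multidimensional scaling with stress refinement
#'
#' Classical (Torgerson) solution refined by stress majorization (SMACOF
#' iterations); reports Kruskal stress-1. Coordinates are centered at the
#' origin, with the sign of each dimension fixed so that its first nonzero
#' loading is positive.
#'
#' @param D symmetric dissimilarity matrix (zero diagonal).
#' @param dims embedding dimension (default 2).
#' @param maxit majorization iterations.
#' @param tol relative stress-improvement tolerance.
#' @return list with \code{points} (n x dims matrix) and \code{stress}
#'   (Kruskal stress-1).
#' @export
mdsEmbed <- function(D, dims = 2, maxit = 200, tol = 1e-10) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (dims >= n) stop("dims must be smaller than the number of labels",
                      call. = FALSE)
  if (dims < 1) stop("dims must be >= 1", call. = FALSE)
  X <- cmdscale(D, k = dims)
  if (ncol(X) < dims)  # degenerate: pad with zeros
    X <- cbind(X, matrix(0, n, dims - ncol(X)))
  stress1 <- function(X) {
    dc <- as.matrix(dist(X))
    lt <- lower.tri(D)
    denom <- sum(dc[lt]^2)
    if (denom == 0) return(if (sum(D[lt]^2) == 0) 0 else 1)
    sqrt(sum((D[lt] - dc[lt])^2) / denom)
  }
  sOld <- stress1(X)
  for (it in seq_len(maxit)) {
    dc <- as.matrix(dist(X))
    B <- matrix(0, n, n)
    nz <- dc > 0
    B[nz] <- -D[nz] / dc[nz]
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    sNew <- stress1(X)
    if (sOld - sNew < tol * max(sOld, 1e-300)) { sOld <- sNew; break }
    sOld <- sNew
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  for (k in seq_len(dims)) {
    nz <- which(abs(X[, k]) > 1e-12)
    if (length(nz) && X[nz[1], k] < 0) X[, k] <- -X[, k]
  }
  rownames(X) <- rownames(D)
  colnames(X) <- paste0("Dim", seq_len(dims))
  list(points = X[, , drop = FALSE], stress = sOld)
}

#' PCA of haplogroup frequency tables
#'
#' Column-centered singular value decomposition of a populations x
#' haplogroups frequency table (rows sum to 1).
#'
#' @param freq numeric matrix, rows = populations, columns = haplogroups.
#' @return list with \code{scores} (population scores), \code{loadings},
#'   \code{explained} (variance ratios). A constant table yields empty
#'   scores with a notice.
#' @export
pcaFrequencies <- function(freq) {
  freq <- as.matrix(freq)
  if (nrow(freq) < 2) stop("need at least two populations", call. = FALSE)
  if (any(abs(rowSums(freq) - 1) > 1e-6))
    warning("rows do not sum to 1")
  ctr <- scale(freq, center = TRUE, scale = FALSE)
  if (all(abs(ctr) < 1e-12)) {
    message("constant frequency table: zero variance")
    return(list(scores = matrix(0, nrow(freq), 0), loadings = NULL,
                explained = numeric(0)))
  }
  p <- prcomp(freq, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  list(scores = p$x, loadings = p$rotation, explained = ev / sum(ev))
}
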