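## Approximate Bayesian computation: rejection sampling on MAD-standardized
## summary statistics, model choice by acceptance-rejection shares and by
## weighted multinomial logistic regression, local-linear regression
## adjustment of parameter posteriors, and a pseudo-observed validation
## suite (model-choice confusion / type-I error and per-parameter R2, bias,
## RMSE, factor-2 and 95% HPD coverage).

#' Names of the default summary-statistic vector
#'
#' Per population: number of distinct haplotypes (K), haplotype diversity
#' (H), segregating sites (S), mean pairwise differences (pi), Tajima's D;
#' per population pair: PhiST and the shared-haplotype count.
#'
#' @param pops population labels in their fixed order.
#' @return Character vector of statistic names.
#' @export
summaryStatNames <- function(pops) {
  per <- as.vector(vapply(pops, function(p)
    paste0(c("K_", "H_", "S_", "pi_", "TajD_"), p), character(5)))
  pairs <- character(0)
  if (length(pops) > 1)
    for (i in seq_len(length(pops) - 1)) for (j in seq(i + 1, length(pops)))
      pairs <- c(pairs, paste0("phist_", pops[i], "_", pops[j]),
                 paste0("shared_", pops[i], "_", pops[j]))
  c(per, pairs)
}

.CHAR_STATES <- c(A = 0L, C = 1L, G = 2L, T = 3L, "-" = 4L)

#' Summary statistics of an observed or simulated dataset
#'
#' Deterministic fixed-order vector (see \code{\link{summaryStatNames}}).
#' Populations of size < 2 yield zero-valued diversity entries (Tajima's D
#' undefined at S = 0 is encoded as 0).
#'
#' @param blocks named list of \linkS4class{SequenceBlock}, one per
#'   population (order defines the statistic order), or a single block with
#'   \code{pop} given.
#' @param pop population label per sequence when a single block is given.
#' @return Named numeric vector.
#' @export
summaryStats <- function(blocks, pop = NULL) {
  if (is(blocks, "SequenceBlock")) {
    stopifnot(!is.null(pop))
    seqs <- blockSequences(blocks)
    pops <- unique(pop)
  } else {
    seqs <- unlist(lapply(blocks, blockSequences), use.names = FALSE)
    pop <- rep(names(blocks), vapply(blocks, function(b)
      length(blockLabels(b)), integer(1)))
    pops <- names(blocks)
  }
  chars <- strsplit(seqs, "")
  L <- length(chars[[1]])
  X <- matrix(0L, length(seqs), L)
  for (i in seq_along(chars)) {
    st <- .CHAR_STATES[chars[[i]]]
    st[is.na(st)] <- 0L  # N treated as reference state
    X[i, ] <- st
  }
  v <- cpp_stats_state(X, match(pop, pops) - 1L, length(pops))
  setNames(as.numeric(v), summaryStatNames(pops))
}

# Summary statistics directly from simulator state output.
.statsFromStates <- function(states, pop, pops = unique(pop)) {
  v <- cpp_stats_state(states, match(pop, pops) - 1L, length(pops))
  setNames(as.numeric(v), summaryStatNames(pops))
}

## ---- reference tables ----------------------------------------------------

# Precompile a model template into the C++ argument list plus slots for
# fast per-draw instantiation.
.precompileModel <- function(template, mutation) {
  args <- .modelArgs(template, mutation)
  g <- template@generationTime
  dn <- names(template@demes)
  npulse <- nrow(template@pulses)
  ndiv <- nrow(template@divergences)
  divIdx <- if (ndiv) npulse + seq_len(ndiv) else integer(0)
  divAges <- template@divergences$age
  list(args = args, g = g, demeNames = dn,
       pulseIdx = seq_len(npulse),
       divT2 = if (ndiv) divIdx[which.min(divAges)] else integer(0),
       divT1 = if (ndiv) divIdx[which.max(divAges)] else integer(0))
}

.instantiateArgs <- function(pre, params) {
  a <- pre$args
  a$ne <- unname(params[paste0("Ne_", pre$demeNames)])
  if (length(pre$divT2)) a$ev_time[pre$divT2] <- params[["T2"]] / pre$g
  if (length(pre$divT1)) a$ev_time[pre$divT1] <- params[["T1"]] / pre$g
  if (length(pre$pulseIdx) && "T2" %in% names(params))
    a$ev_time[pre$pulseIdx] <- params[["T2"]] / pre$g
  if (length(pre$pulseIdx) && "a" %in% names(params))
    a$ev_p[pre$pulseIdx] <- params[["a"]]
  a
}

.simStatsFromArgs <- function(a) {
  cpp_sim_stats(a$ne, a$samp_deme, a$samp_time, a$samp_n, a$ev_time,
                a$ev_type, a$ev_a, a$ev_b, a$ev_p, a$mu_seq_gen, a$L,
                a$scheme)
}

#' Build an ABC reference table by simulating from the priors
#'
#' For each model template, draws parameter vectors from its prior,
#' simulates a dataset and records the summary-statistic vector.
#' Standardization constants (per-statistic median absolute deviations,
#' pooled across models) are computed and stored.
#'
#' @param templates named list of \linkS4class{DemographicModel}.
#' @param priors named list of \linkS4class{PriorSpec} (default
#'   \code{\link{modelPrior}} of each template).
#' @param mutation a \linkS4class{MutationModel}.
#' @param nrep replicates per model.
#' @param seed optional integer seed.
#' @param progress print a line every \code{progress} replicates (0 = quiet).
#' @return A \linkS4class{ReferenceTable}.
#' @export
buildReferenceTable <- function(templates, priors = NULL,
                                mutation = MutationModel(), nrep = 1000,
                                seed = NULL, progress = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(priors)) priors <- lapply(templates, modelPrior)
  statN <- summaryStatNames(
    .modelArgs(templates[[1]], mutation)$popNames)
  paramsL <- statsL <- list()
  for (m in names(templates)) {
    pre <- .precompileModel(templates[[m]], mutation)
    pr <- priors[[m]]@params
    cons <- priors[[m]]@constraints
    P <- matrix(NA_real_, nrep, nrow(pr),
                dimnames = list(NULL, pr$name))
    S <- matrix(NA_real_, nrep, length(statN),
                dimnames = list(NULL, statN))
    for (r in seq_len(nrep)) {
      repeat {
        x <- setNames(runif(nrow(pr), pr$lower, pr$upper), pr$name)
        ok <- all(vapply(cons, function(cn) {
          ab <- strsplit(cn, "<", fixed = TRUE)[[1]]
          x[[ab[1]]] < x[[ab[2]]]
        }, logical(1)))
        if (ok) break
      }
      P[r, ] <- x
      S[r, ] <- .simStatsFromArgs(.instantiateArgs(pre, x))
      if (progress > 0 && r %% progress == 0)
        message(m, ": ", r, "/", nrep)
    }
    paramsL[[m]] <- P
    statsL[[m]] <- S
  }
  pooled <- do.call(rbind, statsL)
  sc <- apply(pooled, 2, mad)
  zero <- sc == 0
  sc[zero] <- apply(pooled[, zero, drop = FALSE], 2, sd)
  sc[sc == 0 | is.na(sc)] <- 1
  new("ReferenceTable", models = names(templates), params = paramsL,
      stats = statsL, scale = setNames(sc, statN))
}

setMethod("show", "ReferenceTable", function(object) {
  cat("ReferenceTable:", length(object@models), "model(s):",
      paste(object@models, vapply(object@stats, nrow, integer(1)),
            sep = " x ", collapse = ", "), "replicates;",
      length(object@scale), "statistics\n")
})

#' @describeIn buildReferenceTable Write a reference table as delimited text
#'   (one params and one stats file per model, plus a manifest).
#' @param table a \linkS4class{ReferenceTable}.
#' @param dir output directory.
#' @export
writeReferenceTable <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in table@models) {
    write.table(table@params[[m]], file.path(dir, paste0(m, "_params.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(table@stats[[m]], file.path(dir, paste0(m, "_stats.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(models = table@models,
                            scale = as.list(table@scale)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @describeIn buildReferenceTable Read a reference table written by
#'   \code{writeReferenceTable}.
#' @export
readReferenceTable <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  paramsL <- statsL <- list()
  for (m in man$models) {
    paramsL[[m]] <- as.matrix(read.delim(
      file.path(dir, paste0(m, "_params.tsv"))))
    statsL[[m]] <- as.matrix(read.delim(
      file.path(dir, paste0(m, "_stats.tsv"))))
  }
  new("ReferenceTable", models = man$models, params = paramsL,
      stats = statsL, scale = unlist(man$scale))
}

## ---- rejection and model choice ------------------------------------------

# Standardized Euclidean distances of every pooled replicate to the
# observed vector; returns data.frame(model, index, distance) sorted.
.pooledDistances <- function(observed, table) {
  sc <- table@scale
  obs <- observed[names(sc)] / sc
  rows <- lapply(table@models, function(m) {
    Z <- sweep(table@stats[[m]], 2, sc, "/")
    d <- sqrt(rowSums(sweep(Z, 2, obs, "-")^2))
    data.frame(model = m, index = seq_along(d), distance = d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$distance, out$model, out$index), , drop = FALSE]
}

#' Rejection-stage ABC
#'
#' Accepts the \code{ceiling(eps * total)} replicates nearest to the
#' observed statistics in MAD-standardized Euclidean distance, pooled
#' across models; ties at the cutoff are broken by model then replicate
#' index for determinism. The acceptance-rejection (AR) model probability
#' is each model's share of the accepted set.
#'
#' @param observed named numeric summary-statistic vector.
#' @param table a \linkS4class{ReferenceTable}.
#' @param eps accepted fraction (0 < eps <= 1).
#' @return An \linkS4class{AbcResult} with AR probabilities, the accepted
#'   set and per-model raw posterior draws.
#' @export
abcReject <- function(observed, table, eps = 0.005) {
  stopifnot(eps > 0, eps <= 1)
  dd <- .pooledDistances(observed, table)
  nacc <- ceiling(eps * nrow(dd))
  if (nacc == 0) stop("no replicates accepted", call. = FALSE)
  if (nacc < 10) warning("fewer than 10 replicates accepted")
  acc <- dd[seq_len(nacc), , drop = FALSE]
  pr <- vapply(table@models, function(m) sum(acc$model == m) / nacc,
               numeric(1))
  post <- lapply(table@models, function(m) {
    idx <- acc$index[acc$model == m]
    list(raw = table@params[[m]][idx, , drop = FALSE],
         adjusted = NULL, weights = rep(1, length(idx)))
  })
  names(post) <- table@models
  new("AbcResult",
      modelProb = matrix(pr, 1, length(pr),
                         dimnames = list("AR", table@models)),
      accepted = acc, posterior = post, estimates = list(),
      eps = eps, notes = character(0))
}

#' Model choice by acceptance-rejection and weighted logistic regression
#'
#' The LR probabilities come from a multinomial logistic regression of the
#' model label on the standardized statistics over the accepted set, with
#' Epanechnikov weights in the distance to the observed vector, evaluated
#' at the observed statistics. Degenerate accepted sets (a single model, or
#' a failed fit) fall back to the AR shares with a logged note.
#'
#' @param observed named numeric summary-statistic vector.
#' @param table a \linkS4class{ReferenceTable}.
#' @param eps accepted fraction.
#' @return An \linkS4class{AbcResult} with rows "AR" and "LR" in
#'   \code{modelProb}.
#' @export
abcModelChoice <- function(observed, table, eps = 0.005) {
  res <- abcReject(observed, table, eps)
  acc <- res@accepted
  sc <- table@scale
  obs <- observed[names(sc)] / sc
  Z <- do.call(rbind, lapply(table@models, function(m)
    sweep(table@stats[[m]][acc$index[acc$model == m], , drop = FALSE],
          2, sc, "/")))
  lab <- factor(rep(table@models,
                    vapply(table@models, function(m) sum(acc$model == m),
                           integer(1))),
                levels = table@models)
  dmax <- max(acc$distance)
  dAll <- unlist(lapply(table@models, function(m)
    acc$distance[acc$model == m]))
  w <- if (dmax > 0) 1 - (dAll / dmax)^2 else rep(1, length(dAll))
  w[w <= 0] <- min(w[w > 0], 1e-8)
  present <- levels(droplevels(lab))
  lr <- setNames(rep(0, length(table@models)), table@models)
  note <- character(0)
  if (length(present) < 2) {
    lr[present] <- 1
    note <- "LR fallback: single model in accepted set"
    lr <- res@modelProb["AR", ]
  } else {
    # drop constant columns to keep the design full rank
    keep <- apply(Z, 2, function(x) sd(x) > 1e-10)
    dat <- data.frame(.lab = droplevels(lab), Z[, keep, drop = FALSE])
    fit <- tryCatch(
      nnet::multinom(.lab ~ ., data = dat, weights = w, trace = FALSE,
                     maxit = 200, MaxNWts = 5000),
      error = function(e) NULL)
    if (is.null(fit)) {
      note <- "LR fallback: multinom failed, using AR"
      lr <- res@modelProb["AR", ]
    } else {
      nd <- as.data.frame(t(obs[keep]))
      names(nd) <- names(dat)[-1]
      p <- predict(fit, newdata = nd, type = "probs")
      if (length(present) == 2) {
        lr[present[1]] <- 1 - p
        lr[present[2]] <- p
      } else lr[present] <- as.numeric(p)
    }
  }
  mp <- rbind(res@modelProb, LR = lr / sum(lr))
  new("AbcResult", modelProb = mp, accepted = res@accepted,
      posterior = res@posterior, estimates = list(), eps = eps,
      notes = note)
}

## ---- parameter adjustment and intervals ----------------------------------

#' Shortest interval containing a given mass of a weighted sample
#'
#' @param x numeric draws.
#' @param w weights (default equal).
#' @param level probability mass (default 0.95).
#' @return Numeric (lower, upper).
#' @export
weightedHPD <- function(x, w = NULL, level = 0.95) {
  if (is.null(w)) w <- rep(1, length(x))
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  n <- length(x)
  best <- c(x[1], x[n])
  for (i in seq_len(n)) {
    target <- (if (i > 1) cw[i - 1] else 0) + level
    j <- which(cw >= target - 1e-12)[1]
    if (is.na(j)) break
    if (x[j] - x[i] < best[2] - best[1]) best <- c(x[i], x[j])
  }
  best
}

.weightedMode <- function(x, w = NULL) {
  if (length(unique(x)) == 1) return(x[1])
  if (is.null(w)) w <- rep(1, length(x))
  d <- suppressWarnings(stats::density(x, weights = w / sum(w), n = 512))
  d$x[which.max(d$y)]
}

.weightedMean <- function(x, w) sum(x * w) / sum(w)

#' Regression-adjusted parameter posteriors
#'
#' Within-model rejection (nearest \code{ceiling(eps * m)} replicates of
#' that model's table) followed by local-linear regression adjustment of
#' each parameter on the standardized statistics, with Epanechnikov
#' weights; adjusted draws are clamped to the prior support. Reports the
#' weighted posterior mean, kernel-density mode and shortest 95% HPD
#' interval per parameter.
#'
#' @param observed named numeric summary-statistic vector.
#' @param table a \linkS4class{ReferenceTable}.
#' @param model model label to estimate under.
#' @param eps accepted fraction of the model's table.
#' @param method "loclinear" (default) or "rejection" (no adjustment).
#' @param prior optional \linkS4class{PriorSpec} providing the clamping
#'   support (default: the model's parameter ranges in the table).
#' @param level HPD mass.
#' @return list with \code{raw}, \code{adjusted} (matrices of draws),
#'   \code{weights}, \code{estimates} (data.frame: parameter, mean, mode,
#'   hpd_lo, hpd_hi) and \code{note}.
#' @export
abcAdjust <- function(observed, table, model, eps = 0.005,
                      method = c("loclinear", "rejection"), prior = NULL,
                      level = 0.95) {
  method <- match.arg(method)
  stopifnot(model %in% table@models)
  sc <- table@scale
  obs <- observed[names(sc)] / sc
  Z <- sweep(table@stats[[model]], 2, sc, "/")
  d <- sqrt(rowSums(sweep(Z, 2, obs, "-")^2))
  nacc <- max(2L, ceiling(eps * length(d)))
  idx <- order(d, seq_along(d))[seq_len(nacc)]
  raw <- table@params[[model]][idx, , drop = FALSE]
  dmax <- max(d[idx])
  w <- if (dmax > 0) 1 - (d[idx] / dmax)^2 else rep(1, nacc)
  w[w <= 0] <- min(w[w > 0], 1e-8)
  lo <- apply(table@params[[model]], 2, min)
  hi <- apply(table@params[[model]], 2, max)
  if (!is.null(prior)) {
    pp <- prior@params
    lo[pp$name] <- pp$lower
    hi[pp$name] <- pp$upper
  }
  note <- character(0)
  adjusted <- raw
  if (method == "loclinear") {
    Xc <- sweep(Z[idx, , drop = FALSE], 2, obs, "-")
    keep <- apply(Xc, 2, function(x) sd(x) > 1e-10)
    X <- cbind(1, Xc[, keep, drop = FALSE])
    fit <- tryCatch(stats::lm.wfit(X, raw, w), error = function(e) NULL)
    cf <- if (!is.null(fit)) as.matrix(fit$coefficients) else NULL
    if (is.null(cf) || nrow(cf) != ncol(X) || anyNA(cf[1, ])) {
      # singular design: keep the unadjusted draws
      note <- "adjustment fallback: singular design, rejection sample kept"
    } else {
      cf[is.na(cf)] <- 0
      colnames(cf) <- colnames(raw)
      adjusted <- raw - Xc[, keep, drop = FALSE] %*%
        cf[-1, , drop = FALSE]
      adjusted <- pmin(pmax(adjusted,
                            matrix(lo[colnames(raw)], nrow(raw),
                                   ncol(raw), byrow = TRUE)),
                       matrix(hi[colnames(raw)], nrow(raw), ncol(raw),
                              byrow = TRUE))
    }
  }
  est <- do.call(rbind, lapply(colnames(raw), function(pn) {
    x <- adjusted[, pn]
    hpd <- weightedHPD(x, w, level)
    data.frame(parameter = pn, mean = .weightedMean(x, w),
               mode = .weightedMode(x, w), hpd_lo = hpd[1],
               hpd_hi = hpd[2], stringsAsFactors = FALSE)
  }))
  rownames(est) <- NULL
  list(raw = raw, adjusted = adjusted, weights = w, estimates = est,
       note = note)
}

setMethod("show", "AbcResult", function(object) {
  cat("AbcResult (eps =", object@eps, ")\n")
  print(round(object@modelProb, 4))
  if (length(object@notes)) cat("notes:", object@notes, "\n")
})

#' @describeIn abcModelChoice Model-probability matrix accessor.
#' @param x an \linkS4class{AbcResult}.
#' @export
modelProbabilities <- function(x) x@modelProb

## ---- validation suite -----------------------------------------------------

#' Pseudo-observed validation of the ABC machinery
#'
#' For each model, draws \code{q} pseudo-observed datasets from the prior,
#' runs model choice against the full reference table and parameter
#' estimation against the true model's table, and reports the model-choice
#' confusion matrix with the overall type-I error (fraction of
#' pseudo-observed whose true model is not the selected one) plus
#' per-parameter R2 (regression of estimate on truth), relative bias,
#' relative RMSE, factor-2 fraction and 95% HPD coverage.
#'
#' @param table a \linkS4class{ReferenceTable} built from the same
#'   templates/priors.
#' @param templates named list of \linkS4class{DemographicModel}.
#' @param priors named list of \linkS4class{PriorSpec}.
#' @param mutation a \linkS4class{MutationModel}.
#' @param q pseudo-observed datasets per model (>= 20).
#' @param eps accepted fraction.
#' @param seed optional integer seed.
#' @param pointEstimate "mode" (default) or "mean".
#' @param choice "LR" (default) or "AR" model selector.
#' @return list with \code{confusion} (matrix true x selected),
#'   \code{typeIError} (overall fraction, also as percent),
#'   \code{parameters} (data.frame per model and parameter) and the
#'   settings used.
#' @export
abcValidate <- function(table, templates, priors = NULL,
                        mutation = MutationModel(), q = 200, eps = 0.005,
                        seed = NULL, pointEstimate = c("mode", "mean"),
                        choice = c("LR", "AR")) {
  pointEstimate <- match.arg(pointEstimate)
  choice <- match.arg(choice)
  if (q < 20) stop("q < 20: validation metrics are meaningless",
                   call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(priors)) priors <- lapply(templates, modelPrior)
  models <- table@models
  confusion <- matrix(0L, length(models), length(models),
                      dimnames = list(true = models, selected = models))
  paramRows <- list()
  for (m in models) {
    pre <- .precompileModel(templates[[m]], mutation)
    pr <- priors[[m]]@params
    cons <- priors[[m]]@constraints
    truth <- matrix(NA_real_, q, nrow(pr), dimnames = list(NULL, pr$name))
    est <- matrix(NA_real_, q, nrow(pr), dimnames = list(NULL, pr$name))
    cover <- matrix(NA, q, nrow(pr), dimnames = list(NULL, pr$name))
    for (r in seq_len(q)) {
      repeat {
        x <- setNames(runif(nrow(pr), pr$lower, pr$upper), pr$name)
        ok <- all(vapply(cons, function(cn) {
          ab <- strsplit(cn, "<", fixed = TRUE)[[1]]
          x[[ab[1]]] < x[[ab[2]]]
        }, logical(1)))
        if (ok) break
      }
      truth[r, ] <- x
      obs <- setNames(as.numeric(.simStatsFromArgs(
        .instantiateArgs(pre, x))), names(table@scale))
      mc <- abcModelChoice(obs, table, eps)
      sel <- models[which.max(mc@modelProb[choice, ])]
      confusion[m, sel] <- confusion[m, sel] + 1L
      ad <- abcAdjust(obs, table, m, eps, prior = priors[[m]])
      e <- ad$estimates
      est[r, e$parameter] <- if (pointEstimate == "mode") e$mode else e$mean
      cover[r, e$parameter] <- e$hpd_lo <= x[e$parameter] &
        x[e$parameter] <= e$hpd_hi
    }
    for (pn in pr$name) {
      rel <- (est[, pn] - truth[, pn]) / truth[, pn]
      r2 <- if (sd(est[, pn]) > 0)
        suppressWarnings(stats::cor(est[, pn], truth[, pn])^2) else 0
      paramRows[[paste(m, pn)]] <- data.frame(
        model = m, parameter = pn, R2 = r2, bias = mean(rel),
        RMSE = sqrt(mean(rel^2)),
        factor2 = mean(est[, pn] / truth[, pn] >= 0.5 &
                         est[, pn] / truth[, pn] <= 2),
        coverage = mean(cover[, pn]), stringsAsFactors = FALSE)
    }
  }
  mis <- 1 - sum(diag(confusion)) / sum(confusion)
  list(confusion = confusion,
       typeIError = mis, typeIErrorPercent = 100 * mis,
       parameters = do.call(rbind, c(paramRows, make.row.names = FALSE)),
       settings = list(q = q, eps = eps, pointEstimate = pointEstimate,
                       choice = choice))
}
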