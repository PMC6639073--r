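#' Configuration for simulated polysome fraction count tables
#'
#' Defines, per condition and per gene group, the expected distribution of
#' a transcript across the four gradient fractions, together with the
#' sequencing-free nanoString-like count model: expected total counts per
#' gene, per-fraction spike-in recovery factors, and a negative-binomial
#' dispersion.
#'
#' @param profiles named list (condition) of named lists (gene group) of
#'   numeric(4) fraction proportions, each summing to 1.
#' @param nGenes named integer vector: genes per group.
#' @param libraryScale expected total counts per gene across fractions.
#' @param spikeRecovery numeric(4) positive recovery factor per fraction
#'   (1 = lossless).
#' @param nbDispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param nReplicates replicates per condition.
#' @param spikeNominal expected spike-in counts at recovery 1.
#' @return A list with class \code{"countSimConfig"}.
#' @examples
#' cfg <- countSimConfig(
#'   profiles = list(control = list(APC_dependent = c(.1, .15, .3, .45))),
#'   nGenes = c(APC_dependent = 5))
#' @export
countSimConfig <- function(profiles, nGenes,
                           libraryScale = 4000,
                           spikeRecovery = c(1, 1, 1, 1),
                           nbDispersion = 0.05,
                           nReplicates = 3,
                           spikeNominal = 20000) {
  stopifnot(is.list(profiles), length(profiles) >= 1,
            !is.null(names(profiles)))
  for (cond in names(profiles)) {
    for (grp in names(profiles[[cond]])) {
      p <- profiles[[cond]][[grp]]
      if (length(p) != 4L || any(p < 0) ||
          abs(sum(p) - 1) > 1e-9) {
        stop("profile for condition '", cond, "', group '", grp,
             "' must be 4 non-negative proportions summing to 1")
      }
    }
  }
  stopifnot(length(spikeRecovery) == 4L, all(spikeRecovery > 0),
            nbDispersion >= 0, libraryScale > 0, nReplicates >= 1,
            spikeNominal > 0, all(nGenes >= 1))
  structure(list(profiles = profiles, nGenes = nGenes,
                 libraryScale = libraryScale, spikeRecovery = spikeRecovery,
                 nbDispersion = nbDispersion,
                 nReplicates = as.integer(nReplicates),
                 spikeNominal = spikeNominal),
            class = "countSimConfig")
}

#' Default fraction-profile configuration
#'
#' A ready-made \code{\link{countSimConfig}} emulating the study design:
#' 20 APC-dependent genes, 6 APC-independent genes and 8 controls, all well
#' translated under control conditions (majority of counts in the polysomal
#' fractions 3-4), with a puromycin condition that collapses polysomes and
#' shifts counts towards fractions 1-2.
#'
#' @param ... overrides passed on to \code{\link{countSimConfig}}.
#' @return A \code{"countSimConfig"}.
#' @examples
#' defaultCountSimConfig()
#' @export
defaultCountSimConfig <- function(...) {
  ctrl <- list(APC_dependent = c(0.10, 0.15, 0.30, 0.45),
               APC_independent = c(0.10, 0.15, 0.30, 0.45),
               control = c(0.15, 0.15, 0.30, 0.40))
  puro <- list(APC_dependent = c(0.35, 0.35, 0.20, 0.10),
               APC_independent = c(0.35, 0.35, 0.20, 0.10),
               control = c(0.40, 0.35, 0.15, 0.10))
  args <- list(profiles = list(control = ctrl, puromycin = puro),
               nGenes = c(APC_dependent = 20, APC_independent = 6,
                          control = 8))
  args[names(list(...))] <- list(...)
  do.call(countSimConfig, args)
}

#' Simulate spike-in polysome fraction count tables
#'
#' Draws gene-by-fraction counts with mean
#' \code{libraryScale * profile[g, f] * spikeRecovery[f]} from a
#' negative-binomial (Poisson when dispersion is 0), and a spike-in row
#' with mean \code{spikeNominal * spikeRecovery[f]}, for every condition
#' and replicate in the configuration. Per-gene library scales vary
#' log-normally (25% CV) around \code{libraryScale} and are shared across
#' conditions and replicates so that fraction profiles, not gene abundance,
#' differ between conditions.
#'
#' @param config a \code{\link{countSimConfig}}.
#' @param seed integer seed.
#' @return A list of \linkS4class{FractionCountTable}, one per condition x
#'   replicate, plus an attribute \code{"truth"} holding the true per-gene
#'   profiles.
#' @examples
#' tabs <- simulateFractionCounts(defaultCountSimConfig(), seed = 1)
#' tabs[[1]]
#' @export
simulateFractionCounts <- function(config, seed = NULL) {
  stopifnot(inherits(config, "countSimConfig"))
  withSeed(seed)
  groups <- rep(names(config$nGenes), config$nGenes)
  genes <- unlist(lapply(names(config$nGenes), function(g) {
    sprintf("%s_%02d", g, seq_len(config$nGenes[[g]]))
  }))
  scales <- config$libraryScale *
    exp(rnorm(length(genes), -0.5 * 0.25^2, 0.25))
  names(scales) <- genes

  drawCounts <- function(mu) {
    if (config$nbDispersion <= 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / config$nbDispersion)
  }

  out <- list()
  truth <- list()
  for (cond in names(config$profiles)) {
    prof <- config$profiles[[cond]]
    profMat <- t(vapply(groups, function(g) prof[[g]], numeric(4)))
    rownames(profMat) <- genes
    truth[[cond]] <- profMat
    for (rep in seq_len(config$nReplicates)) {
      mu <- sweep(profMat * scales, 2, config$spikeRecovery, `*`)
      cts <- matrix(drawCounts(as.vector(mu)), nrow(mu), 4,
                    dimnames = list(genes, paste0("F", 1:4)))
      # the spike-in is a technical control (equal RNA added to every
      # fraction): Poisson counting noise only; recovery differences are
      # the systematic effect carried by spikeRecovery
      spike <- pmax(rpois(4, config$spikeNominal * config$spikeRecovery),
                    1)
      out[[sprintf("%s_rep%d", cond, rep)]] <-
        FractionCountTable(cts, spikeCounts = spike, geneGroups = groups,
                           condition = cond, replicate = rep)
    }
  }
  attr(out, "truth") <- truth
  out
}
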