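#' Spike-in normalization of a fraction count table
#'
#' Corrects per-fraction recovery losses using the spike-in RNA that was
#' added in equal amount to every fraction: counts in fraction f are
#' multiplied by \code{referenceSpike / spikeCounts[f]}, where the
#' reference is the geometric mean of the four spike counts. After
#' normalization the spike counts are equalized, so the operation is
#' idempotent.
#'
#' @param table a \linkS4class{FractionCountTable}.
#' @return A \linkS4class{FractionCountTable} with normalized counts and
#'   equalized spike counts.
#' @examples
#' cts <- matrix(c(100, 200, 100, 100), 1, dimnames = list("g", NULL))
#' tab <- FractionCountTable(cts, spikeCounts = c(100, 200, 100, 100))
#' SummarizedExperiment::assay(spikeNormalize(tab))
#' @export
spikeNormalize <- function(table) {
  stopifnot(is(table, "FractionCountTable"))
  sp <- table@spikeCounts
  if (any(sp <= 0)) {
    stop("zero spike count in fraction ", paste(which(sp <= 0),
         collapse = ", "), "; cannot normalize")
  }
  ref <- geomMean(sp)
  factors <- ref / sp
  cts <- SummarizedExperiment::assay(table, "counts")
  norm <- sweep(cts, 2, factors, `*`)
  FractionCountTable(norm, spikeCounts = rep(ref, 4),
                     geneGroups = SummarizedExperiment::rowData(table)$group,
                     condition = table@condition,
                     replicate = table@replicate)
}

#' Per-gene distribution across gradient fractions
#'
#' Row-normalizes (spike-normalized) counts to proportions per gene, and
#' averages across replicates when a list of tables is given. The
#' translated fraction of a gene is the proportion found in the polysomal
#' fractions, p3 + p4. Genes with zero total counts are dropped with a
#' warning.
#'
#' @param x a \linkS4class{FractionCountTable} or a list of them
#'   (replicates of one condition).
#' @param normalize spike-normalize before computing proportions?
#' @return A \linkS4class{FractionDistribution}.
#' @examples
#' cts <- matrix(c(700, 100, 100, 100), 1, dimnames = list("g", NULL))
#' tab <- FractionCountTable(cts, spikeCounts = rep(1000, 4))
#' translatedFraction(fractionDistribution(tab))
#' @export
fractionDistribution <- function(x, normalize = TRUE) {
  tables <- if (is(x, "FractionCountTable")) list(x) else x
  stopifnot(length(tables) >= 1,
            all(vapply(tables, is, logical(1), "FractionCountTable")))
  props <- lapply(tables, function(tab) {
    if (normalize) tab <- spikeNormalize(tab)
    cts <- SummarizedExperiment::assay(tab, "counts")
    tot <- rowSums(cts)
    if (any(tot == 0)) {
      warning("dropping ", sum(tot == 0), " gene(s) with zero total counts")
      cts <- cts[tot > 0, , drop = FALSE]
      tot <- tot[tot > 0]
    }
    sweep(cts, 1, tot, `/`)
  })
  genes <- Reduce(intersect, lapply(props, rownames))
  avg <- Reduce(`+`, lapply(props, function(p) p[genes, , drop = FALSE])) /
    length(props)
  avg <- sweep(avg, 1, rowSums(avg), `/`)   # guard against rounding drift
  new("FractionDistribution", proportions = avg,
      translatedFraction = setNames(avg[, 3] + avg[, 4], genes),
      condition = tables[[1]]@condition,
      nReplicates = length(tables))
}

# Per-replicate long-format proportions for a list of tables.
proportionsLong <- function(tables, normalize = TRUE) {
  do.call(rbind, lapply(tables, function(tab) {
    if (normalize) tab <- spikeNormalize(tab)
    cts <- SummarizedExperiment::assay(tab, "counts")
    tot <- rowSums(cts)
    keep <- tot > 0
    p <- sweep(cts[keep, , drop = FALSE], 1, tot[keep], `/`)
    data.frame(gene = rep(rownames(p), 4),
               fraction = rep(1:4, each = nrow(p)),
               proportion = as.vector(p),
               condition = tab@condition,
               replicate = tab@replicate)
  }))
}

#' Compare fraction distributions between conditions
#'
#' For each gene, fits a two-way ANOVA of the per-replicate fraction
#' proportions on condition x fraction and tests the treated-minus-control
#' difference within each of the four fractions, adjusting the four
#' comparisons jointly by the single-step multivariate-t method (Dunnett-
#' style contrasts of cell means).
#'
#' @param controlTables,treatedTables lists of
#'   \linkS4class{FractionCountTable} replicates (>= 2 each).
#' @param alpha significance level for the \code{significant} flag.
#' @return A data.frame with one row per gene x fraction: \code{gene},
#'   \code{fraction}, \code{estimate} (treated - control proportion),
#'   \code{p_adj}, \code{significant}.
#' @importFrom multcomp glht adjusted
#' @export
compareFractionDistributions <- function(controlTables, treatedTables,
                                         alpha = 0.05) {
  if (length(controlTables) < 2 || length(treatedTables) < 2) {
    stop("need at least 2 replicates per condition")
  }
  ctl <- proportionsLong(controlTables)
  trt <- proportionsLong(treatedTables)
  ctl$condition <- "control"; trt$condition <- "treated"
  long <- rbind(ctl, trt)
  genes <- intersect(unique(ctl$gene), unique(trt$gene))
  out <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    d <- long[long$gene == genes[gi], ]
    d$cell <- factor(paste0(d$condition, ".F", d$fraction),
                     levels = c(paste0("control.F", 1:4),
                                paste0("treated.F", 1:4)))
    fit <- lm(proportion ~ 0 + cell, data = d)
    K <- cbind(-diag(4), diag(4))   # treated.Ff - control.Ff
    rownames(K) <- paste0("F", 1:4)
    gl <- multcomp::glht(fit, linfct = K)
    sm <- summary(gl, test = multcomp::adjusted("single-step"))
    out[[gi]] <- data.frame(gene = genes[gi], fraction = 1:4,
                            estimate = as.numeric(sm$test$coefficients),
                            p_adj = as.numeric(sm$test$pvalues))
  }
  res <- do.call(rbind, out)
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL
  res
}

#' Protrusion / cell-body enrichment ratios
#'
#' Computes per-gene Ps/CB enrichment: the ratio of a transcript's
#' normalized abundance in isolated protrusion (Ps) samples to matched
#' cell-body (CB) samples. Samples are made comparable either by equalizing
#' the geometric mean of a declared set of non-enriched control genes
#' between the Ps and CB columns (default) or by total counts. When a
#' two-level \code{treatment} factor is given, treatment effects are tested
#' per gene group by two-way ANOVA on log ratios (treatment x group) with
#' Bonferroni-adjusted per-group p-values.
#'
#' @param psCounts,cbCounts numeric matrices, genes x samples, with
#'   matching row and column structure.
#' @param geneGroups character vector of per-gene group labels; genes in
#'   group \code{"control"} are the normalizer set.
#' @param normalizer \code{"control_gene_geomean"} or \code{"total_counts"}.
#' @param treatment optional factor over samples (e.g. vehicle vs drug);
#'   first level is the reference.
#' @return A list: \code{ratios} data.frame (gene, group, mean ratio, SE
#'   per treatment level), \code{contrasts} (NULL or per-group data.frame
#'   with \code{estimate} = log2 ratio change, \code{p_adj}).
#' @export
psCbEnrichment <- function(psCounts, cbCounts, geneGroups,
                           normalizer = c("control_gene_geomean",
                                          "total_counts"),
                           treatment = NULL) {
  normalizer <- match.arg(normalizer)
  psCounts <- as.matrix(psCounts); cbCounts <- as.matrix(cbCounts)
  stopifnot(identical(dim(psCounts), dim(cbCounts)),
            length(geneGroups) == nrow(psCounts))
  nSamp <- ncol(psCounts)
  zero <- rowSums(cbCounts == 0) > 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " gene(s) with zero cell-body counts")
    psCounts <- psCounts[!zero, , drop = FALSE]
    cbCounts <- cbCounts[!zero, , drop = FALSE]
    geneGroups <- geneGroups[!zero]
  }
  ratios <- matrix(NA_real_, nrow(psCounts), nSamp,
                   dimnames = dimnames(psCounts))
  for (s in seq_len(nSamp)) {
    f <- if (normalizer == "control_gene_geomean") {
      ctrlIdx <- geneGroups == "control"
      if (!any(ctrlIdx)) stop("no genes in group 'control' to normalize by")
      geomMean(cbCounts[ctrlIdx, s]) / geomMean(psCounts[ctrlIdx, s])
    } else {
      sum(cbCounts[, s]) / sum(psCounts[, s])
    }
    ratios[, s] <- f * psCounts[, s] / cbCounts[, s]
  }
  if (is.null(treatment)) treatment <- factor(rep("all", nSamp))
  treatment <- as.factor(treatment)
  ratioTab <- do.call(rbind, lapply(levels(treatment), function(lv) {
    r <- ratios[, treatment == lv, drop = FALSE]
    data.frame(gene = rownames(ratios), group = geneGroups,
               treatment = lv, ratio = rowMeans(r),
               se = apply(r, 1, sd) / sqrt(ncol(r)))
  }))
  contrasts <- NULL
  if (nlevels(treatment) == 2) {
    long <- data.frame(
      logr = as.vector(log2(ratios)),
      group = rep(geneGroups, nSamp),
      treatment = rep(treatment, each = nrow(ratios)))
    grps <- unique(geneGroups)
    fit <- lm(logr ~ 0 + group:treatment, data = long)
    cf <- names(coef(fit))
    K <- t(vapply(grps, function(g) {
      k <- numeric(length(cf))
      k[cf == paste0("group", g, ":treatment", levels(treatment)[2])] <- 1
      k[cf == paste0("group", g, ":treatment", levels(treatment)[1])] <- -1
      k
    }, numeric(length(cf))))
    rownames(K) <- grps
    gl <- summary(multcomp::glht(fit, linfct = K),
                  test = multcomp::adjusted("bonferroni"))
    contrasts <- data.frame(group = grps,
                            estimate = as.numeric(gl$test$coefficients),
                            p_adj = as.numeric(gl$test$pvalues))
    rownames(contrasts) <- NULL
  }
  list(ratios = ratioTab, contrasts = contrasts)
}

#' Fraction-distribution heatmap matrix
#'
#' Assembles the genes x 4 matrix of mean fraction proportions in a given
#' gene order, optionally writing it to CSV and rendering a simple heatmap
#' image (PNG).
#'
#' @param distribution a \linkS4class{FractionDistribution}.
#' @param geneOrder character vector of genes (rows of the output, top to
#'   bottom); all must be present.
#' @param csv,png optional output file paths.
#' @return The ordered matrix, invisibly when files are written.
#' @importFrom grDevices png dev.off hcl.colors
#' @importFrom graphics image axis
#' @export
heatmapMatrix <- function(distribution, geneOrder = NULL, csv = NULL,
                          png = NULL) {
  stopifnot(is(distribution, "FractionDistribution"))
  m <- distribution@proportions
  if (is.null(geneOrder)) geneOrder <- rownames(m)
  missing <- setdiff(geneOrder, rownames(m))
  if (length(missing) > 0) {
    stop("unknown gene(s) in 'geneOrder': ",
         paste(missing, collapse = ", "))
  }
  m <- m[geneOrder, , drop = FALSE]
  if (!is.null(csv)) {
    write.csv(data.frame(gene = rownames(m), m, check.names = FALSE),
              csv, row.names = FALSE)
  }
  if (!is.null(png)) {
    grDevices::png(png, width = 480, height = 120 + 14 * nrow(m))
    op <- graphics::par(mar = c(4, 8, 2, 1))
    graphics::image(x = 1:4, y = seq_len(nrow(m)),
                    z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "fraction", ylab = "", axes = FALSE,
                    zlim = c(0, max(m)))
    graphics::axis(1, at = 1:4, labels = paste0("F", 1:4))
    graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                   las = 2, cex.axis = 0.6)
    graphics::par(op)
    grDevices::dev.off()
  }
  if (is.null(csv) && is.null(png)) m else invisible(m)
}
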