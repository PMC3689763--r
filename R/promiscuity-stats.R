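# Per-drug promiscuity table and the statistics reported on it: Pearson
# correlations with t-based significance, sqrt-transformed pair counts,
# two-sample Kolmogorov-Smirnov comparisons, multiple linear regression
# and drug-centric summaries.

#' Pearson correlation report
#'
#' @slot r Pearson coefficient.
#' @slot pValue two-sided P-value from the t statistic with n-2 df.
#' @slot n sample size used.
#' @slot yTransform "none" or "sqrt".
#' @exportClass CorrelationReport
setClass("CorrelationReport",
  representation(r = "numeric", pValue = "numeric", n = "integer",
                 yTransform = "character")
)

setMethod("show", "CorrelationReport", function(object) {
  cat(sprintf("CorrelationReport: r = %.3f, P = %.3g, n = %d%s\n",
              object@r, object@pValue, object@n,
              if (object@yTransform == "sqrt") " (y sqrt-transformed)" else ""))
})

#' Correlate a drug property with the degree of promiscuity
#'
#' Pearson correlation with the two-sided P-value of `cor.test` (t
#' statistic with n-2 degrees of freedom).  For pair counts the square
#' root of y is taken before correlating (`yTransform = "sqrt"`), since a
#' drug with n targets has up to n(n-1)/2 similar pairs.  Pairs with
#' missing values are dropped (pairwise deletion).
#'
#' @param x,y numeric vectors of per-drug values.
#' @param yTransform "none" (default) or "sqrt".
#' @return A [CorrelationReport-class].
#' @examples
#' correlatePromiscuity(1:10, (1:10) * 2 + 1)  # r = 1
#' @export
correlatePromiscuity <- function(x, y, yTransform = c("none", "sqrt")) {
  yTransform <- match.arg(yTransform)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (yTransform == "sqrt") {
    if (any(y < 0)) stop("sqrt transform requires non-negative y")
    y <- sqrt(y)
  }
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  new("CorrelationReport", r = unname(ct$estimate),
      pValue = ct$p.value, n = length(x), yTransform = yTransform)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum of the ECDF difference; the P-value is asymptotic.
#' A high P-value (> 0.05) indicates similar distributions.
#'
#' @param sampleA,sampleB non-empty numeric samples.
#' @return list with `D`, `pValue`, `nA`, `nB`.
#' @export
ksCompare <- function(sampleA, sampleB) {
  sampleA <- sampleA[is.finite(sampleA)]
  sampleB <- sampleB[is.finite(sampleB)]
  if (!length(sampleA) || !length(sampleB)) stop("empty sample")
  kt <- suppressWarnings(ks.test(sampleA, sampleB, exact = FALSE))
  list(D = unname(kt$statistic), pValue = kt$p.value,
       nA = length(sampleA), nB = length(sampleB))
}

#' Regress the degree of promiscuity on all drug properties
#'
#' Ordinary least squares of the target count on logP, molecular weight,
#' conformer cluster count and the relative and absolute rotatable-bond
#' counts (complete cases).
#'
#' @param table promiscuity table from [buildPromiscuityTable()].
#' @return list with `coefficients`, `rSquared` and `pValue` (overall F).
#' @export
regressCombined <- function(table) {
  preds <- c("logp", "mw", "conformer_cluster_count", "rotatable_rel",
             "rotatable_abs")
  missingCols <- setdiff(c(preds, "target_count"), names(table))
  if (length(missingCols))
    stop("table lacks columns: ", paste(missingCols, collapse = ", "))
  dat <- table[, c("target_count", preds)]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(preds) + 2L)
    stop("need at least ", length(preds) + 2L, " complete rows")
  fit <- lm(target_count ~ ., data = dat)
  cf <- coef(fit)
  if (any(is.na(cf)))
    stop("rank-deficient design; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)
  fs <- sm$fstatistic
  list(coefficients = cf, rSquared = sm$r.squared,
       pValue = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))
}

#' Assemble the per-drug promiscuity table
#'
#' One row per promiscuous drug (degree at or above the threshold) with
#' the target count, the number of non-redundant target pairs with
#' similar binding sites, the number of such pairs that are additionally
#' globally similar (TM-score at or above the cut), the conformer cluster
#' count, the descriptors and optionally the Pfam family count.  Missing
#' optional descriptors are kept as NA and excluded pairwise by the
#' downstream analyses.
#'
#' @param degrees data.frame with columns `drug` and `degree`
#'   (non-redundant target counts).
#' @param pairVerdicts data.frame with columns `drug`, `similar`
#'   (logical) and optionally `tm_score`, one row per non-redundant target
#'   pair.
#' @param conformerTable data.frame with columns `drug` and
#'   `conformer_clusters` (may be missing for some drugs).
#' @param descriptors data.frame with columns `drug`, `mw`, `logp`,
#'   `rotatable_abs`, `rotatable_rel`.
#' @param pfamCounts optional data.frame with columns `drug` and
#'   `families`.
#' @param thresholds a [Thresholds-class].
#' @return data.frame, one row per promiscuous drug.
#' @export
buildPromiscuityTable <- function(degrees, pairVerdicts, conformerTable,
                                  descriptors, pfamCounts = NULL,
                                  thresholds = defaultThresholds()) {
  orphans <- setdiff(unique(pairVerdicts$drug), degrees$drug)
  if (length(orphans))
    stop("pair verdicts for unknown drugs: ",
         paste(head(orphans, 10), collapse = ", "))
  prom <- degrees[degrees$degree >= thresholds@promiscuityMinTargets, ,
                  drop = FALSE]
  tab <- data.frame(drug = prom$drug, target_count = prom$degree,
                    stringsAsFactors = FALSE)
  simCount <- function(d) {
    pv <- pairVerdicts[pairVerdicts$drug == d, , drop = FALSE]
    sum(pv$similar)
  }
  structCount <- function(d) {
    pv <- pairVerdicts[pairVerdicts$drug == d, , drop = FALSE]
    if (!"tm_score" %in% names(pv) || !nrow(pv)) return(NA_integer_)
    sum(pv$similar & !is.na(pv$tm_score) &
          pv$tm_score >= thresholds@tmSimilar)
  }
  tab$similar_pair_count <- vapply(tab$drug, simCount, numeric(1))
  tab$structural_similar_pair_count <- vapply(tab$drug, structCount,
                                              numeric(1))
  tab$possible_pairs <- choose(tab$target_count, 2)
  m <- match(tab$drug, conformerTable$drug)
  tab$conformer_cluster_count <- conformerTable$conformer_clusters[m]
  m <- match(tab$drug, descriptors$drug)
  tab$mw <- descriptors$mw[m]
  tab$logp <- descriptors$logp[m]
  tab$rotatable_abs <- descriptors$rotatable_abs[m]
  tab$rotatable_rel <- descriptors$rotatable_rel[m]
  if (!is.null(pfamCounts)) {
    m <- match(tab$drug, pfamCounts$drug)
    tab$pfam_family_count <- pfamCounts$families[m]
  }
  bad <- tab$similar_pair_count > tab$possible_pairs
  if (any(bad, na.rm = TRUE))
    stop("similar pair count exceeds n(n-1)/2 for: ",
         paste(tab$drug[which(bad)], collapse = ", "))
  rownames(tab) <- NULL
  tab
}

#' The correlation panels of the promiscuity analysis
#'
#' Correlates the target count with each studied property: molecular
#' weight, hydrophobicity (logP), conformer cluster count, Pfam family
#' count (when present), and the square roots of the globally-similar and
#' similar-binding-site pair counts.
#'
#' @param table promiscuity table from [buildPromiscuityTable()].
#' @return named list of [CorrelationReport-class] objects.
#' @export
analyzeCorrelations <- function(table) {
  x <- table$target_count
  out <- list()
  safe <- function(y, tr) tryCatch(correlatePromiscuity(x, y, tr),
                                   error = function(e) NULL)
  out$mw <- safe(table$mw, "none")
  out$logp <- safe(table$logp, "none")
  out$conformers <- safe(table$conformer_cluster_count, "none")
  if ("pfam_family_count" %in% names(table))
    out$pfam <- safe(table$pfam_family_count, "none")
  out$structural_similar <- safe(table$structural_similar_pair_count, "sqrt")
  out$similar_sites <- safe(table$similar_pair_count, "sqrt")
  out[!vapply(out, is.null, logical(1))]
}

#' Drug-centric summary of the similarity analysis
#'
#' @param table promiscuity table from [buildPromiscuityTable()].
#' @param pairIdentities optional data.frame with columns `drug` and
#'   `identity_pct`, one row per similar non-redundant target pair, used
#'   for the identity quantiles of the top drugs.
#' @param topK how many top drugs to tabulate (default 10).
#' @param histogramCap degrees at or above this value are pooled into one
#'   final histogram bin (default 10).
#' @return list with `fractionWithSimilar`, `fractionAllSimilar`,
#'   `degreeHistogram`, `topBySimilar`.
#' @export
summarizeDrugs <- function(table, pairIdentities = NULL, topK = 10L,
                           histogramCap = 10L) {
  withSim <- table$similar_pair_count >= 1
  allSim <- table$similar_pair_count == table$possible_pairs &
    table$possible_pairs > 0
  degree <- pmin(table$target_count, histogramCap)
  hist <- table(factor(degree, levels = seq_len(histogramCap)))
  names(hist)[histogramCap] <- paste0(">=", histogramCap)
  top <- table[order(-table$similar_pair_count, table$drug), , drop = FALSE]
  top <- head(top[, c("drug", "target_count", "similar_pair_count")], topK)
  if (!is.null(pairIdentities)) {
    qs <- lapply(top$drug, function(d) {
      idv <- pairIdentities$identity_pct[pairIdentities$drug == d]
      if (!length(idv)) return(rep(NA_real_, 6))
      c(min(idv), quantile(idv, 0.25), median(idv), mean(idv),
        quantile(idv, 0.75), max(idv))
    })
    qm <- do.call(rbind, qs)
    colnames(qm) <- c("id_min", "id_q25", "id_median", "id_mean",
                      "id_q75", "id_max")
    top <- cbind(top, round(qm, 1))
  }
  rownames(top) <- NULL
  list(fractionWithSimilar = mean(withSim),
       fractionAllSimilar = mean(allSim),
       degreeHistogram = hist,
       topBySimilar = top)
}
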