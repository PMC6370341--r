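# Pangenome gene-content analysis for partial genome assemblies:
# recovery-corrected core/flexible classification, Jaccard average-linkage
# clustering of flexible genes, marker enrichment, and the PCR-vs-annotation
# concordance arithmetic.

#' Recovery-corrected core-gene threshold
#'
#' With partial assemblies a gene cluster present in every underlying
#' genome is still expected to be observed in only about
#' median-recovery of them.  A cluster is therefore classified core when
#' it is found in at least \code{floor(nGenomes * medianRecovery)} genomes.
#'
#' @param nGenomes number of genomes in the set.
#' @param medianRecovery median genome-recovery fraction, in (0, 1].
#' @return Integer threshold count.
#' @examples
#' coreThreshold(22, 0.87)  # 19
#' @export
coreThreshold <- function(nGenomes, medianRecovery) {
  if (nGenomes < 1) stop("nGenomes must be >= 1")
  if (medianRecovery <= 0 || medianRecovery > 1) {
    stop("medianRecovery must lie in (0, 1]")
  }
  as.integer(floor(nGenomes * medianRecovery))
}

#' Restrict a presence table to informative flexible gene clusters
#'
#' Removes clusters at or above the recovery-corrected core threshold
#' (computed from the table's own recovery fractions) and clusters present
#' in fewer than \code{minGenomes} genomes; genomes are unchanged.
#' Idempotent.
#'
#' @param table a [GenePresenceTable-class].
#' @param minGenomes minimum genome count for a cluster to be retained
#'   (default 3).
#' @return A [GenePresenceTable-class] containing only the flexible
#'   clusters.  Warns (rather than errors) when nothing survives.
#' @export
filterFlexible <- function(table, minGenomes = 3) {
  m <- presenceMatrix(table)
  thr <- coreThreshold(nrow(m), median(table@recovery))
  counts <- colSums(m)
  keep <- counts < thr & counts >= minGenomes
  if (!any(keep)) {
    warning("no flexible gene clusters survive filtering")
  }
  genePresenceTable(m[, keep, drop = FALSE], recovery = table@recovery,
                    marker = table@marker)
}

#' Average-linkage clustering of gene clusters on Jaccard distance
#'
#' Pairwise Jaccard distance \eqn{d = 1 - |A \cap B| / |A \cup B|} between
#' the genome-presence sets of every pair of gene clusters, followed by
#' average-linkage (UPGMA) hierarchical clustering.
#'
#' @param table a [GenePresenceTable-class] (typically after
#'   [filterFlexible()]); at least 2 clusters.
#' @return An \code{\link[stats]{hclust}} object (merge history with
#'   heights).
#' @export
jaccardLinkage <- function(table) {
  m <- presenceMatrix(table)
  if (ncol(m) < 2L) stop("need at least 2 gene clusters to cluster")
  if (any(colSums(m) == 0)) {
    stop("gene cluster present in zero genomes: Jaccard distance undefined (",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "), ")")
  }
  inter <- crossprod(m)            # |A n B|
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  hclust(as.dist(d), method = "average")
}

#' Marker-set enrichment of flexible gene clusters
#'
#' For each gene cluster, tests whether its occurrence among marker-positive
#' genomes is higher (over-representation) or lower (under-representation)
#' than expected from its overall frequency, by exact hypergeometric tail
#' probabilities.  Both directions are reported separately and
#' Benjamini-Hochberg adjusted across all tested clusters within each
#' direction.
#'
#' @param table a [GenePresenceTable-class] whose marker flags contain at
#'   least one TRUE and one FALSE.
#' @return A data.frame with columns \code{cluster}, \code{k} (count in
#'   marker-positive genomes), \code{n} (marker-positive genomes), \code{K}
#'   (count in all genomes), \code{N} (all genomes), \code{direction},
#'   \code{p}, \code{q}, sorted by \code{q}.
#' @export
markerEnrichment <- function(table) {
  m <- presenceMatrix(table)
  flag <- table@marker
  if (any(is.na(flag))) {
    keep <- !is.na(flag)
    m <- m[keep, , drop = FALSE]
    flag <- flag[keep]
  }
  if (sum(flag) < 1L || sum(!flag) < 1L) {
    stop("need at least one marker-positive and one marker-negative genome")
  }
  N <- nrow(m)
  n <- sum(flag)
  K <- colSums(m)
  k <- colSums(m[flag, , drop = FALSE])
  pOver <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pUnder <- phyper(k, K, N - K, n)
  res <- rbind(
    data.frame(cluster = colnames(m), k = k, n = n, K = K, N = N,
               direction = "over", p = pOver,
               q = p.adjust(pOver, "BH"), row.names = NULL),
    data.frame(cluster = colnames(m), k = k, n = n, K = K, N = N,
               direction = "under", p = pUnder,
               q = p.adjust(pUnder, "BH"), row.names = NULL))
  res[order(res$q, res$p, res$cluster), , drop = FALSE]
}

#' Concordance between PCR screening and genome annotation
#'
#' Agreement arithmetic for a marker gene assayed both by PCR and by
#' annotation of partial assemblies: percent agreement, conditional
#' percentages, the expected number of PCR-positive genomes whose
#' (partial) assembly should contain an annotated copy given the median
#' recovery, and the post hoc false-negative rate of the comparison.
#' Reported percents are rounded half-up to integers; raw values are
#' retained.
#'
#' @param total number of genomes screened by both methods.
#' @param annotated number with an annotated marker gene.
#' @param pcr number PCR-positive.
#' @param both number positive by both methods.
#' @param medianRecovery median genome recovery of the PCR-positive
#'   genomes, in (0, 1].
#' @return A list with raw and rounded components: \code{agreement},
#'   \code{pctAnnotatedPcr} (share of annotated-positive that are
#'   PCR-positive), \code{pctPcrAnnotated}, \code{expectedAnnotated}
#'   (= round(pcr x medianRecovery)), \code{fnRate}
#'   (= (expected - both)/expected; NA when expected is 0) and a
#'   \code{report} of integer percents.
#' @examples
#' concordanceStats(206, 61, 81, 59, medianRecovery = 0.80)
#' @export
concordanceStats <- function(total, annotated, pcr, both, medianRecovery) {
  if (both > min(annotated, pcr)) {
    stop("'both' cannot exceed either single-method count")
  }
  if (any(c(annotated, pcr, both) > total)) {
    stop("counts cannot exceed 'total'")
  }
  if (medianRecovery <= 0 || medianRecovery > 1) {
    stop("medianRecovery must lie in (0, 1]")
  }
  bothNeg <- total - (annotated + pcr - both)
  agreement <- (both + bothNeg) / total
  pctAnnotatedPcr <- both / annotated
  pctPcrAnnotated <- both / pcr
  expected <- .roundHalfUp(pcr * medianRecovery)
  fnRate <- if (expected == 0) NA_real_ else (expected - both) / expected
  list(
    agreement = agreement,
    pctAnnotatedPcr = pctAnnotatedPcr,
    pctPcrAnnotated = pctPcrAnnotated,
    expectedAnnotated = expected,
    fnRate = fnRate,
    report = c(
      agreement_pct = .roundHalfUp(100 * agreement),
      annotated_positive_by_pcr_pct = .roundHalfUp(100 * pctAnnotatedPcr),
      pcr_positive_annotated_pct = .roundHalfUp(100 * pctPcrAnnotated),
      expected_annotated = expected,
      false_negative_rate_pct =
        if (is.na(fnRate)) NA_real_ else .roundHalfUp(100 * fnRate)))
}

#' Read a genome x gene-cluster presence table from TSV
#'
#' @param path TSV with genomes as rows (first column = genome id) and
#'   gene clusters as columns, entries 0/1.
#' @param recoveryPath optional TSV with columns \code{genome},
#'   \code{recovery}.
#' @param markerPath optional TSV with columns \code{genome},
#'   \code{marker} (0/1 or TRUE/FALSE).
#' @return A [GenePresenceTable-class].
#' @export
readGenePresenceTable <- function(path, recoveryPath = NULL,
                                  markerPath = NULL) {
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  recov <- rep(1, nrow(m))
  if (!is.null(recoveryPath)) {
    r <- read.delim(recoveryPath)
    recov <- r$recovery[match(rownames(m), r$genome)]
    if (anyNA(recov)) stop("recovery table is missing some genomes")
  }
  marker <- NULL
  if (!is.null(markerPath)) {
    mk <- read.delim(markerPath)
    marker <- as.logical(mk$marker[match(rownames(m), mk$genome)])
  }
  genePresenceTable(m, recovery = recov, marker = marker)
}
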