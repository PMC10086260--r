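#' Per-gene log2 fold change between two groups
#'
#' Difference of group means per gene, case minus control, on data that
#' is already log2 scale — so a value of 1 is a doubling.
#'
#' @param se expression `SummarizedExperiment` whose `colData$group` has
#'   exactly two levels.
#' @param caseGroup,controlGroup which group is case / control; defaults
#'   to the alphabetically last / first group.
#' @return named numeric vector of log2 fold changes.
#' @export
logFoldChange <- function(se, caseGroup = NULL, controlGroup = NULL) {
  parts <- .twoGroups(se, caseGroup, controlGroup)
  rowMeans(exprsMatrix(parts$case)) - rowMeans(exprsMatrix(parts$control))
}

.twoGroups <- function(se, caseGroup = NULL, controlGroup = NULL) {
  parts <- splitByGroup(se)
  if (length(parts) != 2L)
    stop("exactly 2 groups required, got ", length(parts), " (",
         paste(names(parts), collapse = ", "), ")")
  if (is.null(controlGroup)) controlGroup <- names(parts)[1L]
  if (is.null(caseGroup))
    caseGroup <- setdiff(names(parts), controlGroup)
  if (!all(c(caseGroup, controlGroup) %in% names(parts)) ||
      caseGroup == controlGroup)
    stop("case/control groups must name the two distinct groups")
  list(case = parts[[caseGroup]], control = parts[[controlGroup]],
       caseGroup = caseGroup, controlGroup = controlGroup)
}

#' Per-gene Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test (Satterthwaite degrees of freedom)
#' of each gene between the two groups.  This is a simple per-gene stand-in
#' for moderated differential-expression statistics: it borrows no
#' information across genes, which is adequate for the simulated and
#' well-powered designs this package targets.
#'
#' @inheritParams logFoldChange
#' @return named numeric vector of two-sided p-values.
#' @export
welchTTest <- function(se, caseGroup = NULL, controlGroup = NULL) {
  parts <- .twoGroups(se, caseGroup, controlGroup)
  a <- exprsMatrix(parts$case)
  b <- exprsMatrix(parts$control)
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("each group needs at least 2 samples")
  p <- vapply(seq_len(nrow(a)), function(i) {
    if (stats::sd(a[i, ]) == 0 && stats::sd(b[i, ]) == 0) {
      if (mean(a[i, ]) == mean(b[i, ])) return(1)
      return(0)
    }
    stats::t.test(a[i, ], b[i, ], var.equal = FALSE)$p.value
  }, numeric(1))
  stats::setNames(p, rownames(a))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment: with p-values ordered
#' ascending, the adjusted value at rank i is
#' \eqn{\min_{j \ge i} m\,p_{(j)}/j}, capped at 1, reported in the
#' original order.  Delegates to [stats::p.adjust()] after validating the
#' input range.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
benjaminiHochberg <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential-expression table
#'
#' Combines [logFoldChange()], [welchTTest()] and [benjaminiHochberg()]
#' into one table and assigns each gene a status via [callDEGs()].
#'
#' @inheritParams logFoldChange
#' @inheritParams callDEGs
#' @return data.frame with columns `gene`, `logFC`, `pRaw`, `pAdj`,
#'   `status`.
#' @examples
#' d <- syntheticDesign(
#'   modules = list(), rho = list(),
#'   meanShift = c(up1 = 3, up2 = 3), shiftGroup = "AD",
#'   groupSizes = c(AD = 20, CON = 20), seed = 3, extraGenes = 10)
#' head(degTable(simulateExpression(d), caseGroup = "AD"))
#' @export
degTable <- function(se, caseGroup = NULL, controlGroup = NULL,
                     lfcThresh = 1.5, pThresh = 0.05,
                     useAdjusted = TRUE) {
  lfc <- logFoldChange(se, caseGroup, controlGroup)
  p <- welchTTest(se, caseGroup, controlGroup)
  tab <- data.frame(gene = names(lfc), logFC = unname(lfc),
                    pRaw = unname(p),
                    pAdj = benjaminiHochberg(unname(p)))
  callDEGs(tab, lfcThresh = lfcThresh, pThresh = pThresh,
           useAdjusted = useAdjusted)
}

#' Call differentially expressed genes
#'
#' Applies joint fold-change and significance thresholds with strict
#' inequalities: `up` when `logFC > lfcThresh` and p below `pThresh`,
#' `down` when `logFC < -lfcThresh` and p below `pThresh`, otherwise
#' `ns`.  A gene sitting exactly on a threshold is `ns`.
#'
#' @param table data.frame with columns `logFC`, `pRaw`, `pAdj` (and
#'   optionally `gene`).
#' @param lfcThresh absolute log2-fold-change threshold (default 1.5).
#' @param pThresh significance threshold (default 0.05).
#' @param useAdjusted apply `pThresh` to the BH-adjusted p (default) or,
#'   when `FALSE`, to the raw p.
#' @return the table with a `status` factor column (`up`, `down`, `ns`).
#' @export
callDEGs <- function(table, lfcThresh = 1.5, pThresh = 0.05,
                     useAdjusted = TRUE) {
  stopifnot(all(c("logFC", "pRaw", "pAdj") %in% colnames(table)))
  p <- if (useAdjusted) table$pAdj else table$pRaw
  status <- rep("ns", nrow(table))
  status[table$logFC > lfcThresh & p < pThresh] <- "up"
  status[table$logFC < -lfcThresh & p < pThresh] <- "down"
  table$status <- factor(status, levels = c("up", "down", "ns"))
  table
}
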