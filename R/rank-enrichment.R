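#' Ranked-list word enrichment and target fold-change statistics
#'
#' Orders a differential-expression table from most down- to most
#' up-regulated, computes a signed hypergeometric enrichment landscape
#' for a 3'UTR word over successive leading-set cutoffs, and provides
#' target percentage / fold-change summaries, cumulative-fraction curves,
#' and set-vs-set distribution comparisons.
#'
#' @name rank_enrichment
NULL

validate_de_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("gene", "log2fc")
  if (!all(need %in% names(table))) {
    stop("DE table must have columns gene and log2fc")
  }
  if (nrow(table) == 0) stop("DE table is empty")
  if (anyDuplicated(table$gene)) stop("DE table has duplicate genes")
  if (any(!is.finite(table$log2fc))) stop("DE table has missing log2fc")
  invisible(table)
}

#' Rank genes from most down- to most up-regulated
#'
#' Ascending log2 fold change, ties broken lexicographically by gene
#' identifier so the ordering is stable and independent of input row
#' order. Genes whose expression did not change are included.
#'
#' @param table DE data.frame (`gene`, `log2fc`, optionally `adj_p`).
#' @param direction Only `"down_to_up"` is defined.
#' @return Character vector of gene identifiers in rank order.
#' @export
rank_genes <- function(table, direction = "down_to_up") {
  direction <- match.arg(direction, "down_to_up")
  validate_de_table(table)
  table$gene[order(table$log2fc, table$gene)]
}

#' Hypergeometric word-enrichment landscape over a ranked gene list
#'
#' At each leading-set cutoff t (every `step` genes plus the final
#' cutoff N) with K of the N ranked genes carrying at least one UTR
#' occurrence of `word` and x of those in the leading t, the landscape
#' value is `-log10 P(X >= x)` when the leading set is enriched
#' (x/t >= K/N) and `+log10 P(X <= x)` otherwise, with
#' X ~ Hypergeometric(N, K, t). Positive values therefore mean
#' enrichment in the leading (most down-regulated) genes.
#'
#' Counting is by gene presence/absence of the word, not occurrence
#' totals, and no sequence-composition correction is applied; both
#' choices are recorded in the result's metadata.
#'
#' @param ranked Character vector of genes in rank order.
#' @param utrome Named character vector, gene -> UTR. Ranked genes
#'   without a UTR are dropped (count reported in metadata).
#' @param word Site motif string, 6-8 nt.
#' @param step Cutoff spacing in genes (default 100).
#' @return data.frame with `cutoff`, `value`; attributes `word`, `K`,
#'   `N`, `n_dropped`, `counting`.
#' @export
word_landscape <- function(ranked, utrome, word, step = 100L) {
  word <- normalize_rna(word)
  if (nchar(word) < 6 || nchar(word) > 8) {
    stop("word must be 6 to 8 nt long")
  }
  keep <- ranked %in% names(utrome)
  n_dropped <- sum(!keep)
  ranked <- ranked[keep]
  N <- length(ranked)
  if (N == 0) stop("no ranked genes have a UTR")
  step <- as.integer(step)
  if (step <= 0 || step > N) stop("step must be in 1..N")
  has_word <- vapply(utrome[ranked],
                     function(u) grepl(word, normalize_rna(u), fixed = TRUE),
                     logical(1))
  K <- sum(has_word)
  cutoffs <- unique(c(seq(step, N, by = step), N))
  x <- cumsum(has_word)[cutoffs]
  enriched <- x / cutoffs >= K / N
  value <- ifelse(
    enriched,
    -log10(stats::phyper(x - 1, K, N - K, cutoffs, lower.tail = FALSE)),
    log10(stats::phyper(x, K, N - K, cutoffs))
  )
  out <- data.frame(cutoff = cutoffs, value = value)
  attr(out, "word") <- word
  attr(out, "K") <- K
  attr(out, "N") <- N
  attr(out, "n_dropped") <- n_dropped
  attr(out, "counting") <- "gene presence/absence, no composition correction"
  out
}

# Significance classes: adj_p < alpha split by sign of log2fc; a
# significant gene with log2fc exactly 0 counts as no_change.
de_direction_class <- function(table, alpha = 0.05) {
  if (!"adj_p" %in% names(table)) stop("DE table needs adj_p for this operation")
  sig <- table$adj_p < alpha
  ifelse(sig & table$log2fc > 0, "up",
  ifelse(sig & table$log2fc < 0, "down", "no_change"))
}

#' Percentage of a direction class that are predicted targets
#'
#' 100 times the number of targets among the genes in the requested
#' class (significantly up, significantly down, or no change at level
#' `alpha`) divided by the class size. An empty class yields NA, never
#' zero.
#'
#' @param table DE data.frame with `gene`, `log2fc`, `adj_p`.
#' @param targets Character vector of predicted target genes.
#' @param direction One of `"up"`, `"down"`, `"no_change"`.
#' @param alpha Significance level on adjusted P (default 0.05).
#' @return Percentage (0-100) or NA.
#' @export
percent_targets <- function(table, targets, direction = c("up", "down",
                                                          "no_change"),
                            alpha = 0.05) {
  direction <- match.arg(direction)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  validate_de_table(table)
  cls <- de_direction_class(table, alpha)
  in_class <- cls == direction
  if (!any(in_class)) return(NA_real_)
  100 * sum(table$gene[in_class] %in% targets) / sum(in_class)
}

#' Mean or median log2 fold change of a target set
#'
#' @param table DE data.frame.
#' @param targets Character vector of target genes.
#' @param stat `"mean"` or `"median"`.
#' @return The statistic over member log2fc, or NA when no target is in
#'   the table.
#' @export
target_fc_summary <- function(table, targets, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  validate_de_table(table)
  x <- table$log2fc[table$gene %in% targets]
  if (length(x) == 0) return(NA_real_)
  if (stat == "mean") mean(x) else stats::median(x)
}

#' Cumulative-fraction curve of a gene set's log2 fold changes
#'
#' The empirical CDF of log2fc over the members of `gene_set` present in
#' the table; used to visualize set-wide repression relative to all
#' genes.
#'
#' @param table DE data.frame.
#' @param gene_set Character vector of genes; defaults to all genes.
#' @param grid Optional threshold grid; defaults to the sorted member
#'   values.
#' @return A `CumulativeFractionCurve`: list with `threshold`,
#'   `fraction` (non-decreasing, 0 to 1) and `value_at(cutoff)`.
#' @export
cumulative_fraction <- function(table, gene_set = NULL, grid = NULL) {
  validate_de_table(table)
  if (is.null(gene_set)) gene_set <- table$gene
  x <- table$log2fc[table$gene %in% gene_set]
  if (length(x) == 0) stop("gene_set does not intersect the table")
  f <- stats::ecdf(x)
  if (is.null(grid)) grid <- sort(unique(x))
  out <- list(threshold = grid, fraction = f(grid), value_at = f,
              n = length(x))
  class(out) <- c("CumulativeFractionCurve", "list")
  out
}

#' Compare log2 fold-change distributions of two gene sets
#'
#' Two-sided Mann-Whitney U by default (Welch t-test selectable); both
#' sets must have at least two members present in the table.
#'
#' @param table DE data.frame.
#' @param setA,setB Character vectors of genes.
#' @param test `"wilcox"` (default) or `"t"`.
#' @return List with `statistic`, `p_value`, `test`, `nA`, `nB`.
#' @export
compare_target_distributions <- function(table, setA, setB,
                                         test = c("wilcox", "t")) {
  test <- match.arg(test)
  validate_de_table(table)
  a <- table$log2fc[table$gene %in% setA]
  b <- table$log2fc[table$gene %in% setB]
  if (length(a) < 2 || length(b) < 2) {
    stop("both gene sets need >= 2 members present in the table")
  }
  res <- if (test == "wilcox") {
    suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  } else {
    stats::t.test(a, b, alternative = "two.sided")
  }
  list(statistic = unname(res$statistic), p_value = res$p.value,
       test = test, nA = length(a), nB = length(b))
}
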