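#' Host-gene surrogate inverse-correlation analysis
#'
#' The expression change of the protein-coding gene hosting an intronic
#' miRNA is used as a proxy for the miRNA's own change across a
#' compendium of differential-expression studies: studies are filtered
#' for a significant host-gene change, per-study target statistics are
#' computed (mean target log2FC, percent of targets among up/down genes,
#' their up/down enrichment ratio, and a random-gene control), and mean
#' target fold change is regressed on host fold change.
#'
#' @name surrogate_correlation
NULL

#' Build StudyComparison records from DE tables
#'
#' @param studies Named list of DE data.frames (study id -> table).
#' @param host Host gene identifier.
#' @return List of `StudyComparison` records (study_id, de, host_log2fc,
#'   host_adj_p); studies lacking the host gene are dropped with a
#'   message and their count in attribute `n_dropped`.
#' @export
study_comparisons <- function(studies, host) {
  stopifnot(is.list(studies), length(names(studies)) == length(studies))
  out <- list()
  dropped <- 0L
  for (id in names(studies)) {
    de <- studies[[id]]
    validate_de_table(de)
    row <- de[de$gene == host, , drop = FALSE]
    if (nrow(row) == 0) { dropped <- dropped + 1L; next }
    rec <- list(study_id = id, de = de, host_log2fc = row$log2fc[1],
                host_adj_p = row$adj_p[1])
    class(rec) <- c("StudyComparison", "list")
    out[[id]] <- rec
  }
  if (dropped > 0) {
    message(dropped, " study(ies) dropped: host gene '", host, "' absent")
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Filter a compendium for significant host-gene change
#'
#' Retains studies with host adjusted P below `alpha`; no fold-change
#' cutoff is applied.
#'
#' @param compendium List of `StudyComparison` records.
#' @param alpha Significance level (default 0.05).
#' @return Filtered list (same structure).
#' @export
filter_studies <- function(compendium, alpha = 0.05) {
  if (length(compendium) == 0) stop("compendium is empty")
  keep <- vapply(compendium, function(s) s$host_adj_p < alpha, logical(1))
  out <- compendium[keep]
  attr(out, "n_filtered_out") <- sum(!keep)
  out
}

#' Per-study surrogate summary statistics
#'
#' For each target set: mean target log2FC, percent of targets within
#' significantly up- and down-regulated genes, and the up/down
#' enrichment ratio (percent-up divided by percent-down, missing when
#' the denominator is undefined or zero). A random control set of
#' `random_set_size` genes is drawn without replacement from the study's
#' genes under the given seed and summarized alongside as `"random"`.
#'
#' @param study A `StudyComparison`.
#' @param target_sets Named list of character vectors (set id -> genes).
#' @param random_set_size Random control size (default 500).
#' @param rng_seed Seed for the random control draw.
#' @param alpha Significance level for up/down classes (default 0.05).
#' @return data.frame, one row per target set (plus `"random"`):
#'   `study_id`, `set_id`, `mean_target_log2fc`, `pct_targets_up`,
#'   `pct_targets_down`, `enrichment_up_down`, `host_log2fc`.
#' @export
study_summary <- function(study, target_sets, random_set_size = 500L,
                          rng_seed = 1L, alpha = 0.05) {
  stopifnot(inherits(study, "StudyComparison"))
  de <- study$de
  if (random_set_size > 0) {
    if (random_set_size > nrow(de)) {
      stop("random_set_size exceeds the study's gene count")
    }
    set.seed(as.integer(rng_seed))
    target_sets <- c(target_sets,
                     list(random = sample(de$gene, random_set_size)))
  }
  rows <- lapply(names(target_sets), function(id) {
    tg <- target_sets[[id]]
    if (!any(de$gene %in% tg)) {
      warning("target set '", id, "' does not intersect study ",
              study$study_id, "; statistics are missing")
    }
    up <- percent_targets(de, tg, "up", alpha)
    dn <- percent_targets(de, tg, "down", alpha)
    ratio <- if (is.na(up) || is.na(dn) || dn == 0) NA_real_ else up / dn
    data.frame(study_id = study$study_id, set_id = id,
               mean_target_log2fc = target_fc_summary(de, tg, "mean"),
               pct_targets_up = up, pct_targets_down = dn,
               enrichment_up_down = ratio,
               host_log2fc = study$host_log2fc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize every study in a compendium
#'
#' Applies [study_summary()] per study with a reproducible study-derived
#' seed offset for the random control.
#'
#' @param compendium List of `StudyComparison` records.
#' @param target_sets Named list of target gene vectors.
#' @param random_set_size Random control size (default 500).
#' @param rng_seed Base seed; study i uses `rng_seed + i`.
#' @param alpha Significance level (default 0.05).
#' @return Row-bound summary data.frame.
#' @export
summarize_compendium <- function(compendium, target_sets,
                                 random_set_size = 500L, rng_seed = 1L,
                                 alpha = 0.05) {
  rows <- lapply(seq_along(compendium), function(i) {
    study_summary(compendium[[i]], target_sets, random_set_size,
                  rng_seed = as.integer(rng_seed) + i, alpha = alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress mean target fold change on host-gene fold change
#'
#' Ordinary least squares of per-study mean target log2FC on host
#' log2FC; r-squared is the squared Pearson correlation and the P-value
#' the two-sided t-test on the slope.
#'
#' @param summaries Summary data.frame from [summarize_compendium()].
#' @param target_set_id Which `set_id` to regress.
#' @return A `RegressionResult`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n_studies`.
#' @export
regress_targets_vs_host <- function(summaries, target_set_id) {
  s <- summaries[summaries$set_id == target_set_id, , drop = FALSE]
  s <- s[is.finite(s$mean_target_log2fc) & is.finite(s$host_log2fc), ,
         drop = FALSE]
  if (nrow(s) < 3) stop("need >= 3 studies with defined mean target log2FC")
  if (stats::var(s$host_log2fc) == 0) {
    stop("host fold change has no variance; slope undefined")
  }
  fit <- stats::lm(mean_target_log2fc ~ host_log2fc, data = s)
  sm <- summary(fit)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = sm$r.squared,
              p_value = sm$coefficients[2, 4],
              n_studies = nrow(s))
  class(out) <- c("RegressionResult", "list")
  out
}

#' Cumulative-mean trend line over host-ordered studies
#'
#' Studies are ordered by host fold change; the k-th trend value is the
#' mean of the metric over the first k studies starting from the most
#' up-regulated (`from_most_up`) or most down-regulated
#' (`from_most_down`) host.
#'
#' @param summaries Summary data.frame rows for one set_id.
#' @param metric Column to average (default `mean_target_log2fc`).
#' @param branch `"from_most_down"` or `"from_most_up"`.
#' @return data.frame with `host_log2fc`, `cumulative_mean` in branch
#'   order.
#' @export
cumulative_mean_trend <- function(summaries, metric = "mean_target_log2fc",
                                  branch = c("from_most_down",
                                             "from_most_up")) {
  branch <- match.arg(branch)
  if (nrow(summaries) < 1) stop("need >= 1 study")
  o <- order(summaries$host_log2fc,
             decreasing = (branch == "from_most_up"))
  x <- summaries[[metric]][o]
  if (any(!is.finite(x))) stop("metric has missing values; drop them first")
  data.frame(host_log2fc = summaries$host_log2fc[o],
             cumulative_mean = cumsum(x) / seq_along(x))
}

#' Contrast a metric between host-down and host-up studies
#'
#' Groups studies by the sign of the host fold change (exact zeros are
#' assigned to neither group; their count is reported) and compares
#' group means with a two-sided Welch t-test by default.
#'
#' @param summaries Summary data.frame rows for one set_id.
#' @param metric Column to contrast (`mean_target_log2fc` or
#'   `enrichment_up_down`).
#' @param test `"welch"` (default) or `"wilcox"`.
#' @return List with `mean_host_down`, `mean_host_up`, `p_value`,
#'   `n_down`, `n_up`, `n_zero_host`, `n_missing_metric`, `test`.
#' @export
group_contrast <- function(summaries, metric = "mean_target_log2fc",
                           test = c("welch", "wilcox")) {
  test <- match.arg(test)
  if (!metric %in% names(summaries)) stop("unknown metric: ", metric)
  x <- summaries[[metric]]
  n_missing <- sum(!is.finite(x))
  keep <- is.finite(x)
  host <- summaries$host_log2fc[keep]
  x <- x[keep]
  n_zero <- sum(host == 0)
  dn <- x[host < 0]
  up <- x[host > 0]
  if (length(dn) == 0 || length(up) == 0) {
    stop("both host-direction groups must be non-empty (after dropping ",
         n_missing, " missing metric values)")
  }
  res <- if (test == "welch") {
    stats::t.test(dn, up, alternative = "two.sided")
  } else {
    suppressWarnings(stats::wilcox.test(dn, up, alternative = "two.sided"))
  }
  list(mean_host_down = mean(dn), mean_host_up = mean(up),
       p_value = res$p.value, n_down = length(dn), n_up = length(up),
       n_zero_host = n_zero, n_missing_metric = n_missing, test = test)
}
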