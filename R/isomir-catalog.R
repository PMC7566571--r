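#' IsomiR cataloguing against hairpin references
#'
#' Aligns small-RNA reads exactly to a mature miRNA within its hairpin
#' context (plus genomic flanks), computes 5'/3' offsets, splits off the
#' minimal nontemplated 3' tail (templated extension is consumed greedily
#' first), classifies each read as canonical / 5prime_only / 3prime_only /
#' mixed, extracts seeds, and applies strict read-count and fraction
#' thresholds to call 5' isomiRs.
#'
#' Offset sign convention: `five_prime_offset = mature 5' start - read 5'
#' start` in hairpin coordinates, so a read whose 5' end starts one nt
#' downstream of the annotation (a shorter read, seed shifted toward the
#' 3' direction) has offset -1.
#'
#' @name isomir_catalog
NULL

#' Extract the seed heptamer of a miRNA sequence
#'
#' The seed is positions 2-8 (1-based, inclusive) of the mature sequence,
#' the primary determinant of target binding.
#'
#' @param sequence RNA or DNA string(s), length >= 8 nt.
#' @return Character vector of 7-nt seeds (RNA alphabet).
#' @examples
#' extract_seed("ACCACAGGGUAGAACCACGGAC")  # "CCACAGG"
#' @export
extract_seed <- function(sequence) {
  s <- normalize_rna(sequence)
  if (any(nchar(s) < 8)) stop("sequence shorter than 8 nt has no seed")
  substr(s, 2, 8)
}

#' Align one read to a mature reference within its hairpin context
#'
#' Exact matching only: the longest 3' suffix of the read that cannot be
#' explained by templated sequence is the nontemplated tail, found by
#' trying tail lengths 0, 1, 2, ... and accepting the first (longest
#' templated core) that matches the context anchored near the mature 5'
#' end. Among equally long cores, the placement with the smallest
#' absolute 5' offset wins (ties toward the more negative offset).
#'
#' @param read Read sequence (DNA or RNA).
#' @param ref One-row data.frame (or list) with `sequence` and `start`
#'   (0-based mature start within the hairpin).
#' @param hairpin_context Hairpin sequence with flanks attached.
#' @param context_offset Number of flank bases before hairpin position 0
#'   in `hairpin_context` (default 10).
#' @param max_shift Maximum absolute 5' offset considered anchored to
#'   this mature (default 5 nt).
#' @param min_core Minimum templated core length (default 16 nt);
#'   also the minimum read length accepted.
#' @param max_read_length Maximum read length accepted (default 30 nt).
#' @return List with `five_prime_offset`, `three_prime_offset`,
#'   `nontemplated_tail`, or NULL when the read cannot be placed
#'   (callers route such reads to a reject table).
#' @export
align_read <- function(read, ref, hairpin_context, context_offset = 10L,
                       max_shift = 5L, min_core = 16L, max_read_length = 30L) {
  read <- normalize_rna(read)
  n <- nchar(read)
  if (n < min_core || n > max_read_length) return(NULL)
  ctx <- normalize_rna(hairpin_context)
  m_start <- as.integer(ref$start)                      # hairpin coords
  m_len <- nchar(ref$sequence)
  for (k in 0:(n - min_core)) {
    core <- substr(read, 1L, n - k)
    starts0 <- find_all_0based(ctx, core)               # context coords
    if (length(starts0) == 0) next
    start_h <- starts0 - context_offset
    offset5 <- m_start - start_h
    ok <- abs(offset5) <= max_shift
    if (!any(ok)) next
    offset5 <- offset5[ok]
    start_h <- start_h[ok]
    pick <- order(abs(offset5), offset5)[1]
    return(list(
      five_prime_offset = offset5[pick],
      three_prime_offset = (start_h[pick] + nchar(core)) - (m_start + m_len),
      nontemplated_tail = if (k > 0) substr(read, n - k + 1L, n) else ""
    ))
  }
  NULL
}

#' Classify an alignment into isomiR category and templated status
#'
#' Canonical means both offsets zero with an empty tail; 5prime_only a 5'
#' shift with a canonical 3' side; 3prime_only the converse (including a
#' nontemplated tail with no 5' shift); mixed otherwise. A read is
#' templated iff its nontemplated tail is empty.
#'
#' @param alignment List as returned by [align_read()].
#' @return List with `category` and `templated`.
#' @export
classify_isomir <- function(alignment) {
  list(
    category = isomir_category(alignment$five_prime_offset,
                               alignment$three_prime_offset,
                               alignment$nontemplated_tail),
    templated = nchar(alignment$nontemplated_tail) == 0L
  )
}

#' Build an isomiR catalog from a read-count table
#'
#' Each distinct read sequence is aligned against every mature reference;
#' a read matching several matures is assigned to the one with the
#' smallest absolute 5' offset (ties broken lexicographically by
#' reference name) and flagged ambiguous. Unplaceable reads go to the
#' reject table, not an error.
#'
#' @param reads data.frame with columns `sequence`, `count`.
#' @param refs data.frame of mature references ([mature_refs()]).
#' @param hairpin_context Context string ([locus_context()]).
#' @param context_offset Flank bases before hairpin position 0.
#' @param ... Passed to [align_read()].
#' @return List with `catalog` (one row per read sequence: ref, offsets,
#'   tail, templated, seed, category, ambiguous) and `rejects`.
#' @export
build_catalog <- function(reads, refs, hairpin_context, context_offset = 10L,
                          ...) {
  stopifnot(is.data.frame(reads), all(c("sequence", "count") %in% names(reads)))
  reads$sequence <- normalize_rna(reads$sequence)
  if (anyDuplicated(reads$sequence)) {
    reads <- stats::aggregate(count ~ sequence, data = reads, sum)
  }
  refs <- refs[order(refs$name), , drop = FALSE]
  rows <- vector("list", nrow(reads))
  rej <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    best <- NULL; best_ref <- NULL; n_hit <- 0L
    for (j in seq_len(nrow(refs))) {
      al <- align_read(reads$sequence[i], refs[j, ], hairpin_context,
                       context_offset = context_offset, ...)
      if (is.null(al)) next
      n_hit <- n_hit + 1L
      if (is.null(best) ||
          abs(al$five_prime_offset) < abs(best$five_prime_offset)) {
        best <- al; best_ref <- refs$name[j]
      }
    }
    if (is.null(best)) { rej[i] <- TRUE; next }
    cl <- classify_isomir(best)
    rows[[i]] <- data.frame(
      sequence = reads$sequence[i], count = reads$count[i], ref = best_ref,
      five_prime_offset = best$five_prime_offset,
      three_prime_offset = best$three_prime_offset,
      nontemplated_tail = best$nontemplated_tail,
      templated = cl$templated, seed = extract_seed(reads$sequence[i]),
      category = cl$category, ambiguous = n_hit > 1L,
      stringsAsFactors = FALSE
    )
  }
  catalog <- do.call(rbind, rows[!rej])
  if (is.null(catalog)) {
    catalog <- data.frame(sequence = character(0), count = integer(0),
                          ref = character(0), five_prime_offset = integer(0),
                          three_prime_offset = integer(0),
                          nontemplated_tail = character(0),
                          templated = logical(0), seed = character(0),
                          category = character(0), ambiguous = logical(0),
                          stringsAsFactors = FALSE)
  }
  catalog <- catalog[order(-catalog$count, catalog$sequence), , drop = FALSE]
  rownames(catalog) <- NULL
  list(catalog = catalog,
       rejects = reads[rej, , drop = FALSE])
}

#' Call 5' isomiRs with strict thresholds
#'
#' A 5' isomiR call passes iff (i) its 5' end differs from the annotation
#' by at least one nucleotide, (ii) its read count is strictly greater
#' than `min_reads`, and (iii) its fraction of the miRNA's reads is
#' strictly greater than `min_fraction`. A record with count exactly
#' `min_reads` or fraction exactly `min_fraction` never passes.
#'
#' @param catalog Catalog data.frame from [build_catalog()].
#' @param min_reads Read-count threshold (default 100; strict `>`).
#' @param min_fraction Fraction threshold (default 0.05; strict `>`).
#' @param fraction_denominator `"arm_total"` (all reads assigned to the
#'   mature arm, default) or `"canonical_only"` (reads exactly matching
#'   the annotated mature).
#' @return data.frame with one row per catalog record: `mirna`,
#'   `sequence`, `count`, `fraction`, `offset`, `passes`.
#' @export
call_5p_isomirs <- function(catalog, min_reads = 100, min_fraction = 0.05,
                            fraction_denominator = c("arm_total",
                                                     "canonical_only")) {
  fraction_denominator <- match.arg(fraction_denominator)
  if (nrow(catalog) == 0) {
    return(data.frame(mirna = character(0), sequence = character(0),
                      count = integer(0), fraction = numeric(0),
                      offset = integer(0), passes = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(catalog, catalog$ref), function(cc) {
    denom <- if (fraction_denominator == "arm_total") {
      sum(cc$count)
    } else {
      sum(cc$count[cc$category == "canonical"])
    }
    frac <- if (denom > 0) cc$count / denom else rep(NA_real_, nrow(cc))
    data.frame(mirna = cc$ref, sequence = cc$sequence, count = cc$count,
               fraction = frac, offset = cc$five_prime_offset,
               passes = abs(cc$five_prime_offset) >= 1 &
                 cc$count > min_reads &
                 !is.na(frac) & frac > min_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$mirna, -out$count, out$sequence), , drop = FALSE]
}

#' Group the records of one miRNA by seed heptamer
#'
#' One group per distinct seed, sorted by descending total read count;
#' the representative is the most abundant member sequence and fractions
#' are of all reads for the miRNA. Suffix names ".1", ".2", ... follow
#' descending abundance unless an override map (seed -> suffix) is
#' supplied to reproduce published naming.
#'
#' @param records Catalog data.frame rows for one miRNA.
#' @param name_override Optional named character vector, seed -> suffix.
#' @return data.frame with `seed`, `total_count`, `fraction_of_mirna`,
#'   `representative`, `suffix_name`, `n_members`.
#' @export
group_by_seed <- function(records, name_override = NULL) {
  if (is.null(records) || nrow(records) == 0) {
    return(data.frame(seed = character(0), total_count = integer(0),
                      fraction_of_mirna = numeric(0),
                      representative = character(0),
                      suffix_name = character(0), n_members = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (length(unique(records$ref)) > 1) {
    stop("group_by_seed expects records for a single miRNA")
  }
  total <- sum(records$count)
  gl <- split(records, records$seed)
  out <- do.call(rbind, lapply(gl, function(g) {
    rep_seq <- g$sequence[order(-g$count, g$sequence)][1]
    data.frame(seed = g$seed[1], total_count = sum(g$count),
               fraction_of_mirna = sum(g$count) / total,
               representative = rep_seq, n_members = nrow(g),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$total_count, out$seed), , drop = FALSE]
  out$suffix_name <- if (!is.null(name_override)) {
    unname(name_override[out$seed])
  } else {
    paste0(".", seq_len(nrow(out)))
  }
  rownames(out) <- NULL
  out[, c("seed", "total_count", "fraction_of_mirna", "representative",
          "suffix_name", "n_members")]
}

#' Nontemplated tail nucleotide composition
#'
#' Counts of A/C/G/U over all nontemplated tail positions, weighted by
#' read count.
#'
#' @param records Catalog data.frame (any subset).
#' @return Named numeric vector with entries A, C, G, U.
#' @export
tail_composition <- function(records) {
  out <- c(A = 0, C = 0, G = 0, U = 0)
  if (is.null(records) || nrow(records) == 0) return(out)
  tails <- records$nontemplated_tail
  has <- nchar(tails) > 0
  if (!any(has)) return(out)
  chars <- strsplit(tails[has], "")
  for (i in seq_along(chars)) {
    tb <- table(chars[[i]]) * records$count[has][i]
    out[names(tb)] <- out[names(tb)] + tb
  }
  out
}
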