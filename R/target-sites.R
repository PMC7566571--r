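#' Canonical seed-match target sites
#'
#' Derives the four canonical site motifs (6mer, 7mer-A1, 7mer-m8, 8mer)
#' from a mature miRNA sequence, scans 3'UTRs for them, and builds
#' predicted target sets with the strongest-site-per-anchor convention
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer). The position-1 adenosine is a
#' literal A in the mRNA, not a complement of the miRNA's first base.
#'
#' @name target_sites
NULL

site_type_rank <- function(site_type) {
  match(site_type, SITE_TYPES)  # 6mer < 7mer-A1 < 7mer-m8 < 8mer
}

#' Site motifs of a mature miRNA
#'
#' The 6mer is the reverse complement of miRNA positions 2-7; the 7mer-m8
#' of positions 2-8; 7mer-A1 appends an A to the 6mer and the 8mer
#' appends an A to the 7mer-m8. All motifs are written 5'->3' in the
#' mRNA sense.
#'
#' @param mature Mature miRNA sequence (>= 8 nt, DNA or RNA).
#' @param isomir Optional identifier carried along in output.
#' @return A `SiteMotifSet`: list with `isomir`, `six_mer`, `seven_a1`,
#'   `seven_m8`, `eight_mer`.
#' @examples
#' site_motifs("ACCACAGGGUAGAACCACGGAC")$six_mer    # "CUGUGG"
#' site_motifs("UACCACAGGGUAGAACCACGGA")$eight_mer  # "CUGUGGUA"
#' @export
site_motifs <- function(mature, isomir = NA_character_) {
  m <- normalize_rna(mature)
  if (nchar(m) < 8) stop("mature sequence must be >= 8 nt")
  six <- rc_rna(substr(m, 2, 7))
  m8 <- rc_rna(substr(m, 2, 8))
  out <- list(isomir = isomir, six_mer = six, seven_a1 = paste0(six, "A"),
              seven_m8 = m8, eight_mer = paste0(m8, "A"))
  class(out) <- c("SiteMotifSet", "list")
  out
}

#' Scan one 3'UTR for seed-match sites
#'
#' Finds every occurrence of the 6mer core (overlaps allowed) and
#' promotes each anchor to the strongest matching type: a match to the
#' m8 position immediately 5' of the core and/or a literal A immediately
#' 3' of it.
#'
#' @param utr UTR sequence (DNA or RNA).
#' @param motifs A `SiteMotifSet`.
#' @return data.frame with `position` (0-based offset of the 6mer core)
#'   and `site_type`, in ascending position; zero rows when nothing
#'   matches.
#' @export
scan_utr <- function(utr, motifs) {
  stopifnot(inherits(motifs, "SiteMotifSet"))
  empty <- data.frame(position = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(utr) == 0) return(empty)
  u <- normalize_rna(utr)
  pos0 <- find_all_0based(u, motifs$six_mer)
  if (length(pos0) == 0) return(empty)
  m8_char <- substr(motifs$seven_m8, 1, 1)
  has_m8 <- pos0 >= 1 & substring(u, pos0, pos0) == m8_char
  has_a1 <- substring(u, pos0 + 7, pos0 + 7) == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", "6mer")))
  data.frame(position = pos0, site_type = type, stringsAsFactors = FALSE)
}

#' Site-hit table over a UTRome
#'
#' @param utrome Named character vector, gene -> UTR sequence.
#' @param motifs A `SiteMotifSet`.
#' @return data.frame with `gene`, `position`, `site_type`.
#' @export
site_table <- function(utrome, motifs) {
  if (anyDuplicated(names(utrome))) stop("duplicate gene identifiers in utrome")
  hits <- lapply(names(utrome), function(g) {
    h <- scan_utr(utrome[[g]], motifs)
    if (nrow(h) == 0) return(NULL)
    cbind(gene = g, h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), position = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Strongest site per gene
#'
#' @param hits Site-hit table from [site_table()].
#' @return data.frame with `gene`, `strongest_site`.
#' @export
strongest_site <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(gene = character(0), strongest_site = character(0),
                      stringsAsFactors = FALSE))
  }
  best <- vapply(split(hits$site_type, hits$gene),
                 function(tt) SITE_TYPES[max(site_type_rank(tt))],
                 character(1))
  data.frame(gene = names(best), strongest_site = unname(best),
             stringsAsFactors = FALSE)
}

#' Predict the target set of one isomiR over a UTRome
#'
#' A gene is a predicted target when it carries at least one site at or
#' above `min_site_type` stringency.
#'
#' @param utrome Named character vector, gene -> UTR.
#' @param motifs A `SiteMotifSet`.
#' @param min_site_type Weakest qualifying site class (default
#'   `"7mer-A1"`).
#' @return A `TargetSet`: list with `isomir`, `genes` (character vector),
#'   `min_site_type`.
#' @export
predict_targets <- function(utrome, motifs, min_site_type = "7mer-A1") {
  if (!min_site_type %in% SITE_TYPES) {
    stop("min_site_type must be one of: ", paste(SITE_TYPES, collapse = ", "))
  }
  hits <- site_table(utrome, motifs)
  keep <- hits[site_type_rank(hits$site_type) >=
                 site_type_rank(min_site_type), , drop = FALSE]
  out <- list(isomir = motifs$isomir,
              genes = sort(unique(keep$gene)),
              min_site_type = min_site_type)
  class(out) <- c("TargetSet", "list")
  out
}

#' Unique targets of one isomiR after excluding others' targets
#'
#' Implements the unique-target logic used when comparing isomiR target
#' repertoires: the focal target set minus the union of the excluded
#' isomiRs' target sets.
#'
#' @param sets Named list mapping isomiR id to `TargetSet` or character
#'   vector of genes.
#' @param focal Name of the focal isomiR in `sets`.
#' @param exclude Character vector of names in `sets` to subtract.
#' @return Character vector of unique target genes (sorted).
#' @export
unique_targets <- function(sets, focal, exclude = character(0)) {
  get_genes <- function(x) if (inherits(x, "TargetSet")) x$genes else x
  missing_keys <- setdiff(c(focal, exclude), names(sets))
  if (length(missing_keys) > 0) {
    stop("unknown target-set identifier(s): ",
         paste(missing_keys, collapse = ", "))
  }
  excl <- unique(unlist(lapply(sets[exclude], get_genes)))
  sort(setdiff(get_genes(sets[[focal]]), excl))
}

#' Read an externally produced target list
#'
#' One gene identifier per line (single-column TSV, optional header
#' `gene`), for importing e.g. conserved-target lists produced elsewhere.
#'
#' @param path File path.
#' @return Character vector of gene identifiers.
#' @export
read_target_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nchar(x) > 0]
  if (length(x) > 0 && tolower(x[1]) == "gene") x <- x[-1]
  unique(x)
}
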