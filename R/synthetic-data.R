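#' Synthetic miRNA locus, read pools, UTRomes, DE tables and compendia
#'
#' Every downstream stage of the pipeline (isomiR cataloguing, target-site
#' scanning, ranked enrichment, host-gene surrogate regression) can be run
#' on data from these generators, each of which emits a ground-truth
#' manifest alongside its output. All generators are deterministic for a
#' fixed seed.
#'
#' @name synthetic_data
NULL

SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Generate a synthetic miRNA hairpin locus
#'
#' Builds a random hairpin with one 5p and one 3p mature annotation plus
#' genomic flanks, emulating an intronic miRNA stem-loop. The eight bases
#' immediately downstream of each mature 3' end are drawn from C/G/U only,
#' so that a nontemplated adenine tail is never confusable with templated
#' 3' extension. The second base of each mature is drawn from A/C/G so
#' that the annotated and -1-shifted seed registers give distinct site
#' motifs (were it U, every 8mer site of the shifted species would
#' contain the annotated species' 7mer-m8 site), matching the situation
#' of interest where the two isomiRs have largely different target
#' repertoires.
#'
#' @param rng_seed Integer seed.
#' @param hairpin_length Hairpin length in nt; must be at least
#'   `2 * mature_length + 10` so both arms fit with a loop between them.
#' @param mature_length Mature miRNA length in nt (default 22).
#' @param flank_length Genomic flank on each side, nt (default 10, min 10).
#' @return A `LocusSpec`: list with `hairpin_name`, `hairpin_seq`,
#'   `flank5`, `flank3`, and `mature_annotations` (data.frame with
#'   `name`, `arm`, `start` (0-based, into hairpin), `length`).
#' @export
gen_locus <- function(rng_seed, hairpin_length = 110L, mature_length = 22L,
                      flank_length = 10L) {
  hairpin_length <- as.integer(hairpin_length)
  mature_length <- as.integer(mature_length)
  if (hairpin_length < 2L * mature_length + 10L) {
    stop("hairpin_length must be >= 2*mature_length + 10 (got ",
         hairpin_length, " for mature_length ", mature_length, ")")
  }
  if (flank_length < 10L) stop("flank_length must be >= 10 nt")
  set.seed(as.integer(rng_seed))
  hp <- strsplit(random_rna(hairpin_length), "")[[1]]
  start5 <- 3L
  start3 <- hairpin_length - mature_length - 3L
  flank5 <- random_rna(flank_length)
  flank3_chars <- strsplit(random_rna(flank_length), "")[[1]]
  # position 2 of each mature: non-U, so shifted and annotated seed
  # registers yield distinct site motifs
  for (p2 in c(start5 + 1L, start3 + 1L)) {
    if (hp[p2 + 1L] == "U") hp[p2 + 1L] <- sample(c("A", "C", "G"), 1L)
  }
  # non-A zone downstream of each mature 3' end (tail-vs-template disambiguation)
  noA <- c("C", "G", "U")
  for (end0 in c(start5 + mature_length, start3 + mature_length)) {
    for (j in end0:(end0 + 7L)) {
      if (j < hairpin_length) {
        if (hp[j + 1L] == "A") hp[j + 1L] <- sample(noA, 1L)
      } else {
        k <- j - hairpin_length
        if (k < flank_length && flank3_chars[k + 1L] == "A") {
          flank3_chars[k + 1L] <- sample(noA, 1L)
        }
      }
    }
  }
  hairpin_seq <- paste(hp, collapse = "")
  name <- "syn-mir-1"
  locus <- list(
    hairpin_name = name,
    hairpin_seq = hairpin_seq,
    flank5 = flank5,
    flank3 = paste(flank3_chars, collapse = ""),
    mature_annotations = data.frame(
      name = paste0(sub("mir", "miR", name), c("-5p", "-3p")),
      arm = c("5p", "3p"),
      start = c(start5, start3),
      length = mature_length,
      stringsAsFactors = FALSE
    ),
    rng_seed = as.integer(rng_seed)
  )
  class(locus) <- c("LocusSpec", "list")
  validate_locus(locus)
}

#' @export
print.LocusSpec <- function(x, ...) {
  cat("LocusSpec:", x$hairpin_name, "(", nchar(x$hairpin_seq), "nt hairpin,",
      nchar(x$flank5), "/", nchar(x$flank3), "nt flanks )\n")
  print(x$mature_annotations)
  invisible(x)
}

validate_locus <- function(locus) {
  ann <- locus$mature_annotations
  stopifnot(is.data.frame(ann), nrow(ann) >= 1)
  normalize_rna(c(locus$hairpin_seq, locus$flank5, locus$flank3))
  hl <- nchar(locus$hairpin_seq)
  if (any(ann$start < 0) || any(ann$start + ann$length > hl)) {
    stop("mature annotation escapes the hairpin")
  }
  o <- order(ann$start)
  if (nrow(ann) > 1 &&
      any(ann$start[o][-1] < (ann$start + ann$length)[o][-nrow(ann)])) {
    stop("mature arms overlap")
  }
  if (nchar(locus$flank5) < 10 || nchar(locus$flank3) < 10) {
    stop("flanks must be >= 10 nt")
  }
  locus
}

#' Templated context of a locus (flank5 + hairpin + flank3)
#' @param locus A `LocusSpec`.
#' @return Single RNA string.
#' @export
locus_context <- function(locus) {
  paste0(locus$flank5, locus$hairpin_seq, locus$flank3)
}

#' Mature reference table for a locus
#'
#' One row per annotated mature miRNA, in the form the cataloguing stage
#' consumes: name, sequence, hairpin name, 0-based start within the
#' hairpin, and arm.
#'
#' @param locus A `LocusSpec`.
#' @return data.frame of mature references.
#' @export
mature_refs <- function(locus) {
  ann <- locus$mature_annotations
  seqs <- substring(locus$hairpin_seq, ann$start + 1L, ann$start + ann$length)
  data.frame(name = ann$name, sequence = seqs,
             hairpin_name = locus$hairpin_name,
             start = ann$start, arm = ann$arm, stringsAsFactors = FALSE)
}

#' Construct a read-composition specification
#'
#' Describes the isomiR mixture a synthetic read pool should contain:
#' one entry per isomiR species with its 5' offset (positive = extended
#' upstream, negative = trimmed; the mature 5' start minus the read 5'
#' start), templated 3' offset, nontemplated 3' tail and mixture weight,
#' plus the overall depth and the probability that any read gains one
#' extra nontemplated adenine.
#'
#' @param entries data.frame with columns `five_prime_offset`,
#'   `three_prime_templated`, `nontemplated_tail`, `weight`.
#' @param total_depth Total read count (> 0).
#' @param tail_A_rate Probability in \[0,1\] of one extra nontemplated A.
#' @return A `ReadCompositionSpec`.
#' @export
read_composition_spec <- function(entries, total_depth, tail_A_rate = 0) {
  stopifnot(is.data.frame(entries))
  need <- c("five_prime_offset", "three_prime_templated",
            "nontemplated_tail", "weight")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns: ", paste(need, collapse = ", "))
  }
  if (abs(sum(entries$weight) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(entries$weight < 0)) stop("weights must be non-negative")
  if (total_depth <= 0) stop("total_depth must be > 0")
  if (tail_A_rate < 0 || tail_A_rate > 1) stop("tail_A_rate must be in [0,1]")
  entries$nontemplated_tail <- ifelse(
    nchar(entries$nontemplated_tail) > 0,
    normalize_rna(entries$nontemplated_tail), "")
  spec <- list(entries = entries, total_depth = as.integer(total_depth),
               tail_A_rate = tail_A_rate)
  class(spec) <- c("ReadCompositionSpec", "list")
  spec
}

#' Default cartilage-like isomiR composition
#'
#' A mixture emulating the read structure reported for an abundant 3p
#' miRNA in cartilage small-RNA data: only ~5% of reads exactly match the
#' annotation, reads split roughly evenly between the annotated seed and
#' a seed shifted by -1 nt, most reads carry templated 3' extension
#' and/or a nontemplated adenine tail, and about 25% are fully templated
#' once the extra-adenylation rate is applied.
#'
#' @param total_depth Total read count (default 1e5).
#' @param tail_A_rate Extra-adenylation probability (default 0.3).
#' @return A `ReadCompositionSpec`.
#' @export
default_composition <- function(total_depth = 1e5, tail_A_rate = 0.3) {
  entries <- data.frame(
    five_prime_offset     = c( 0L,  0L,  0L,  0L, -1L, -1L, -1L, -1L),
    three_prime_templated = c( 0L,  1L,  0L,  1L,  0L,  1L,  0L,  1L),
    nontemplated_tail     = c("",  "A", "A", "",  "A", "A", "",  ""),
    weight                = c(0.05, 0.18, 0.12, 0.10, 0.20, 0.10, 0.13, 0.12),
    stringsAsFactors = FALSE
  )
  read_composition_spec(entries, total_depth, tail_A_rate)
}

# Category from true offsets/tail; definitional, shared with the catalog module.
isomir_category <- function(five_prime_offset, three_prime_offset,
                            nontemplated_tail) {
  five_mod <- five_prime_offset != 0L
  three_mod <- three_prime_offset != 0L | nchar(nontemplated_tail) > 0L
  ifelse(!five_mod & !three_mod, "canonical",
  ifelse(five_mod & !three_mod, "5prime_only",
  ifelse(!five_mod & three_mod, "3prime_only", "mixed")))
}

#' Generate a synthetic small-RNA read pool with ground truth
#'
#' Draws multinomial read counts over the isomiR species in `spec`,
#' constructs each read from the templated locus context plus its
#' nontemplated tail, and applies the extra-adenylation rate. The truth
#' manifest records, for every emitted distinct sequence, its true
#' offsets, tail, templated status and category.
#'
#' A nontemplated tail whose first base equals the next templated base
#' downstream of the read would be indistinguishable from templated
#' extension; such compositions are rejected with an error.
#'
#' @param locus A `LocusSpec`.
#' @param spec A `ReadCompositionSpec`.
#' @param rng_seed Integer seed.
#' @param mature Name or arm ("5p"/"3p") of the mature reference the
#'   composition is relative to (default "3p").
#' @return List with `reads` (data.frame sequence, count), `truth`
#'   (per-sequence manifest) and `rng_seed`.
#' @export
gen_read_pool <- function(locus, spec, rng_seed, mature = "3p") {
  stopifnot(inherits(locus, "LocusSpec"), inherits(spec, "ReadCompositionSpec"))
  refs <- mature_refs(locus)
  ref <- refs[refs$name == mature | refs$arm == mature, , drop = FALSE]
  if (nrow(ref) != 1) stop("mature '", mature, "' not found in locus")
  ctx <- locus_context(locus)
  off <- nchar(locus$flank5)                       # hairpin 0 in context coords
  m_start <- ref$start + off                      # 0-based in context
  m_end <- m_start + nchar(ref$sequence)          # exclusive

  e <- spec$entries
  core_start <- m_start - e$five_prime_offset
  core_end <- m_end + e$three_prime_templated
  if (any(core_start < 0) || any(core_end > nchar(ctx)) ||
      any(core_end <= core_start)) {
    stop("isomiR offset escapes the templated context")
  }
  cores <- substring(ctx, core_start + 1L, core_end)
  next_base <- substring(ctx, core_end + 1L, core_end + 1L)
  amb <- nchar(e$nontemplated_tail) > 0 &
    substr(e$nontemplated_tail, 1, 1) == next_base
  if (any(amb)) {
    stop("nontemplated tail matches the next templated base for entry ",
         which(amb)[1], "; tail would be indistinguishable from templated extension")
  }
  if (spec$tail_A_rate > 0 && any(e$nontemplated_tail == "" & next_base == "A")) {
    stop("extra-A tailing is ambiguous: templated base after read end is A")
  }

  set.seed(as.integer(rng_seed))
  counts <- as.integer(stats::rmultinom(1, spec$total_depth, e$weight))
  n_extra <- stats::rbinom(nrow(e), counts, spec$tail_A_rate)

  rows <- list()
  for (i in seq_len(nrow(e))) {
    for (extra in c(FALSE, TRUE)) {
      cnt <- if (extra) n_extra[i] else counts[i] - n_extra[i]
      if (cnt == 0) next
      tail_i <- paste0(e$nontemplated_tail[i], if (extra) "A" else "")
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = paste0(cores[i], tail_i),
        count = cnt,
        ref = ref$name,
        five_prime_offset = e$five_prime_offset[i],
        three_prime_offset = e$three_prime_templated[i],
        nontemplated_tail = tail_i,
        templated = nchar(tail_i) == 0L,
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, rows)
  # merge rows that are the same species; conflicting truths for one
  # sequence would make the manifest ill-defined
  key <- paste(truth$sequence, truth$five_prime_offset,
               truth$three_prime_offset, truth$nontemplated_tail)
  agg <- stats::aggregate(count ~ key, data = cbind(truth, key = key), sum)
  truth <- truth[!duplicated(key), ]
  truth$count <- agg$count[match(paste(truth$sequence, truth$five_prime_offset,
                                       truth$three_prime_offset,
                                       truth$nontemplated_tail), agg$key)]
  if (anyDuplicated(truth$sequence)) {
    stop("composition yields one sequence with two distinct truths; ",
         "choose offsets that do not collide")
  }
  truth$category <- isomir_category(truth$five_prime_offset,
                                    truth$three_prime_offset,
                                    truth$nontemplated_tail)
  truth <- truth[order(-truth$count, truth$sequence), ]
  rownames(truth) <- NULL
  list(reads = truth[, c("sequence", "count")],
       truth = truth,
       rng_seed = as.integer(rng_seed))
}

#' Generate a synthetic 3'UTR set with planted seed-match sites
#'
#' Background sequence is uniform over A/C/G/U with rejection of any
#' accidental occurrence of the 6mer cores of the supplied motif sets, so
#' the planted-site truth table is exact. Planted sites are written at
#' the requested positions and guarded so that the site type observed by
#' a scanner is exactly the type planted (no accidental promotion of a
#' 6mer to a 7mer-A1, etc.). Core occurrences that overlap a planted
#' site span are permitted: isomiRs with overlapping seeds necessarily
#' share site sequence, so a site planted for one isomiR can contain
#' another's core.
#'
#' @param n_genes Number of UTRs to emit (gene ids `g1..gN`).
#' @param planting data.frame with columns `gene`, `isomir`, `site_type`
#'   (one of 6mer/7mer-A1/7mer-m8/8mer) and `utr_position` (0-based
#'   offset of the 6mer core), or NULL for no planting.
#' @param motif_sets Named list of `SiteMotifSet` objects (names are
#'   isomiR ids); required when planting, and all their 6mer cores are
#'   excluded from background sequence.
#' @param rng_seed Integer seed.
#' @param utr_length UTR length in nt (default 200).
#' @return List with `utrs` (named character vector) and `truth`
#'   (the planting table) and `rng_seed`.
#' @export
gen_utrome <- function(n_genes, planting = NULL, motif_sets = NULL,
                       rng_seed = 1L, utr_length = 200L) {
  n_genes <- as.integer(n_genes)
  utr_length <- as.integer(utr_length)
  if (n_genes == 0) {
    return(list(utrs = stats::setNames(character(0), character(0)),
                truth = planting_frame(NULL), rng_seed = as.integer(rng_seed)))
  }
  genes <- paste0("g", seq_len(n_genes))
  planting <- planting_frame(planting)
  if (nrow(planting) > 0) {
    if (is.null(motif_sets)) stop("motif_sets required when planting sites")
    if (!all(planting$isomir %in% names(motif_sets))) {
      stop("planting references isomiRs absent from motif_sets")
    }
    if (!all(planting$gene %in% genes)) {
      stop("planting references genes outside g1..g", n_genes)
    }
  }
  cores <- unique(vapply(motif_sets, function(m) m$six_mer, character(1)))

  set.seed(as.integer(rng_seed))
  utrs <- stats::setNames(character(n_genes), genes)
  for (g in genes) {
    plant_g <- planting[planting$gene == g, , drop = FALSE]
    utrs[[g]] <- build_planted_utr(utr_length, plant_g, motif_sets, cores)
  }
  list(utrs = utrs, truth = planting, rng_seed = as.integer(rng_seed))
}

planting_frame <- function(planting) {
  if (is.null(planting)) {
    return(data.frame(gene = character(0), isomir = character(0),
                      site_type = character(0), utr_position = integer(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(planting))
  need <- c("gene", "isomir", "site_type", "utr_position")
  if (!all(need %in% names(planting))) {
    stop("planting must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(planting$site_type %in% SITE_TYPES)) {
    stop("site_type must be one of: ", paste(SITE_TYPES, collapse = ", "))
  }
  planting
}

# Site string and its 0-based span relative to the 6mer-core anchor.
site_string <- function(motifs, site_type) {
  switch(site_type,
         "6mer"    = list(seq = motifs$six_mer,   lead = 0L),
         "7mer-A1" = list(seq = motifs$seven_a1,  lead = 0L),
         "7mer-m8" = list(seq = motifs$seven_m8,  lead = 1L),
         "8mer"    = list(seq = motifs$eight_mer, lead = 1L),
         stop("unknown site_type: ", site_type))
}

build_planted_utr <- function(utr_length, plant_g, motif_sets, cores,
                              max_tries = 1000L) {
  # precompute planted spans and guard requirements
  spans <- lapply(seq_len(nrow(plant_g)), function(i) {
    m <- motif_sets[[plant_g$isomir[i]]]
    s <- site_string(m, plant_g$site_type[i])
    p <- as.integer(plant_g$utr_position[i])
    from <- p - s$lead
    to <- from + nchar(s$seq)            # exclusive, 0-based
    if (from < 0 || to > utr_length) {
      stop("planted ", plant_g$site_type[i], " at position ", p,
           " does not fit in a ", utr_length, " nt UTR")
    }
    has_m8 <- plant_g$site_type[i] %in% c("7mer-m8", "8mer")
    has_a1 <- plant_g$site_type[i] %in% c("7mer-A1", "8mer")
    list(seq = s$seq, from = from, to = to, core0 = p,
         m8_char = substr(m$seven_m8, 1, 1),
         guard_left = if (!has_m8) from - 1L else NA_integer_,
         guard_right = if (!has_a1) p + 6L else NA_integer_)
  })
  if (length(spans) > 1) {
    iv <- do.call(rbind, lapply(spans, function(s) c(s$from, s$to)))
    o <- order(iv[, 1])
    if (any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)])) {
      stop("planted sites overlap within one UTR")
    }
  }
  core_positions <- unlist(lapply(spans, function(s) s$core0))

  for (try in seq_len(max_tries)) {
    chars <- sample(c("A", "C", "G", "U"), utr_length, replace = TRUE)
    for (s in spans) {
      chars[(s$from + 1L):s$to] <- strsplit(s$seq, "")[[1]]
      if (!is.na(s$guard_left) && s$guard_left >= 0 &&
          chars[s$guard_left + 1L] == s$m8_char) {
        chars[s$guard_left + 1L] <- sample(setdiff(c("A", "C", "G", "U"),
                                                   s$m8_char), 1L)
      }
      if (!is.na(s$guard_right) && s$guard_right < utr_length &&
          chars[s$guard_right + 1L] == "A") {
        chars[s$guard_right + 1L] <- sample(c("C", "G", "U"), 1L)
      }
    }
    utr <- paste(chars, collapse = "")
    # background must be core-free; occurrences overlapping a planted
    # span are legitimate (overlapping seeds share site sequence)
    hit0 <- unlist(lapply(cores, function(w) find_all_0based(utr, w)))
    in_span <- vapply(hit0, function(p) {
      any(vapply(spans, function(s) p < s$to && (p + 6L) > s$from,
                 logical(1)))
    }, logical(1))
    anchored <- all(core_positions %in% hit0)
    if (all(in_span) && anchored) return(utr)
  }
  stop("could not build a seed-free background UTR in ", max_tries, " tries")
}

#' Generate a synthetic differential-expression table
#'
#' Non-target genes get log2 fold changes from Normal(0, noise_sd^2);
#' planted targets from Normal(-effect_delta, noise_sd^2). Adjusted
#' P-values come from two-sided z-tests (known sd) with
#' Benjamini-Hochberg correction. With noise_sd = 0 the table is exact
#' (targets at -effect_delta, others at 0) and P is 0 for any nonzero
#' change.
#'
#' @param truth_targets Character vector of target gene ids; must be a
#'   subset of the gene universe.
#' @param effect_delta Planted repression in log2 units (targets shift
#'   down by this amount).
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param n_genes Size of the gene universe (ids `g1..gN`) when
#'   `gene_universe` is not given.
#' @param rng_seed Integer seed.
#' @param gene_universe Optional explicit gene id vector.
#' @return data.frame with columns `gene`, `log2fc`, `adj_p`.
#' @export
gen_de_table <- function(truth_targets, effect_delta, noise_sd, n_genes,
                         rng_seed, gene_universe = NULL) {
  if (!is.finite(effect_delta)) stop("effect_delta must be finite")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  genes <- if (is.null(gene_universe)) paste0("g", seq_len(n_genes)) else gene_universe
  if (!all(truth_targets %in% genes)) {
    stop("truth_targets contains genes outside the universe")
  }
  set.seed(as.integer(rng_seed))
  is_target <- genes %in% truth_targets
  fc <- stats::rnorm(length(genes), mean = ifelse(is_target, -effect_delta, 0),
                     sd = noise_sd)
  de_table(genes, fc, noise_sd)
}

# Assemble a DE table: BH-adjusted two-sided z-test P at known sd.
de_table <- function(genes, fc, sd) {
  p <- if (sd > 0) 2 * stats::pnorm(-abs(fc / sd)) else as.numeric(fc == 0)
  data.frame(gene = genes, log2fc = fc,
             adj_p = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Construct a compendium specification
#'
#' Parameters of a multi-study synthetic compendium in which the mean
#' log2 fold change of a fixed target set is linearly coupled to the
#' fold change of a designated host gene.
#'
#' @param n_studies Number of studies (>= 2).
#' @param host_gene Host gene identifier.
#' @param coupling_beta Planted slope of mean target log2FC per unit
#'   host-gene log2FC (negative for repression coupling).
#' @param noise_sd Study-level sd of the mean target shift around the
#'   coupled value (>= 0).
#' @param n_genes Genes per study table.
#' @param target_fraction Fraction of genes designated targets (0,1).
#' @param rng_seed Integer seed.
#' @param host_fc_range Host log2FC drawn uniformly over
#'   \[-host_fc_range, host_fc_range\] (default 2).
#' @param gene_noise_sd Within-study per-gene sd (default 0.3); the
#'   gene-level noise is mean-centred within the target set so the
#'   realized mean target shift is exactly the coupled value plus the
#'   study-level noise.
#' @return A `CompendiumSpec`.
#' @export
compendium_spec <- function(n_studies, host_gene, coupling_beta, noise_sd,
                            n_genes, target_fraction, rng_seed,
                            host_fc_range = 2, gene_noise_sd = 0.3) {
  if (n_studies < 2) stop("n_studies must be >= 2")
  if (target_fraction <= 0 || target_fraction >= 1) {
    stop("target_fraction must be in (0,1)")
  }
  if (noise_sd < 0 || gene_noise_sd < 0) stop("noise sds must be >= 0")
  spec <- list(n_studies = as.integer(n_studies), host_gene = host_gene,
               coupling_beta = coupling_beta, noise_sd = noise_sd,
               n_genes = as.integer(n_genes),
               target_fraction = target_fraction,
               rng_seed = as.integer(rng_seed),
               host_fc_range = host_fc_range, gene_noise_sd = gene_noise_sd)
  class(spec) <- c("CompendiumSpec", "list")
  spec
}

#' Generate a synthetic multi-study compendium
#'
#' Each study is a DE table over a shared gene universe containing the
#' host gene and a fixed planted target set. Per study, the host log2FC
#' is drawn uniformly over a symmetric range and the target set is
#' shifted by `coupling_beta * host_fc` plus Normal(0, noise_sd) study
#' noise; per-gene noise is mean-centred within the targets so the
#' realized per-study mean target shift equals that value exactly.
#'
#' @param spec A `CompendiumSpec`.
#' @return List with `studies` (named list of DE tables), `targets`
#'   (planted target gene ids), `manifest` (per-study truth: host fold
#'   change and adjusted P, realized target shift) and `spec`.
#' @export
gen_compendium <- function(spec) {
  stopifnot(inherits(spec, "CompendiumSpec"))
  set.seed(spec$rng_seed)
  n_bg <- spec$n_genes - 1L
  genes <- c(paste0("g", seq_len(n_bg)), spec$host_gene)
  n_t <- max(1L, round(spec$target_fraction * spec$n_genes))
  targets <- sample(paste0("g", seq_len(n_bg)), n_t)
  host_fc <- stats::runif(spec$n_studies, -spec$host_fc_range, spec$host_fc_range)
  study_ids <- sprintf("study%03d", seq_len(spec$n_studies))

  is_target <- genes %in% targets
  is_host <- genes == spec$host_gene
  studies <- vector("list", spec$n_studies)
  delta <- numeric(spec$n_studies)
  for (s in seq_len(spec$n_studies)) {
    delta[s] <- spec$coupling_beta * host_fc[s] +
      stats::rnorm(1, 0, spec$noise_sd)
    fc <- stats::rnorm(length(genes), 0, spec$gene_noise_sd)
    e_t <- fc[is_target]
    fc[is_target] <- delta[s] + e_t - mean(e_t)
    fc[is_host] <- host_fc[s]
    studies[[s]] <- de_table(genes, fc, spec$gene_noise_sd)
  }
  names(studies) <- study_ids
  manifest <- data.frame(
    study_id = study_ids,
    host_log2fc = host_fc,
    host_adj_p = vapply(studies, function(d) d$adj_p[d$gene == spec$host_gene],
                        numeric(1)),
    true_target_shift = delta,
    stringsAsFactors = FALSE
  )
  rownames(manifest) <- NULL
  list(studies = studies, targets = targets, manifest = manifest, spec = spec)
}
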