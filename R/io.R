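#' File formats
#'
#' Plain-text readers and writers for the pipeline's interchange
#' formats: FASTA (via Biostrings), FASTQ read pools with dummy
#' qualities, two-column sequence/count TSVs, DE tables
#' (`gene log2fc adj_p`), and compendium directories with a JSON
#' manifest.
#'
#' @name io
NULL

#' Write a named set of RNA sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::RNAStringSet(normalize_rna(unname(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector (RNA alphabet)
#' @param path FASTA file; DNA input is converted to RNA.
#' @param first_word_only Truncate names at the first whitespace
#'   (miRBase-style headers carry descriptions; default TRUE).
#' @export
read_fasta <- function(path, first_word_only = TRUE) {
  x <- Biostrings::readBStringSet(path)
  out <- normalize_rna(as.character(x))
  nm <- names(x)
  if (first_word_only) nm <- sub("\\s.*$", "", nm)
  stats::setNames(out, nm)
}

#' Write a locus reference bundle
#'
#' Hairpin FASTA, mature FASTA, and a sidecar TSV with the mature
#' coordinates (`name`, `hairpin_name`, `start`; 0-based) plus flank
#' FASTA so templated context can be rebuilt.
#'
#' @param locus A `LocusSpec`.
#' @param dir Output directory (created if needed).
#' @return Invisible named vector of written paths.
#' @export
write_locus <- function(locus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refs <- mature_refs(locus)
  paths <- c(
    hairpin = file.path(dir, "hairpin.fa"),
    mature = file.path(dir, "mature.fa"),
    flanks = file.path(dir, "flanks.fa"),
    coords = file.path(dir, "mature_coords.tsv")
  )
  write_fasta(stats::setNames(locus$hairpin_seq, locus$hairpin_name),
              paths["hairpin"])
  write_fasta(stats::setNames(refs$sequence, refs$name), paths["mature"])
  write_fasta(c(flank5 = locus$flank5, flank3 = locus$flank3),
              paths["flanks"])
  utils::write.table(refs[, c("name", "hairpin_name", "start", "arm")],
                     paths["coords"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a locus reference bundle written by [write_locus()]
#' @param dir Directory containing the bundle.
#' @return A `LocusSpec`.
#' @export
read_locus <- function(dir) {
  hp <- read_fasta(file.path(dir, "hairpin.fa"))
  fl <- read_fasta(file.path(dir, "flanks.fa"))
  coords <- utils::read.delim(file.path(dir, "mature_coords.tsv"),
                              stringsAsFactors = FALSE)
  mature <- read_fasta(file.path(dir, "mature.fa"))
  locus <- list(
    hairpin_name = names(hp)[1], hairpin_seq = unname(hp[1]),
    flank5 = unname(fl["flank5"]), flank3 = unname(fl["flank3"]),
    mature_annotations = data.frame(
      name = coords$name, arm = coords$arm, start = coords$start,
      length = nchar(mature[coords$name]), stringsAsFactors = FALSE)
  )
  class(locus) <- c("LocusSpec", "list")
  validate_locus(locus)
}

#' Write a read pool as a two-column TSV (sequence, count)
#' @param reads data.frame with `sequence`, `count`.
#' @param path Output file.
#' @export
write_read_tsv <- function(reads, path) {
  utils::write.table(reads[, c("sequence", "count")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column read-count TSV
#' @param path File with header `sequence  count`.
#' @export
read_read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "integer"))
}

#' Write a read pool as FASTQ with dummy qualities
#'
#' Each distinct sequence is expanded to `count` records with quality
#' "I" at every base.
#'
#' @param reads data.frame with `sequence`, `count`.
#' @param path Output .fastq file.
#' @export
write_read_fastq <- function(reads, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  n <- 0L
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    q <- strrep("I", nchar(s))
    for (r in seq_len(reads$count[i])) {
      n <- n + 1L
      writeLines(c(sprintf("@read%07d", n), s, "+", q), con)
    }
  }
  invisible(path)
}

#' Read a FASTQ file, collapsing identical sequences to counts
#' @param path .fastq file.
#' @return data.frame with `sequence`, `count`.
#' @export
read_read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("malformed FASTQ: ", path)
  seqs <- lines[seq(2, length(lines), by = 4)]
  tb <- table(seqs)
  data.frame(sequence = names(tb), count = as.integer(tb),
             stringsAsFactors = FALSE)
}

#' Write / read a DE table TSV (`gene  log2fc  adj_p`)
#' @param table DE data.frame.
#' @param path File path.
#' @export
write_de_table <- function(table, path) {
  validate_de_table(table)
  utils::write.table(table[, c("gene", "log2fc", "adj_p")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_de_table(t)
  t
}

#' Write a compendium as a directory of DE TSVs plus JSON manifest
#' @param compendium Output of [gen_compendium()].
#' @param dir Output directory.
#' @export
write_compendium <- function(compendium, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- stats::setNames(paste0(names(compendium$studies), ".tsv"),
                           names(compendium$studies))
  for (id in names(compendium$studies)) {
    write_de_table(compendium$studies[[id]], file.path(dir, files[[id]]))
  }
  manifest <- list(
    host_gene = compendium$spec$host_gene,
    rng_seed = compendium$spec$rng_seed,
    studies = as.list(files),
    targets = compendium$targets,
    truth = compendium$manifest
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(dir)
}

#' Read a compendium directory written by [write_compendium()]
#' @param dir Directory with DE TSVs and `manifest.json`.
#' @return List with `studies`, `host_gene`, `targets`, `manifest`.
#' @export
read_compendium <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  studies <- lapply(manifest$studies,
                    function(f) read_de_table(file.path(dir, f)))
  list(studies = studies, host_gene = manifest$host_gene,
       targets = manifest$targets, manifest = manifest$truth)
}
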