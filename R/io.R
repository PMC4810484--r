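# Flat-file interfaces: FASTA via Biostrings, GFF3 import via rtracklayer
# (with a small deterministic writer of our own so that seeded runs are
# byte-identical), coordinate convention 0-based half-open internally,
# converted from GFF3's 1-based inclusive at the boundary.

#' Read a protein FASTA file
#'
#' Wrapped and unwrapped dialects are accepted; duplicate ids are rejected.
#' An empty file yields an empty set with a warning.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    smx_stop("steromine_input_error", "no such file: %s", path)
  if (file.size(path) == 0) {
    warning(sprintf("empty FASTA file: %s", path))
    return(setNames(character(0), character(0)))
  }
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e)
                    smx_stop("steromine_input_error",
                             "cannot parse FASTA %s: %s", path,
                             conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    smx_stop("steromine_input_error", "duplicate FASTA id: %s", dup[1])
  setNames(as.character(set), ids)
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (length(seqs)) check_proteome(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, max(1, nchar(s)), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write a gene annotation table as GFF3
#'
#' One `gene` feature per row with `ID`, `replicon_type` and `Is_circular`
#' attributes; internal 0-based half-open coordinates are converted to
#' GFF3's 1-based inclusive. `##sequence-region` pragmas carry replicon
#' lengths.
#'
#' @param annotation data frame with `gene_id`, `replicon_id`,
#'   `replicon_type`, `circular`, `start`, `end`, `strand`.
#' @param replicons data frame with `replicon_id` and `length`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, replicons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(replicons)))
    writeLines(sprintf("##sequence-region %s 1 %d",
                       replicons$replicon_id[i], replicons$length[i]), con)
  a <- annotation[order(annotation$replicon_id, annotation$start,
                        annotation$end, annotation$gene_id,
                        method = "radix"), ]
  writeLines(sprintf(
    "%s\tsteromine\tgene\t%d\t%d\t.\t%s\t.\tID=%s;replicon_type=%s;Is_circular=%s",
    a$replicon_id, a$start + 1L, a$end, a$strand, a$gene_id,
    a$replicon_type, ifelse(a$circular, "true", "false")), con)
  invisible(path)
}

#' Read a GFF3 gene annotation
#'
#' Parses with rtracklayer, converts to the internal 0-based half-open
#' convention and assigns `gene_index` per replicon by start coordinate
#' (ties broken by end, then id).
#'
#' @param path GFF3 file carrying `gene` features with `ID`,
#'   `replicon_type` and `Is_circular` attributes.
#' @param genome_id optional genome id stamped on the rows.
#' @return annotation data frame in the internal convention.
#' @export
read_annotation <- function(path, genome_id = NA_character_) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e)
                   smx_stop("steromine_input_error",
                            "cannot parse GFF3 %s: %s", path,
                            conditionMessage(e)))
  df <- as.data.frame(gr)
  if (!all(c("ID", "replicon_type") %in% names(df)))
    smx_stop("steromine_input_error",
             "GFF3 %s lacks ID/replicon_type attributes", path)
  if (any(!as.character(df$strand) %in% c("+", "-")))
    smx_stop("steromine_input_error", "unknown strand in %s", path)
  out <- data.frame(
    gene_id = as.character(df$ID), genome_id = genome_id,
    replicon_id = as.character(df$seqnames),
    replicon_type = as.character(df$replicon_type),
    circular = tolower(as.character(df$Is_circular %||% "false")) == "true",
    start = df$start - 1L, end = df$end,
    strand = as.character(df$strand))
  if (any(out$end <= out$start))
    smx_stop("steromine_input_error", "feature with end <= start in %s", path)
  ord <- order(out$replicon_id, out$start, out$end, out$gene_id,
               method = "radix")
  out <- out[ord, ]
  out$gene_index <- as.integer(ave(out$start, out$replicon_id,
                                   FUN = seq_along))
  rownames(out) <- NULL
  out
}

#' Read a community previously written by [write_community()]
#' @param dir directory produced by [write_community()].
#' @return list with `genomes`, `markers`, `species_tree`, `truth`.
#' @export
read_community <- function(dir) {
  pfiles <- sort(list.files(file.path(dir, "proteomes"), "\\.faa$",
                            full.names = TRUE))
  genomes <- list()
  for (p in pfiles) {
    gid <- sub("\\.faa$", "", basename(p))
    ann <- read_annotation(file.path(dir, "annotations",
                                     paste0(gid, ".gff3")), genome_id = gid)
    genomes[[gid]] <- list(genome_id = gid, proteome = read_fasta(p),
                           annotation = ann,
                           replicons = unique(ann[, c("replicon_id",
                                                      "replicon_type",
                                                      "circular")]))
  }
  truth_g <- file.path(dir, "truth_genomes.tsv")
  list(genomes = genomes,
       markers = read_fasta(file.path(dir, "markers.faa")),
       species_tree = ape::read.tree(file.path(dir, "species_tree.nwk")),
       truth = if (file.exists(truth_g))
         list(genomes = read.delim(truth_g),
              loci = read.delim(file.path(dir, "truth_loci.tsv"))) else NULL)
}
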