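#' Read a genome from a FASTA file
#'
#' Sequences are uppercased and RNA input (U) is converted to DNA (T).
#' Only the alphabet A/C/G/T/N is accepted.
#'
#' @param path path to a single- or multi-record FASTA file.
#' @return a named character vector of sequences (one element per contig),
#'   of class `genome_record`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("format error: empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- sub("\\s.*$", "", names(set))
  as_genome(seqs)
}

#' Coerce sequences to the genome container used throughout the package
#'
#' @param x a named character vector, a `DNAStringSet`, or a single unnamed
#'   sequence (which gets contig name "chr").
#' @return named uppercase character vector of class `genome_record`.
#' @export
as_genome <- function(x) {
  if (inherits(x, "genome_record")) return(x)
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("genome must be a character vector or XStringSet")
  seqs <- toupper(x)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (is.null(names(seqs))) {
    if (length(seqs) == 1) names(seqs) <- "chr"
    else stop("multi-contig genome must be named")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("format error: illegal characters in contig(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  if (any(nchar(seqs) == 0)) stop("format error: empty sequence record")
  structure(seqs, class = "genome_record")
}

#' Read gene annotations from a GFF3 file
#'
#' @param path path to a GFF3 file.
#' @param feature_type feature types to keep (first one present is used).
#' @return data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @export
read_gene_annotation <- function(path, feature_type = c("gene", "CDS")) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- feature_type[feature_type %in% as.character(gr$type)][1]
  if (is.na(keep)) stop("no features of type ", paste(feature_type, collapse = "/"),
                        " in ", path)
  gr <- gr[gr$type == keep]
  id <- if (!is.null(gr$locus_tag)) as.character(gr$locus_tag)
        else if (!is.null(gr$ID)) as.character(gr$ID)
        else as.character(gr$Name)
  genes <- data.frame(
    gene_id = id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  validate_genes(genes)
}

validate_genes <- function(genes, genome = NULL) {
  stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(genes)))
  if (is.null(genes$contig)) genes$contig <- "chr"
  if (any(genes$start < 1 | genes$start > genes$end))
    stop("invalid gene coordinates: need 1 <= start <= end")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation")
  if (!is.null(genome)) {
    len <- nchar(genome)[match(genes$contig, names(genome))]
    if (any(is.na(len)) || any(genes$end > len))
      stop("gene coordinates exceed genome length")
  }
  genes
}

#' Write gene annotations as GFF3
#'
#' @param genes data.frame as returned by [read_gene_annotation()].
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$locus_tag <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an operon map from a TSV file
#'
#' Expects columns `operon_id`, `gene_id`, `order`, `strand`. Genes are
#' sorted by `order` within each operon; monocistronic and polycistronic
#' operons are both allowed. All genes of an operon must share one strand.
#'
#' @param path path to the TSV.
#' @param genes optional gene annotation data.frame; when given, every
#'   mapped gene must exist in it.
#' @return data.frame with one row per (operon, gene), ordered by operon
#'   and transcription order.
#' @export
read_operon_map <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("operon map not found: ", path)
  op <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_operon_map(op, genes)
}

validate_operon_map <- function(op, genes = NULL) {
  need <- c("operon_id", "gene_id", "order", "strand")
  if (!all(need %in% names(op)))
    stop("operon map needs columns: ", paste(need, collapse = ", "))
  op <- op[order(op$operon_id, op$order), need, drop = FALSE]
  ns <- tapply(op$strand, op$operon_id, function(s) length(unique(s)))
  if (any(ns > 1))
    stop("validation error: mixed strands within operon(s): ",
         paste(names(ns)[ns > 1], collapse = ", "))
  if (!is.null(genes)) {
    missing <- setdiff(op$gene_id, genes$gene_id)
    if (length(missing))
      stop("reference error: operon map gene(s) absent from annotation: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  rownames(op) <- NULL
  op
}

#' Read a per-gene expression / read-depth table
#'
#' @param path TSV with columns `gene_id` and `value` (or any two columns,
#'   first = gene, second = abundance).
#' @param kind one of "read_depth", "transcript", "protein".
#' @return data.frame with columns `gene_id`, `value`, attribute `kind`.
#' @export
read_expression_table <- function(path,
                                  kind = c("read_depth", "transcript", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("expression table not found: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "value") %in% names(x))) {
    if (ncol(x) < 2) stop("expression table needs gene_id and value columns")
    names(x)[1:2] <- c("gene_id", "value")
  }
  x <- x[, c("gene_id", "value")]
  x$value <- as.numeric(x$value)
  if (any(is.na(x$value)) || any(x$value < 0))
    stop("abundances must be nonnegative numbers")
  attr(x, "kind") <- kind
  x
}

.sl_columns <- c("id", "contig", "start", "end", "strand", "sequence",
                 "structure", "dG", "stem_len", "loop_len", "total_len")

#' Write a stem-loop table to TSV
#'
#' The full column set (coordinates, structure, free energy, U-features,
#' positional category, operon context, class) round-trips losslessly
#' through [read_sl_table()]. An empty table yields a header-only file.
#'
#' @param sls stem-loop data.frame.
#' @param path output path.
#' @export
write_sl_table <- function(sls, path) {
  utils::write.table(as.data.frame(sls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a stem-loop table written by [write_sl_table()]
#'
#' @param path path to the TSV.
#' @return stem-loop data.frame.
#' @export
read_sl_table <- function(path) {
  if (!file.exists(path)) stop("SL table not found: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = NA, na.strings = "NA")
  for (col in c("start", "end", "stem_len", "loop_len", "total_len",
                "polyU_len", "U_content"))
    if (col %in% names(x)) x[[col]] <- as.integer(x[[col]])
  for (col in c("dG", "S1", "S2", "S3", "S4", "S4_norm"))
    if (col %in% names(x)) x[[col]] <- as.numeric(x[[col]])
  x
}
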