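#' Assign each stem-loop a positional category relative to genes
#'
#' The five categories, relative to annotated genes on either strand of the
#' same contig:
#' * `intragenic` - fully inside one gene;
#' * `intergenic` - touching no gene;
#' * `overlapped_on_3` / `overlapped_on_5` - straddling exactly one boundary
#'   of one gene, named after the gene end (in the gene's own orientation)
#'   that is crossed;
#' * `overlapped_with_two_genes` - straddling two genes, or enclosing an
#'   entire gene.
#'
#' @param sls stem-loop data.frame.
#' @param genes gene annotation data.frame (`gene_id`, `contig`, `start`,
#'   `end`, `strand`).
#' @return `sls` with a `category` column appended.
#' @export
categorize_position <- function(sls, genes) {
  if (is.null(genes$contig)) genes$contig <- "chr"
  cat <- character(nrow(sls))
  for (i in seq_len(nrow(sls))) {
    g <- genes[genes$contig == sls$contig[i], , drop = FALSE]
    s <- sls$start[i]; e <- sls$end[i]
    ov <- g$start <= e & g$end >= s
    if (!any(ov)) { cat[i] <- "intergenic"; next }
    g <- g[ov, , drop = FALSE]
    inside <- g$start <= s & e <= g$end
    if (any(inside)) { cat[i] <- "intragenic"; next }
    if (nrow(g) >= 2) { cat[i] <- "overlapped_with_two_genes"; next }
    left <- s < g$start   # SL crosses the gene's genomic-left boundary
    right <- e > g$end    # SL crosses the gene's genomic-right boundary
    if (left && right) { cat[i] <- "overlapped_with_two_genes"; next }
    crossed_end3 <- if (g$strand == "+") right else left
    cat[i] <- if (crossed_end3) "overlapped_on_3" else "overlapped_on_5"
  }
  sls$category <- cat
  sls
}

#' Intra- vs inter-operonic context of intergenic stem-loops
#'
#' For each intergenic SL, the flanking genes are the nearest genes upstream
#' and downstream of the SL in transcription orientation, on the SL's own
#' strand. The SL is `intra_operonic` when both flanks belong to the same
#' operon, `inter_operonic` when they belong to different operons or one
#' side has no flanking gene, and `not_applicable` for non-intergenic SLs.
#'
#' @param sls stem-loop data.frame with a `category` column.
#' @param operons operon map data.frame (`operon_id`, `gene_id`, `order`,
#'   `strand`).
#' @param genes gene annotation data.frame.
#' @return `sls` with columns `operon_context`, `operon_id`,
#'   `upstream_gene`, `downstream_gene` appended.
#' @export
operon_context <- function(sls, operons, genes) {
  stopifnot("category" %in% names(sls))
  if (is.null(genes$contig)) genes$contig <- "chr"
  n <- nrow(sls)
  ctx <- rep("not_applicable", n)
  opid <- rep(NA_character_, n)
  upg <- rep(NA_character_, n)
  dng <- rep(NA_character_, n)
  op_of <- stats::setNames(as.character(operons$operon_id), operons$gene_id)
  for (i in seq_len(n)) {
    if (sls$category[i] != "intergenic") next
    g <- genes[genes$contig == sls$contig[i] & genes$strand == sls$strand[i], ,
               drop = FALSE]
    s <- sls$start[i]; e <- sls$end[i]
    if (sls$strand[i] == "+") {
      up <- g[g$end < s, , drop = FALSE]
      up <- if (nrow(up)) up$gene_id[which.max(up$end)] else NA_character_
      dn <- g[g$start > e, , drop = FALSE]
      dn <- if (nrow(dn)) dn$gene_id[which.min(dn$start)] else NA_character_
    } else {
      up <- g[g$start > e, , drop = FALSE]
      up <- if (nrow(up)) up$gene_id[which.min(up$start)] else NA_character_
      dn <- g[g$end < s, , drop = FALSE]
      dn <- if (nrow(dn)) dn$gene_id[which.max(dn$end)] else NA_character_
    }
    upg[i] <- up; dng[i] <- dn
    flanks <- c(up, dn)
    known <- flanks[!is.na(flanks)]
    if (length(known) && any(!known %in% names(op_of)))
      stop("reference error: flanking gene(s) absent from the operon map: ",
           paste(setdiff(known, names(op_of)), collapse = ", "))
    if (length(known) == 2 && op_of[[known[1]]] == op_of[[known[2]]]) {
      ctx[i] <- "intra_operonic"
      opid[i] <- op_of[[known[1]]]
    } else {
      ctx[i] <- "inter_operonic"
      if (!is.na(up) && up %in% names(op_of)) opid[i] <- op_of[[up]]
    }
  }
  sls$operon_context <- ctx
  sls$operon_id <- opid
  sls$upstream_gene <- upg
  sls$downstream_gene <- dng
  sls
}
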