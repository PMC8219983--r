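#' SRPS operon container
#'
#' An operon together with its control stem-loops, used for stoichiometry
#' prediction. Control SLs are indexed by the gene they follow
#' (`after_gene`, in transcription order); an operon-terminal SL has
#' `after_gene` equal to the gene count.
#'
#' @param operon_id operon label.
#' @param genes character vector of gene ids in transcription order.
#' @param sls data.frame with columns `sl_id`, `after_gene`, `dG`, `class`,
#'   `terminal` (logical).
#' @param strand operon strand.
#' @return object of class `srps_operon`.
#' @export
srps_operon <- function(operon_id, genes, sls, strand = "+") {
  stopifnot(length(genes) >= 1,
            all(c("sl_id", "after_gene", "dG", "class", "terminal") %in%
                  names(sls)))
  if (nrow(sls)) {
    stopifnot(all(sls$after_gene >= 1 & sls$after_gene <= length(genes)),
              all(sls$dG <= 0))
    sls <- sls[order(sls$after_gene, sls$terminal), , drop = FALSE]
    rownames(sls) <- NULL
  }
  structure(list(operon_id = operon_id, genes = genes, sls = sls,
                 strand = strand),
            class = "srps_operon")
}

#' @export
print.srps_operon <- function(x, ...) {
  cat("SRPS operon", x$operon_id, "(", length(x$genes), "genes,",
      nrow(x$sls), "control SLs )\n")
  invisible(x)
}

#' Identify SRPS operons from classified stem-loops
#'
#' An operon is an SRPS candidate when it harbors at least one intergenic,
#' intra-operonic stem-loop classified as SSL or STSL. All intra-operonic
#' classified SLs of such an operon become its control SLs (internal TSLs
#' included), and an inter-operonic SL immediately following the operon's
#' last gene is attached as the terminal terminator when present.
#'
#' @param sls classified stem-loop data.frame (needs `class`,
#'   `operon_context`, `operon_id`, `upstream_gene`, `downstream_gene`).
#' @param operons operon map data.frame.
#' @return list of [srps_operon()] objects, one per SRPS operon.
#' @export
identify_srps <- function(sls, operons) {
  stopifnot(all(c("class", "operon_context", "operon_id", "upstream_gene") %in%
                  names(sls)))
  out <- list()
  for (op in unique(operons$operon_id)) {
    rows <- operons[operons$operon_id == op, , drop = FALSE]
    rows <- rows[order(rows$order), , drop = FALSE]
    genes <- rows$gene_id
    strand <- rows$strand[1]
    intra <- sls[!is.na(sls$operon_id) & sls$operon_id == as.character(op) &
                   sls$operon_context == "intra_operonic" &
                   sls$class != "unclassified", , drop = FALSE]
    if (!nrow(intra) || !any(intra$class %in% c("SSL", "STSL"))) next
    ctrl <- data.frame(
      sl_id = intra$id,
      after_gene = match(intra$upstream_gene, genes),
      dG = intra$dG,
      class = intra$class,
      terminal = FALSE,
      stringsAsFactors = FALSE)
    term <- sls[sls$operon_context == "inter_operonic" &
                  sls$class == "TSL" &
                  !is.na(sls$upstream_gene) &
                  sls$upstream_gene == genes[length(genes)] &
                  sls$strand == strand, , drop = FALSE]
    if (nrow(term)) {
      # nearest to the operon 3' end
      term <- if (strand == "+") term[which.min(term$start), , drop = FALSE]
              else term[which.max(term$end), , drop = FALSE]
      ctrl <- rbind(ctrl, data.frame(
        sl_id = term$id, after_gene = length(genes), dG = term$dG,
        class = term$class, terminal = TRUE, stringsAsFactors = FALSE))
    }
    out[[as.character(op)]] <- srps_operon(op, genes, ctrl, strand)
  }
  out
}

#' Predict the per-gene stoichiometry ratio of an SRPS operon
#'
#' Each gene is assigned the free energy of the nearest control stem-loop at
#' or downstream of its 3' end within the operon (the gene block sharing one
#' control SL is its upstream control unit); genes with no downstream SL are
#' predicted to have zero expression. Values are normalized by the free
#' energy of the 5'-most control SL and rounded to two decimals.
#'
#' @param op an [srps_operon()].
#' @param tsl_controls use internal terminator SLs as control values for
#'   their own upstream control unit (the operon-terminal SL is always
#'   used).
#' @return data.frame with columns `operon_id`, `gene_id`, `control_sl`,
#'   `dG`, `ratio`.
#' @export
predict_ratio <- function(op, tsl_controls = TRUE) {
  stopifnot(inherits(op, "srps_operon"))
  ctrl <- op$sls
  if (!tsl_controls)
    ctrl <- ctrl[ctrl$class != "TSL" | ctrl$terminal, , drop = FALSE]
  if (!nrow(ctrl))
    stop("invalid-input error: operon ", op$operon_id, " has no control SLs")
  ctrl <- ctrl[order(ctrl$after_gene), , drop = FALSE]
  dg_first <- ctrl$dG[1]
  n <- length(op$genes)
  sl_of <- rep(NA_character_, n)
  dg_of <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- which(ctrl$after_gene >= i)[1]
    if (!is.na(j)) {
      sl_of[i] <- ctrl$sl_id[j]
      dg_of[i] <- ctrl$dG[j]
    }
  }
  ratio <- ifelse(is.na(dg_of), 0, round(dg_of / dg_first, 2))
  data.frame(operon_id = op$operon_id, gene_id = op$genes,
             control_sl = sl_of, dG = dg_of, ratio = ratio,
             stringsAsFactors = FALSE)
}
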