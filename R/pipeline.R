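#' Pipeline configuration
#'
#' Collects every tunable parameter of the SLOFE pipeline with its default:
#' the search descriptor bounds, the free-energy floor, the stability factor
#' and its selection threshold, classification and ratio flags, and the NRD
#' validation threshold.
#'
#' @inheritParams sl_descriptor
#' @param dg_max free-energy floor for deduplication, kcal/mol.
#' @param score stability factor used for stable-SL selection.
#' @param stable_threshold normalized stability cutoff.
#' @param stsl_priority see [classify_sl()].
#' @param tsl_controls see [predict_ratio()].
#' @param nrd_threshold see [validate_sls()].
#' @param dg_rescue see [validate_sls()].
#' @param backend folding backend.
#' @param pseudocount optional pseudocount for correlation; see
#'   [correlate_ratio()].
#' @return list of class `slofe_config`.
#' @export
slofe_config <- function(stem_min = 6L, stem_max = 40L, loop_min = 3L,
                         loop_max = 30L, allow_GU = TRUE, max_mismatch = 2L,
                         max_bulge = 2L, dg_max = -5.0,
                         score = "S4", stable_threshold = 0.60,
                         stsl_priority = TRUE, tsl_controls = TRUE,
                         nrd_threshold = 0.5, dg_rescue = FALSE,
                         backend = c("internal", "external"),
                         pseudocount = NULL) {
  backend <- match.arg(backend)
  structure(as.list(environment()), class = "slofe_config")
}

#' Run the full SLOFE pipeline
#'
#' Scan -> fold -> trim -> deduplicate -> stable selection -> gene/operon
#' mapping -> classification -> SRPS identification -> ratio prediction ->
#' (optional) NRD validation and expression correlation. When `out_dir` is
#' given, each stage's table is written as TSV together with a
#' `summary.json` of per-stage counts and the configuration.
#'
#' @param genome genome (path to FASTA, or [genome_record][as_genome]).
#' @param genes gene annotation (path to GFF3, or data.frame).
#' @param operons operon map (path to TSV, or data.frame).
#' @param depths optional read-depth table (path or data.frame) for NRD
#'   validation.
#' @param expression optional expression table (path or data.frame) for
#'   ratio correlation.
#' @param out_dir optional output directory.
#' @param config a [slofe_config()].
#' @return list with elements `sls`, `stable`, `classified`, `srps`,
#'   `ratios`, `validation`, `correlations`, `summary` (invisibly when
#'   `out_dir` is given).
#' @export
slofe_run <- function(genome, genes, operons, depths = NULL,
                      expression = NULL, out_dir = NULL,
                      config = slofe_config()) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_genome(genome)
  genome <- as_genome(genome)
  if (is.character(genes)) genes <- read_gene_annotation(genes)
  genes <- validate_genes(genes, genome)
  if (is.character(operons)) operons <- read_operon_map(operons, genes)
  else operons <- validate_operon_map(operons, genes)
  if (is.character(depths)) depths <- read_expression_table(depths, "read_depth")
  if (is.character(expression))
    expression <- read_expression_table(expression, "transcript")

  d <- sl_descriptor(config$stem_min, config$stem_max, config$loop_min,
                     config$loop_max, config$allow_GU, config$max_mismatch,
                     config$max_bulge)
  sls <- discover_stemloops(genome, d, backend = config$backend)
  trimmed <- trim_flanks(sls)
  dedup <- deduplicate(trimmed, dg_max = config$dg_max)
  dedup <- stability_scores(dedup)
  stable <- select_stable(dedup, score = config$score,
                          threshold = config$stable_threshold)
  stable <- u_features(stable, genome)
  mapped <- categorize_position(stable, genes)
  mapped <- operon_context(mapped, operons, genes)
  classified <- classify_sls(mapped, stsl_priority = config$stsl_priority)
  srps <- identify_srps(classified, operons)
  ratios <- if (length(srps)) {
    do.call(rbind, lapply(srps, predict_ratio,
                          tsl_controls = config$tsl_controls))
  } else {
    data.frame(operon_id = character(), gene_id = character(),
               control_sl = character(), dG = numeric(), ratio = numeric())
  }
  rownames(ratios) <- NULL

  validation <- NULL
  if (!is.null(depths)) {
    cand <- classified[classified$operon_context == "intra_operonic", ,
                       drop = FALSE]
    validation <- validate_sls(cand, depths, threshold = config$nrd_threshold,
                               dg_rescue = config$dg_rescue)
  } else {
    message("no read-depth table supplied: validation stage skipped")
  }
  correlations <- NULL
  if (!is.null(expression) && nrow(ratios)) {
    correlations <- do.call(rbind, lapply(split(ratios, ratios$operon_id),
                                          correlate_ratio, expr = expression,
                                          pseudocount = config$pseudocount))
    rownames(correlations) <- NULL
  }

  summary <- list(
    config = unclass(config),
    n_discovered = nrow(sls),
    n_after_dedup = nrow(dedup),
    n_stable = nrow(stable),
    category_counts = as.list(table(classified$category)),
    operon_context_counts = as.list(table(classified$operon_context)),
    class_counts = as.list(table(
      classified$class[classified$operon_context == "intra_operonic"])),
    n_srps_operons = length(srps),
    n_validated_pass = if (is.null(validation)) NA_integer_
                       else sum(validation$passed, na.rm = TRUE)
  )
  out <- list(sls = sls, stable = stable, classified = classified,
              srps = srps, ratios = ratios, validation = validation,
              correlations = correlations, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sl_table(sls, file.path(out_dir, "sls.tsv"))
    write_sl_table(stable, file.path(out_dir, "stable.tsv"))
    write_sl_table(classified, file.path(out_dir, "classified.tsv"))
    srps_tab <- data.frame(
      operon_id = vapply(srps, function(x) as.character(x$operon_id), ""),
      n_genes = vapply(srps, function(x) length(x$genes), 0L),
      n_control_sls = vapply(srps, function(x) nrow(x$sls), 0L))
    utils::write.table(srps_tab, file.path(out_dir, "srps_operons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ratios, file.path(out_dir, "ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(validation))
      utils::write.table(validation, file.path(out_dir, "validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(correlations))
      utils::write.table(correlations, file.path(out_dir, "correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    return(invisible(out))
  }
  out
}
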