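#' Normalized read-depth difference
#'
#' `NRD = (Rd5 - Rd3) / max(Rd5, Rd3)`, where `Rd5` and `Rd3` are the read
#' depths of the genes flanking a stem-loop at its 5' and 3' side. Lies in
#' `[-1, 1]`; large positive values indicate selective stabilization of the
#' upstream segment. Undefined (NA) when both depths are zero.
#'
#' @param rd5,rd3 nonnegative read depths (vectorized).
#' @return numeric vector of NRD values.
#' @export
nrd <- function(rd5, rd3) {
  stopifnot(all(rd5 >= 0, na.rm = TRUE), all(rd3 >= 0, na.rm = TRUE))
  out <- (rd5 - rd3) / pmax(rd5, rd3)
  out[rd5 == 0 & rd3 == 0] <- NA_real_
  out
}

#' NRD as a whole percentage
#'
#' Truncates towards zero so the reported coverage drop is never overstated
#' (0.976 prints as 97%).
#'
#' @inheritParams nrd
#' @return integer percentage.
#' @export
nrd_percent <- function(rd5, rd3) {
  trunc(100 * nrd(rd5, rd3))
}

#' Validate candidate SRPS stem-loops against read depths
#'
#' Computes the NRD of every stabilizer-type (SSL/STSL) candidate from the
#' read depths of its flanking genes. Candidates lacking depth data on
#' either side are reported with `status = "no_data"`. With `dg_rescue`, a
#' sub-threshold candidate is rescued when, within its operon, the flanking
#' 5' gene depths correlate positively with the stability (|dG|) of the
#' associated SLs.
#'
#' @param sls classified stem-loop data.frame (typically the intra-operonic
#'   SSL/STSL candidates; other classes are dropped).
#' @param depths read-depth table (`gene_id`, `value`).
#' @param threshold NRD pass threshold (default 0.5).
#' @param dg_rescue enable the correlation-based rescue of failed records.
#' @return data.frame with columns `sl_id`, `operon_id`, `Rd5`, `Rd3`,
#'   `nrd`, `passed`, `status`.
#' @export
validate_sls <- function(sls, depths, threshold = 0.5, dg_rescue = FALSE) {
  cand <- sls[sls$class %in% c("SSL", "STSL"), , drop = FALSE]
  d <- stats::setNames(depths$value, depths$gene_id)
  rd5 <- unname(d[cand$upstream_gene])
  rd3 <- unname(d[cand$downstream_gene])
  val <- nrd(ifelse(is.na(rd5), 0, rd5), ifelse(is.na(rd3), 0, rd3))
  no_data <- is.na(rd5) | is.na(rd3)
  undefined <- !no_data & rd5 == 0 & rd3 == 0
  val[no_data | undefined] <- NA_real_
  passed <- ifelse(is.na(val), NA, val > threshold)
  status <- ifelse(no_data, "no_data",
                   ifelse(undefined, "undefined",
                          ifelse(passed, "pass", "fail")))
  rec <- data.frame(sl_id = cand$id, operon_id = cand$operon_id,
                    Rd5 = rd5, Rd3 = rd3, nrd = val, passed = passed,
                    status = status, stringsAsFactors = FALSE)
  if (dg_rescue && any(!is.na(rec$passed) & !rec$passed)) {
    for (op in unique(rec$operon_id[!is.na(rec$passed) & !rec$passed])) {
      in_op <- which(!is.na(rec$operon_id) & rec$operon_id == op)
      dg <- abs(cand$dG[in_op])
      dep <- rec$Rd5[in_op]
      ok <- !is.na(dep)
      if (sum(ok) >= 3 && stats::sd(dg[ok]) > 0 && stats::sd(dep[ok]) > 0 &&
          stats::cor(dep[ok], dg[ok]) > 0) {
        fix <- in_op[!is.na(rec$passed[in_op]) & !rec$passed[in_op]]
        rec$passed[fix] <- TRUE
        rec$status[fix] <- "rescued"
      }
    }
  }
  rec
}

#' Correlate a predicted ratio with measured abundances
#'
#' Pearson correlation between the predicted per-gene ratio and log10
#' abundance over the genes shared with the expression table. Genes with
#' zero abundance are excluded pairwise unless a pseudocount is supplied.
#' Not computed (NA) for fewer than `min_genes` usable genes or zero
#' variance on either side.
#'
#' @param pred ratio prediction for one operon ([predict_ratio()]).
#' @param expr expression table (`gene_id`, `value`).
#' @param min_genes minimum usable genes (default 3).
#' @param pseudocount optional value added to all abundances before log10.
#' @return one-row data.frame with `operon_id`, `r`, `n_genes`, `computed`.
#' @export
correlate_ratio <- function(pred, expr, min_genes = 3L, pseudocount = NULL) {
  e <- stats::setNames(expr$value, expr$gene_id)
  y <- unname(e[pred$gene_id])
  x <- pred$ratio
  if (!is.null(pseudocount)) y <- y + pseudocount
  use <- !is.na(y) & y > 0
  x <- x[use]; y <- log10(y[use])
  r <- NA_real_
  computed <- length(x) >= min_genes &&
    stats::sd(x) > 0 && stats::sd(y) > 0
  if (computed) r <- stats::cor(x, y)
  data.frame(operon_id = pred$operon_id[1], r = r,
             n_genes = length(x), computed = computed,
             stringsAsFactors = FALSE)
}
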