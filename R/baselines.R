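# Codon-usage expression predictors used as comparison baselines:
#   CAI  - codon adaptation index (Sharp & Li 1987, NAR)
#   RCBS - relative codon usage bias score (Roymondal et al. 2009, DNA Res)
#   RCA  - relative codon adaptation (Fox & Erill 2010, DNA Res)
#   MELP - MILC-based expression level predictor (Supek & Vlahovicek 2005,
#          BMC Bioinformatics)
# plus the positional gene-order heuristic (5' genes expressed above 3').

.codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  data.frame(codon = names(code), aa = unname(code),
             stringsAsFactors = FALSE)
}

split_codons <- function(seq) {
  seq <- toupper(chartr("U", "T", seq))
  if (nchar(seq) %% 3 != 0)
    stop("coding sequence length must be divisible by 3")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  if (any(grepl("[^ACGT]", codons)))
    stop("invalid codons in coding sequence")
  codons
}

# drops the terminal stop; warns on (and skips) internal stops
coding_codons <- function(seq) {
  codons <- split_codons(seq)
  tab <- .codon_table()
  aa <- tab$aa[match(codons, tab$codon)]
  n <- length(codons)
  if (aa[n] == "*") { codons <- codons[-n]; aa <- aa[-n] }
  internal_stop <- aa == "*"
  if (any(internal_stop)) {
    warning("internal stop codon(s) skipped")
    codons <- codons[!internal_stop]
  }
  codons
}

codon_counts <- function(seqs) {
  tab <- .codon_table()
  counts <- stats::setNames(rep(0, nrow(tab)), tab$codon)
  for (s in seqs) {
    cc <- table(coding_codons(s))
    counts[names(cc)] <- counts[names(cc)] + as.numeric(cc)
  }
  counts
}

# per-family relative frequencies with a 0.5 pseudocount on absent codons
family_freqs <- function(counts) {
  tab <- .codon_table()
  counts[counts == 0] <- 0.5
  ave <- stats::ave(counts, tab$aa, FUN = sum)
  counts / ave
}

positional_freqs <- function(counts) {
  codons <- names(counts)
  lapply(1:3, function(p) {
    b <- substring(codons, p, p)
    tapply(counts, b, sum) / sum(counts)
  })
}

#' Build a codon-usage model from a reference gene set
#'
#' @param ref_cds character vector of reference coding sequences (the
#'   canonical default is all annotated CDS of the genome).
#' @param method one of `"CAI"`, `"RCBS"`, `"RCA"`, `"MELP"`.
#' @param melp_reference for MELP only: coding sequences of the
#'   highly-expressed reference set. When `NULL`, the top decile of
#'   `ref_cds` ranked by CAI is used as the highly-expressed proxy (MELP is
#'   identically 1 when its reference equals the background set).
#' @return list of class `codon_usage_model`.
#' @export
codon_usage_model <- function(ref_cds, method = c("CAI", "RCBS", "RCA", "MELP"),
                              melp_reference = NULL) {
  method <- match.arg(method)
  counts <- codon_counts(ref_cds)
  m <- list(method = method)
  if (method == "CAI") {
    f <- family_freqs(counts)
    tab <- .codon_table()
    fmax <- stats::ave(f, tab$aa, FUN = max)
    m$w <- f / fmax # relative adaptiveness, per-family maximum = 1
  } else if (method == "RCA") {
    pf <- positional_freqs(counts)
    codons <- names(counts)
    expected <- pf[[1]][substring(codons, 1, 1)] *
      pf[[2]][substring(codons, 2, 2)] *
      pf[[3]][substring(codons, 3, 3)]
    cnt <- counts
    cnt[cnt == 0] <- 0.5
    m$rca <- stats::setNames(as.numeric((cnt / sum(cnt)) / expected), codons)
  } else if (method == "MELP") {
    m$u_background <- family_freqs(counts)
    if (is.null(melp_reference)) {
      cai_model <- codon_usage_model(ref_cds, "CAI")
      scores <- vapply(ref_cds, score_gene, 0, model = cai_model)
      k <- max(1L, ceiling(length(ref_cds) / 10))
      melp_reference <- ref_cds[order(scores, decreasing = TRUE)[seq_len(k)]]
    }
    m$u_reference <- family_freqs(codon_counts(melp_reference))
  }
  structure(m, class = "codon_usage_model")
}

# MILC of one gene against a reference usage u (per-family frequencies):
# sum over amino acids of M_a = 2 * sum_c n_c log(f_c / u_c), divided by the
# gene length in codons, minus the correction (sum_a (r_a - 1)) / L.
milc <- function(codons, u) {
  tab <- .codon_table()
  aa <- tab$aa[match(codons, tab$codon)]
  keep <- !aa %in% "*"
  codons <- codons[keep]; aa <- aa[keep]
  L <- length(codons)
  total <- 0
  corr <- 0
  for (a in unique(aa)) {
    fam <- tab$codon[tab$aa == a]
    if (length(fam) < 2) next
    n_c <- table(factor(codons[aa == a], levels = fam))
    f_c <- n_c / sum(n_c)
    uu <- u[fam]
    nz <- n_c > 0
    total <- total + 2 * sum(n_c[nz] * log(as.numeric(f_c[nz]) / uu[nz]))
    corr <- corr + (length(fam) - 1)
  }
  total / L - corr / L
}

#' Score one gene under a codon-usage model
#'
#' CAI is the geometric mean of the relative adaptiveness of the gene's
#' codons (single-codon families and stops excluded); RCA the geometric
#' mean of the reference-derived relative codon adaptation; RCBS the
#' gene-intrinsic codon-bias score; MELP the ratio of the gene's MILC
#' against the genome background to its MILC against the highly-expressed
#' reference.
#'
#' @param seq coding DNA sequence (length divisible by 3; internal stop
#'   codons are skipped with a warning).
#' @param model a [codon_usage_model()].
#' @return numeric score.
#' @export
score_gene <- function(seq, model) {
  stopifnot(inherits(model, "codon_usage_model"))
  codons <- coding_codons(seq)
  tab <- .codon_table()
  aa <- tab$aa[match(codons, tab$codon)]
  if (model$method == "CAI") {
    fam_size <- table(tab$aa)
    use <- fam_size[aa] > 1 & aa != "*"
    exp(mean(log(model$w[codons[use]])))
  } else if (model$method == "RCA") {
    exp(mean(log(model$rca[codons])))
  } else if (model$method == "RCBS") {
    # d_xyz = f(xyz)/(f1(x) f2(y) f3(z)) - 1, all from the gene itself
    counts <- stats::setNames(rep(0, nrow(tab)), tab$codon)
    cc <- table(codons)
    counts[names(cc)] <- as.numeric(cc)
    pf <- positional_freqs(counts)
    f <- counts / sum(counts)
    expected <- pf[[1]][substring(names(counts), 1, 1)] *
      pf[[2]][substring(names(counts), 2, 2)] *
      pf[[3]][substring(names(counts), 3, 3)]
    d <- as.numeric(f / expected)[match(codons, names(counts))]
    exp(mean(log(d))) - 1
  } else { # MELP
    milc(codons, model$u_background) / milc(codons, model$u_reference)
  }
}

#' Baseline per-operon stoichiometry ratio
#'
#' Scores every gene of an operon under one of the five baseline predictors
#' and normalizes by the first gene's score. The `order` method assigns
#' strictly decreasing values n, n-1, ..., 1 (normalized by n), encoding
#' the heuristic that 5' genes are expressed above 3' genes.
#'
#' @param cds named character vector of coding sequences, in transcription
#'   order.
#' @param method `"cai"`, `"rcbs"`, `"rca"`, `"melp"` or `"order"`.
#' @param model optional prebuilt [codon_usage_model()]; when absent, it is
#'   estimated from `reference` (default: the operon's own genes plus any
#'   sequences in `reference`).
#' @param reference reference coding sequences for model estimation.
#' @return data.frame with columns `gene_id`, `score`, `ratio`.
#' @export
baseline_ratio <- function(cds, method = c("cai", "rcbs", "rca", "melp",
                                           "order"),
                           model = NULL, reference = NULL) {
  method <- match.arg(method)
  drop <- is.na(cds) | !nzchar(cds)
  if (any(drop)) {
    warning("dropping gene(s) without CDS: ",
            paste(names(cds)[drop], collapse = ", "))
    cds <- cds[!drop]
  }
  n <- length(cds)
  if (method == "order") {
    score <- seq(n, 1)
  } else if (method == "rcbs") {
    score <- vapply(cds, score_gene, 0,
                    model = structure(list(method = "RCBS"),
                                      class = "codon_usage_model"))
  } else {
    if (is.null(model)) {
      ref <- if (is.null(reference)) cds else reference
      model <- codon_usage_model(ref, toupper(method))
    }
    score <- vapply(cds, score_gene, 0, model = model)
  }
  data.frame(gene_id = names(cds), score = unname(score),
             ratio = round(unname(score) / score[1], 2),
             stringsAsFactors = FALSE)
}
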