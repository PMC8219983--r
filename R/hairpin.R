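#' Stem-loop search descriptor
#'
#' Constraints used by the genome scanner: stem length between `stem_min`
#' and `stem_max` base pairs, loop length between `loop_min` and `loop_max`
#' nt, optional G-U wobble pairing, and a cap on imperfections in the stem.
#' The defaults are the descriptor used for genome-wide prediction in
#' Clostridia (stems 6-40 bp, loops 3-30 nt, GU allowed).
#'
#' @param stem_min,stem_max minimal/maximal stem length (bp).
#' @param loop_min,loop_max minimal/maximal loop length (nt).
#' @param allow_GU allow G-U wobble pairs in the stem.
#' @param max_mismatch maximum mispaired positions tolerated by the scanner.
#' @param max_bulge maximum unpaired (bulged) bases per stem interruption
#'   tolerated by the folding stage.
#' @return a list of class `sl_descriptor`.
#' @export
sl_descriptor <- function(stem_min = 6L, stem_max = 40L,
                          loop_min = 3L, loop_max = 30L,
                          allow_GU = TRUE, max_mismatch = 2L,
                          max_bulge = 2L) {
  stopifnot(stem_min >= 1, stem_min <= stem_max,
            loop_min >= 1, loop_min <= loop_max,
            is.finite(stem_max), is.finite(loop_max),
            max_mismatch >= 0, max_bulge >= 0)
  structure(list(stem_min = as.integer(stem_min),
                 stem_max = as.integer(stem_max),
                 loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max),
                 allow_GU = isTRUE(allow_GU),
                 max_mismatch = as.integer(max_mismatch),
                 max_bulge = as.integer(max_bulge)),
            class = "sl_descriptor")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Scan a genome for candidate stem-loop motifs
#'
#' Both strands are scanned. A candidate is the maximal hairpin locus around
#' one (loop start, loop length): the stem extends outwards while at most
#' `max_mismatch` mispairs accumulate, the outermost and loop-adjacent
#' positions must pair, and the stem length must fall inside the descriptor
#' bounds. Candidates containing N are discarded; candidates may overlap.
#'
#' @param genome a [genome_record][as_genome] (or coercible).
#' @param d an [sl_descriptor()].
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `sequence` (genomic coordinates, 1-based inclusive; sequence is given
#'   5'->3' on the candidate's strand, as RNA).
#' @export
scan_motifs <- function(genome, d = sl_descriptor()) {
  genome <- as_genome(genome)
  out <- list()
  for (contig in names(genome)) {
    seq <- genome[[contig]]
    n <- nchar(seq)
    if (n == 0) next
    fw <- .scan_candidates_cpp(seq, d$stem_min, d$stem_max, d$loop_min,
                               d$loop_max, d$allow_GU, d$max_mismatch)
    rc <- .scan_candidates_cpp(revcomp(seq), d$stem_min, d$stem_max,
                               d$loop_min, d$loop_max, d$allow_GU,
                               d$max_mismatch)
    if (nrow(fw)) {
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, start = fw[, "start"], end = fw[, "end"],
        strand = "+", stringsAsFactors = FALSE)
    }
    if (nrow(rc)) {
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, start = n - rc[, "end"] + 1L,
        end = n - rc[, "start"] + 1L, strand = "-",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, out)
  cand <- unique(cand)
  cand <- cand[order(cand$contig, cand$start, cand$end, cand$strand), ,
               drop = FALSE]
  rownames(cand) <- NULL
  cand$sequence <- sl_genomic_sequence(genome, cand$contig, cand$start,
                                       cand$end, cand$strand)
  cand
}

# 5'->3' RNA sequence of a genomic interval on the given strand
sl_genomic_sequence <- function(genome, contig, start, end, strand) {
  seqs <- substring(genome[contig], start, end)
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  chartr("T", "U", seqs)
}

#' Fold a candidate sequence into its minimum-free-energy hairpin
#'
#' The internal backend computes the best single-hairpin structure under the
#' nearest-neighbor model of [slofe_energy_params()]. The external backend
#' delegates to an installed `RNAfold` binary and parses its dot-bracket
#' output. Both return the free energy in kcal/mol; an unpairable sequence
#' folds to all dots with dG = 0.
#'
#' @param seq character vector of RNA/DNA sequences.
#' @param backend `"internal"` or `"external"`.
#' @param params energy parameter set (internal backend).
#' @param min_loop minimum hairpin loop size.
#' @param allow_GU allow G-U wobble pairs.
#' @return data.frame with columns `sequence`, `structure`, `dG`.
#' @export
fold_candidate <- function(seq, backend = c("internal", "external"),
                           params = slofe_energy_params(), min_loop = 3L,
                           allow_GU = TRUE) {
  backend <- match.arg(backend)
  seq <- toupper(seq)
  if (backend == "internal") {
    res <- lapply(seq, .fold_hairpin_cpp, pars = params,
                  min_loop = as.integer(min_loop), allow_gu = allow_GU)
    data.frame(sequence = chartr("T", "U", seq),
               structure = vapply(res, `[[`, "", "structure"),
               dG = vapply(res, `[[`, 0, "dG"),
               stringsAsFactors = FALSE)
  } else {
    fold_external(seq)
  }
}

fold_external <- function(seq) {
  bin <- Sys.which("RNAfold")
  if (!nzchar(bin))
    stop("configuration error: external backend requires the 'RNAfold' ",
         "binary on PATH; install ViennaRNA or use backend = \"internal\"")
  inp <- tempfile(fileext = ".fa")
  on.exit(unlink(inp))
  writeLines(as.character(seq), inp)
  out <- system2(bin, c("--noPS"), stdin = inp, stdout = TRUE)
  stopifnot(length(out) == 2L * length(seq))
  strc <- out[seq(2L, length(out), by = 2L)]
  m <- regmatches(strc, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", strc))
  data.frame(sequence = chartr("T", "U", toupper(seq)),
             structure = vapply(m, `[[`, "", 2L),
             dG = as.numeric(vapply(m, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

# stem length, hairpin loop length and hairpin count from a dot-bracket string
structure_stats <- function(structure) {
  stem <- vapply(gregexpr("(", structure, fixed = TRUE),
                 function(m) if (m[1] == -1) 0L else length(m), 0L)
  n_hairpin <- vapply(gregexpr("\\([.]*\\)", structure),
                      function(m) if (m[1] == -1) 0L else length(m), 0L)
  loop <- rep(NA_integer_, length(structure))
  has <- n_hairpin > 0
  loop[has] <- vapply(regmatches(structure[has],
                                 regexpr("\\([.]*\\)", structure[has])),
                     function(x) nchar(x) - 2L, 0L)
  data.frame(stem_len = stem, loop_len = loop, n_hairpin = n_hairpin)
}

#' Discover stem-loops genome-wide
#'
#' Scans both strands for candidate motifs ([scan_motifs()]), folds each
#' candidate ([fold_candidate()]), and keeps candidates whose fold is a
#' single hairpin with descriptor-conformant stem and loop lengths.
#'
#' @inheritParams scan_motifs
#' @inheritParams fold_candidate
#' @return stem-loop data.frame with columns `id`, `contig`, `start`, `end`,
#'   `strand`, `sequence`, `structure`, `dG`, `stem_len`, `loop_len`,
#'   `total_len`.
#' @export
discover_stemloops <- function(genome, d = sl_descriptor(),
                               backend = c("internal", "external"),
                               params = slofe_energy_params(
                                 max_intloop = 2L * d$max_bulge)) {
  backend <- match.arg(backend)
  genome <- as_genome(genome)
  cand <- scan_motifs(genome, d)
  if (!nrow(cand)) return(empty_sl_table())
  fold <- fold_candidate(cand$sequence, backend = backend, params = params,
                         min_loop = d$loop_min, allow_GU = d$allow_GU)
  st <- structure_stats(fold$structure)
  keep <- fold$dG < 0 & st$n_hairpin == 1L &
    st$stem_len >= d$stem_min & st$stem_len <= d$stem_max &
    !is.na(st$loop_len) & st$loop_len >= d$loop_min & st$loop_len <= d$loop_max
  sls <- cbind(cand[keep, , drop = FALSE],
               fold[keep, c("structure", "dG"), drop = FALSE],
               st[keep, c("stem_len", "loop_len"), drop = FALSE])
  sls$total_len <- sls$end - sls$start + 1L
  sls$id <- sl_id(sls)
  rownames(sls) <- NULL
  sls[, .sl_columns]
}

sl_id <- function(sls) {
  sprintf("%s:%d-%d(%s)", sls$contig, sls$start, sls$end, sls$strand)
}

empty_sl_table <- function() {
  data.frame(id = character(), contig = character(), start = integer(),
             end = integer(), strand = character(), sequence = character(),
             structure = character(), dG = numeric(), stem_len = integer(),
             loop_len = integer(), total_len = integer(),
             stringsAsFactors = FALSE)
}
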