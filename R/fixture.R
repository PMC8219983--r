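# Synthetic genomes with planted stem-loops and SRPS-consistent expression
# tables: every pipeline stage is testable against recorded ground truth
# without any external data.

#' Specification of a synthetic fixture
#'
#' Defaults emulate a small Clostridium-like genome: AT-rich background
#' (GC ~ 37%), operons of 2-5 genes, planted control stem-loops in a strong
#' free-energy band, and per-gene read depth proportional to the |dG| of
#' the controlling SL with multiplicative log-normal noise (genes with no
#' downstream control SL get zero depth).
#'
#' @param seed RNG seed; the same seed reproduces byte-identical fixtures.
#' @param n_operons total operons.
#' @param n_srps operons carrying one planted internal stabilizer SL
#'   (SSL/STSL alternating).
#' @param genes_per_operon inclusive range of genes per operon.
#' @param gene_len_codons inclusive range of gene lengths, in codons
#'   (including start and stop).
#' @param intergenic_len range of within-operon intergenic gap lengths, nt.
#' @param operon_gap range of between-operon gap lengths, nt.
#' @param dg_band target free-energy band for planted SLs, kcal/mol.
#' @param noise_sigma log10-scale standard deviation of expression noise.
#' @param gc_background background GC fraction.
#' @param base_depth read-depth scale factor.
#' @param bg_dg_floor background rejection threshold: intergenic filler is
#'   resampled until no fold reaches below this energy, so planted SLs
#'   dominate the stability cohort by construction.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_operons = 10L, n_srps = 5L,
                         genes_per_operon = c(2L, 5L),
                         gene_len_codons = c(50L, 80L),
                         intergenic_len = c(55L, 85L),
                         operon_gap = c(110L, 160L),
                         dg_band = c(-30, -24), noise_sigma = 0.1,
                         gc_background = 0.37, base_depth = 1000,
                         bg_dg_floor = -10) {
  stopifnot(n_srps <= n_operons, genes_per_operon[1] >= 2,
            dg_band[1] < dg_band[2], dg_band[2] < -5)
  structure(as.list(environment()), class = "fixture_spec")
}

.sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

random_cds <- function(n_codons) {
  body <- sample(.sense_codons(), n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# background with no fold below `floor` (rejection sampled); `prefix` is
# fixed adjacent sequence included in the stability check so that no
# unchecked intergenic span exists after assembly
background_seq <- function(n, gc, floor, prefix = "", max_tries = 400L) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  for (k in seq_len(max_tries)) {
    s <- paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
    if (n + nchar(prefix) < 14 ||
        fold_candidate(paste0(prefix, s))$dG > floor) return(s)
  }
  stop("generation error: could not sample background above ", floor,
       " kcal/mol")
}

.window_for_class <- function(uclass) {
  if (uclass == "TSL") {
    # run >= 4 from position 1, U content >= 7: downstream tail
    paste0("TTTTTTT", paste(sample(c("G", "A", "C"), 3, TRUE), collapse = ""))
  } else if (uclass == "STSL") {
    # U content >= 4 without a run of 4: discontinuous tail
    paste0("TTA", "TTA", "TT",
           paste(sample(c("G", "C", "A"), 2, TRUE), collapse = ""))
  } else { # SSL
    w <- sample(c("G", "C", "A"), 10, TRUE)
    w[sample(10, 2)] <- "T"  # U content 2 <= 5, run <= 2
    paste(w, collapse = "")
  }
}

#' Generate one hairpin with a chosen free energy and U-window class
#'
#' Builds a GC-rich stem around an unpairable loop, tuning stem length and
#' composition until the internal fold lands inside `dg_band`, and appends
#' a 10-nt downstream window whose U features match the requested class
#' exactly (so classification recovers the class by construction).
#'
#' @param dg_band free-energy interval, kcal/mol (e.g. `c(-30, -22)`).
#' @param uclass planted class: `"SSL"`, `"STSL"` or `"TSL"`.
#' @param max_tries resampling bound before a generation error.
#' @return list with `hairpin` (DNA), `window` (DNA), `structure`, `dG`,
#'   `class`.
#' @export
make_hairpin <- function(dg_band = c(-30, -24), uclass = "SSL",
                         max_tries = 40L) {
  stopifnot(uclass %in% c("SSL", "STSL", "TSL"), dg_band[1] < dg_band[2])
  for (try in seq_len(max_tries)) {
    loop <- paste(sample(c("A", "C"), sample(4:6, 1), TRUE), collapse = "")
    stem <- sample(c("G", "C"), 6, TRUE)
    dg <- 0
    seq <- ""
    while (length(stem) <= 40) {
      seq <- paste0(paste(stem, collapse = ""), loop,
                    revcomp(paste(stem, collapse = "")))
      dg <- fold_candidate(seq)$dG
      if (dg <= dg_band[2]) break
      stem <- c(sample(c("G", "C"), 1), stem)
    }
    # overshoot: weaken by swapping stem GC pairs for AT pairs
    weaken <- 0L
    while (dg < dg_band[1] && weaken < length(stem)) {
      weaken <- weaken + 1L
      stem[weaken] <- sample(c("A", "T"), 1)
      seq <- paste0(paste(stem, collapse = ""), loop,
                    revcomp(paste(stem, collapse = "")))
      dg <- fold_candidate(seq)$dG
    }
    if (dg >= dg_band[1] && dg <= dg_band[2]) {
      fold <- fold_candidate(seq)
      return(list(hairpin = seq, window = .window_for_class(uclass),
                  structure = fold$structure, dG = fold$dG, class = uclass))
    }
  }
  stop("generation error: infeasible free-energy band [",
       dg_band[1], ", ", dg_band[2], "]")
}

# a pad base that cannot pair (WC or GU) with the first window base, so the
# planted stem cannot be extended across the insertion boundary; never A, so
# the mirror-strand window stays U-poor
.nonpairing_pad <- function(first_base) {
  partners <- list(A = c("T"), C = c("G"), G = c("C", "T"),
                   T = c("A", "G"))
  setdiff(c("C", "T", "G", "A"), partners[[first_base]])[1]
}

#' Generate a synthetic genome fixture with planted ground truth
#'
#' Assembles a single-contig genome of `n_operons` operons on alternating
#' strands. Each SRPS operon carries one planted intergenic stabilizer SL
#' (SSL/STSL alternating) after a random non-terminal gene and no further
#' downstream SL, so its true stoichiometry ratio is 1 for the genes of the
#' upstream control unit and 0 after it. Non-SRPS operons carry no internal
#' stabilizer; some receive an operon-terminal terminator SL, and one (when
#' available) an internal terminator only. Read depths follow the
#' controlling-SL model of [fixture_spec()]; protein abundances add a
#' second noise draw on top of the depths.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, FASTA/GFF3/TSV files are
#'   written there.
#' @return list with `genome`, `genes`, `operons`, `depth`, `protein`,
#'   `cds`, and `truth` (planted SLs, per-gene true ratios, SRPS operon
#'   ids).
#' @export
make_fixture <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n_op <- spec$n_operons
  strands <- rep(c("+", "-"), length.out = n_op)
  srps_ops <- sort(sample(n_op, spec$n_srps))
  ssl_classes <- rep(c("SSL", "STSL"), length.out = spec$n_srps)
  non_srps <- setdiff(seq_len(n_op), srps_ops)
  term_ops <- non_srps[seq_len(ceiling(length(non_srps) / 2))]
  itsl_op <- if (length(non_srps) > length(term_ops))
    non_srps[length(term_ops) + 1L] else NA_integer_

  segs <- character(0)
  genes <- list(); op_rows <- list(); truth_sls <- list(); ratios <- list()
  cds <- character(0)
  depth <- numeric(0); protein <- numeric(0)
  cursor <- 0L

  rint <- function(rng) sample(seq(rng[1], rng[2]), 1)
  noise <- function() 10 ^ stats::rnorm(1, 0, spec$noise_sigma)

  for (op in seq_len(n_op)) {
    segs <- c(segs, background_seq(rint(spec$operon_gap),
                                   spec$gc_background, spec$bg_dg_floor))
    cursor <- cursor + nchar(segs[length(segs)])

    strand <- strands[op]
    n_genes <- rint(spec$genes_per_operon)
    is_srps <- op %in% srps_ops
    sl_after <- NA_integer_; sl_class <- NA_character_
    if (is_srps) {
      sl_after <- if (n_genes == 2) 1L else sample(n_genes - 1L, 1)
      sl_class <- ssl_classes[match(op, srps_ops)]
    } else if (!is.na(itsl_op) && op == itsl_op && n_genes >= 2) {
      sl_after <- if (n_genes == 2) 1L else sample(n_genes - 1L, 1)
      sl_class <- "TSL"
    }
    has_term <- op %in% term_ops

    # build the operon in transcript orientation, then place by strand
    tseq <- ""
    t_genes <- data.frame(gene = seq_len(n_genes), start = NA_integer_,
                          end = NA_integer_)
    gene_seqs <- character(n_genes)
    t_sls <- list()
    # The pad upstream of a planted hairpin is resampled until the local
    # fold of pad + hairpin + window is exactly the planted hairpin: no
    # accidental pairing may extend the stem across the insertion
    # boundary (which would shift the trimmed SL into a flanking gene).
    # The pad is long enough (>= 11 nt) that bases beyond it are out of
    # reach of the folder's interior-loop span, and its 3' end carries at
    # most two A so the mirror-strand window cannot mimic a poly(U) tail.
    add_sl <- function(tseq, uclass) {
      repeat {
        hp <- make_hairpin(spec$dg_band, uclass)
        want <- paste0(strrep(".", 11), hp$structure,
                       strrep(".", nchar(hp$window)))
        ok <- FALSE
        for (k in seq_len(50)) {
          core <- background_seq(10L, spec$gc_background, spec$bg_dg_floor)
          if (lengths(regmatches(core, gregexpr("A", core))) > 2) next
          pad5 <- paste0(core, .nonpairing_pad(substring(hp$window, 1, 1)))
          local <- fold_candidate(paste0(pad5, hp$hairpin, hp$window))
          if (local$structure == want) { ok <- TRUE; break }
        }
        if (ok) break
      }
      s <- nchar(tseq) + nchar(pad5) + 1L
      tseq <- paste0(tseq, pad5, hp$hairpin, hp$window)
      list(tseq = tseq, start = s, end = s + nchar(hp$hairpin) - 1L,
           dG = hp$dG, class = uclass, window = hp$window)
    }
    for (j in seq_len(n_genes)) {
      g <- random_cds(rint(spec$gene_len_codons))
      gene_seqs[j] <- g
      t_genes$start[j] <- nchar(tseq) + 1L
      t_genes$end[j] <- nchar(tseq) + nchar(g)
      tseq <- paste0(tseq, g)
      planted_here <- !is.na(sl_after) && j == sl_after
      win <- ""
      if (planted_here) {
        sl <- add_sl(tseq, sl_class)
        tseq <- sl$tseq
        win <- sl$window
        t_sls[[length(t_sls) + 1L]] <-
          data.frame(after_gene = j, class = sl$class, dG = sl$dG,
                     t_start = sl$start, t_end = sl$end, terminal = FALSE)
      }
      if (j < n_genes) {
        gap <- background_seq(rint(spec$intergenic_len), spec$gc_background,
                              spec$bg_dg_floor, prefix = win)
        tseq <- paste0(tseq, gap)
      }
    }
    if (has_term) {
      sl <- add_sl(tseq, "TSL")
      tseq <- sl$tseq
      t_sls[[length(t_sls) + 1L]] <-
        data.frame(after_gene = n_genes, class = sl$class, dG = sl$dG,
                   t_start = sl$start, t_end = sl$end, terminal = TRUE)
    }

    # transcript -> genomic coordinates
    L <- nchar(tseq)
    gseq <- if (strand == "+") tseq else revcomp(tseq)
    tmap <- function(a, b) {
      if (strand == "+") c(cursor + a, cursor + b)
      else c(cursor + L - b + 1L, cursor + L - a + 1L)
    }
    for (j in seq_len(n_genes)) {
      gid <- sprintf("op%02d_g%d", op, j)
      gc <- tmap(t_genes$start[j], t_genes$end[j])
      genes[[length(genes) + 1L]] <-
        data.frame(gene_id = gid, contig = "chr", start = gc[1], end = gc[2],
                   strand = strand, stringsAsFactors = FALSE)
      op_rows[[length(op_rows) + 1L]] <-
        data.frame(operon_id = op, gene_id = gid, order = j, strand = strand,
                   stringsAsFactors = FALSE)
      cds[gid] <- gene_seqs[j]
      # expression: |dG| of the nearest downstream control SL, else zero
      ctrl <- NA_real_
      if (length(t_sls)) {
        after <- vapply(t_sls, function(x) x$after_gene, 0)
        dgv <- vapply(t_sls, function(x) x$dG, 0)
        hit <- which(after >= j)[1]
        if (!is.na(hit)) ctrl <- abs(dgv[hit])
      }
      if (is.na(ctrl) && !is_srps && is.na(sl_class)) {
        # operon without any SL: flat expression at a nominal scale
        ctrl <- 25
      }
      d <- if (is.na(ctrl)) 0 else spec$base_depth * ctrl * noise()
      depth[gid] <- d
      protein[gid] <- if (d == 0) 0 else d * noise()
      ratios[[length(ratios) + 1L]] <-
        data.frame(operon_id = op, gene_id = gid,
                   ratio = if (is_srps && j > sl_after) 0 else 1,
                   stringsAsFactors = FALSE)
    }
    for (x in t_sls) {
      gc <- tmap(x$t_start, x$t_end)
      truth_sls[[length(truth_sls) + 1L]] <-
        data.frame(operon_id = op, after_gene = x$after_gene,
                   class = x$class, dG = x$dG, contig = "chr",
                   start = gc[1], end = gc[2], strand = strand,
                   terminal = x$terminal, stringsAsFactors = FALSE)
    }
    segs <- c(segs, gseq)
    cursor <- cursor + L
  }
  segs <- c(segs, background_seq(rint(spec$operon_gap), spec$gc_background,
                                 spec$bg_dg_floor))

  fixture <- list(
    genome = as_genome(c(chr = paste(segs, collapse = ""))),
    genes = do.call(rbind, genes),
    operons = do.call(rbind, op_rows),
    depth = data.frame(gene_id = names(depth), value = unname(depth),
                       stringsAsFactors = FALSE),
    protein = data.frame(gene_id = names(protein), value = unname(protein),
                         stringsAsFactors = FALSE),
    cds = cds,
    truth = list(sls = do.call(rbind, truth_sls),
                 ratios = do.call(rbind, ratios),
                 srps_operons = srps_ops,
                 spec = spec)
  )
  if (!is.null(dir)) write_fixture(fixture, dir)
  fixture
}

#' Write a fixture to disk in standard formats
#'
#' @param fixture result of [make_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(fixture$genome)),
    file.path(dir, "genome.fa"))
  write_gene_annotation(fixture$genes, file.path(dir, "genes.gff3"))
  utils::write.table(fixture$operons, file.path(dir, "operons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$depth, file.path(dir, "depth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$protein, file.path(dir, "protein.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$truth$sls, file.path(dir, "truth_sls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$truth$ratios, file.path(dir, "truth_ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
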