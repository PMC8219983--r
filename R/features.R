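#' Trim unpaired flanks from folded stem-loops
#'
#' Removes leading and trailing unpaired positions (dots before and after the
#' parentheses) from each structure, updating sequence, genomic coordinates
#' and total length so the structure begins with '(' and ends with ')'.
#' Idempotent.
#'
#' @param sls stem-loop data.frame from [discover_stemloops()].
#' @return trimmed stem-loop data.frame (ids regenerated from coordinates).
#' @export
trim_flanks <- function(sls) {
  if (!nrow(sls)) return(sls)
  if (any(!grepl("(", sls$structure, fixed = TRUE)))
    stop("empty-SL error: cannot trim an all-dot structure")
  lead <- regexpr("(", sls$structure, fixed = TRUE) - 1L
  trail <- nchar(sls$structure) -
    vapply(gregexpr(")", sls$structure, fixed = TRUE),
           function(m) m[length(m)], 0L)
  n <- nchar(sls$structure)
  sls$structure <- substring(sls$structure, lead + 1L, n - trail)
  sls$sequence <- substring(sls$sequence, lead + 1L, n - trail)
  plus <- sls$strand == "+"
  # 5' lead is at the genomic start on '+', at the genomic end on '-'
  sls$start <- sls$start + ifelse(plus, lead, trail)
  sls$end <- sls$end - ifelse(plus, trail, lead)
  sls$total_len <- sls$end - sls$start + 1L
  sls$id <- sl_id(sls)
  sls
}

#' Remove redundant stem-loops
#'
#' Applies the four quality-control constraints, in order: (iv) a free-energy
#' floor (retained SLs must have dG strictly below `dg_max`); (ii) removal of
#' SLs with identical (sequence, structure); (i) removal of SLs whose genomic
#' interval is contained in another retained SL's on the same strand; and
#' (iii) for partially overlapping same-strand pairs that are similar
#' (overlap fraction of the shorter SL above `overlap_min`, or fewer than
#' `mismatch_max` mismatching bases over the aligned overlap), only the
#' lower-dG member survives. At equal dG the 5'-most SL is kept.
#'
#' @param sls trimmed stem-loop data.frame.
#' @param dg_max free-energy floor in kcal/mol (strict: dG < dg_max).
#' @param overlap_min overlap fraction (of the shorter SL) above which two
#'   SLs are considered redundant.
#' @param mismatch_max Hamming-distance bound below which two overlapping
#'   SLs are considered redundant.
#' @return deduplicated stem-loop data.frame.
#' @export
deduplicate <- function(sls, dg_max = -5.0, overlap_min = 0.75,
                        mismatch_max = 3L) {
  sls <- sls[sls$dG < dg_max, , drop = FALSE]
  if (!nrow(sls)) return(sls)
  # most stable first; 5'-most wins ties
  sls <- sls[order(sls$dG, sls$start, sls$end), , drop = FALSE]
  sls <- sls[!duplicated(paste(sls$sequence, sls$structure)), , drop = FALSE]

  keep <- logical(nrow(sls))
  for (grp in split(seq_len(nrow(sls)),
                    paste(sls$contig, sls$strand))) {
    ks <- integer(0) # kept indices of this contig/strand, in dG order
    for (i in grp) {
      s <- sls$start[i]; e <- sls$end[i]
      redundant <- FALSE
      for (k in ks) {
        s2 <- sls$start[k]; e2 <- sls$end[k]
        ov <- min(e, e2) - max(s, s2) + 1L
        if (ov <= 0L) next
        if ((s2 <= s && e <= e2) || (s <= s2 && e2 <= e)) { # containment
          redundant <- TRUE; break
        }
        frac <- ov / min(e - s + 1L, e2 - s2 + 1L)
        if (frac > overlap_min ||
            overlap_mismatches(sls[i, ], sls[k, ], max(s, s2), min(e, e2)) <
              mismatch_max) {
          redundant <- TRUE; break
        }
      }
      if (!redundant) { keep[i] <- TRUE; ks <- c(ks, i) }
    }
  }
  out <- sls[keep, , drop = FALSE]
  out <- out[order(out$contig, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hamming distance between two same-strand SLs over a genomic overlap window.
overlap_mismatches <- function(a, b, o1, o2) {
  sub_seq <- function(sl) {
    if (sl$strand == "+") {
      substring(sl$sequence, o1 - sl$start + 1L, o2 - sl$start + 1L)
    } else {
      substring(sl$sequence, sl$end - o2 + 1L, sl$end - o1 + 1L)
    }
  }
  x <- strsplit(sub_seq(a), "")[[1]]
  y <- strsplit(sub_seq(b), "")[[1]]
  sum(x != y)
}

#' Poly(U) features of the 10-nt window downstream of a stem-loop
#'
#' Reads the `window_size` nt immediately 3' of each (trimmed) SL on the
#' SL's strand (clipped at the contig end; T counted as U) and derives the
#' longest run of consecutive U (`polyU_len`), the total U count
#' (`U_content`), and the tail position class:
#' * `downstream` - a genuine poly(U) run (length >= `min_run`) starting
#'   within the first `run_start_max` window positions;
#' * `upstream` - at least `min_run` U residues among the paired bases of
#'   the lower (3'-proximal) `upstream_frac` portion of the 3' stem side;
#' * `discontinuous` - U content >= `min_run` without a run of `min_run`;
#' * `none` otherwise.
#'
#' @param sls trimmed stem-loop data.frame.
#' @param genome the genome the SLs were discovered on.
#' @param window_size downstream window length, nt.
#' @param run_start_max latest window position at which a downstream poly(U)
#'   run may start.
#' @param min_run minimum U run/content used by the tail-position rules.
#' @param upstream_frac fraction of the 3' stem side, nearest the tail,
#'   inspected for the upstream rule.
#' @return `sls` with columns `window`, `polyU_len`, `U_content`,
#'   `tail_position` appended.
#' @export
u_features <- function(sls, genome, window_size = 10L, run_start_max = 3L,
                       min_run = 4L, upstream_frac = 0.4) {
  genome <- as_genome(genome)
  n <- nrow(sls)
  win <- character(n); polyU <- integer(n); ucont <- integer(n)
  tail <- character(n)
  clen <- nchar(genome)[match(sls$contig, names(genome))]
  for (i in seq_len(n)) {
    if (sls$strand[i] == "+") {
      w <- substring(genome[[sls$contig[i]]], sls$end[i] + 1L,
                     min(clen[i], sls$end[i] + window_size))
    } else {
      w <- substring(genome[[sls$contig[i]]],
                     max(1L, sls$start[i] - window_size), sls$start[i] - 1L)
      w <- if (nchar(w)) revcomp(w) else w
    }
    w <- chartr("T", "U", w)
    win[i] <- w
    ch <- strsplit(w, "")[[1]]
    ucont[i] <- sum(ch == "U")
    run_len <- 0L; run_start <- NA_integer_
    if (length(ch)) {
      r <- rle(ch == "U")
      if (any(r$values)) {
        run_len <- max(r$lengths[r$values])
        first_max <- which(r$values & r$lengths == run_len)[1]
        run_start <- if (first_max == 1) 1L
                     else sum(r$lengths[seq_len(first_max - 1L)]) + 1L
      }
    }
    polyU[i] <- run_len
    tail[i] <- if (run_len >= min_run && !is.na(run_start) &&
                   run_start <= run_start_max) {
      "downstream"
    } else if (stem_lower_u(sls$sequence[i], sls$structure[i],
                            upstream_frac) >= min_run) {
      "upstream"
    } else if (ucont[i] >= min_run && run_len < min_run) {
      "discontinuous"
    } else "none"
  }
  sls$window <- win
  sls$polyU_len <- polyU
  sls$U_content <- ucont
  sls$tail_position <- tail
  sls
}

# U count among the paired positions of the lower (3'-most) fraction of the
# 3' side of the stem
stem_lower_u <- function(sequence, structure, frac) {
  close_pos <- gregexpr(")", structure, fixed = TRUE)[[1]]
  if (close_pos[1] == -1) return(0L)
  k <- ceiling(frac * length(close_pos))
  pos <- close_pos[seq(length(close_pos) - k + 1L, length(close_pos))]
  ch <- strsplit(chartr("T", "U", sequence), "")[[1]]
  sum(ch[pos] == "U")
}

#' Stability factors S1-S4
#'
#' S1 = dG, S2 = dG / L, S3 = dG x sl, S4 = dG x sl / L, where dG is the
#' minimum folding free energy (kcal/mol), L the stem-loop length and sl the
#' stem length. `S4_norm` (and analogously for the other factors when used
#' for selection) is the factor divided by the cohort-wide minimum, so the
#' most stable SL scores 1.
#'
#' @param sls stem-loop data.frame with `dG`, `stem_len`, `total_len`.
#' @return `sls` with columns `S1`..`S4`, `S4_norm` appended.
#' @export
stability_scores <- function(sls) {
  if (!nrow(sls)) {
    for (col in c("S1", "S2", "S3", "S4", "S4_norm")) sls[[col]] <- numeric(0)
    return(sls)
  }
  if (any(sls$total_len <= 0 | sls$stem_len <= 0))
    stop("domain error: stem and total lengths must be positive")
  sls$S1 <- sls$dG
  sls$S2 <- sls$dG / sls$total_len
  sls$S3 <- sls$dG * sls$stem_len
  sls$S4 <- sls$dG * sls$stem_len / sls$total_len
  m <- min(sls$S4)
  sls$S4_norm <- if (m == 0) rep(0, nrow(sls)) else sls$S4 / m
  sls
}

#' Select the stable stem-loop set
#'
#' Retains SLs whose normalized stability factor (factor divided by the
#' cohort minimum, so the most stable SL scores 1) is at least `threshold`.
#'
#' @param sls stem-loop data.frame with stability columns (see
#'   [stability_scores()]; computed on the fly if absent).
#' @param score which stability factor to rank by (default `"S4"`).
#' @param threshold normalized-score cutoff in `[0, 1]` (default 0.60).
#' @return the stable subset of `sls`.
#' @export
select_stable <- function(sls, score = c("S4", "S1", "S2", "S3"),
                          threshold = 0.60) {
  score <- match.arg(score)
  if (!nrow(sls)) return(sls)
  if (is.null(sls[[score]])) sls <- stability_scores(sls)
  m <- min(sls[[score]])
  if (m >= 0) return(sls[0, , drop = FALSE])
  norm <- sls[[score]] / m
  out <- sls[norm >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intergenic enrichment along the stability ranking
#'
#' Diagnostic used to compare stability factors: SLs are ranked from most to
#' least stable under each factor and the fraction of intergenic SLs is
#' reported per consecutive rank window, mirroring the
#' "intergenic stem-loops per 100 SLs" selection diagnostic.
#'
#' @param sls stem-loop data.frame with stability scores and a `category`
#'   column (see [categorize_position()]).
#' @param scores stability factors to compare.
#' @param window rank-window width.
#' @return data.frame with columns `score`, `rank_window`, `n`,
#'   `intergenic_frac`.
#' @export
sl_enrichment <- function(sls, scores = c("S1", "S2", "S3", "S4"),
                          window = 100L) {
  stopifnot("category" %in% names(sls))
  out <- list()
  for (sc in scores) {
    ord <- order(sls[[sc]])
    blocks <- ceiling(seq_along(ord) / window)
    inter <- sls$category[ord] == "intergenic"
    out[[sc]] <- data.frame(
      score = sc,
      rank_window = as.integer(unique(blocks)),
      n = as.integer(table(blocks)),
      intergenic_frac = as.numeric(tapply(inter, blocks, mean)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
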