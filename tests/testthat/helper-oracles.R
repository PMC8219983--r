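# Independent oracles and shared fixtures for the test suite.

# --- base pairing (WC + optional GU), independent of the C++ encoding ------
pairs_ok <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  gu <- (a == "G" & b == "T") | (a == "T" & b == "G")
  if (allow_gu) wc | gu else wc
}

# --- declarative scanner oracle -------------------------------------------
# A candidate exists at (loop start a, loop length l) iff the loop-adjacent
# position pairs and the maximal stem s* (largest k <= stem_max with position
# k paired and at most max_mismatch mispairs among positions 1..k, all
# positions in bounds and N-free) satisfies s* >= stem_min.
scan_oracle_one_strand <- function(seq, d) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- list()
  for (a in 2:max(2, n - 1)) {
    for (l in d$loop_min:d$loop_max) {
      b <- a + l - 1L
      if (b > n - 1L) break
      if (any(ch[a:b] == "N")) next
      ks <- seq_len(d$stem_max)
      i <- a - ks; j <- b + ks
      ok <- i >= 1 & j <= n
      if (!any(ok)) next
      ks <- ks[ok]; i <- i[ok]; j <- j[ok]
      usable <- ch[i] != "N" & ch[j] != "N"
      if (!all(usable)) { # contiguity: stop at the first N
        stop_at <- which(!usable)[1] - 1L
        if (stop_at < 1) next
        ks <- ks[seq_len(stop_at)]; i <- i[seq_len(stop_at)]
        j <- j[seq_len(stop_at)]
      }
      p <- pairs_ok(ch[i], ch[j], d$allow_GU)
      if (!p[1]) next # loop-adjacent position must pair
      cum_mm <- cumsum(!p)
      valid <- p & cum_mm <= d$max_mismatch
      if (!any(valid)) next
      s <- max(which(valid))
      if (s >= d$stem_min)
        out[[length(out) + 1L]] <- c(start = a - s, end = b + s)
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  unique(as.data.frame(do.call(rbind, out)))
}

scan_oracle <- function(genome, d) {
  seq <- unclass(genome)[[1]]
  n <- nchar(seq)
  fw <- scan_oracle_one_strand(seq, d)
  fw$strand <- rep("+", nrow(fw))
  rc <- scan_oracle_one_strand(slofe:::revcomp(seq), d)
  rc <- data.frame(start = n - rc$end + 1L, end = n - rc$start + 1L,
                   strand = rep("-", nrow(rc)))
  out <- unique(rbind(fw, rc))
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# --- memoized recursive fold oracle ---------------------------------------
# Best single-hairpin energy by direct recursion over the closing pair, using
# the package's published parameter tables but an independent R evaluation.
fold_oracle <- function(seq, min_loop = 3L, allow_gu = TRUE,
                        pars = slofe_energy_params()) {
  ch <- strsplit(chartr("TU", "TT", toupper(seq)), "")[[1]]
  n <- length(ch)
  pair_name <- function(i, j) {
    key <- paste0(chartr("T", "U", ch[i]), chartr("T", "U", ch[j]))
    if (key %in% c("CG", "GC", "AU", "UA")) return(key)
    if (allow_gu && key %in% c("GU", "UG")) return(key)
    NA_character_
  }
  stack_tab <- slofe:::.stack37
  mm_tab <- slofe:::.mismatch_hairpin37
  rev_pair <- c(CG = "GC", GC = "CG", GU = "UG", UG = "GU",
                AU = "UA", UA = "AU")
  end_pen <- function(p) if (p %in% c("GU", "UG", "AU", "UA"))
    pars$term_au else 0
  loop_e <- function(tab, size) {
    if (size <= length(tab)) tab[size]
    else tab[length(tab)] + pars$lxc * log(size / length(tab))
  }
  memo <- new.env()
  closed <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    p <- pair_name(i, j)
    if (is.na(p) || j - i - 1 < min_loop) { memo[[key]] <- Inf; return(Inf) }
    ls <- j - i - 1
    best <- loop_e(pars$hp_init, ls)
    if (is.finite(best)) {
      best <- best + if (ls == 3) end_pen(p) else
        mm_tab[p, chartr("T", "U", ch[i + 1]), chartr("T", "U", ch[j - 1])]
    }
    for (k1 in 0:pars$max_intloop) {
      k <- i + 1 + k1
      if (k >= j - min_loop - 1) break
      for (k2 in 0:(pars$max_intloop - k1)) {
        l <- j - 1 - k2
        if (l - k < min_loop + 1) break
        p2 <- pair_name(k, l)
        if (is.na(p2)) next
        inner <- closed(k, l)
        if (!is.finite(inner)) next
        e <- if (k1 == 0 && k2 == 0) {
          stack_tab[p, rev_pair[[p2]]]
        } else if (k1 == 0 || k2 == 0) {
          loop_e(pars$bulge, k1 + k2) +
            if (k1 + k2 == 1) stack_tab[p, rev_pair[[p2]]]
            else end_pen(p) + end_pen(p2)
        } else {
          loop_e(pars$interior, k1 + k2) +
            min(pars$ninio_max, pars$ninio_m * abs(k1 - k2)) +
            end_pen(p) + end_pen(p2)
        }
        best <- min(best, e + inner)
      }
    }
    memo[[key]] <- best
    best
  }
  mfe <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i - 1 < min_loop) next
      p <- pair_name(i, j)
      if (is.na(p)) next
      e <- closed(i, j) + end_pen(p)
      if (is.finite(e)) mfe <- min(mfe, e)
    }
  }
  mfe
}

# --- misc helpers ----------------------------------------------------------
random_genome <- function(n, gc = 0.45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  as_genome(paste(sample(names(p), n, TRUE, prob = p), collapse = ""))
}

# minimal stem-loop table row
make_sl <- function(start, end, strand = "+", sequence, structure,
                    dG = -10, contig = "chr") {
  st <- slofe:::structure_stats(structure)
  data.frame(id = sprintf("%s:%d-%d(%s)", contig, start, end, strand),
             contig = contig, start = start, end = end, strand = strand,
             sequence = chartr("T", "U", sequence), structure = structure,
             dG = dG, stem_len = st$stem_len, loop_len = st$loop_len,
             total_len = end - start + 1L, stringsAsFactors = FALSE)
}

# one fixture + pipeline run shared across test files (built lazily)
.shared <- new.env()
shared_fixture <- function() {
  if (is.null(.shared$fx)) {
    .shared$fx <- make_fixture(fixture_spec(seed = 101L))
    .shared$res <- slofe_run(.shared$fx$genome, .shared$fx$genes,
                             .shared$fx$operons, depths = .shared$fx$depth)
  }
  list(fx = .shared$fx, res = .shared$res)
}
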