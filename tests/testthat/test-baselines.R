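# small codon helpers for constructed genes
codon_gene <- function(..., n = 1) {
  paste0("ATG", strrep(paste0(...), n), "TAA")
}

test_that("CAI is 1 for genes built from the reference's preferred codons", {
  # reference biased towards GCT (Ala) and AAA (Lys)
  ref <- c(codon_gene("GCT", "GCT", "GCT", "GCC", "AAA", "AAA", "AAG", n = 4),
           codon_gene("GCT", "AAA", n = 10))
  m <- codon_usage_model(ref, "CAI")
  best <- codon_gene("GCT", "AAA", n = 5)
  expect_equal(score_gene(best, m), 1.0)
  worse <- codon_gene("GCC", "AAG", n = 5)
  expect_lt(score_gene(worse, m), 1.0)
})

test_that("a uniform reference makes all genes equally adapted", {
  m <- codon_usage_model(character(0), "CAI") # all counts 0 -> pseudo-uniform
  set.seed(23)
  genes <- replicate(4, slofe:::random_cds(30))
  scores <- vapply(genes, score_gene, 0, model = m)
  expect_true(all(abs(scores - 1) < 1e-12))
})

test_that("CAI matches a hand-computed toy geometric mean and seqinr", {
  ref <- c(codon_gene("TTT", "TTC", "TTC", n = 3),   # Phe: TTC preferred
           codon_gene("GGT", "GGT", "GGC", n = 3))   # Gly: GGT preferred
  m <- codon_usage_model(ref, "CAI")
  gene <- codon_gene("TTT", "GGT")                   # w = 0.5, 1.0
  # also Met/stop excluded: CAI = (0.5 * 1)^(1/2)
  expect_equal(score_gene(gene, m), sqrt(0.5), tolerance = 1e-9)

  # independent cross-check against seqinr's CAI on the same weights
  w <- m$w
  names(w) <- tolower(names(w))
  s <- seqinr::s2c(tolower("TTTGGT"))
  expect_equal(score_gene(gene, m),
               as.numeric(seqinr::cai(s, w = w[order(names(w))],
                                      numcode = 1)),
               tolerance = 1e-6)
})

test_that("RCBS, RCA and MELP produce finite, bias-sensitive scores", {
  set.seed(41)
  ref <- replicate(12, slofe:::random_cds(40))
  genes <- replicate(5, slofe:::random_cds(40))
  for (method in c("RCA", "MELP")) {
    m <- codon_usage_model(ref, method)
    sc <- vapply(genes, score_gene, 0, model = m)
    expect_true(all(is.finite(sc)))
    expect_gt(stats::sd(sc), 0)
  }
  rcbs <- vapply(genes, score_gene, 0,
                 model = structure(list(method = "RCBS"),
                                   class = "codon_usage_model"))
  expect_true(all(is.finite(rcbs)))
  expect_true(all(rcbs > -1))
})

test_that("internal stop codons are skipped with a warning", {
  gene <- paste0("ATG", "AAA", "TAA", "AAA", "TAA")
  m <- codon_usage_model(codon_gene("AAA", n = 5), "CAI")
  expect_warning(s <- score_gene(gene, m), "internal stop")
  expect_equal(s, 1.0)
  expect_error(slofe:::split_codons("ACGTA"), "divisible by 3")
})

test_that("gene order descends linearly and single genes score 1 everywhere", {
  cds <- stats::setNames(replicate(4, slofe:::random_cds(30)), paste0("g", 1:4))
  ord <- baseline_ratio(cds, "order")
  expect_equal(ord$ratio, c(1.0, 0.75, 0.5, 0.25))
  one <- cds[1]
  for (method in c("cai", "rcbs", "rca", "melp", "order")) {
    expect_equal(baseline_ratio(one, method,
                                reference = c(cds, one))$ratio, 1.0)
  }
})

test_that("baseline ratios are invariant to gene-score rescaling", {
  set.seed(55)
  cds <- stats::setNames(replicate(4, slofe:::random_cds(35)), paste0("g", 1:4))
  m <- codon_usage_model(cds, "CAI")
  r1 <- baseline_ratio(cds, "cai", model = m)
  # normalization by the first gene makes any common rescaling vanish
  expect_equal(r1$ratio, round(r1$score / r1$score[1], 2))
  expect_equal(r1$ratio[1], 1.0)
})

test_that("SLOFE's fixture correlations beat every baseline's mean", {
  sh <- shared_fixture()
  fx <- sh$fx; res <- sh$res
  ops <- names(res$srps)
  log_depth <- function(gids) log10(fx$depth$value[
    match(gids, fx$depth$gene_id)] + 1)
  slofe_r <- vapply(ops, function(op) {
    p <- res$ratios[res$ratios$operon_id == as.integer(op), ]
    y <- log_depth(p$gene_id)
    if (stats::sd(p$ratio) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(p$ratio, y)
  }, 0)
  base_r <- function(method) {
    model <- if (method %in% c("cai", "rca", "melp"))
      codon_usage_model(fx$cds, toupper(method)) else NULL
    vapply(ops, function(op) {
      gids <- fx$operons$gene_id[fx$operons$operon_id == as.integer(op)]
      br <- baseline_ratio(fx$cds[gids], method, model = model)
      y <- log_depth(br$gene_id)
      if (stats::sd(br$ratio) == 0 || stats::sd(y) == 0) return(NA_real_)
      stats::cor(br$ratio, y)
    }, 0)
  }
  slofe_mean <- mean(slofe_r, na.rm = TRUE)
  for (method in c("cai", "rcbs", "rca", "melp", "order")) {
    bm <- mean(base_r(method), na.rm = TRUE)
    if (is.nan(bm)) bm <- 0
    expect_gt(slofe_mean, bm)
  }
})
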