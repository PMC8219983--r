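test_that("flank trimming removes outer dots and updates coordinates", {
  sl <- make_sl(100, 114, "+", "AAGGGGACCCCCCTT", "..((((....)))).")
  tr <- trim_flanks(sl)
  expect_equal(tr$structure, "((((....))))")
  expect_equal(tr$start, 102L)
  expect_equal(tr$end, 113L)
  expect_equal(tr$total_len, 12L)
  expect_equal(trim_flanks(tr), tr) # idempotent

  # on the minus strand the 5' lead sits at the genomic end
  slm <- make_sl(100, 114, "-", "AAGGGGACCCCCCTT", "..((((....)))).")
  trm <- trim_flanks(slm)
  expect_equal(trm$start, 101L)
  expect_equal(trm$end, 112L)

  bad <- make_sl(1, 8, "+", "AAAAAAAA", "........")
  expect_error(trim_flanks(bad), "empty-SL")
})

test_that("trimming is idempotent on discovered SLs", {
  g <- random_genome(800, seed = 31)
  tr <- trim_flanks(discover_stemloops(g))
  expect_equal(trim_flanks(tr), tr)
  expect_true(all(substr(tr$structure, 1, 1) == "("))
  expect_true(all(substr(tr$structure, nchar(tr$structure),
                         nchar(tr$structure)) == ")"))
})

test_that("deduplication applies the dG floor strictly", {
  a <- make_sl(10, 29, "+", strrep("A", 20), paste0("((((((....))))))...."),
               dG = -4.9)
  b <- make_sl(50, 69, "+", strrep("C", 20), paste0("((((((....))))))...."),
               dG = -5.1)
  kept <- deduplicate(rbind(a, b))
  expect_equal(kept$dG, -5.1)
  expect_equal(nrow(deduplicate(a)), 0L)
})

test_that("deduplication removes identical, contained and similar SLs", {
  seqA <- "GGGGGGAAAACCCCCC"
  strA <- "((((((....))))))"
  a1 <- make_sl(100, 115, "+", seqA, strA, dG = -12)
  a2 <- make_sl(100, 115, "+", seqA, strA, dG = -12) # identical
  expect_equal(nrow(deduplicate(rbind(a1, a2))), 1L)

  inner <- make_sl(102, 113, "+", "GGGGAAAACCCC", "((((....))))", dG = -8)
  expect_equal(deduplicate(rbind(a1, inner))$dG, -12) # containment

  # 80% overlap of the shorter: lower dG survives
  s1 <- make_sl(100, 119, "+", "GGGGGGGGAAAACCCCCCCC",
                "((((((((....))))))))", dG = -10)
  s2 <- make_sl(104, 123, "+", "GGGGAAAACCCCCCCCAAAA",
                "((((....))))........", dG = -7)
  kept <- deduplicate(rbind(s2, s1))
  expect_equal(kept$dG, -10)
  # order-insensitive
  expect_equal(deduplicate(rbind(s1, s2)), kept)

  # disjoint SLs with distinct sequences are both kept; dedup is idempotent
  far <- make_sl(300, 315, "+", "GCGCGCAAAAGCGCGC", strA, dG = -12)
  both <- deduplicate(rbind(a1, far))
  expect_equal(nrow(both), 2L)
  expect_equal(deduplicate(both), both)
})

test_that("deduplication is idempotent on a discovered SL set", {
  g <- random_genome(2000, gc = 0.5, seed = 17)
  dd <- deduplicate(trim_flanks(discover_stemloops(g)))
  expect_equal(deduplicate(dd), dd)
  expect_true(all(dd$dG < -5))
  # no containment on the same strand
  for (i in seq_len(nrow(dd))) {
    same <- dd[dd$strand == dd$strand[i], ]
    inside <- same$start <= dd$start[i] & same$end >= dd$end[i]
    expect_equal(sum(inside), 1L)
  }
})

test_that("U-window features match the worked feature patterns", {
  # terminator pattern: poly(U) 6, U content 7, downstream tail
  g1 <- as_genome(paste0("GGGGGG", "AAAA", "CCCCCC", "TTTTTTAGTA"))
  sl1 <- make_sl(1, 16, "+", "GGGGGGAAAACCCCCC", "((((((....))))))")
  f1 <- u_features(sl1, g1)
  expect_equal(f1$polyU_len, 6L)
  expect_equal(f1$U_content, 7L)
  expect_equal(f1$tail_position, "downstream")

  # no U at all
  g2 <- as_genome(paste0("GGGGGG", "AAAA", "CCCCCC", "GACGACGACG"))
  f2 <- u_features(sl1, g2)
  expect_equal(f2$polyU_len, 0L)
  expect_equal(f2$U_content, 0L)
  expect_equal(f2$tail_position, "none")

  # discontinuous: U content 4 without a run of 4
  g3 <- as_genome(paste0("GGGGGG", "AAAA", "CCCCCC", "TTATAGCTAC"))
  f3 <- u_features(sl1, g3)
  expect_equal(f3$polyU_len, 2L)
  expect_equal(f3$U_content, 4L)
  expect_equal(f3$tail_position, "discontinuous")

  # upstream: >= 4 U paired in the lower 40% of the 3' stem side
  sl4 <- make_sl(1, 20, "+", "AAAAGCGCCAACGCGCTTTT",
                 "((((((((....))))))))")
  expect_equal(slofe:::stem_lower_u(sl4$sequence, sl4$structure, 0.4), 4L)
  g4 <- as_genome(paste0("AAAAGCGCCAACGCGCTTTT", "GACGACGACG"))
  f4 <- u_features(sl4, g4)
  expect_equal(f4$tail_position, "upstream")
})

test_that("U-window features are strand-correct under mirroring", {
  core <- paste0("GGGGGG", "AAAA", "CCCCCC", "TTTTTTAGCA")
  pad <- strrep("A", 12)
  g <- as_genome(paste0(pad, core, pad))
  n <- nchar(unclass(g)[[1]])
  gm <- as_genome(c(chr = slofe:::revcomp(unclass(g)[[1]])))
  sl <- make_sl(13, 28, "+", "GGGGGGAAAACCCCCC", "((((((....))))))")
  slm <- make_sl(n - 28 + 1, n - 13 + 1, "-", "GGGGGGAAAACCCCCC",
                 "((((((....))))))")
  f <- u_features(sl, g)
  fm <- u_features(slm, gm)
  expect_equal(fm$window, f$window)
  expect_equal(fm$polyU_len, f$polyU_len)
  expect_equal(fm$U_content, f$U_content)
  expect_equal(fm$tail_position, f$tail_position)
})

test_that("stability factors follow their definitions", {
  sl <- make_sl(1, 26, "+", strrep("G", 26),
                paste0("((((((((", "..........", "))))))))"), dG = -20)
  sl$stem_len <- 8L; sl$total_len <- 26L
  sc <- stability_scores(sl)
  expect_equal(sc$S1, -20)
  expect_equal(sc$S2, -20 / 26)
  expect_equal(sc$S3, -160)
  expect_equal(sc$S4, -20 * 8 / 26, tolerance = 1e-12)
  expect_equal(round(sc$S4, 3), -6.154)
  expect_equal(sc$S4_norm, 1.0) # cohort of one

  z <- sl; z$dG <- 0
  expect_equal(stability_scores(z)[, c("S1", "S2", "S3", "S4")],
               data.frame(S1 = 0, S2 = 0, S3 = 0, S4 = 0),
               ignore_attr = TRUE)
})

test_that("stable selection applies the normalized threshold monotonically", {
  sls <- do.call(rbind, lapply(1:3, function(i)
    make_sl(i * 100, i * 100 + 15, "+", "GGGGGGAAAACCCCCC",
            "((((((....))))))", dG = c(-20, -14, -6)[i])))
  sc <- stability_scores(sls)
  expect_equal(nrow(select_stable(sc, threshold = 0.6)), 2L)
  expect_equal(nrow(select_stable(sc, threshold = 0)), 3L)
  # raising the threshold never adds an SL
  sizes <- vapply(seq(0, 1, by = 0.1), function(th)
    nrow(select_stable(sc, threshold = th)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("S4 ranks planted intergenic SLs at least as well as S1-S3", {
  sh <- shared_fixture()
  res <- sh$res
  sls <- categorize_position(stability_scores(deduplicate(trim_flanks(
    res$sls))), sh$fx$genes)
  truth <- sh$fx$truth$sls
  planted_hit <- function(df) {
    hits <- vapply(seq_len(nrow(df)), function(i) {
      any(truth$strand == df$strand[i] &
            pmin(truth$end, df$end[i]) - pmax(truth$start, df$start[i]) + 1 >=
            0.8 * (truth$end - truth$start + 1))
    }, TRUE)
    sum(hits & df$category == "intergenic")
  }
  top100 <- function(score) {
    ord <- order(sls[[score]])
    planted_hit(sls[ord[seq_len(min(100, nrow(sls)))], ])
  }
  expect_gte(top100("S4"), max(top100("S1"), top100("S2"), top100("S3")))
})
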