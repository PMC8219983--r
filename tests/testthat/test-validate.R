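test_that("NRD reproduces the printed flanking-depth examples", {
  expect_equal(nrd(3094, 74), 3020 / 3094, tolerance = 1e-12)
  expect_equal(nrd_percent(3094, 74), 97)
  expect_equal(nrd(18300, 2367), 15933 / 18300, tolerance = 1e-12)
  expect_equal(nrd_percent(18300, 2367), 87)
  expect_equal(nrd(5, 5), 0)
  expect_true(is.na(nrd(0, 0)))
})

test_that("NRD is antisymmetric, bounded, and maximal at zero 3' depth", {
  set.seed(19)
  a <- runif(200, 0, 1e5); b <- runif(200, 0, 1e5)
  expect_equal(nrd(a, b), -nrd(b, a))
  expect_true(all(abs(nrd(a, b)) <= 1))
  expect_true(all(nrd(a[a > 0], 0) == 1))
})

make_cands <- function(rd) {
  n <- nrow(rd)
  data.frame(id = sprintf("SL%d", seq_len(n)), contig = "chr",
             start = seq_len(n) * 100L, end = seq_len(n) * 100L + 20L,
             strand = "+", dG = rd$dG,
             class = rd$class, operon_id = rd$op,
             upstream_gene = rd$up, downstream_gene = rd$dn,
             stringsAsFactors = FALSE)
}

test_that("SL validation applies the threshold and reports missing data", {
  cands <- make_cands(data.frame(
    class = c("SSL", "STSL", "TSL", "SSL"),
    op = "1", dG = c(-20, -15, -10, -18),
    up = c("gA", "gB", "gC", "gD"), dn = c("gB", "gC", "gD", "gZ"),
    stringsAsFactors = FALSE))
  depths <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                       value = c(1000, 400, 90, 80))
  rec <- validate_sls(cands, depths, threshold = 0.5)
  # terminator candidates are excluded up front
  expect_equal(rec$sl_id, c("SL1", "SL2", "SL4"))
  expect_equal(rec$passed[1:2], c(TRUE, TRUE))
  expect_equal(rec$status[3], "no_data")
  expect_true(is.na(rec$nrd[3]))
  # passed <=> nrd strictly above the threshold
  ok <- !is.na(rec$passed)
  expect_equal(rec$passed[ok], rec$nrd[ok] > 0.5)

  # at threshold 1.0 only a zero 3' depth can reach nrd = 1, and the strict
  # inequality excludes even that
  depths0 <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                        value = c(1000, 0, 90, 80))
  rec1 <- validate_sls(cands, depths0, threshold = 1.0)
  expect_equal(rec1$nrd[1], 1)
  expect_false(rec1$passed[1])
})

test_that("the dG-rescue pass requires a positive depth-stability trend", {
  cands <- make_cands(data.frame(
    class = "SSL", op = "1",
    dG = c(-30, -20, -10),
    up = c("gA", "gB", "gC"), dn = c("gB", "gC", "gD"),
    stringsAsFactors = FALSE))
  # depths track |dG| but the drops are shallow: all fail at 0.5
  depths <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                       value = c(3000, 2000, 1000, 900))
  plain <- validate_sls(cands, depths, threshold = 0.5)
  expect_false(any(plain$passed))
  rescued <- validate_sls(cands, depths, threshold = 0.5, dg_rescue = TRUE)
  expect_true(all(rescued$passed))
  expect_true(all(rescued$status == "rescued"))
})

test_that("ratio correlation is exact for affine data and sign-correct", {
  pred <- data.frame(operon_id = 1L, gene_id = paste0("g", 1:5),
                     control_sl = "SL1", dG = -20,
                     ratio = c(1, 0.9, 0.7, 0.5, 0.3))
  expr <- data.frame(gene_id = paste0("g", 1:5),
                     value = 10 ^ (2 + 3 * pred$ratio))
  expect_equal(correlate_ratio(pred, expr)$r, 1.0)
  anti <- data.frame(gene_id = paste0("g", 1:5),
                     value = 10 ^ (2 - 3 * pred$ratio))
  expect_equal(correlate_ratio(pred, anti)$r, -1.0)
  # scale invariance
  scaled <- expr; scaled$value <- scaled$value * 1e3
  expect_equal(correlate_ratio(pred, scaled)$r, 1.0)
  # too few genes or zero variance: not computed
  expect_false(correlate_ratio(pred[1:2, ], expr)$computed)
  flat <- pred; flat$ratio <- 1
  expect_false(correlate_ratio(flat, expr)$computed)
})

test_that("correlation beats 0.9 in at least 95 of 100 noisy replicates", {
  pred <- data.frame(operon_id = 1L, gene_id = paste0("g", 1:6),
                     control_sl = "SL1", dG = -20,
                     ratio = c(1, 1, 0.8, 0.6, 0.4, 0.2))
  set.seed(77)
  hits <- sum(replicate(100, {
    expr <- data.frame(gene_id = pred$gene_id,
                       value = 10 ^ (pred$ratio + rnorm(6, 0, 0.1)))
    correlate_ratio(pred, expr)$r > 0.9
  }))
  expect_gte(hits, 95)
})
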