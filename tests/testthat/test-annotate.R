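toy_genes <- data.frame(
  gene_id = c("gPlus", "gMinus"),
  contig = "chr",
  start = c(101L, 301L),
  end = c(200L, 400L),
  strand = c("+", "-"),
  stringsAsFactors = FALSE)

# independent interval classifier used as the oracle for the sweep
category_oracle <- function(s, e, genes) {
  ov <- genes[genes$start <= e & genes$end >= s, , drop = FALSE]
  if (nrow(ov) == 0) return("intergenic")
  if (any(ov$start <= s & e <= ov$end)) return("intragenic")
  if (nrow(ov) >= 2) return("overlapped_with_two_genes")
  g <- ov[1, ]
  crosses_left <- s < g$start
  crosses_right <- e > g$end
  if (crosses_left && crosses_right) return("overlapped_with_two_genes")
  end3 <- if (g$strand == "+") crosses_right else crosses_left
  if (end3) "overlapped_on_3" else "overlapped_on_5"
}

test_that("positional categories match a brute-force classifier everywhere", {
  len <- 20L
  starts <- seq(1L, 440L)
  sls <- do.call(rbind, lapply(starts, function(s)
    make_sl(s, s + len - 1L, "+", strrep("G", len),
            paste0("((((((....))))))", strrep(".", len - 16)))))
  got <- categorize_position(sls, toy_genes)$category
  want <- vapply(starts, function(s) category_oracle(s, s + len - 1L,
                                                     toy_genes), "")
  expect_equal(got, want)
  # every SL gets exactly one category
  expect_true(all(got %in% c("intragenic", "intergenic", "overlapped_on_3",
                             "overlapped_on_5", "overlapped_with_two_genes")))
})

test_that("boundary-crossing SLs are named after the gene end they cross", {
  # + strand gene [101,200]: crossing its stop boundary is the 3' end
  sl <- make_sl(190, 209, "+", strrep("G", 20),
                "((((((....))))))....")
  expect_equal(categorize_position(sl, toy_genes)$category, "overlapped_on_3")
  # - strand gene [301,400]: its 3' end is the genomic left boundary
  sl2 <- make_sl(295, 310, "+", strrep("G", 16), "((((((....))))))")
  expect_equal(categorize_position(sl2, toy_genes)$category, "overlapped_on_3")
  sl3 <- make_sl(395, 410, "+", strrep("G", 16), "((((((....))))))")
  expect_equal(categorize_position(sl3, toy_genes)$category, "overlapped_on_5")
})

op4 <- data.frame(operon_id = 1L,
                  gene_id = paste0("g", 1:4),
                  order = 1:4,
                  strand = "+")
genes4 <- data.frame(gene_id = paste0("g", 1:4), contig = "chr",
                     start = c(1L, 201L, 401L, 601L),
                     end = c(150L, 350L, 550L, 750L),
                     strand = "+", stringsAsFactors = FALSE)

test_that("operon context separates intra- from inter-operonic SLs", {
  sl <- make_sl(360, 380, "+", strrep("G", 21),
                "((((((.....))))))....")
  sl <- categorize_position(sl, genes4)
  ctx <- operon_context(sl, op4, genes4)
  expect_equal(ctx$operon_context, "intra_operonic")
  expect_equal(ctx$operon_id, "1")
  expect_equal(ctx$upstream_gene, "g2")
  expect_equal(ctx$downstream_gene, "g3")

  after <- make_sl(760, 780, "+", strrep("G", 21),
                   "((((((.....))))))....")
  after <- categorize_position(after, genes4)
  ctx2 <- operon_context(after, op4, genes4)
  expect_equal(ctx2$operon_context, "inter_operonic")
  expect_equal(ctx2$upstream_gene, "g4")

  # non-intergenic SLs get not_applicable
  inside <- categorize_position(
    make_sl(50, 69, "+", strrep("G", 20), "((((((....))))))...."), genes4)
  expect_equal(operon_context(inside, op4, genes4)$operon_context,
               "not_applicable")

  # flanking gene missing from the operon map is a reference error
  op_bad <- op4[op4$gene_id != "g3", ]
  expect_error(operon_context(sl, op_bad, genes4), "reference error")
})

test_that("context assignment is invariant under coordinate translation", {
  sl <- categorize_position(
    make_sl(360, 380, "+", strrep("G", 21), "((((((.....))))))...."), genes4)
  base <- operon_context(sl, op4, genes4)
  shift <- 5000L
  genes_s <- genes4; genes_s$start <- genes_s$start + shift
  genes_s$end <- genes_s$end + shift
  sl_s <- categorize_position(
    make_sl(360 + shift, 380 + shift, "+", strrep("G", 21),
            "((((((.....))))))...."), genes_s)
  shifted <- operon_context(sl_s, op4, genes_s)
  expect_equal(shifted$operon_context, base$operon_context)
  expect_equal(shifted$upstream_gene, base$upstream_gene)
  expect_equal(shifted$downstream_gene, base$downstream_gene)
})

test_that("fixture operon contexts agree with the planted truth", {
  sh <- shared_fixture()
  cls <- sh$res$classified
  truth <- sh$fx$truth$sls
  for (i in seq_len(nrow(truth))) {
    hit <- cls[cls$strand == truth$strand[i] &
                 pmin(cls$end, truth$end[i]) - pmax(cls$start, truth$start[i]) +
                   1 >= 0.8 * (truth$end[i] - truth$start[i] + 1), ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$operon_context,
                 if (truth$terminal[i]) "inter_operonic" else "intra_operonic")
  }
})
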