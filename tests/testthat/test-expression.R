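test_that("rpkm follows its closed form and scaling laws", {
  expect_equal(rpkm(100, 1000, 1e6), 100)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  # doubling count and library together leaves RPKM unchanged
  expect_equal(rpkm(100, 1000, 1e6), rpkm(200, 1000, 2e6))
  # linear in count, inverse-linear in length and library
  expect_equal(rpkm(300, 1000, 1e6), 3 * rpkm(100, 1000, 1e6))
  expect_equal(rpkm(100, 2000, 1e6), rpkm(100, 1000, 1e6) / 2)
  expect_equal(rpkm(100, 1000, 2e6), rpkm(100, 1000, 1e6) / 2)
  expect_error(rpkm(1, 0, 1e6), "length_bp")
  expect_error(rpkm(1, 1000, 0), "library_size")
  expect_error(rpkm(-1, 1000, 1e6), "non-negative")
})

test_that("screen applies strict thresholds on abundance and fold change", {
  mk <- function(rpkm_a, rpkm_b) {
    # one gene, 1 kb, library 1e6 per replicate: counts equal RPKM / 1000 * 1e6 / 1e9...
    # choose length 1000 bp and library 1e6 so count == RPKM
    expression_table(data.frame(gene_id = "g1", length_bp = 1000),
                     matrix(round(rpkm_a), 1, 3),
                     matrix(round(rpkm_b), 1, 3),
                     list(A = rep(1e6, 3), B = rep(1e6, 3)))
  }
  # abundance floor is strict: both means at 49 are excluded even at huge FC
  expect_equal(nrow(screen_expression(mk(c(49, 49, 49), c(1, 1, 1)))), 0)
  # log2 FC exactly 1.0 is excluded (eps = 0 isolates the boundary)
  t2 <- mk(c(100, 100, 100), c(200, 200, 200))
  expect_equal(nrow(screen_expression(t2, eps = 0)), 0)
  # just past both thresholds passes
  t3 <- mk(c(100, 100, 100), c(201, 201, 201))
  hits <- screen_expression(t3, eps = 0)
  expect_equal(hits$gene_id, "g1")
  expect_equal(hits$direction, "up")
  # induced from near zero is kept in "max" mode, dropped in "both" mode
  t4 <- mk(c(0, 0, 0), c(300, 300, 300))
  expect_equal(nrow(screen_expression(t4)), 1)
  expect_equal(nrow(screen_expression(t4, abundance = "both")), 0)
})

test_that("the screen recovers exactly the planted genes", {
  gen <- generate_expression_table(500, 25, seed = 11)
  hits <- screen_expression(gen$table)
  expect_setequal(intersect(hits$gene_id, gen$truth$gene_id),
                  gen$truth$gene_id)  # full recall
  # direction agrees with the planted truth
  m <- merge(hits, gen$truth, by = "gene_id")
  expect_identical(m$direction.x, m$direction.y)
  # false positives are rare (noise only)
  expect_lt(nrow(hits) - 25, 0.01 * 500)
})

test_that("screen output is order-invariant and sorted by |log2FC|", {
  gen <- generate_expression_table(200, 10, seed = 4)
  t1 <- gen$table
  perm <- sample(nrow(t1$genes))
  t2 <- expression_table(t1$genes[perm, ], t1$counts_a[perm, ],
                         t1$counts_b[perm, ], t1$library_sizes)
  h1 <- screen_expression(t1); h2 <- screen_expression(t2)
  expect_identical(h1$gene_id, h2$gene_id)
  expect_true(all(diff(abs(h1$log2fc)) <= 0))
})

test_that("raising either threshold never admits more genes", {
  gen <- generate_expression_table(300, 15, seed = 9)
  n_base <- nrow(screen_expression(gen$table))
  for (rmin in c(50, 100, 200))
    expect_lte(nrow(screen_expression(gen$table, rpkm_min = rmin)), n_base)
  for (lmin in c(1, 1.5, 2))
    expect_lte(nrow(screen_expression(gen$table, log2fc_min = lmin)), n_base)
})

test_that("a signal-free table yields almost no hits across seeds", {
  fp <- vapply(1:20, function(s) {
    gen <- generate_expression_table(400, 0, seed = s)
    nrow(screen_expression(gen$table))
  }, 0L)
  expect_lt(mean(fp), 0.01 * 400)
})

test_that("generation is deterministic and respects its contract", {
  a <- generate_expression_table(100, 5, seed = 42)
  b <- generate_expression_table(100, 5, seed = 42)
  expect_identical(a, b)
  expect_error(generate_expression_table(10, 11, seed = 1), "n_planted")
  expect_equal(nrow(a$truth), 5)
})

test_that("expression TSV round trip preserves counts and library sizes", {
  gen <- generate_expression_table(50, 5, seed = 13)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(gen$table, path)
  t2 <- read_expression_table(path)
  expect_equal(gen$table$genes$gene_id, t2$genes$gene_id)
  expect_equal(unname(gen$table$counts_a), unname(t2$counts_a))
  expect_equal(unname(gen$table$counts_b), unname(t2$counts_b))
  expect_equal(as.numeric(gen$table$library_sizes$A),
               as.numeric(t2$library_sizes$A))
  expect_identical(screen_expression(gen$table), screen_expression(t2))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlength_bp\tA_rep1\tB_rep1", "g1\t100\t1\t2"), bad)
  expect_error(read_expression_table(bad), "library_sizes")
})
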