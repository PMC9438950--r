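test_that("nx follows the >=half prefix convention", {
  r <- nx(c(10, 8, 6, 4, 2), 50, 30)
  expect_equal(r$nx, 8)
  expect_equal(r$lx, 2)
  expect_equal(nx(c(42), 50)$nx, 42)
  expect_equal(nx(c(42), 50)$lx, 1)
  rg <- nx(c(10, 8, 6, 4, 2), 50, 40)   # NG50 against a genome size
  expect_equal(rg$nx, 6)
  expect_equal(rg$lx, 3)
  # exact half: the first qualifying prefix counts
  rh <- nx(c(5, 5), 50)
  expect_equal(rh$nx, 5)
  expect_equal(rh$lx, 1)
  expect_error(nx(c(1, 2), 50, 0), "reference_total")
  expect_error(nx(numeric(), 50), "non-empty")
  # NGx undefined when the target exceeds the assembly
  far <- nx(c(10, 8), 90, 100)
  expect_true(is.na(far$nx))
})

test_that("aun is the length-weighted mean length", {
  expect_equal(aun(c(10, 8, 6, 4, 2)), 7.33)
  expect_equal(aun(17), 17)
  expect_equal(aun(c(3, 3, 3)), 3)
  expect_true(is.na(aun(numeric())))
})

test_that("nx and aun match the brute-force oracle on random multisets", {
  withr::local_seed(7011)
  for (rep in 1:200) {
    lens <- sample(1:500, sample(1:40, 1), replace = TRUE)
    x <- sample(c(10, 25, 50, 75, 90), 1)
    ref <- if (runif(1) < 0.5) sum(lens) else round(sum(lens) * runif(1, 0.5, 1.5))
    if (ref <= 0) ref <- sum(lens)
    mine <- nx(lens, x, ref)
    oracle <- naive_nx(lens, x, ref)
    expect_equal(mine$nx, oracle$nx)
    expect_equal(mine$lx, oracle$lx)
    expect_equal(aun(lens), round(sum(lens^2) / sum(lens), 2))
  }
})

test_that("Nx is non-increasing and Lx non-decreasing in x", {
  withr::local_seed(88)
  for (rep in 1:20) {
    lens <- sample(1:1000, 30, replace = TRUE)
    xs <- seq(5, 100, by = 5)
    res <- lapply(xs, function(x) nx(lens, x))
    nxs <- vapply(res, function(r) r$nx, numeric(1))
    lxs <- vapply(res, function(r) r$lx, numeric(1))
    expect_true(all(diff(nxs) <= 0))
    expect_true(all(diff(lxs) >= 0))
  }
})

test_that("base composition counts cases and ambiguity separately", {
  asm <- make_asm(c(s = "ACGT"))
  bc <- base_composition(asm)
  expect_equal(bc$gc_content, 50)
  expect_equal(unname(bc$base_counts[c("A", "C", "G", "T")]), rep(1, 4))

  soft <- new_assembly() |> add_segment("s", "acgGGG")
  bs <- base_composition(soft)
  expect_equal(bs$soft_masked, 3)
  expect_equal(bs$gc_content, 83.33)

  amb <- new_assembly() |> add_segment("s", "ACGTRY")
  ba <- base_composition(amb)
  expect_equal(unname(ba$base_counts["other"]), 2)
  expect_equal(ba$gc_content, 50)  # ambiguity excluded from the denominator

  be <- base_composition(new_assembly())
  expect_true(all(be$base_counts == 0))
  expect_true(is.na(be$gc_content))
})

test_that("summarize_assembly fills the three-tier report", {
  asm <- make_asm(c(sc1 = "ACGNNNTTG"))
  st <- summarize_assembly(asm)
  expect_equal(st$n_scaffolds, 1)
  expect_equal(st$n_contigs, 2)
  expect_equal(st$n_gaps, 1)
  expect_equal(st$total_scaffold_len, 9)
  expect_equal(st$total_contig_len, 6)
  expect_equal(st$total_gap_len, 3)
  expect_equal(st$scaffold_n50, 9)
  expect_equal(st$contig_n50, 3)
  expect_equal(st$scaffold_l50, 1)
  expect_equal(st$n_count, 3)
  expect_equal(st$graph_components, 1)

  empty <- summarize_assembly(new_assembly())
  expect_equal(empty$n_scaffolds, 0)
  expect_equal(empty$total_scaffold_len, 0)
  expect_true(is.na(empty$scaffold_n50))

  stg <- summarize_assembly(asm, genome_size = 20)
  expect_true(is.na(stg$scaffold_ng50))  # 50% of 20 exceeds the assembly
  stg2 <- summarize_assembly(asm, genome_size = 12)
  expect_equal(stg2$scaffold_ng50, 9)
  expect_equal(stg2$scaffold_lg50, 1)
})

test_that("a SAK split updates the report with conserved contig bases", {
  asm <- fig1b_assembly()
  before <- summarize_assembly(asm)
  res <- sak_execute(asm, "SPLIT A B")
  after <- summarize_assembly(res$assembly)
  expect_equal(after$n_scaffolds, before$n_scaffolds + 1)
  expect_equal(after$total_contig_len, before$total_contig_len)
  expect_equal(after$total_scaffold_len,
               before$total_scaffold_len - 10)  # the dropped gap c
})

test_that("summary statistics are invariant to scaffold order", {
  fx <- generate_fixture(n_scaffolds = 6, seed = 3)
  shuffled <- sort_assembly(fx$assembly, by = "length", descending = TRUE)
  a <- summarize_assembly(fx$assembly)
  b <- summarize_assembly(shuffled)
  skip_fields <- c("scaffold_lengths", "contig_lengths")
  for (f in setdiff(names(a), skip_fields)) {
    expect_equal(a[[f]], b[[f]], info = f)
  }
})

test_that("per-sequence rows add up to the report totals", {
  asm <- make_asm(c(sc1 = "ACGNNNTTG"))
  tbl <- per_sequence_stats(asm)
  expect_equal(tbl$name, "sc1")
  expect_equal(tbl$length, 9)
  expect_equal(tbl$n_contigs, 2L)
  expect_equal(tbl$n_gaps, 1L)
  expect_equal(tbl$gap_bp, 3)
  expect_equal(tbl$gc, 50)  # GC of ACGTTG

  gapless <- make_asm(c(s = "ACGT"))
  t2 <- per_sequence_stats(gapless)
  expect_equal(t2$n_gaps, 0L)
  expect_equal(t2$gap_bp, 0)

  fx <- generate_fixture(n_scaffolds = 5, seed = 9)
  t3 <- per_sequence_stats(fx$assembly)
  st <- summarize_assembly(fx$assembly)
  expect_equal(nrow(t3), 5)
  expect_equal(sum(t3$length), st$total_scaffold_len)
  expect_equal(sum(t3$n_contigs), st$n_contigs)
  expect_equal(sum(t3$gap_bp), st$total_gap_len)
})

test_that("tidy/glance/autoplot expose the report as tibbles and a plot", {
  st <- summarize_assembly(make_asm(c(sc1 = "ACGNNNTTG")))
  td <- tidy(st)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("metric", "value") %in% names(td)))
  g <- glance(st)
  expect_equal(nrow(g), 1)
  expect_equal(g$scaffold_n50, 9)
  p <- ggplot2::autoplot(st)
  expect_s3_class(p, "ggplot")
})
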