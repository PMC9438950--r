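test_that("name selection keeps list order, then excludes, with pruning", {
  asm <- make_asm(c(sc1 = "ACGT", sc2 = "GGCC", sc3 = "TTAA"))
  inc <- apply_selection(asm, include_names = c("sc3", "sc1"))
  expect_equal(inc$paths$name, c("sc3", "sc1"))
  expect_equal(nrow(inc$segments), 2)

  exc <- apply_selection(asm, exclude_names = "sc2")
  expect_equal(exc$paths$name, c("sc1", "sc3"))

  expect_identical(apply_selection(asm)$paths$name, asm$paths$name)
  expect_warning(apply_selection(asm, include_names = "nope"), "nope")
  expect_error(apply_selection(asm, include_names = "nope", strict = TRUE),
               "nope")
})

test_that("interval extraction slices segments and flags pure-gap regions", {
  asm <- make_asm(c(sc1 = "ACGNNNTTG"))
  bed <- tibble::tibble(chrom = "sc1", start = 2L, end = 8L)
  out <- apply_selection(asm, include_bed = bed)
  expect_equal(out$paths$name, "sc1:2-8")
  expect_equal(unname(linearize_paths(out)), "GNNNTT")

  gap_only <- tibble::tibble(chrom = "sc1", start = 3L, end = 6L)
  expect_warning(g <- apply_selection(asm, include_bed = gap_only),
                 "only gap")
  expect_equal(nrow(g$segments), 0)
  expect_equal(unname(path_lengths(g)), 3)

  expect_error(apply_selection(
    asm, include_bed = tibble::tibble(chrom = "sc1", start = 0L, end = 99L)),
    "out of bounds")

  excl <- apply_selection(
    asm, exclude_bed = tibble::tibble(chrom = "sc1", start = 3L, end = 6L))
  expect_equal(unname(linearize_paths(excl)), "ACGTTG")
})

test_that("selection then stats equals stats of the selected subset", {
  fx <- generate_fixture(n_scaffolds = 6, seed = 41)
  keep <- fx$assembly$paths$name[c(2, 5)]
  sel <- apply_selection(fx$assembly, include_names = keep)
  st <- summarize_assembly(sel)
  per <- per_sequence_stats(fx$assembly)
  expect_equal(st$total_scaffold_len, sum(per$length[match(keep, per$name)]))
  expect_equal(st$n_scaffolds, 2)
})

test_that("sorting permutes order only, stably, with natural names", {
  asm <- make_asm(c(a = "AAAAA", b = "AAAAAAAAA", c = "AAAAAAA"))
  bylen <- sort_assembly(asm, by = "length", descending = TRUE)
  expect_equal(unname(path_lengths(bylen)), c(9, 7, 5))

  nat <- make_asm(c(s2 = "AA", s10 = "CC", s1 = "GG"))
  expect_equal(sort_assembly(nat, by = "name")$paths$name,
               c("s1", "s2", "s10"))

  twice <- sort_assembly(sort_assembly(asm, by = "length"), by = "length")
  expect_identical(twice$paths$name,
                   sort_assembly(asm, by = "length")$paths$name)

  lst <- sort_assembly(asm, by = "list", custom_order = c("c", "a"))
  expect_equal(lst$paths$name, c("c", "a", "b"))
  expect_error(sort_assembly(asm, by = "list"), "custom_order")

  st_a <- summarize_assembly(asm)
  st_b <- summarize_assembly(bylen)
  expect_equal(st_a$total_scaffold_len, st_b$total_scaffold_len)
  expect_equal(st_a$scaffold_n50, st_b$scaffold_n50)
})

test_that("homopolymer compression collapses runs and tracks lengths", {
  asm <- new_assembly() |> add_segment("s1", "AAACCGTT")
  hp <- homopolymer_compress(asm)
  expect_equal(hp$assembly$segments$sequence, "ACGT")
  expect_equal(hp$tracks$runs[[1]], c(3L, 2L, 1L, 2L))

  fixed <- homopolymer_compress(new_assembly() |> add_segment("s", "ACGT"))
  expect_equal(fixed$assembly$segments$sequence, "ACGT")
  expect_equal(fixed$tracks$runs[[1]], rep(1L, 4))

  empty <- homopolymer_compress(new_assembly() |> add_segment("s", ""))
  expect_equal(empty$assembly$segments$sequence, "")
  expect_equal(empty$tracks$runs[[1]], integer())

  # a soft-masking (case) boundary ends a run, keeping the round trip exact
  mixed <- homopolymer_compress(new_assembly() |> add_segment("s", "aAAcCC"))
  expect_equal(mixed$assembly$segments$sequence, "aAcC")
  expect_equal(mixed$tracks$runs[[1]], c(1L, 2L, 1L, 2L))
})

test_that("decompression inverts compression exactly", {
  asm <- new_assembly() |> add_segment("s", "ACGT")
  tracks <- tibble::tibble(segment = "s", runs = list(c(3L, 2L, 1L, 2L)))
  out <- homopolymer_decompress(asm, tracks)
  expect_equal(out$segments$sequence, "AAACCGTT")
  expect_error(homopolymer_decompress(asm, tibble::tibble(
    segment = "other", runs = list(1L))), "no homopolymer track")
  expect_error(homopolymer_decompress(asm, tibble::tibble(
    segment = "s", runs = list(c(1L, 1L)))), "2 runs")

  withr::local_seed(5150)
  for (rep in 1:50) {
    seq <- paste0(sample(c("A", "a", "C", "c", "G", "g", "T", "t", "N"),
                         sample(0:80, 1),
                         replace = TRUE, prob = c(rep(0.12, 8), 0.04)),
                  collapse = "")
    a <- new_assembly() |> add_segment("s", seq)
    hp <- homopolymer_compress(a)
    expect_lte(nchar(hp$assembly$segments$sequence), max(nchar(seq), 0))
    back <- homopolymer_decompress(hp$assembly, hp$tracks)
    expect_identical(back$segments$sequence, seq)
  }
})

test_that("homopolymer tracks survive the TSV sidecar round trip", {
  fx <- generate_fixture(n_scaffolds = 3, contig_meanlog = 3, seed = 77)
  hp <- homopolymer_compress(fx$assembly)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hp_track(hp$tracks, f)
  back <- read_hp_track(f)
  expect_equal(back$segment, hp$tracks$segment)
  expect_equal(back$runs, hp$tracks$runs)
  restored <- homopolymer_decompress(hp$assembly, back)
  expect_identical(restored$segments$sequence, fx$assembly$segments$sequence)
})
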