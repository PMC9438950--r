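test_that("parse_sak accepts the grammar and rejects bad lines whole", {
  p <- parse_sak("JOIN sc1+ sc2+ 100 scJ")
  expect_equal(p$verb, "JOIN")
  expect_equal(p$args[[1]], c("sc1+", "sc2+", "100", "scJ"))
  expect_equal(nrow(parse_sak("# comment\n\n")), 0)
  expect_equal(parse_sak("  split  a b  # trailing comment")$verb, "SPLIT")
  expect_error(parse_sak("FROBNICATE x"), "line 1")
  expect_error(parse_sak("JOIN onlyone"), "operand")
  expect_error(parse_sak("SPLIT a b\nRENAME x"), "line 2")
})

test_that("the split example disconnects A, and a join restores the scaffold", {
  asm <- fig1b_assembly()
  res <- sak_execute(asm, "SPLIT A B")
  expect_equal(nrow(res$assembly$paths), 2)
  wc <- walk_components(build_graph(res$assembly))
  expect_equal(nrow(wc), 2)
  expect_equal(wc$segments[[1]], 1L)
  expect_equal(wc$segments[[2]], c(2L, 3L))
  expect_equal(nrow(res$log), 1)

  led0 <- ledger(asm)
  led1 <- ledger(res$assembly)
  expect_equal(led1$contig, led0$contig)

  back <- sak_execute(res$assembly, "JOIN sc.1+ sc.2+ 10 sc")
  expect_equal(nrow(back$assembly$paths), 1)
  expect_equal(unname(linearize_paths(back$assembly)),
               unname(linearize_paths(asm)))

  idle <- sak_execute(asm, "# nothing\n")
  expect_equal(linearize_paths(idle$assembly), linearize_paths(asm))
  expect_equal(nrow(idle$log), 0)
})

test_that("JOIN honors minus orientation by reverse-complementing that path", {
  two <- make_asm(c(p = "ACGT", q = "GGAA"))
  j <- sak_join(two, "p+", "q-", gap_len = 2, new_name = "pq")
  expect_equal(unname(linearize_paths(j)), paste0("ACGT", "NN", revcomp("GGAA")))
  j2 <- sak_join(two, "p-", "q+", gap_len = 0, new_name = "x")
  expect_equal(unname(linearize_paths(j2)), paste0(revcomp("ACGT"), "GGAA"))
  expect_error(sak_join(two, "p+", "p+"), "itself")
})

test_that("SPLIT requires adjacency across a single gap", {
  asm <- fig1b_assembly()
  expect_error(sak_split(asm, "A", "C"), "not adjacent")
  expect_error(sak_split(asm, "A", "nope"), "no segment")
  s <- sak_split(asm, "B", "C")
  expect_equal(nrow(s$paths), 2)
  lens <- path_lengths(s)
  expect_equal(unname(lens[["sc.1"]]), 5 + 8 + 10 + 8)
  expect_equal(unname(lens[["sc.2"]]), 8 + 4)
})

test_that("EXCISE leaves a singleton and a length-conserving gap by default", {
  asm <- fig1b_assembly()
  e <- sak_excise(asm, "B")
  expect_equal(nrow(e$paths), 2)
  expect_true("B" %in% e$paths$name)
  # default replacement gap = flanks (10 + 7) + segment (8)
  expect_equal(unname(path_lengths(e)[["sc"]]), 5 + 8 + 25 + 8 + 4)
  led <- ledger(e)
  expect_equal(led$contig, ledger(asm)$contig)

  r <- sak_remove(asm, "B")
  expect_false("B" %in% r$segments$name)
  expect_equal(ledger(r)$contig, ledger(asm)$contig - 8)
  expect_equal(nrow(r$paths), 1)
})

test_that("ERASE truncates, splits and removes elements by coordinates", {
  asm <- make_asm(c(sc1 = "ACGNNNTTG"))
  # erase across the gap boundary: bases 2..7 (0-based half-open)
  e <- sak_erase(asm, "sc1", "2-7")
  expect_equal(unname(linearize_paths(e)), "ACTG")
  expect_equal(ledger(e)$contig, 4)

  # interior erase strictly inside one segment splits it around a 0-gap
  one <- make_asm(c(s = "AAACCCGGG"))
  e2 <- sak_erase(one, "s", "3-6")
  expect_equal(unname(linearize_paths(e2)), "AAAGGG")
  expect_equal(nrow(e2$segments), 2)
  expect_equal(e2$gaps$distance, 0L)

  # whole-segment erase removes the segment record
  e3 <- sak_erase(asm, "sc1", "0-3")
  expect_equal(nrow(e3$segments), 1)
  expect_equal(unname(linearize_paths(e3)), "NNNTTG")

  expect_error(sak_erase(asm, "sc1", "5-99"), "out of bounds")
  expect_error(sak_erase(asm, "sc1", "bad"), "start-end")
})

test_that("RVCP is an involution that matches hand reverse-complements", {
  expect_equal(revcomp("AACG"), "CGTT")
  one <- make_asm(c(s = "AACG"))
  expect_equal(sak_rvcp(one, "s.1")$segments$sequence, "CGTT")

  asm <- fig1b_assembly()
  rv <- sak_rvcp(asm, "sc")
  expect_equal(unname(linearize_paths(rv)),
               revcomp(unname(linearize_paths(asm))))
  expect_equal(linearize_paths(sak_rvcp(rv, "sc")), linearize_paths(asm))
  expect_equal(nrow(validate_assembly(rv)), 0)
})

test_that("INVERT flips one segment orientation in place, twice = identity", {
  asm <- fig1b_assembly()
  iv <- sak_invert(asm, "B")
  el <- iv$paths$elements[[1]]
  expect_equal(el$orient[el$kind == "segment"], c("+", "-", "+"))
  expect_equal(nrow(validate_assembly(iv)), 0)
  lin <- unname(linearize_paths(iv))
  expect_equal(substr(lin, 24, 31), revcomp("GGGGCCCC"))
  expect_equal(linearize_paths(sak_invert(iv, "B")), linearize_paths(asm))
})

test_that("TRIM_NS drops terminal gap edges and shortens the scaffold", {
  asm <- fig1b_assembly()
  tr <- sak_trim_ns(asm, "sc")
  expect_equal(unname(path_lengths(tr)), unname(path_lengths(asm)) - 5 - 4)
  expect_equal(nrow(tr$gaps), 2)
  all_tr <- sak_trim_ns(asm)
  expect_equal(path_lengths(all_tr), path_lengths(tr))
  lead <- make_asm(c(s = "NNACGT"))
  expect_equal(unname(linearize_paths(sak_trim_ns(lead))), "ACGT")
})

test_that("RENAME renames scaffolds first, segments second, enforcing uniqueness", {
  asm <- fig1b_assembly()
  rn <- sak_rename(asm, "sc", "chr1")
  expect_true("chr1" %in% rn$paths$name)
  rn2 <- sak_rename(asm, "B", "Bnew")
  expect_true("Bnew" %in% rn2$segments$name)
  expect_error(sak_rename(rn2, "A", "Bnew"), "already in use")
})

test_that("execution is transactional and the log replays to the same result", {
  asm <- fig1b_assembly()
  expect_error(sak_execute(asm, "SPLIT A B\nRVCP missing"),
               "instruction 2")
  # `asm` itself must be untouched by the failed run (value semantics)
  expect_equal(nrow(asm$paths), 1)

  script <- "SPLIT A B\nRVCP sc.2\nJOIN sc.2+ sc.1- 3 merged\nTRIM_NS"
  res <- sak_execute(asm, script)
  replay <- sak_execute(asm, paste(res$log$instruction, collapse = "\n"))
  expect_equal(linearize_paths(replay$assembly),
               linearize_paths(res$assembly))
  expect_equal(res$log$index, 1:4)
})

test_that("random scripts keep every model invariant and the ledger balanced", {
  withr::local_seed(3100)
  for (rep in 1:10) {
    fx <- generate_fixture(n_scaffolds = 3, contig_meanlog = 3.5,
                           terminal_gap_prob = 0.3, seed = rep)
    asm <- fx$assembly
    for (step in 1:6) {
      ins <- random_instruction(asm)
      loss <- expected_contig_loss(asm, ins$verb, ins$args)
      before <- ledger(asm)
      asm <- sak_execute(asm, ins$text)$assembly
      after <- ledger(asm)
      expect_equal(after$scaffold, after$contig + after$gap, info = ins$text)
      expect_equal(after$contig, before$contig - loss, info = ins$text)
      expect_equal(nrow(validate_assembly(asm)), 0, info = ins$text)
    }
  }
})
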