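test_that("build_graph realizes gaps as bidirected end-attachments", {
  asm <- fig1b_assembly()
  g <- build_graph(asm)
  expect_length(g$segment_uids, 3)
  internal <- g$incidences[!is.na(g$incidences$other_seg), ]
  expect_equal(nrow(internal), 4)  # 2 internal gaps x 2 directions
  expect_equal(sum(is.na(g$incidences$other_seg)), 2)  # terminal gaps once
  # symmetry: every internal incidence has its mirror
  for (i in seq_len(nrow(internal))) {
    mirror <- internal[internal$seg == internal$other_seg[i] &
                         internal$side == internal$other_side[i] &
                         internal$edge_uid == internal$edge_uid[i], ]
    expect_equal(nrow(mirror), 1)
  }
  expect_length(build_graph(new_assembly())$segment_uids, 0)
  iso <- Reduce(function(a, n) add_segment(a, paste0("s", n), "ACGT"),
                1:5, new_assembly())
  expect_equal(nrow(walk_components(build_graph(iso))), 5)
})

test_that("build_graph rejects dangling end references by edge name", {
  asm <- new_assembly() |> add_segment("s1", "ACGT")
  asm$gaps <- tibble::add_row(asm$gaps, uid = 1L, name = "gx", seg1 = 1L,
                              side1 = "T", seg2 = 99L, side2 = "H",
                              distance = 5L, tags = list(character()))
  expect_error(build_graph(asm), "gx")
})

test_that("walk_components linearizes the three-segment scaffold in order", {
  wc <- walk_components(build_graph(fig1b_assembly()))
  expect_equal(nrow(wc), 1)
  expect_false(wc$branching[1])
  expect_equal(wc$order[[1]]$uid, c(1L, 2L, 3L))
  expect_equal(wc$order[[1]]$orient, rep("+", 3))
})

test_that("removing the A-B gap disconnects A from {B,C}", {
  asm <- fig1b_assembly()
  asm$gaps <- asm$gaps[asm$gaps$name != "c", ]
  asm$paths <- asm$paths[0, ]  # look at the raw graph
  wc <- walk_components(build_graph(asm))
  expect_equal(nrow(wc), 2)
  expect_equal(wc$segments[[1]], 1L)
  expect_equal(wc$segments[[2]], c(2L, 3L))
})

test_that("a side with two incident gaps flags the component as branching", {
  asm <- new_assembly() |>
    add_segment("s1", "ACGT") |> add_segment("s2", "ACGT") |>
    add_segment("s3", "ACGT") |>
    add_gap(seg1 = 1, side1 = "T", seg2 = 2, side2 = "H", distance = 1) |>
    add_gap(seg1 = 1, side1 = "T", seg2 = 3, side2 = "H", distance = 1)
  wc <- walk_components(build_graph(asm))
  expect_equal(nrow(wc), 1)
  expect_true(wc$branching[1])
  expect_null(wc$order[[1]])
})

test_that("component count matches a union-find oracle on random graphs", {
  withr::local_seed(421)
  for (rep in 1:25) {
    n <- sample(2:50, 1)
    asm <- Reduce(function(a, i) add_segment(a, paste0("s", i), "AC"),
                  seq_len(n), new_assembly())
    pairs <- list()
    # random matching over free ends keeps every side at degree <= 1
    free <- expand.grid(seg = seq_len(n), side = c("H", "T"),
                        stringsAsFactors = FALSE)
    free <- free[sample(nrow(free)), ]
    m <- sample(0:(n %/% 2), 1)
    used <- 0L
    i <- 1L
    while (used < m && i + 1L <= nrow(free)) {
      e1 <- free[i, ]; e2 <- free[i + 1L, ]
      i <- i + 2L
      if (e1$seg == e2$seg) next
      asm <- add_gap(asm, seg1 = e1$seg, side1 = e1$side,
                     seg2 = e2$seg, side2 = e2$side, distance = 1)
      pairs[[length(pairs) + 1L]] <- c(e1$seg, e2$seg)
      used <- used + 1L
    }
    wc <- walk_components(build_graph(asm))
    expect_equal(nrow(wc), uf_components(n, pairs))
  }
})

test_that("graph round-trips path order on linear assemblies", {
  withr::local_seed(99)
  for (seed in 1:8) {
    fx <- generate_fixture(n_scaffolds = 3, contig_meanlog = 4, seed = seed)
    asm <- fx$assembly
    wc <- walk_components(build_graph(asm))
    for (k in seq_len(nrow(asm$paths))) {
      el <- asm$paths$elements[[k]]
      segs <- el$uid[el$kind == "segment"]
      hit <- which(vapply(wc$segments, function(s) segs[1] %in% s, logical(1)))
      ord <- wc$order[[hit]]
      # a walk may come back in either direction
      expect_true(identical(ord$uid, segs) || identical(rev(ord$uid), segs))
    }
  }
})

test_that("paths_from_graph synthesizes scaffolds and keeps existing paths", {
  asm <- new_assembly() |>
    add_segment("s1", "ACG") |> add_segment("s2", "TTG") |>
    add_gap(seg1 = 1, side1 = "T", seg2 = 2, side2 = "H", distance = 3)
  out <- paths_from_graph(asm)
  expect_equal(nrow(out$paths), 1)
  expect_equal(unname(linearize_paths(out)), "ACGNNNTTG")
  expect_identical(paths_from_graph(out)$paths, out$paths)

  star <- new_assembly() |>
    add_segment("a", "AA") |> add_segment("b", "CC") |> add_segment("c", "GG") |>
    add_gap(seg1 = 1, side1 = "T", seg2 = 2, side2 = "H", distance = 1) |>
    add_gap(seg1 = 1, side1 = "T", seg2 = 3, side2 = "H", distance = 1)
  expect_warning(out2 <- paths_from_graph(star), "branching")
  expect_equal(nrow(out2$paths), 3)
  expect_true(all(vapply(out2$paths$elements, nrow, integer(1)) == 1))
})

test_that("validate_assembly reports violations and passes clean input", {
  expect_equal(nrow(validate_assembly(fig1b_assembly())), 0)

  bad <- fig1b_assembly()
  bad$paths$elements[[1]]$uid[2] <- 77L
  d <- validate_assembly(bad)
  expect_true(any(grepl("missing segment", d$rule)))

  dup <- new_assembly() |> add_segment("s", "AC") |> add_segment("s", "GT")
  d2 <- validate_assembly(dup)
  expect_equal(nrow(d2), 1)
  expect_match(d2$rule, "duplicate segment name")

  qbad <- new_assembly() |> add_segment("s", "ACGT", qualities = "II")
  expect_true(any(grepl("qualities", validate_assembly(qbad)$rule)))
})

test_that("scaffold length obeys the conservation law after linearization", {
  withr::local_seed(5)
  for (seed in 1:5) {
    fx <- generate_fixture(n_scaffolds = 4, contig_meanlog = 4,
                           unknown_gap_fraction = 0.3, seed = seed)
    asm <- fx$assembly
    lens <- path_lengths(asm)
    seqs <- linearize_paths(asm)
    expect_equal(unname(nchar(seqs)), unname(as.integer(lens)))
    led <- ledger(asm)
    expect_equal(led$scaffold, led$contig + led$gap)
  }
})
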