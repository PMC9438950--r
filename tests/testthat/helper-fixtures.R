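# Shared builders and independent oracles for the test suite.

# assembly built by parsing FASTA text (one record per element of `seqs`)
make_asm <- function(seqs) {
  f <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))), f)
  read_fasta(f)
}

# the three-segment scaffold with two internal and two terminal gaps used by
# the graph and SAK tests: (a) A -c- B -e- C (h)
fig1b_assembly <- function() {
  new_assembly() |>
    add_segment("A", "ACGTACGT") |>
    add_segment("B", "GGGGCCCC") |>
    add_segment("C", "TTTTAAAA") |>
    add_gap("a", seg2 = 1, side2 = "H", distance = 5) |>
    add_gap("c", seg1 = 1, side1 = "T", seg2 = 2, side2 = "H", distance = 10) |>
    add_gap("e", seg1 = 2, side1 = "T", seg2 = 3, side2 = "H", distance = 7) |>
    add_gap("h", seg1 = 3, side1 = "T", distance = 4) |>
    add_path("sc", tibble::tibble(
      kind = c("gap", "segment", "gap", "segment", "gap", "segment", "gap"),
      uid = c(1L, 1L, 2L, 2L, 3L, 3L, 4L),
      orient = rep("+", 7)
    ))
}

# brute-force Nx oracle: explicit descending scan, no cumsum
naive_nx <- function(lengths, x, reference_total = sum(lengths)) {
  lens <- sort(lengths, decreasing = TRUE)
  target <- x / 100 * reference_total
  run <- 0
  for (i in seq_along(lens)) {
    run <- run + lens[i]
    if (run >= target) return(list(nx = lens[i], lx = i))
  }
  list(nx = NA_real_, lx = NA_integer_)
}

# union-find connected-component count oracle
uf_components <- function(n_nodes, edge_pairs) {
  parent <- seq_len(n_nodes)
  root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (e in edge_pairs) {
    a <- root(e[1]); b <- root(e[2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n_nodes), root, integer(1))))
}

# direct ledger arithmetic, independent of summarize_assembly()
ledger <- function(asm, unknown_gap_size = 100L) {
  list(
    scaffold = sum(path_lengths(asm, unknown_gap_size)),
    contig = sum(asm$segments$length),
    gap = sum(gap_effective_length(asm$gaps$distance, unknown_gap_size))
  )
}

# contig bases a SAK instruction is expected to delete (0 for all verbs
# except REMOVE and ERASE), computed from the pre-instruction assembly
expected_contig_loss <- function(asm, verb, args) {
  if (verb == "REMOVE") {
    return(asm$segments$length[match(args[1], asm$segments$name)])
  }
  if (verb == "ERASE") {
    rng <- as.integer(strsplit(args[2], "-")[[1]])
    k <- match(args[1], asm$paths$name)
    el <- asm$paths$elements[[k]]
    sp <- gfakit:::path_spans(asm, el)
    seg <- sp[sp$kind == "segment", , drop = FALSE]
    ov <- pmin(seg$end, rng[2]) - pmax(seg$start, rng[1])
    return(sum(pmax(ov, 0L)))
  }
  0L
}

# draw one applicable random instruction for the current assembly state
random_instruction <- function(asm) {
  verbs <- c("RVCP", "INVERT", "TRIM_NS", "RENAME")
  # SPLIT needs a seg-gap-seg triple somewhere
  has_triple <- any(vapply(asm$paths$elements, function(el) {
    nrow(el) >= 3 && any(el$kind[-c(nrow(el) - 1, nrow(el))] == "segment" &
                           el$kind[-c(1, nrow(el))] == "gap" &
                           el$kind[-c(1, 2)] == "segment")
  }, logical(1)))
  if (has_triple) verbs <- c(verbs, "SPLIT", "EXCISE", "REMOVE")
  if (nrow(asm$paths) >= 2) verbs <- c(verbs, "JOIN")
  lens <- path_lengths(asm)
  if (any(lens >= 2)) verbs <- c(verbs, "ERASE")
  verb <- sample(verbs, 1)
  pick_triple <- function() {
    repeat {
      k <- sample(nrow(asm$paths), 1)
      el <- asm$paths$elements[[k]]
      if (nrow(el) < 3) next
      idx <- which(el$kind[-c(nrow(el) - 1, nrow(el))] == "segment" &
                     el$kind[-c(1, nrow(el))] == "gap" &
                     el$kind[-c(1, 2)] == "segment")
      if (!length(idx)) next
      j <- sample(rep(idx, 2), 1)
      s1 <- asm$segments$name[match(el$uid[j], asm$segments$uid)]
      s2 <- asm$segments$name[match(el$uid[j + 2], asm$segments$uid)]
      return(c(s1, s2))
    }
  }
  args <- switch(verb,
    RVCP = sample(asm$paths$name, 1),
    INVERT = {
      placed <- unlist(lapply(asm$paths$elements,
                              function(el) el$uid[el$kind == "segment"]))
      asm$segments$name[match(sample(rep(placed, 2), 1), asm$segments$uid)]
    },
    TRIM_NS = character(),
    RENAME = {
      old <- sample(asm$paths$name, 1)
      c(old, paste0("rn_", paste(sample(letters, 8), collapse = "")))
    },
    SPLIT = pick_triple(),
    EXCISE = pick_triple()[1],
    REMOVE = pick_triple()[1],
    JOIN = {
      pair <- sample(asm$paths$name, 2)
      c(paste0(pair[1], sample(c("+", "-"), 1)),
        paste0(pair[2], sample(c("+", "-"), 1)),
        as.character(sample(0:50, 1)),
        paste0("jn_", paste(sample(letters, 8), collapse = "")))
    },
    ERASE = {
      ok <- names(lens)[lens >= 2]
      nm <- sample(rep(ok, 2), 1)
      n <- lens[[nm]]
      a <- sample(0:(n - 1), 1)
      b <- sample(rep((a + 1):n, 2), 1)
      c(nm, paste0(a, "-", b))
    }
  )
  list(verb = verb, args = args,
       text = paste(c(verb, args), collapse = " "))
}
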