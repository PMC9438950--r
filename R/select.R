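# Pre-processing: include/exclude scaffolds by name list or BED intervals,
# scaffold sorting, and homopolymer compression/decompression.

#' Filter an assembly by scaffold names and/or BED intervals
#'
#' Operations compose in a fixed order: include-names (kept in list order),
#' then exclude-names, then include-intervals (each interval extracted as a
#' new scaffold named `chrom:start-end`, replacing the assembly content),
#' then exclude-intervals (deleted with ERASE semantics). Elements no longer
#' referenced by any scaffold are pruned. The input is never modified.
#'
#' @inheritParams add_segment
#' @param include_names,exclude_names Character vectors of scaffold names.
#' @param include_bed,exclude_bed Tibbles/data frames with columns
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param strict Unknown names/intervals are errors instead of warnings.
#' @param unknown_gap_size Placeholder length for unknown gaps (bp).
#' @return The filtered assembly.
#' @export
apply_selection <- function(asm, include_names = NULL, exclude_names = NULL,
                            include_bed = NULL, exclude_bed = NULL,
                            strict = FALSE, unknown_gap_size = 100L) {
  complain <- function(...) {
    if (strict) stop(..., call. = FALSE) else warning(..., call. = FALSE)
  }
  if (!is.null(include_names)) {
    missing <- setdiff(include_names, asm$paths$name)
    if (length(missing)) {
      complain("include list names not in assembly: ",
               paste(missing, collapse = ", "))
    }
    idx <- match(intersect(include_names, asm$paths$name), asm$paths$name)
    asm$paths <- asm$paths[idx, , drop = FALSE]
    asm <- prune_unreferenced(asm)
  }
  if (!is.null(exclude_names)) {
    missing <- setdiff(exclude_names, asm$paths$name)
    if (length(missing)) {
      complain("exclude list names not in assembly: ",
               paste(missing, collapse = ", "))
    }
    asm$paths <- asm$paths[!(asm$paths$name %in% exclude_names), ,
                           drop = FALSE]
    asm <- prune_unreferenced(asm)
  }
  if (!is.null(include_bed)) {
    asm <- extract_intervals(asm, include_bed, strict, unknown_gap_size)
  }
  if (!is.null(exclude_bed)) {
    for (i in seq_len(nrow(exclude_bed))) {
      chrom <- exclude_bed$chrom[i]
      if (!(chrom %in% asm$paths$name)) {
        complain("exclude interval names unknown scaffold '", chrom, "'")
        next
      }
      asm <- sak_op_erase(asm, chrom,
                          paste0(exclude_bed$start[i], "-", exclude_bed$end[i]),
                          unknown_gap_size = unknown_gap_size)$asm
    }
    asm <- prune_unreferenced(asm)
  }
  asm
}

# build a new assembly holding one scaffold per requested interval
extract_intervals <- function(asm, bed, strict, unknown_gap_size) {
  out <- new_assembly(header_tags = asm$header_tags)
  for (i in seq_len(nrow(bed))) {
    chrom <- bed$chrom[i]
    start <- as.integer(bed$start[i])
    end <- as.integer(bed$end[i])
    k <- match(chrom, asm$paths$name)
    if (is.na(k)) {
      msg <- paste0("include interval names unknown scaffold '", chrom, "'")
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      next
    }
    el <- asm$paths$elements[[k]]
    sp <- path_spans(asm, el, unknown_gap_size)
    total <- if (nrow(sp)) sp$end[nrow(sp)] else 0L
    if (start < 0L || end > total || start >= end) {
      stop("interval ", chrom, ":", start, "-", end,
           " out of bounds (scaffold length ", total, ")")
    }
    new_name <- paste0(chrom, ":", start, "-", end)
    new_el <- path_elements()
    pure_gap <- TRUE
    for (j in seq_len(nrow(el))) {
      a <- sp$start[j]; b <- sp$end[j]
      ov_a <- max(a, start); ov_b <- min(b, end)
      if (ov_a >= ov_b) next
      if (el$kind[j] == "gap") {
        gi <- match(el$uid[j], asm$gaps$uid)
        d <- asm$gaps$distance[gi]
        kept <- if (ov_a == a && ov_b == b && is.na(d)) NA_integer_ else
          as.integer(ov_b - ov_a)
        out <- add_gap(out, distance = kept)
        new_el <- tibble::add_row(new_el, kind = "gap",
                                  uid = out$gaps$uid[nrow(out$gaps)],
                                  orient = "+")
      } else {
        pure_gap <- FALSE
        si <- match(el$uid[j], asm$segments$uid)
        s <- asm$segments[si, , drop = FALSE]
        if (is.na(s$sequence)) {
          stop("segment '", s$name, "' has no stored sequence; cannot extract")
        }
        slen <- b - a
        if (el$orient[j] == "+") {
          cut_a <- ov_a - a; cut_b <- ov_b - a
        } else {
          cut_a <- slen - (ov_b - a); cut_b <- slen - (ov_a - a)
        }
        nm <- if (cut_a == 0L && cut_b == slen) s$name else
          paste0(s$name, ":", cut_a, "-", cut_b)
        out <- add_segment(
          out, unique_seg_name(out, nm),
          sequence = substr(s$sequence, cut_a + 1L, cut_b),
          qualities = if (is.na(s$qualities)) NA_character_ else
            substr(s$qualities, cut_a + 1L, cut_b),
          tags = s$tags[[1]]
        )
        new_el <- tibble::add_row(new_el, kind = "segment",
                                  uid = out$segments$uid[nrow(out$segments)],
                                  orient = el$orient[j])
      }
    }
    if (pure_gap) {
      warning("interval ", new_name, " covers only gap sequence",
              call. = FALSE)
    }
    out <- add_path(out, unique_path_name(out, new_name), new_el)
    out <- refresh_path_gaps(out, out$paths$uid[nrow(out$paths)])
  }
  out
}

#' Sort the scaffolds of an assembly
#'
#' Permutes scaffold order only; element content is untouched. Sorting is
#' stable (ties keep input order). `"name"` uses natural ordering (numeric
#' substrings compare numerically, so `chr2` sorts before `chr10`);
#' `"length"` uses linearized scaffold length; `"list"` places the names in
#' `custom_order` first, in that order, with unlisted scaffolds after in
#' input order.
#'
#' @inheritParams add_segment
#' @param by `"input"`, `"name"`, `"length"` or `"list"`.
#' @param descending Reverse the sort key (common for length).
#' @param custom_order Character vector of names, required for
#'   `by = "list"`.
#' @return The reordered assembly.
#' @export
sort_assembly <- function(asm, by = c("input", "name", "length", "list"),
                          descending = FALSE, custom_order = NULL) {
  by <- match.arg(by)
  n <- nrow(asm$paths)
  idx <- switch(by,
    input = seq_len(n),
    name = {
      rank <- integer(n)
      rank[natural_order(asm$paths$name)] <- seq_len(n)
      order(if (descending) -rank else rank)
    },
    length = {
      key <- as.numeric(path_lengths(asm))
      order(if (descending) -key else key)
    },
    list = {
      if (is.null(custom_order)) stop("by = 'list' requires custom_order")
      listed <- match(intersect(custom_order, asm$paths$name),
                      asm$paths$name)
      c(listed, setdiff(seq_len(n), listed))
    }
  )
  asm$paths <- asm$paths[idx, , drop = FALSE]
  asm
}

#' Homopolymer compression and decompression
#'
#' Collapses every maximal run of one repeated base to a single base and
#' records the run lengths, one per retained base, so decompression is an
#' exact inverse. Run detection is case-sensitive: case encodes soft
#' masking, so a masking boundary ends a run and the round trip preserves
#' the case pattern exactly. Gaps are untouched. Per-base qualities keep the
#' first base's value over each run and are re-expanded by replication.
#'
#' @inheritParams add_segment
#' @return `homopolymer_compress()`: a list with `assembly` (compressed) and
#'   `tracks` (tibble `segment`/`runs`, run lengths as an integer list
#'   column); `homopolymer_decompress()`: the expanded assembly.
#' @export
#' @examples
#' asm <- new_assembly() |> add_segment("s1", "AAACCGTT")
#' hp <- homopolymer_compress(asm)
#' hp$assembly$segments$sequence   # "ACGT"
#' hp$tracks$runs[[1]]             # 3 2 1 2
homopolymer_compress <- function(asm) {
  tracks <- vector("list", nrow(asm$segments))
  for (i in seq_len(nrow(asm$segments))) {
    s <- asm$segments$sequence[i]
    if (is.na(s)) {
      stop("segment '", asm$segments$name[i], "' has no stored sequence")
    }
    if (nchar(s) == 0L) {
      tracks[[i]] <- integer()
      next
    }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    r <- rle(chars)
    first <- cumsum(r$lengths) - r$lengths + 1L
    asm$segments$sequence[i] <- paste0(chars[first], collapse = "")
    asm$segments$length[i] <- length(first)
    if (!is.na(asm$segments$qualities[i])) {
      q <- strsplit(asm$segments$qualities[i], "", fixed = TRUE)[[1]]
      asm$segments$qualities[i] <- paste0(q[first], collapse = "")
    }
    tracks[[i]] <- r$lengths
  }
  list(assembly = asm,
       tracks = tibble::tibble(segment = asm$segments$name, runs = tracks))
}

#' @rdname homopolymer_compress
#' @param tracks The `tracks` tibble produced by [homopolymer_compress()]
#'   (or read back with [read_hp_track()]).
#' @export
homopolymer_decompress <- function(asm, tracks) {
  for (i in seq_len(nrow(asm$segments))) {
    nm <- asm$segments$name[i]
    t <- match(nm, tracks$segment)
    if (is.na(t)) stop("no homopolymer track for segment '", nm, "'")
    runs <- tracks$runs[[t]]
    s <- asm$segments$sequence[i]
    if (length(runs) != nchar(s)) {
      stop("track for segment '", nm, "' has ", length(runs),
           " runs but the compressed sequence has ", nchar(s), " bases")
    }
    if (length(runs) == 0L) next
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    asm$segments$sequence[i] <- paste0(rep(chars, runs), collapse = "")
    asm$segments$length[i] <- sum(runs)
    if (!is.na(asm$segments$qualities[i])) {
      q <- strsplit(asm$segments$qualities[i], "", fixed = TRUE)[[1]]
      asm$segments$qualities[i] <- paste0(rep(q, runs), collapse = "")
    }
  }
  asm
}

#' Homopolymer track sidecar files
#'
#' No standard format exists for run-length tracks, so they travel as a
#' two-column TSV sidecar: segment name, comma-separated run lengths.
#'
#' @param tracks Tracks tibble from [homopolymer_compress()].
#' @param path Output (or input) TSV path.
#' @return `write_hp_track()`: the lines, invisibly; `read_hp_track()`: the
#'   tracks tibble.
#' @export
write_hp_track <- function(tracks, path = NULL) {
  lines <- vapply(seq_len(nrow(tracks)), function(i) {
    paste0(tracks$segment[i], "\t",
           paste(tracks$runs[[i]], collapse = ","))
  }, character(1))
  emit(lines, path)
}

#' @rdname write_hp_track
#' @export
read_hp_track <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    segment = vapply(parts, `[`, "", 1L),
    runs = lapply(parts, function(p) {
      if (length(p) < 2L || !nzchar(p[2])) integer() else
        as.integer(strsplit(p[2], ",", fixed = TRUE)[[1]])
    })
  )
}
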