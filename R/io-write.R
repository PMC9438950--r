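# Writers: FASTA/FASTQ/GFA1/GFA2 (gzip when the path ends in .gz), plus AGP,
# BED and sizes exports. All writers are deterministic: elements are emitted
# in uid order, paths in assembly order, and output always uses LF.

#' Linearize scaffold paths to sequence strings
#'
#' Renders each path end to end: segments contribute their sequence
#' (reverse-complemented for `-` orientation), sized gaps contribute exactly
#' `distance` `N` characters and unknown gaps the configured placeholder
#' count. Terminal gaps emit their Ns at the corresponding end.
#'
#' @inheritParams add_segment
#' @param unknown_gap_size Placeholder N count for unknown gaps (bp).
#' @return Named character vector of scaffold sequences, in assembly order.
#' @export
linearize_paths <- function(asm, unknown_gap_size = 100L) {
  vapply(seq_len(nrow(asm$paths)), function(k) {
    linearize_one(asm, asm$paths$elements[[k]], unknown_gap_size,
                  what = "sequence")
  }, character(1)) |>
    stats::setNames(asm$paths$name)
}

# what = "sequence" or "qualities"; gap fill differs
linearize_one <- function(asm, el, unknown_gap_size, what = "sequence",
                          gap_quality = "!", default_quality = "!") {
  if (nrow(el) == 0L) return("")
  parts <- character(nrow(el))
  for (j in seq_len(nrow(el))) {
    if (el$kind[j] == "segment") {
      i <- match(el$uid[j], asm$segments$uid)
      if (what == "sequence") {
        s <- asm$segments$sequence[i]
        if (is.na(s)) {
          stop("segment '", asm$segments$name[i],
               "' has no stored sequence; cannot linearize")
        }
        parts[j] <- if (el$orient[j] == "-") revcomp(s) else s
      } else {
        q <- asm$segments$qualities[i]
        if (is.na(q)) q <- strrep(default_quality, asm$segments$length[i])
        parts[j] <- if (el$orient[j] == "-") stringi::stri_reverse(q) else q
      }
    } else {
      i <- match(el$uid[j], asm$gaps$uid)
      len <- gap_effective_length(asm$gaps$distance[i], unknown_gap_size)
      parts[j] <- strrep(if (what == "sequence") "N" else gap_quality, len)
    }
  }
  paste0(parts, collapse = "")
}

open_out <- function(path) {
  if (endsWith(path, ".gz")) gzfile(path, "wb") else file(path, "wb")
}

emit <- function(lines, path) {
  if (is.null(path)) return(invisible(lines))
  con <- open_out(path)
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(lines)
}

#' Write an assembly as FASTA
#'
#' One record per scaffold path, in assembly order; the stored header comment
#' (`CM` tag) is re-emitted after the name. Writes gzip when `path` ends in
#' `.gz`; with `path = NULL` the lines are returned invisibly.
#'
#' @inheritParams linearize_paths
#' @param path Output file, or `NULL` to return the lines.
#' @param line_width Sequence wrap width; `Inf` for unwrapped.
#' @return The output lines, invisibly.
#' @export
write_fasta <- function(asm, path = NULL, line_width = 60L,
                        unknown_gap_size = 100L) {
  out <- character()
  for (k in seq_len(nrow(asm$paths))) {
    cm <- get_tag(asm$paths$tags[[k]], "CM")
    hdr <- paste0(">", asm$paths$name[k],
                  if (!is.na(cm) && nzchar(cm)) paste0(" ", cm) else "")
    seq <- linearize_one(asm, asm$paths$elements[[k]], unknown_gap_size)
    out <- c(out, hdr, wrap_sequence(seq, line_width))
  }
  emit(out, path)
}

#' Write an assembly as FASTQ
#'
#' Four-line records, unwrapped. Gap positions get the configured gap-quality
#' character; segments without stored qualities are filled with
#' `default_quality`.
#'
#' @inheritParams write_fasta
#' @param gap_quality Quality character emitted over gap Ns.
#' @param default_quality Fill for segments lacking qualities.
#' @return The output lines, invisibly.
#' @export
write_fastq <- function(asm, path = NULL, unknown_gap_size = 100L,
                        gap_quality = "!", default_quality = "!") {
  out <- character()
  for (k in seq_len(nrow(asm$paths))) {
    cm <- get_tag(asm$paths$tags[[k]], "CM")
    hdr <- paste0("@", asm$paths$name[k],
                  if (!is.na(cm) && nzchar(cm)) paste0(" ", cm) else "")
    seq <- linearize_one(asm, asm$paths$elements[[k]], unknown_gap_size)
    qual <- linearize_one(asm, asm$paths$elements[[k]], unknown_gap_size,
                          what = "qualities", gap_quality = gap_quality,
                          default_quality = default_quality)
    out <- c(out, hdr, seq, "+", qual)
  }
  emit(out, path)
}

fmt_tags <- function(tags) {
  tags <- tags[nzchar(tags)]
  if (length(tags) == 0L) return("")
  named <- names(tags)
  if (!is.null(named) && any(nzchar(named))) {
    # named vectors hold bare values, e.g. c(CM = "comment")
    tags <- ifelse(nzchar(named), paste0(named, ":Z:", tags), tags)
  }
  paste0("\t", paste(tags, collapse = "\t"))
}

#' Write an assembly as GFA
#'
#' GFA2 (default) emits `H` (`VN:Z:2.0`), `S` with explicit length, `G` for
#' every gap (unknown distance as `*`; the open side of a terminal gap as
#' `*`), `E` for overlap edges and one `O` line per path; segment qualities
#' travel in a reserved `QL:Z:` tag. GFA1 emits `S`/`L`/`P`: gaps cannot be
#' represented, so they are collapsed out of `P` member lists and their
#' lengths recorded in a reserved `gl:Z:` tag (and the header is marked
#' `ly:Z:1`), which [read_gfa()] uses to restore them.
#'
#' @inheritParams write_fasta
#' @param version GFA major version, `1` or `2`.
#' @return The output lines, invisibly.
#' @export
write_gfa <- function(asm, path = NULL, version = 2L) {
  if (version == 2L) write_gfa2(asm, path) else write_gfa1(asm, path)
}

end_ref <- function(asm, seg, side, first) {
  if (is.na(seg)) return("*")
  nm <- asm$segments$name[match(seg, asm$segments$uid)]
  orient <- if (first) {
    if (side == "T") "+" else "-"
  } else {
    if (side == "H") "+" else "-"
  }
  paste0(nm, orient)
}

write_gfa2 <- function(asm, path) {
  out <- paste0("H\tVN:Z:2.0", fmt_tags(asm$header_tags))
  s <- asm$segments[order(asm$segments$uid), , drop = FALSE]
  for (k in seq_len(nrow(s))) {
    tags <- s$tags[[k]]
    if (!is.na(s$qualities[k])) {
      tags <- c(tags, paste0("QL:Z:", s$qualities[k]))
    }
    out <- c(out, paste0(
      "S\t", s$name[k], "\t", s$length[k], "\t",
      if (is.na(s$sequence[k])) "*" else s$sequence[k], fmt_tags(tags)
    ))
  }
  e <- asm$edges[order(asm$edges$uid), , drop = FALSE]
  for (k in seq_len(nrow(e))) {
    n1 <- asm$segments$name[match(e$seg1[k], asm$segments$uid)]
    n2 <- asm$segments$name[match(e$seg2[k], asm$segments$uid)]
    coord <- function(x) if (is.na(x)) "0" else x
    out <- c(out, paste0(
      "E\t", e$name[k], "\t", n1, e$orient1[k], "\t", n2, e$orient2[k], "\t",
      coord(e$beg1[k]), "\t", coord(e$end1[k]), "\t",
      coord(e$beg2[k]), "\t", coord(e$end2[k]), "\t", e$cigar[k],
      fmt_tags(e$tags[[k]])
    ))
  }
  g <- asm$gaps[order(asm$gaps$uid), , drop = FALSE]
  for (k in seq_len(nrow(g))) {
    out <- c(out, paste0(
      "G\t", g$name[k], "\t",
      end_ref(asm, g$seg1[k], g$side1[k], first = TRUE), "\t",
      end_ref(asm, g$seg2[k], g$side2[k], first = FALSE), "\t",
      if (is.na(g$distance[k])) "*" else g$distance[k], "\t*",
      fmt_tags(g$tags[[k]])
    ))
  }
  for (k in seq_len(nrow(asm$paths))) {
    el <- asm$paths$elements[[k]]
    refs <- vapply(seq_len(nrow(el)), function(j) {
      if (el$kind[j] == "segment") {
        paste0(asm$segments$name[match(el$uid[j], asm$segments$uid)],
               el$orient[j])
      } else {
        asm$gaps$name[match(el$uid[j], asm$gaps$uid)]
      }
    }, character(1))
    out <- c(out, paste0("O\t", asm$paths$name[k], "\t",
                         paste(refs, collapse = " "),
                         fmt_tags(asm$paths$tags[[k]])))
  }
  out <- c(out, asm$extra_lines)
  emit(out, path)
}

write_gfa1 <- function(asm, path) {
  hdr_tags <- asm$header_tags
  if (nrow(asm$gaps) > 0L) hdr_tags <- c(hdr_tags, "ly:Z:1")
  out <- paste0("H\tVN:Z:1.0", fmt_tags(hdr_tags))
  s <- asm$segments[order(asm$segments$uid), , drop = FALSE]
  for (k in seq_len(nrow(s))) {
    tags <- c(paste0("LN:i:", s$length[k]), s$tags[[k]])
    if (!is.na(s$qualities[k])) tags <- c(tags, paste0("QL:Z:", s$qualities[k]))
    out <- c(out, paste0(
      "S\t", s$name[k], "\t",
      if (is.na(s$sequence[k])) "*" else s$sequence[k], fmt_tags(tags)
    ))
  }
  e <- asm$edges[order(asm$edges$uid), , drop = FALSE]
  for (k in seq_len(nrow(e))) {
    n1 <- asm$segments$name[match(e$seg1[k], asm$segments$uid)]
    n2 <- asm$segments$name[match(e$seg2[k], asm$segments$uid)]
    out <- c(out, paste0("L\t", n1, "\t", e$orient1[k], "\t", n2, "\t",
                         e$orient2[k], "\t", e$cigar[k], fmt_tags(e$tags[[k]])))
  }
  for (k in seq_len(nrow(asm$paths))) {
    el <- asm$paths$elements[[k]]
    segs <- el[el$kind == "segment", , drop = FALSE]
    members <- vapply(seq_len(nrow(segs)), function(j) {
      paste0(asm$segments$name[match(segs$uid[j], asm$segments$uid)],
             segs$orient[j])
    }, character(1))
    # gap slots: leading, between each member pair, trailing
    slots <- gfa1_gap_slots(asm, el, nrow(segs))
    tags <- asm$paths$tags[[k]]
    if (!is.null(slots)) tags <- c(tags, stats::setNames(slots, NULL))
    out <- c(out, paste0("P\t", asm$paths$name[k], "\t",
                         paste(members, collapse = ","), "\t*",
                         fmt_tags(tags)))
  }
  out <- c(out, asm$extra_lines)
  emit(out, path)
}

gfa1_gap_slots <- function(asm, el, n_segs) {
  if (!any(el$kind == "gap")) return(NULL)
  slots <- rep("-", n_segs + 1L)
  seg_pos <- 0L
  for (j in seq_len(nrow(el))) {
    if (el$kind[j] == "segment") {
      seg_pos <- seg_pos + 1L
    } else {
      d <- asm$gaps$distance[match(el$uid[j], asm$gaps$uid)]
      slots[seg_pos + 1L] <- if (is.na(d)) "u" else as.character(d)
    }
  }
  paste0("gl:Z:", paste(slots, collapse = ","))
}

# ---- AGP / BED / sizes ----------------------------------------------------

# per-path element coordinate spans, 0-based half-open on the scaffold
path_spans <- function(asm, el, unknown_gap_size = 100L) {
  if (nrow(el) == 0L) {
    return(tibble::tibble(kind = character(), uid = integer(),
                          orient = character(), start = integer(),
                          end = integer()))
  }
  lens <- integer(nrow(el))
  for (j in seq_len(nrow(el))) {
    lens[j] <- if (el$kind[j] == "segment") {
      asm$segments$length[match(el$uid[j], asm$segments$uid)]
    } else {
      gap_effective_length(asm$gaps$distance[match(el$uid[j], asm$gaps$uid)],
                           unknown_gap_size)
    }
  }
  ends <- cumsum(lens)
  tibble::tibble(kind = el$kind, uid = el$uid, orient = el$orient,
                 start = as.integer(ends - lens), end = as.integer(ends))
}

#' AGP v2.1 representation of an assembly
#'
#' One row per scaffold component: `W` rows for segments (1-based inclusive
#' object and component coordinates), `N` rows for sized gaps and `U` rows
#' for unknown gaps (length fixed at the placeholder, per the AGP
#' convention). Rows of one object tile it without overlap or holes.
#'
#' @inheritParams linearize_paths
#' @return A tibble with the nine AGP columns (`object`, `object_beg`,
#'   `object_end`, `part_number`, `component_type`, `component_id`,
#'   `component_beg`, `component_end`, `orientation`; the last four carry gap
#'   length/type/linkage/evidence for N/U rows).
#' @export
agp_table <- function(asm, unknown_gap_size = 100L) {
  rows <- list()
  for (k in seq_len(nrow(asm$paths))) {
    sp <- path_spans(asm, asm$paths$elements[[k]], unknown_gap_size)
    part <- 0L
    for (j in seq_len(nrow(sp))) {
      if (sp$end[j] == sp$start[j]) next  # zero-length gaps have no AGP row
      part <- part + 1L
      if (sp$kind[j] == "segment") {
        i <- match(sp$uid[j], asm$segments$uid)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          object = asm$paths$name[k],
          object_beg = sp$start[j] + 1L, object_end = sp$end[j],
          part_number = part, component_type = "W",
          component_id = asm$segments$name[i],
          component_beg = "1",
          component_end = as.character(asm$segments$length[i]),
          orientation = sp$orient[j]
        )
      } else {
        i <- match(sp$uid[j], asm$gaps$uid)
        unknown <- is.na(asm$gaps$distance[i])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          object = asm$paths$name[k],
          object_beg = sp$start[j] + 1L, object_end = sp$end[j],
          part_number = part,
          component_type = if (unknown) "U" else "N",
          component_id = as.character(sp$end[j] - sp$start[j]),
          component_beg = "scaffold", component_end = "yes",
          orientation = "unspecified"
        )
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(object = character(), object_beg = integer(),
                   object_end = integer(), part_number = integer(),
                   component_type = character(), component_id = character(),
                   component_beg = character(), component_end = character(),
                   orientation = character())
  }
}

#' @rdname agp_table
#' @param path Output file, or `NULL` to return the lines.
#' @export
write_agp <- function(asm, path = NULL, unknown_gap_size = 100L) {
  tbl <- agp_table(asm, unknown_gap_size)
  lines <- c("##agp-version\t2.1",
             apply(tbl, 1L, paste, collapse = "\t"))
  emit(lines, path)
}

#' BED intervals for assembly features
#'
#' Intervals are 0-based half-open on scaffold coordinates.
#'
#' @inheritParams linearize_paths
#' @param feature `"gaps"`, `"segments"` or `"scaffolds"`.
#' @return A tibble `chrom`/`start`/`end`/`name`.
#' @export
bed_table <- function(asm, feature = c("gaps", "segments", "scaffolds"),
                      unknown_gap_size = 100L) {
  feature <- match.arg(feature)
  rows <- list()
  for (k in seq_len(nrow(asm$paths))) {
    nm <- asm$paths$name[k]
    sp <- path_spans(asm, asm$paths$elements[[k]], unknown_gap_size)
    if (feature == "scaffolds") {
      len <- if (nrow(sp)) sp$end[nrow(sp)] else 0L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = nm, start = 0L, end = len, name = nm
      )
    } else {
      want <- if (feature == "gaps") "gap" else "segment"
      sub <- sp[sp$kind == want & sp$end > sp$start, , drop = FALSE]
      if (nrow(sub) == 0L) next
      lab <- if (want == "gap") {
        asm$gaps$name[match(sub$uid, asm$gaps$uid)]
      } else {
        asm$segments$name[match(sub$uid, asm$segments$uid)]
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = nm, start = sub$start, end = sub$end, name = lab
      )
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   name = character())
  }
}

#' @rdname bed_table
#' @param path Output file, or `NULL` to return the lines.
#' @export
write_bed <- function(asm, path = NULL,
                      feature = c("gaps", "segments", "scaffolds"),
                      unknown_gap_size = 100L) {
  tbl <- bed_table(asm, feature, unknown_gap_size)
  emit(sprintf("%s\t%d\t%d\t%s", tbl$chrom, tbl$start, tbl$end, tbl$name),
       path)
}

#' Element sizes by tier
#'
#' @inheritParams linearize_paths
#' @param tier `"scaffold"`, `"contig"` or `"gap"` (unknown gaps at the
#'   placeholder length).
#' @return A tibble `name`/`length`, in input order.
#' @export
sizes_table <- function(asm, tier = c("scaffold", "contig", "gap"),
                        unknown_gap_size = 100L) {
  tier <- match.arg(tier)
  switch(tier,
    scaffold = {
      lens <- path_lengths(asm, unknown_gap_size)
      tibble::tibble(name = asm$paths$name, length = as.integer(lens))
    },
    contig = tibble::tibble(name = asm$segments$name,
                            length = asm$segments$length),
    gap = tibble::tibble(
      name = asm$gaps$name,
      length = gap_effective_length(asm$gaps$distance, unknown_gap_size)
    )
  )
}

#' @rdname sizes_table
#' @param path Output file, or `NULL` to return the lines.
#' @export
write_sizes <- function(asm, path = NULL,
                        tier = c("scaffold", "contig", "gap"),
                        unknown_gap_size = 100L) {
  tbl <- sizes_table(asm, tier, unknown_gap_size)
  emit(sprintf("%s\t%d", tbl$name, tbl$length), path)
}
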