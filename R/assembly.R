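#' The in-memory assembly model
#'
#' An `assembly` is the unified GFA2-like representation every input format is
#' mapped onto: a collection of *segments* (contigs, optionally carrying
#' sequence and per-base qualities), *gaps* (junctions of unknown sequence,
#' sized or of unknown length), *overlap edges* and *paths* (ordered, oriented
#' walks over segments and gaps — one path per scaffold). Each element class
#' lives in its own tibble so the model composes naturally with dplyr verbs.
#'
#' Segment and gap ends are addressed as (segment uid, side), with side
#' `"H"` (head, the 5' start) or `"T"` (tail, the 3' end): traversing a
#' segment in `+` orientation enters at the head and leaves at the tail.
#' A terminal gap (leading/trailing Ns of a scaffold) has one open end,
#' recorded as `NA`.
#'
#' @param header_tags Named character vector of file-level tags.
#' @return An object of class `assembly`.
#' @export
new_assembly <- function(header_tags = character()) {
  structure(
    list(
      segments = tibble::tibble(
        uid = integer(), name = character(), sequence = character(),
        qualities = character(), length = integer(), tags = list()
      ),
      gaps = tibble::tibble(
        uid = integer(), name = character(),
        seg1 = integer(), side1 = character(),
        seg2 = integer(), side2 = character(),
        distance = integer(), tags = list()
      ),
      edges = tibble::tibble(
        uid = integer(), name = character(),
        seg1 = integer(), orient1 = character(),
        seg2 = integer(), orient2 = character(),
        beg1 = character(), end1 = character(),
        beg2 = character(), end2 = character(),
        cigar = character(), tags = list()
      ),
      paths = tibble::tibble(
        uid = integer(), name = character(), elements = list(), tags = list()
      ),
      header_tags = header_tags,
      extra_lines = character()
    ),
    class = "assembly"
  )
}

#' @export
print.assembly <- function(x, ...) {
  cat("<assembly>\n")
  cat(sprintf("  segments: %d   gaps: %d   edges: %d   paths: %d\n",
              nrow(x$segments), nrow(x$gaps), nrow(x$edges), nrow(x$paths)))
  if (nrow(x$paths) > 0) {
    lens <- path_lengths(x)
    cat(sprintf("  total scaffold length: %s bp\n",
                format(sum(lens), big.mark = "")))
  }
  invisible(x)
}

#' @export
is_assembly <- function(x) inherits(x, "assembly")

next_uid <- function(tbl) {
  if (nrow(tbl) == 0L) 1L else max(tbl$uid) + 1L
}

# an empty element list for paths
path_elements <- function(kind = character(), uid = integer(),
                          orient = character()) {
  tibble::tibble(kind = kind, uid = as.integer(uid), orient = orient)
}

#' Add elements to an assembly
#'
#' Low-level constructors used by the readers, the fixture generator and the
#' edit operations. Each returns the modified assembly (value semantics: the
#' input object is never changed in place).
#'
#' @param asm An [assembly][new_assembly].
#' @param name Element name (segment and path names must be unique within
#'   their class).
#' @param sequence Nucleotide string, or `NA` for a sequence-less segment.
#' @param qualities Per-base quality string, or `NA`.
#' @param length Segment length in bp; inferred from `sequence` when omitted.
#' @param tags Named character vector of GFA-style optional tags.
#' @return The modified assembly.
#' @export
add_segment <- function(asm, name, sequence = NA_character_,
                        qualities = NA_character_, length = NULL,
                        tags = character()) {
  if (is.null(length)) {
    length <- if (is.na(sequence)) {
      stop("segment '", name, "': no sequence and no length given")
    } else {
      nchar(sequence)
    }
  }
  asm$segments <- tibble::add_row(
    asm$segments, uid = next_uid(asm$segments), name = name,
    sequence = sequence, qualities = qualities, length = as.integer(length),
    tags = list(tags)
  )
  asm
}

#' @rdname add_segment
#' @param seg1,seg2 Segment uids of the two attached ends (`NA` = open end of
#'   a terminal gap).
#' @param side1,side2 `"H"` or `"T"`.
#' @param distance Gap length in bp, `NA` for unknown.
#' @export
add_gap <- function(asm, name = NULL, seg1 = NA_integer_, side1 = NA_character_,
                    seg2 = NA_integer_, side2 = NA_character_,
                    distance = NA_integer_, tags = character()) {
  uid <- next_uid(asm$gaps)
  if (is.null(name)) name <- paste0("gap", uid)
  asm$gaps <- tibble::add_row(
    asm$gaps, uid = uid, name = name,
    seg1 = as.integer(seg1), side1 = side1,
    seg2 = as.integer(seg2), side2 = side2,
    distance = as.integer(distance), tags = list(tags)
  )
  asm
}

#' @rdname add_segment
#' @param orient1,orient2 Edge orientations as in GFA (`+`/`-`).
#' @param beg1,end1,beg2,end2 GFA2 alignment coordinates, kept verbatim
#'   (character; may carry the `$` end-marker), `NA` when unknown.
#' @param cigar Overlap CIGAR string or `"*"`.
#' @export
add_edge <- function(asm, name = NULL, seg1, orient1, seg2, orient2,
                     beg1 = NA_character_, end1 = NA_character_,
                     beg2 = NA_character_, end2 = NA_character_,
                     cigar = "*", tags = character()) {
  uid <- next_uid(asm$edges)
  if (is.null(name)) name <- paste0("edge", uid)
  asm$edges <- tibble::add_row(
    asm$edges, uid = uid, name = name,
    seg1 = as.integer(seg1), orient1 = orient1,
    seg2 = as.integer(seg2), orient2 = orient2,
    beg1 = beg1, end1 = end1, beg2 = beg2, end2 = end2,
    cigar = cigar, tags = list(tags)
  )
  asm
}

#' @rdname add_segment
#' @param elements A tibble with columns `kind` (`"segment"`/`"gap"`), `uid`
#'   and `orient` (`+`/`-`), in scaffold order.
#' @export
add_path <- function(asm, name, elements, tags = character()) {
  asm$paths <- tibble::add_row(
    asm$paths, uid = next_uid(asm$paths), name = name,
    elements = list(elements), tags = list(tags)
  )
  asm
}

# ---- lookups --------------------------------------------------------------

seg_by_uid <- function(asm, uid) {
  asm$segments[match(uid, asm$segments$uid), , drop = FALSE]
}

seg_uid <- function(asm, name) {
  asm$segments$uid[match(name, asm$segments$name)]
}

path_uid <- function(asm, name) {
  asm$paths$uid[match(name, asm$paths$name)]
}

gap_by_uid <- function(asm, uid) {
  asm$gaps[match(uid, asm$gaps$uid), , drop = FALSE]
}

# ---- derived quantities ---------------------------------------------------

#' Scaffold lengths by arithmetic over path elements
#'
#' The length of a scaffold is the sum of its segment lengths plus its sized
#' gap distances, with unknown gaps counted at the rendering placeholder.
#'
#' @inheritParams add_segment
#' @param unknown_gap_size Placeholder length (bp) for unknown gaps.
#' @return Named numeric vector, one entry per path in assembly order.
#' @export
path_lengths <- function(asm, unknown_gap_size = 100L) {
  seg_len <- stats::setNames(as.numeric(asm$segments$length), asm$segments$uid)
  gap_len <- stats::setNames(
    as.numeric(gap_effective_length(asm$gaps$distance, unknown_gap_size)),
    asm$gaps$uid
  )
  out <- vapply(asm$paths$elements, function(el) {
    if (nrow(el) == 0L) return(0)
    sum(ifelse(el$kind == "segment",
               seg_len[as.character(el$uid)],
               gap_len[as.character(el$uid)]))
  }, numeric(1))
  stats::setNames(out, asm$paths$name)
}

# Recompute each gap element's end attachments in one path from the element
# order and segment orientations, so the gap records always agree with the
# path that owns them. A segment traversed '+' exposes its tail to the next
# element and its head to the previous one.
refresh_path_gaps <- function(asm, puid) {
  i <- match(puid, asm$paths$uid)
  el <- asm$paths$elements[[i]]
  if (nrow(el) == 0L) return(asm)
  for (j in which(el$kind == "gap")) {
    guid <- el$uid[j]
    k <- match(guid, asm$gaps$uid)
    if (j > 1L && el$kind[j - 1L] == "segment") {
      asm$gaps$seg1[k] <- el$uid[j - 1L]
      asm$gaps$side1[k] <- if (el$orient[j - 1L] == "+") "T" else "H"
    } else {
      asm$gaps$seg1[k] <- NA_integer_
      asm$gaps$side1[k] <- NA_character_
    }
    if (j < nrow(el) && el$kind[j + 1L] == "segment") {
      asm$gaps$seg2[k] <- el$uid[j + 1L]
      asm$gaps$side2[k] <- if (el$orient[j + 1L] == "+") "H" else "T"
    } else {
      asm$gaps$seg2[k] <- NA_integer_
      asm$gaps$side2[k] <- NA_character_
    }
  }
  asm
}

# drop segments/gaps no longer referenced by any path, and edges touching
# removed segments (used after selection/removal operations)
prune_unreferenced <- function(asm) {
  el <- dplyr::bind_rows(c(list(path_elements()), asm$paths$elements))
  keep_seg <- unique(el$uid[el$kind == "segment"])
  keep_gap <- unique(el$uid[el$kind == "gap"])
  asm$segments <- asm$segments[asm$segments$uid %in% keep_seg, , drop = FALSE]
  asm$gaps <- asm$gaps[asm$gaps$uid %in% keep_gap, , drop = FALSE]
  asm$edges <- asm$edges[asm$edges$seg1 %in% keep_seg &
                           asm$edges$seg2 %in% keep_seg, , drop = FALSE]
  asm
}

# ---- validation -----------------------------------------------------------

#' Validate an assembly against the model invariants
#'
#' Checks every structural invariant of the model — segment length/sequence
#' agreement, quality lengths, the nucleotide alphabet, name uniqueness, gap
#' and edge end resolution, strict segment/gap alternation inside paths, the
#' agreement of gap end attachments with flanking path members, and the
#' one-path-per-segment rule. Diagnostics are reported, never thrown.
#'
#' @inheritParams add_segment
#' @return A tibble with columns `class`, `name` and `rule`; zero rows when
#'   the assembly is well formed.
#' @export
validate_assembly <- function(asm) {
  bad <- list()
  note <- function(class, name, rule) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(
      class = class, name = as.character(name), rule = rule
    )
  }
  s <- asm$segments
  has_seq <- !is.na(s$sequence)
  mism <- has_seq & nchar(s$sequence) != s$length
  for (n in s$name[mism]) note("segment", n, "length != nchar(sequence)")
  has_q <- !is.na(s$qualities)
  qbad <- has_q & nchar(s$qualities) != s$length
  for (n in s$name[qbad]) note("segment", n, "qualities length != length")
  alpha_bad <- has_seq & grepl(invalid_nt_regex(), s$sequence, perl = TRUE)
  for (n in s$name[alpha_bad]) note("segment", n, "non-IUPAC character")
  for (n in unique(s$name[duplicated(s$name)])) {
    note("segment", n, "duplicate segment name")
  }
  g <- asm$gaps
  neg <- !is.na(g$distance) & g$distance < 0L
  for (n in g$name[neg]) note("gap", n, "negative distance")
  for (k in seq_len(nrow(g))) {
    for (side in c(1L, 2L)) {
      sid <- g[[paste0("seg", side)]][k]
      if (!is.na(sid) && !(sid %in% s$uid)) {
        note("gap", g$name[k], "end references missing segment")
      }
      sd <- g[[paste0("side", side)]][k]
      if (!is.na(sd) && !(sd %in% c("H", "T"))) {
        note("gap", g$name[k], "side not in {H,T}")
      }
    }
  }
  e <- asm$edges
  for (k in seq_len(nrow(e))) {
    if (!(e$seg1[k] %in% s$uid) || !(e$seg2[k] %in% s$uid)) {
      note("edge", e$name[k], "end references missing segment")
    }
    if (!grepl("^(\\*|([0-9]+[MID])+)$", e$cigar[k])) {
      note("edge", e$name[k], "invalid overlap CIGAR")
    }
  }
  p <- asm$paths
  for (n in unique(p$name[duplicated(p$name)])) {
    note("path", n, "duplicate path name")
  }
  seg_owner <- integer(0)
  for (k in seq_len(nrow(p))) {
    el <- p$elements[[k]]
    if (nrow(el) == 0L) next
    seg_el <- el$kind == "segment"
    miss <- el$uid[seg_el][!(el$uid[seg_el] %in% s$uid)]
    for (u in miss) note("path", p$name[k], "element references missing segment")
    missg <- el$uid[!seg_el][!(el$uid[!seg_el] %in% g$uid)]
    for (u in missg) note("path", p$name[k], "element references missing gap")
    runs <- rle(el$kind)
    if (any(runs$lengths > 1L)) {
      note("path", p$name[k], "adjacent elements of the same kind")
    }
    # gap end attachments must match the flanking segments/orientations
    for (j in which(el$kind == "gap")) {
      gk <- match(el$uid[j], g$uid)
      if (is.na(gk)) next
      if (j > 1L && el$kind[j - 1L] == "segment") {
        want_side <- if (el$orient[j - 1L] == "+") "T" else "H"
        if (!identical(g$seg1[gk], el$uid[j - 1L]) ||
            !identical(g$side1[gk], want_side)) {
          note("gap", g$name[gk], "end1 disagrees with flanking path member")
        }
      }
      if (j < nrow(el) && el$kind[j + 1L] == "segment") {
        want_side <- if (el$orient[j + 1L] == "+") "H" else "T"
        if (!identical(g$seg2[gk], el$uid[j + 1L]) ||
            !identical(g$side2[gk], want_side)) {
          note("gap", g$name[gk], "end2 disagrees with flanking path member")
        }
      }
    }
    owned <- el$uid[seg_el]
    dup <- owned[owned %in% seg_owner]
    for (u in dup) {
      note("segment", s$name[match(u, s$uid)], "segment in more than one path")
    }
    seg_owner <- c(seg_owner, owned)
  }
  if (length(bad) == 0L) {
    tibble::tibble(class = character(), name = character(), rule = character())
  } else {
    dplyr::bind_rows(bad)
  }
}
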