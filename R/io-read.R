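# Streaming readers: FASTA, FASTQ, GFA1, GFA2, each optionally
# gzip-compressed. Content decides the format; the file extension is only a
# hint. All readers work through gzfile(), which reads plain text
# transparently, in fixed-size line chunks so no more than one record (plus,
# for GFA, an unresolved-reference table) is held at once.

DEFAULT_CHUNK_LINES <- 65536L

#' Detect the format of a sequence file
#'
#' Looks at the content: the gzip magic bytes decide compression, the first
#' meaningful character decides FASTA (`>`) vs FASTQ (`@`) vs GFA, and GFA1
#' vs GFA2 is decided by the header `VN` tag when present, otherwise by
#' line-type evidence (`E`/`G`/`O`/`F` imply GFA2; `L`/`P` imply GFA1;
#' segment-only files default to GFA2).
#'
#' @param path Path to the file.
#' @return A list of class `format_dialect` with fields `kind` (one of
#'   `"fasta"`, `"fastq"`, `"gfa1"`, `"gfa2"`) and `gzipped`.
#' @export
detect_format <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  gz <- length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  head <- character()
  repeat {
    more <- readLines(con, n = 64L, warn = FALSE)
    head <- c(head, more[nzchar(more)])
    if (length(more) < 64L || length(head) >= 64L) break
  }
  if (length(head) == 0L) stop("empty file: ", path)
  first <- substr(head[1], 1L, 1L)
  kind <- if (first == ">") {
    "fasta"
  } else if (first == "@") {
    "fastq"
  } else if (first %in% c("H", "S", "L", "E", "G", "P", "O", "U", "J", "#")) {
    vn <- stringr::str_match(head, "^H\\t.*VN:Z:([0-9.]+)")[, 2]
    vn <- vn[!is.na(vn)]
    types <- substr(head, 1L, 1L)
    if (length(vn) && startsWith(vn[1], "1")) "gfa1"
    else if (length(vn) && startsWith(vn[1], "2")) "gfa2"
    else if (any(types %in% c("E", "G", "O", "F"))) "gfa2"
    else if (any(types %in% c("L", "P"))) "gfa1"
    else "gfa2"
  } else {
    stop("unrecognized format: first character '", first, "' in ", path)
  }
  structure(list(kind = kind, gzipped = gz), class = "format_dialect")
}

#' Read any supported assembly file
#'
#' Dispatches on [detect_format()] and, for GFA inputs lacking path lines,
#' optionally synthesizes scaffold paths from the gap graph
#' ([paths_from_graph()]).
#'
#' @param path Input file (FASTA/FASTQ/GFA1/GFA2, plain or gzip).
#' @param synthesize_paths For GFA inputs with no path/ordered-group lines,
#'   derive scaffolds by walking the gap graph (default `TRUE`).
#' @param chunk_lines Lines per read chunk (streaming granularity).
#' @return An [assembly][new_assembly].
#' @export
read_assembly <- function(path, synthesize_paths = TRUE,
                          chunk_lines = DEFAULT_CHUNK_LINES) {
  dialect <- detect_format(path)
  asm <- switch(dialect$kind,
    fasta = read_fasta(path, chunk_lines = chunk_lines),
    fastq = read_fastq(path, chunk_lines = chunk_lines),
    gfa1 = ,
    gfa2 = read_gfa(path, chunk_lines = chunk_lines)
  )
  if (dialect$kind %in% c("gfa1", "gfa2") && synthesize_paths &&
      nrow(asm$paths) == 0L) {
    asm <- paths_from_graph(asm)
  }
  asm
}

# iterate over FASTA records without loading the file: calls
# handler(name, comment, sequence, first_line) once per record
stream_fasta_records <- function(path, handler,
                                 chunk_lines = DEFAULT_CHUNK_LINES) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  cur_name <- NULL
  cur_comment <- ""
  cur_line <- 0L
  buf <- character()
  line_no <- 0L
  flush_record <- function() {
    if (!is.null(cur_name)) {
      handler(cur_name, cur_comment, paste0(buf, collapse = ""), cur_line)
    }
  }
  repeat {
    lines <- readLines(con, n = chunk_lines, warn = FALSE)
    if (length(lines) == 0L) break
    lines <- sub("\r$", "", lines)
    for (ln in lines) {
      line_no <- line_no + 1L
      if (startsWith(ln, ">")) {
        flush_record()
        hdr <- substring(ln, 2L)
        sp <- regexpr("[ \t]", hdr)
        if (sp == -1L) {
          cur_name <- hdr
          cur_comment <- ""
        } else {
          cur_name <- substr(hdr, 1L, sp - 1L)
          cur_comment <- substring(hdr, sp + 1L)
        }
        cur_line <- line_no
        buf <- character()
      } else if (nzchar(ln)) {
        if (is.null(cur_name)) {
          stop("sequence data before first '>' header at line ", line_no)
        }
        buf[[length(buf) + 1L]] <- ln
      }
    }
  }
  flush_record()
  invisible(NULL)
}

# Split one record's sequence at maximal N-runs and append the resulting
# segments, gaps and path to the accumulator environment. Leading/trailing
# runs become terminal gaps (one open end).
add_record_to_acc <- function(acc, name, comment, seq, qual = NA_character_,
                              first_line = NA_integer_) {
  n <- nchar(seq)
  if (n == 0L) {
    warning("record '", name, "' has an empty sequence", call. = FALSE)
  }
  bad <- regexpr(invalid_nt_regex(), seq, perl = TRUE)
  if (bad != -1L) {
    stop("record '", name, "' (line ", first_line, "): invalid character '",
         substr(seq, bad, bad), "' at position ", bad)
  }
  if (!is.na(qual) && nchar(qual) != n) {
    stop("record '", name, "': quality length ", nchar(qual),
         " != sequence length ", n)
  }
  runs <- n_runs(seq)
  # contig spans between N-runs, 0-based half-open
  bounds <- c(0L, rbind(runs$start, runs$end), n)
  kinds <- rep(c("segment", "gap"), length.out = length(bounds) - 1L)
  el_kind <- character()
  el_idx <- integer()
  seg_i <- 0L
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    if (b <= a) next  # empty span (record starts/ends with N-run)
    if (kinds[i] == "segment") {
      seg_i <- seg_i + 1L
      acc$seg_name[[length(acc$seg_name) + 1L]] <- paste0(name, ".", seg_i)
      acc$seg_seq[[length(acc$seg_seq) + 1L]] <- substr(seq, a + 1L, b)
      acc$seg_qual[[length(acc$seg_qual) + 1L]] <-
        if (is.na(qual)) NA_character_ else substr(qual, a + 1L, b)
      el_kind <- c(el_kind, "segment")
      el_idx <- c(el_idx, length(acc$seg_name))
    } else {
      acc$gap_dist[[length(acc$gap_dist) + 1L]] <- b - a
      el_kind <- c(el_kind, "gap")
      el_idx <- c(el_idx, length(acc$gap_dist))
    }
  }
  acc$path_name[[length(acc$path_name) + 1L]] <- name
  acc$path_comment[[length(acc$path_comment) + 1L]] <- comment
  acc$path_el[[length(acc$path_el) + 1L]] <- list(kind = el_kind, idx = el_idx)
}

# turn the accumulator into an assembly (uids assigned in encounter order)
acc_to_assembly <- function(acc) {
  asm <- new_assembly()
  nseg <- length(acc$seg_name)
  seqs <- unlist(acc$seg_seq, use.names = FALSE)
  asm$segments <- tibble::tibble(
    uid = seq_len(nseg),
    name = unlist(acc$seg_name, use.names = FALSE) %||% character(),
    sequence = seqs %||% character(),
    qualities = unlist(acc$seg_qual, use.names = FALSE) %||% character(),
    length = if (nseg) nchar(seqs) else integer(),
    tags = rep(list(character()), nseg)
  )
  ngap <- length(acc$gap_dist)
  asm$gaps <- tibble::tibble(
    uid = seq_len(ngap),
    name = paste0("gap", seq_len(ngap)),
    seg1 = NA_integer_, side1 = NA_character_,
    seg2 = NA_integer_, side2 = NA_character_,
    distance = as.integer(unlist(acc$gap_dist, use.names = FALSE) %||% integer()),
    tags = rep(list(character()), ngap)
  )
  npath <- length(acc$path_name)
  elements <- vector("list", npath)
  tags <- vector("list", npath)
  for (k in seq_len(npath)) {
    e <- acc$path_el[[k]]
    elements[[k]] <- path_elements(e$kind, e$idx, rep("+", length(e$kind)))
    cm <- acc$path_comment[[k]]
    tags[[k]] <- if (nzchar(cm)) c(CM = cm) else character()
  }
  asm$paths <- tibble::tibble(
    uid = seq_len(npath),
    name = unlist(acc$path_name, use.names = FALSE) %||% character(),
    elements = elements, tags = tags
  )
  for (pu in asm$paths$uid) asm <- refresh_path_gaps(asm, pu)
  asm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTA file into the assembly model
#'
#' Each record becomes one scaffold path. Maximal runs of `N`/`n` split the
#' record into segments separated by sized gaps whose distance is the run
#' length; leading/trailing runs become terminal gaps. The header comment is
#' kept as a `CM` tag on the path. Single-pass streaming; gzip transparent.
#'
#' @inheritParams read_assembly
#' @return An [assembly][new_assembly].
#' @export
read_fasta <- function(path, chunk_lines = DEFAULT_CHUNK_LINES) {
  acc <- new.env(parent = emptyenv())
  stream_fasta_records(path, function(name, comment, seq, first_line) {
    add_record_to_acc(acc, name, comment, seq, first_line = first_line)
  }, chunk_lines = chunk_lines)
  acc_to_assembly(acc)
}

#' Read a FASTQ file into the assembly model
#'
#' As [read_fasta()], with per-base qualities stored on segments. Qualities
#' are split at the same N-run boundaries; quality characters over an N-run
#' are discarded with the run.
#'
#' @inheritParams read_assembly
#' @return An [assembly][new_assembly].
#' @export
read_fastq <- function(path, chunk_lines = DEFAULT_CHUNK_LINES) {
  acc <- new.env(parent = emptyenv())
  con <- gzfile(path, "rt")
  on.exit(close(con))
  pending <- character()
  line_no <- 0L
  repeat {
    lines <- readLines(con, n = chunk_lines, warn = FALSE)
    if (length(lines) == 0L) break
    pending <- c(pending, sub("\r$", "", lines))
    while (length(pending) >= 4L) {
      rec <- pending[1:4]
      pending <- pending[-(1:4)]
      if (!startsWith(rec[1], "@")) {
        stop("malformed FASTQ record at line ", line_no + 1L,
             ": expected '@' header")
      }
      if (!startsWith(rec[3], "+")) {
        stop("malformed FASTQ record at line ", line_no + 3L,
             ": expected '+' separator")
      }
      hdr <- substring(rec[1], 2L)
      sp <- regexpr("[ \t]", hdr)
      name <- if (sp == -1L) hdr else substr(hdr, 1L, sp - 1L)
      comment <- if (sp == -1L) "" else substring(hdr, sp + 1L)
      add_record_to_acc(acc, name, comment, rec[2], qual = rec[4],
                        first_line = line_no + 1L)
      line_no <- line_no + 4L
    }
  }
  pending <- pending[nzchar(pending)]
  if (length(pending) > 0L) {
    stop("truncated FASTQ record at end of file (", length(pending),
         " trailing lines)")
  }
  acc_to_assembly(acc)
}

# ---- GFA ------------------------------------------------------------------

# split trailing tab-separated tag fields ("XX:T:value") from a GFA line
split_gfa_tags <- function(fields, from) {
  if (length(fields) < from) return(character())
  tags <- fields[from:length(fields)]
  tags[grepl("^[A-Za-z][A-Za-z0-9]:[ABHJZif]:", tags)]
}

tag_value <- function(tags, name) {
  hit <- tags[startsWith(tags, paste0(name, ":"))]
  if (length(hit) == 0L) return(NA_character_)
  sub("^[A-Za-z][A-Za-z0-9]:[ABHJZif]:", "", hit[1])
}

drop_tag <- function(tags, name) {
  tags[!startsWith(tags, paste0(name, ":"))]
}

# tag lookup accepting both storage forms: a named vector of bare values
# (reader-attached, e.g. c(CM = "x")) or full "CM:Z:x" strings (GFA tags)
get_tag <- function(tags, name) {
  if (length(tags) == 0L) return(NA_character_)
  nms <- names(tags)
  if (!is.null(nms) && name %in% nms) return(unname(tags[[name]]))
  tag_value(tags, name)
}

parse_oriented_ref <- function(ref) {
  last <- substr(ref, nchar(ref), nchar(ref))
  if (last %in% c("+", "-")) {
    list(name = substr(ref, 1L, nchar(ref) - 1L), orient = last)
  } else {
    list(name = ref, orient = "+")
  }
}

#' Read a GFA1 or GFA2 file into the assembly model
#'
#' GFA2: `S` lines become segments (explicit length, `*` sequence allowed),
#' `G` lines gaps (`*` distance = unknown; a `*` segment reference marks the
#' open side of a terminal gap), `E` lines overlap edges and `O` ordered
#' groups paths. GFA1: `S`/`L`/`P`, with gaps between consecutive `P` members
#' restored from the reserved `gl:Z:` tag when present, else inferred as
#' 0-length. Unknown line types are preserved verbatim. Forward references
#' are allowed and resolved once the file has been read.
#'
#' @inheritParams read_assembly
#' @param version Force `1` or `2`; default auto-detects per line content.
#' @return An [assembly][new_assembly].
#' @export
read_gfa <- function(path, version = NULL, chunk_lines = DEFAULT_CHUNK_LINES) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  asm <- new_assembly()
  gap_rows <- list()   # unresolved: names instead of uids
  edge_rows <- list()
  path_rows <- list()
  line_no <- 0L
  repeat {
    lines <- readLines(con, n = chunk_lines, warn = FALSE)
    if (length(lines) == 0L) break
    lines <- sub("\r$", "", lines)
    for (ln in lines) {
      line_no <- line_no + 1L
      if (!nzchar(ln)) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      type <- f[1]
      if (type == "H") {
        # the version tag belongs to the serialization, not the model
        keep <- f[-1][!startsWith(f[-1], "VN:")]
        asm$header_tags <- unique(c(asm$header_tags, keep))
      } else if (type == "S") {
        # GFA2 S has a numeric length in field 3; GFA1 has the sequence there
        is_gfa2 <- length(f) >= 3L && grepl("^[0-9]+$", f[3]) &&
          (isTRUE(version == 2) || is.null(version) || FALSE)
        if (isTRUE(version == 1)) is_gfa2 <- FALSE
        if (is_gfa2) {
          seq <- if (length(f) >= 4L && f[4] != "*") f[4] else NA_character_
          len <- as.integer(f[3])
          tags <- split_gfa_tags(f, 5L)
        } else {
          seq <- if (f[3] != "*") f[3] else NA_character_
          tags <- split_gfa_tags(f, 4L)
          ln_tag <- tag_value(tags, "LN")
          len <- if (!is.na(seq)) nchar(seq)
                 else if (!is.na(ln_tag)) as.integer(ln_tag)
                 else stop("line ", line_no, ": S line '", f[2],
                           "' has '*' sequence and no length")
          tags <- drop_tag(tags, "LN")
        }
        qual <- tag_value(tags, "QL")
        tags <- drop_tag(tags, "QL")
        if (!is.na(seq) && grepl(invalid_nt_regex(), seq, perl = TRUE)) {
          stop("line ", line_no, ": segment '", f[2],
               "' contains a non-nucleotide character")
        }
        asm <- add_segment(asm, f[2], sequence = seq, qualities = qual,
                           length = len, tags = tags)
      } else if (type == "G") {
        if (length(f) < 5L) stop("line ", line_no, ": malformed G line")
        gap_rows[[length(gap_rows) + 1L]] <- list(
          name = f[2], ref1 = f[3], ref2 = f[4],
          distance = if (f[5] == "*") NA_integer_ else as.integer(f[5]),
          tags = split_gfa_tags(f, 7L), line = line_no
        )
      } else if (type == "E") {
        if (length(f) < 9L) stop("line ", line_no, ": malformed E line")
        edge_rows[[length(edge_rows) + 1L]] <- list(
          name = f[2], ref1 = f[3], ref2 = f[4],
          beg1 = f[5], end1 = f[6], beg2 = f[7], end2 = f[8], cigar = f[9],
          tags = split_gfa_tags(f, 10L), line = line_no
        )
      } else if (type == "L") {
        if (length(f) < 6L) stop("line ", line_no, ": malformed L line")
        edge_rows[[length(edge_rows) + 1L]] <- list(
          name = NULL, ref1 = paste0(f[2], f[3]), ref2 = paste0(f[4], f[5]),
          beg1 = NA_character_, end1 = NA_character_,
          beg2 = NA_character_, end2 = NA_character_, cigar = f[6],
          tags = split_gfa_tags(f, 7L), line = line_no
        )
      } else if (type == "O") {
        path_rows[[length(path_rows) + 1L]] <- list(
          kind = "O", name = f[2], refs = strsplit(f[3], " ", fixed = TRUE)[[1]],
          tags = split_gfa_tags(f, 4L), line = line_no
        )
      } else if (type == "P") {
        path_rows[[length(path_rows) + 1L]] <- list(
          kind = "P", name = f[2],
          refs = strsplit(f[3], ",", fixed = TRUE)[[1]],
          tags = split_gfa_tags(f, 5L), line = line_no
        )
      } else if (type == "#") {
        asm$extra_lines <- c(asm$extra_lines, ln)
      } else {
        # U/F/J and anything else: opaque pass-through
        asm$extra_lines <- c(asm$extra_lines, ln)
      }
    }
  }
  resolve_gfa(asm, gap_rows, edge_rows, path_rows)
}

resolve_gfa <- function(asm, gap_rows, edge_rows, path_rows) {
  suid <- function(name, line) {
    u <- seg_uid(asm, name)
    if (is.na(u)) {
      stop("line ", line, ": reference to undefined segment '", name, "'")
    }
    u
  }
  for (g in gap_rows) {
    e1 <- parse_oriented_ref(g$ref1)
    e2 <- parse_oriented_ref(g$ref2)
    # '+' on the first sid exposes its tail; on the second, its head
    if (e1$name == "*") {
      s1 <- NA_integer_; d1 <- NA_character_
    } else {
      s1 <- suid(e1$name, g$line)
      d1 <- if (e1$orient == "+") "T" else "H"
    }
    if (e2$name == "*") {
      s2 <- NA_integer_; d2 <- NA_character_
    } else {
      s2 <- suid(e2$name, g$line)
      d2 <- if (e2$orient == "+") "H" else "T"
    }
    nm <- if (g$name == "*") NULL else g$name
    asm <- add_gap(asm, name = nm, seg1 = s1, side1 = d1, seg2 = s2,
                   side2 = d2, distance = g$distance, tags = g$tags)
  }
  for (e in edge_rows) {
    r1 <- parse_oriented_ref(e$ref1)
    r2 <- parse_oriented_ref(e$ref2)
    nm <- if (is.null(e$name) || identical(e$name, "*")) NULL else e$name
    asm <- add_edge(asm, name = nm,
                    seg1 = suid(r1$name, e$line), orient1 = r1$orient,
                    seg2 = suid(r2$name, e$line), orient2 = r2$orient,
                    beg1 = e$beg1, end1 = e$end1, beg2 = e$beg2, end2 = e$end2,
                    cigar = e$cigar, tags = e$tags)
  }
  for (p in path_rows) {
    if (p$kind == "O") {
      asm <- resolve_ordered_group(asm, p)
    } else {
      asm <- resolve_gfa1_path(asm, p)
    }
  }
  for (pu in asm$paths$uid) asm <- refresh_path_gaps(asm, pu)
  asm
}

# GFA2 ordered group: refs may name segments, gaps or edges; consecutive
# segments with nothing between them get an abutting 0-length gap
resolve_ordered_group <- function(asm, p) {
  el <- path_elements()
  last_was_segment <- FALSE
  for (ref in p$refs) {
    r <- parse_oriented_ref(ref)
    su <- seg_uid(asm, r$name)
    if (!is.na(su)) {
      if (last_was_segment) {
        asm <- add_gap(asm, distance = 0L)
        el <- tibble::add_row(el, kind = "gap",
                              uid = asm$gaps$uid[nrow(asm$gaps)], orient = "+")
      }
      el <- tibble::add_row(el, kind = "segment", uid = su, orient = r$orient)
      last_was_segment <- TRUE
      next
    }
    gu <- asm$gaps$uid[match(r$name, asm$gaps$name)]
    if (!is.na(gu)) {
      el <- tibble::add_row(el, kind = "gap", uid = gu, orient = "+")
      last_was_segment <- FALSE
      next
    }
    eu <- asm$edges$uid[match(r$name, asm$edges$name)]
    if (!is.na(eu)) {
      # overlap edges join their flanking segments directly
      last_was_segment <- FALSE
      next
    }
    stop("line ", p$line, ": ordered group '", p$name,
         "' references undefined element '", r$name, "'")
  }
  add_path(asm, p$name, el, tags = p$tags)
}

# GFA1 P line: members are oriented segments; gap lengths restored from the
# reserved gl:Z: tag (slots: leading,internal...,trailing; '-' none, 'u'
# unknown), else 0-length abutting gaps
resolve_gfa1_path <- function(asm, p) {
  members <- lapply(p$refs, parse_oriented_ref)
  n <- length(members)
  gl <- tag_value(p$tags, "gl")
  tags <- drop_tag(p$tags, "gl")
  slots <- if (!is.na(gl)) strsplit(gl, ",", fixed = TRUE)[[1]] else NULL
  slot_dist <- function(i) {
    if (is.null(slots) || i > length(slots)) return(0L)
    v <- slots[i]
    if (v == "-") return(NULL)
    if (v == "u") return(NA_integer_)
    as.integer(v)
  }
  el <- path_elements()
  lead <- if (!is.null(slots)) slot_dist(1L) else NULL
  if (!is.null(lead)) {
    asm <- add_gap(asm, distance = lead)
    el <- tibble::add_row(el, kind = "gap",
                          uid = asm$gaps$uid[nrow(asm$gaps)], orient = "+")
  }
  for (i in seq_len(n)) {
    m <- members[[i]]
    su <- seg_uid(asm, m$name)
    if (is.na(su)) {
      stop("line ", p$line, ": path '", p$name,
           "' references undefined segment '", m$name, "'")
    }
    if (i > 1L) {
      d <- if (!is.null(slots)) slot_dist(i) else 0L
      if (is.null(d)) d <- 0L  # internal slots always join
      asm <- add_gap(asm, distance = d)
      el <- tibble::add_row(el, kind = "gap",
                            uid = asm$gaps$uid[nrow(asm$gaps)], orient = "+")
    }
    el <- tibble::add_row(el, kind = "segment", uid = su, orient = m$orient)
  }
  trail <- if (!is.null(slots)) slot_dist(n + 1L) else NULL
  if (!is.null(trail)) {
    asm <- add_gap(asm, distance = trail)
    el <- tibble::add_row(el, kind = "gap",
                          uid = asm$gaps$uid[nrow(asm$gaps)], orient = "+")
  }
  add_path(asm, p$name, el, tags = tags)
}
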