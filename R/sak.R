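# The "swiss army knife" (SAK): a sequential, human-readable instruction
# script executed against the assembly graph, doubling as a change log.
# Verbs: JOIN, SPLIT, EXCISE, REMOVE, ERASE, RVCP, INVERT, TRIM_NS, RENAME.

SAK_ARITY <- list(
  JOIN = c(2L, 4L), SPLIT = c(2L, 2L), EXCISE = c(1L, 2L),
  REMOVE = c(1L, 1L), ERASE = c(2L, 2L), RVCP = c(1L, 1L),
  INVERT = c(1L, 1L), TRIM_NS = c(0L, 1L), RENAME = c(2L, 2L)
)

#' Parse a SAK instruction script
#'
#' One instruction per line; `#` comments and blank lines are ignored; verbs
#' are case-insensitive. Parsing is all-or-nothing: any unknown verb or
#' wrong operand arity aborts with the offending line number, and nothing is
#' executed.
#'
#' @param text Script text (single string or character vector of lines), or
#'   a path to a script file when `is_file = TRUE`.
#' @param is_file Treat `text` as a file path.
#' @return A tibble with columns `line`, `verb`, `args` (list of character
#'   vectors) and `raw`.
#' @export
#' @examples
#' parse_sak("JOIN sc1+ sc2+ 100 scJ")
parse_sak <- function(text, is_file = FALSE) {
  lines <- if (is_file) readLines(text, warn = FALSE) else
    unlist(strsplit(text, "\n", fixed = TRUE))
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    toks <- strsplit(ln, "[ \t]+")[[1]]
    verb <- toupper(toks[1])
    args <- toks[-1]
    if (!verb %in% names(SAK_ARITY)) {
      stop("SAK parse error, line ", i, ": unknown verb '", toks[1], "'")
    }
    ar <- SAK_ARITY[[verb]]
    if (length(args) < ar[1] || length(args) > ar[2]) {
      stop("SAK parse error, line ", i, ": ", verb, " takes ", ar[1],
           if (ar[2] > ar[1]) paste0("-", ar[2]) else "",
           " operand(s), got ", length(args))
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      line = i, verb = verb, args = list(args), raw = trimws(lines[i])
    )
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(line = integer(), verb = character(), args = list(),
                   raw = character())
  }
}

#' Execute a SAK script against an assembly
#'
#' Instructions are applied strictly in order; each instruction sees the
#' effects of the previous ones. Execution is transactional: an error at any
#' instruction aborts the whole run (the input assembly, being a value, is
#' never modified). The change log has one entry per instruction, so
#' replaying the logged instructions on the original assembly reproduces the
#' edited one.
#'
#' @inheritParams add_segment
#' @param script A script (text or parsed tibble from [parse_sak()]).
#' @param unknown_gap_size Placeholder length for unknown gaps in coordinate
#'   arithmetic (bp).
#' @return A list with `assembly` (the edited assembly) and `log` (a tibble
#'   `index`/`instruction`/`effect`/`created`/`deleted`).
#' @export
sak_execute <- function(asm, script, unknown_gap_size = 100L) {
  if (!inherits(script, "data.frame")) script <- parse_sak(script)
  log_rows <- list()
  for (k in seq_len(nrow(script))) {
    verb <- script$verb[k]
    a <- script$args[[k]]
    res <- tryCatch(
      switch(verb,
        JOIN = sak_op_join(asm, a[1], a[2],
                           gap_len = if (length(a) >= 3) a[3] else "*",
                           new_name = if (length(a) >= 4) a[4] else NULL),
        SPLIT = sak_op_split(asm, a[1], a[2]),
        EXCISE = sak_op_excise(asm, a[1],
                               gap_len = if (length(a) >= 2) a[2] else NULL,
                               unknown_gap_size = unknown_gap_size),
        REMOVE = sak_op_remove(asm, a[1], unknown_gap_size = unknown_gap_size),
        ERASE = sak_op_erase(asm, a[1], a[2],
                             unknown_gap_size = unknown_gap_size),
        RVCP = sak_op_rvcp(asm, a[1]),
        INVERT = sak_op_invert(asm, a[1]),
        TRIM_NS = sak_op_trim_ns(asm, if (length(a) >= 1) a[1] else NULL),
        RENAME = sak_op_rename(asm, a[1], a[2])
      ),
      error = function(e) {
        stop("SAK execution error at instruction ", k, " ('", script$raw[k],
             "'): ", conditionMessage(e), call. = FALSE)
      }
    )
    asm <- res$asm
    log_rows[[k]] <- tibble::tibble(
      index = k, instruction = script$raw[k], effect = res$effect,
      created = paste(res$created, collapse = ";"),
      deleted = paste(res$deleted, collapse = ";")
    )
  }
  log <- if (length(log_rows)) dplyr::bind_rows(log_rows) else {
    tibble::tibble(index = integer(), instruction = character(),
                   effect = character(), created = character(),
                   deleted = character())
  }
  list(assembly = asm, log = log)
}

# ---- shared helpers -------------------------------------------------------

resolve_scaffold <- function(asm, name) {
  u <- path_uid(asm, name)
  if (is.na(u)) stop("no scaffold named '", name, "'")
  u
}

resolve_segment <- function(asm, name) {
  u <- seg_uid(asm, name)
  if (is.na(u)) stop("no segment named '", name, "'")
  u
}

# path index and element position of a segment
locate_segment <- function(asm, suid) {
  for (k in seq_len(nrow(asm$paths))) {
    el <- asm$paths$elements[[k]]
    j <- which(el$kind == "segment" & el$uid == suid)
    if (length(j)) return(list(path = k, pos = j[1]))
  }
  NULL
}

# reverse a path's element list (orientation flips on segments)
rc_elements <- function(el) {
  el <- el[rev(seq_len(nrow(el))), , drop = FALSE]
  flip <- el$kind == "segment"
  el$orient[flip] <- ifelse(el$orient[flip] == "+", "-", "+")
  el
}

set_path_elements <- function(asm, k, el) {
  asm$paths$elements[[k]] <- el
  refresh_path_gaps(asm, asm$paths$uid[k])
}

# enforce strict alternation after an edit: merge adjacent gaps (distances
# add; unknown absorbs) and insert a 0-length abutting gap between adjacent
# segments; returns list(asm, el, deleted) with gap records kept in step
normalize_elements <- function(asm, el) {
  deleted <- character()
  repeat {
    gg <- which(el$kind[-nrow(el)] == "gap" & el$kind[-1] == "gap")
    if (nrow(el) < 2L || length(gg) == 0L) break
    j <- gg[1]
    i1 <- match(el$uid[j], asm$gaps$uid)
    i2 <- match(el$uid[j + 1L], asm$gaps$uid)
    d1 <- asm$gaps$distance[i1]; d2 <- asm$gaps$distance[i2]
    asm$gaps$distance[i1] <- if (is.na(d1) || is.na(d2)) NA_integer_ else d1 + d2
    deleted <- c(deleted, asm$gaps$name[i2])
    asm$gaps <- asm$gaps[-i2, , drop = FALSE]
    el <- el[-(j + 1L), , drop = FALSE]
  }
  j <- 1L
  while (j < nrow(el)) {
    if (el$kind[j] == "segment" && el$kind[j + 1L] == "segment") {
      asm <- add_gap(asm, distance = 0L)
      guid <- asm$gaps$uid[nrow(asm$gaps)]
      el <- dplyr::bind_rows(
        el[seq_len(j), , drop = FALSE],
        path_elements("gap", guid, "+"),
        el[(j + 1L):nrow(el), , drop = FALSE]
      )
    }
    j <- j + 1L
  }
  list(asm = asm, el = el, deleted = deleted)
}

delete_gap_records <- function(asm, guids) {
  asm$gaps <- asm$gaps[!(asm$gaps$uid %in% guids), , drop = FALSE]
  asm
}

unique_seg_name <- function(asm, name) {
  if (!(name %in% asm$segments$name)) return(name)
  i <- 1L
  repeat {
    cand <- paste0(name, "_", i)
    if (!(cand %in% asm$segments$name)) return(cand)
    i <- i + 1L
  }
}

# ---- verb implementations -------------------------------------------------

sak_op_join <- function(asm, a, b, gap_len = "*", new_name = NULL) {
  pa <- parse_oriented_ref(a)
  pb <- parse_oriented_ref(b)
  ka <- match(resolve_scaffold(asm, pa$name), asm$paths$uid)
  kb <- match(resolve_scaffold(asm, pb$name), asm$paths$uid)
  if (ka == kb) stop("cannot join a scaffold to itself")
  if (is.null(new_name)) new_name <- pa$name
  ela <- asm$paths$elements[[ka]]
  elb <- asm$paths$elements[[kb]]
  if (pa$orient == "-") ela <- rc_elements(ela)
  if (pb$orient == "-") elb <- rc_elements(elb)
  deleted <- character()
  # terminal gaps at the junction are replaced by the new junction gap
  if (nrow(ela) && ela$kind[nrow(ela)] == "gap") {
    gi <- match(ela$uid[nrow(ela)], asm$gaps$uid)
    deleted <- c(deleted, asm$gaps$name[gi])
    asm <- delete_gap_records(asm, ela$uid[nrow(ela)])
    ela <- ela[-nrow(ela), , drop = FALSE]
  }
  if (nrow(elb) && elb$kind[1] == "gap") {
    gi <- match(elb$uid[1], asm$gaps$uid)
    deleted <- c(deleted, asm$gaps$name[gi])
    asm <- delete_gap_records(asm, elb$uid[1])
    elb <- elb[-1, , drop = FALSE]
  }
  dist <- if (identical(gap_len, "*")) NA_integer_ else as.integer(gap_len)
  asm <- add_gap(asm, distance = dist)
  guid <- asm$gaps$uid[nrow(asm$gaps)]
  gname <- asm$gaps$name[nrow(asm$gaps)]
  el <- dplyr::bind_rows(ela, path_elements("gap", guid, "+"), elb)
  old_names <- asm$paths$name[c(ka, kb)]
  keep <- setdiff(seq_len(nrow(asm$paths)), c(ka, kb))
  asm$paths <- asm$paths[keep, , drop = FALSE]
  if (new_name %in% asm$paths$name) {
    stop("scaffold name '", new_name, "' already in use")
  }
  asm <- add_path(asm, new_name, el)
  asm <- refresh_path_gaps(asm, asm$paths$uid[nrow(asm$paths)])
  list(asm = asm,
       effect = sprintf("joined %s and %s into %s (gap %s)",
                        old_names[1], old_names[2], new_name,
                        if (is.na(dist)) "unknown" else paste0(dist, " bp")),
       created = c(new_name, gname),
       deleted = c(old_names, deleted))
}

sak_op_split <- function(asm, seg1, seg2) {
  u1 <- resolve_segment(asm, seg1)
  u2 <- resolve_segment(asm, seg2)
  loc <- locate_segment(asm, u1)
  if (is.null(loc)) stop("segment '", seg1, "' is in no scaffold")
  el <- asm$paths$elements[[loc$path]]
  j2 <- which(el$kind == "segment" & el$uid == u2)
  if (length(j2) == 0L) {
    stop("segments '", seg1, "' and '", seg2, "' are not in the same scaffold")
  }
  lo <- min(loc$pos, j2[1]); hi <- max(loc$pos, j2[1])
  if (hi - lo != 2L || el$kind[lo + 1L] != "gap") {
    stop("segments '", seg1, "' and '", seg2,
         "' are not adjacent across a single gap")
  }
  guid <- el$uid[lo + 1L]
  gname <- asm$gaps$name[match(guid, asm$gaps$uid)]
  old_name <- asm$paths$name[loc$path]
  el1 <- el[seq_len(lo), , drop = FALSE]
  el2 <- el[(lo + 2L):nrow(el), , drop = FALSE]
  asm <- delete_gap_records(asm, guid)
  asm$paths <- asm$paths[-loc$path, , drop = FALSE]
  n1 <- unique_path_name(asm, paste0(old_name, ".1"))
  asm <- add_path(asm, n1, el1)
  asm <- refresh_path_gaps(asm, asm$paths$uid[nrow(asm$paths)])
  n2 <- unique_path_name(asm, paste0(old_name, ".2"))
  asm <- add_path(asm, n2, el2)
  asm <- refresh_path_gaps(asm, asm$paths$uid[nrow(asm$paths)])
  list(asm = asm,
       effect = sprintf("split %s between %s and %s (gap %s removed)",
                        old_name, seg1, seg2, gname),
       created = c(n1, n2), deleted = c(old_name, gname))
}

# shared by EXCISE and REMOVE: take `suid` out of its path, substituting one
# replacement gap when the removal is interior
excise_core <- function(asm, suid, gap_len, unknown_gap_size) {
  loc <- locate_segment(asm, suid)
  if (is.null(loc)) stop("segment is in no scaffold")
  el <- asm$paths$elements[[loc$path]]
  j <- loc$pos
  span <- j
  flank_dist <- integer()
  for (side in c(-1L, 1L)) {
    jj <- j + side
    if (jj >= 1L && jj <= nrow(el) && el$kind[jj] == "gap") {
      span <- c(span, jj)
      flank_dist <- c(flank_dist,
                      asm$gaps$distance[match(el$uid[jj], asm$gaps$uid)])
    }
  }
  span <- sort(span)
  left_seg <- min(span) > 1L
  right_seg <- max(span) < nrow(el)
  removed_gaps <- el$uid[span][el$kind[span] == "gap"]
  deleted <- asm$gaps$name[match(removed_gaps, asm$gaps$uid)]
  seg_len <- asm$segments$length[match(suid, asm$segments$uid)]
  asm <- delete_gap_records(asm, removed_gaps)
  keep <- setdiff(seq_len(nrow(el)), span)
  el <- el[keep, , drop = FALSE]
  created <- character()
  if (left_seg && right_seg) {
    dist <- if (is.null(gap_len)) {
      if (anyNA(flank_dist)) NA_integer_ else
        as.integer(seg_len + sum(flank_dist))
    } else if (identical(gap_len, "*")) NA_integer_ else as.integer(gap_len)
    asm <- add_gap(asm, distance = dist)
    guid <- asm$gaps$uid[nrow(asm$gaps)]
    created <- asm$gaps$name[nrow(asm$gaps)]
    # the two sides of the excision are now adjacent; insert the gap there
    at <- min(span) - 1L
    el <- dplyr::bind_rows(el[seq_len(at), , drop = FALSE],
                           path_elements("gap", guid, "+"),
                           el[(at + 1L):nrow(el), , drop = FALSE])
  }
  old_name <- asm$paths$name[loc$path]
  if (nrow(el) == 0L || all(el$kind == "gap")) {
    # nothing sequence-bearing left: drop the path and its stray gaps
    stray <- el$uid[el$kind == "gap"]
    deleted <- c(deleted, asm$gaps$name[match(stray, asm$gaps$uid)])
    asm <- delete_gap_records(asm, stray)
    asm$paths <- asm$paths[-loc$path, , drop = FALSE]
    deleted <- c(deleted, old_name)
  } else {
    asm <- set_path_elements(asm, loc$path, el)
  }
  list(asm = asm, created = created, deleted = deleted, path_name = old_name)
}

sak_op_excise <- function(asm, segment, gap_len = NULL,
                          unknown_gap_size = 100L) {
  suid <- resolve_segment(asm, segment)
  res <- excise_core(asm, suid, gap_len, unknown_gap_size)
  asm <- res$asm
  nm <- unique_path_name(asm, segment)
  asm <- add_path(asm, nm, path_elements("segment", suid, "+"))
  list(asm = asm,
       effect = sprintf("excised %s from %s into singleton %s",
                        segment, res$path_name, nm),
       created = c(nm, res$created), deleted = res$deleted)
}

sak_op_remove <- function(asm, segment, unknown_gap_size = 100L) {
  suid <- resolve_segment(asm, segment)
  res <- excise_core(asm, suid, NULL, unknown_gap_size)
  asm <- res$asm
  asm$segments <- asm$segments[asm$segments$uid != suid, , drop = FALSE]
  asm$edges <- asm$edges[asm$edges$seg1 != suid & asm$edges$seg2 != suid, ,
                         drop = FALSE]
  list(asm = asm,
       effect = sprintf("removed %s from %s", segment, res$path_name),
       created = res$created, deleted = c(segment, res$deleted))
}

sak_op_erase <- function(asm, scaffold, range, unknown_gap_size = 100L) {
  m <- stringr::str_match(range, "^([0-9]+)-([0-9]+)$")
  if (is.na(m[1])) stop("ERASE range must be start-end, got '", range, "'")
  start <- as.integer(m[2]); end <- as.integer(m[3])
  puid <- resolve_scaffold(asm, scaffold)
  k <- match(puid, asm$paths$uid)
  el <- asm$paths$elements[[k]]
  sp <- path_spans(asm, el, unknown_gap_size)
  total <- if (nrow(sp)) sp$end[nrow(sp)] else 0L
  if (start < 0L || end > total || start >= end) {
    stop("range ", start, "-", end, " out of bounds for scaffold '",
         scaffold, "' (length ", total, ")")
  }
  new_el <- path_elements()
  created <- character(); deleted <- character()
  erased_bases <- 0L
  for (j in seq_len(nrow(el))) {
    a <- sp$start[j]; b <- sp$end[j]
    ov_a <- max(a, start); ov_b <- min(b, end)
    if (ov_a >= ov_b) {                       # untouched
      new_el <- dplyr::bind_rows(new_el, el[j, , drop = FALSE])
      next
    }
    if (el$kind[j] == "gap") {
      gi <- match(el$uid[j], asm$gaps$uid)
      if (ov_a == a && ov_b == b) {           # whole gap erased
        deleted <- c(deleted, asm$gaps$name[gi])
        asm$gaps <- asm$gaps[-gi, , drop = FALSE]
      } else {                                # part of the gap; now sized
        asm$gaps$distance[gi] <- as.integer((b - a) - (ov_b - ov_a))
        new_el <- dplyr::bind_rows(new_el, el[j, , drop = FALSE])
      }
      next
    }
    si <- match(el$uid[j], asm$segments$uid)
    if (ov_a == a && ov_b == b) {             # whole segment erased
      erased_bases <- erased_bases + (b - a)
      deleted <- c(deleted, asm$segments$name[si])
      asm$segments <- asm$segments[-si, , drop = FALSE]
      next
    }
    # partial segment: coordinates within the segment follow its orientation
    slen <- b - a
    if (el$orient[j] == "+") {
      cut_a <- ov_a - a; cut_b <- ov_b - a
    } else {
      cut_a <- slen - (ov_b - a); cut_b <- slen - (ov_a - a)
    }
    erased_bases <- erased_bases + (cut_b - cut_a)
    pieces <- segment_cutout(asm, si, cut_a, cut_b)
    asm <- pieces$asm
    for (piece in pieces$keep) {
      created <- c(created, piece$name)
      new_el <- dplyr::bind_rows(
        new_el, path_elements("segment", piece$uid, el$orient[j]))
    }
    if (el$orient[j] == "-" && length(pieces$keep) == 2L) {
      # pieces were appended in segment coordinates; path order reverses them
      n <- nrow(new_el)
      new_el <- new_el[c(seq_len(n - 2L), n, n - 1L), , drop = FALSE]
    }
    deleted <- c(deleted, pieces$old_name)
  }
  norm <- normalize_elements(asm, new_el)
  asm <- norm$asm
  deleted <- c(deleted, norm$deleted)
  if (nrow(norm$el) == 0L) {
    asm$paths <- asm$paths[-k, , drop = FALSE]
    deleted <- c(deleted, scaffold)
  } else {
    asm <- set_path_elements(asm, k, norm$el)
  }
  list(asm = asm,
       effect = sprintf("erased %d-%d of %s (%d contig bases)",
                        start, end, scaffold, erased_bases),
       created = created, deleted = deleted)
}

# remove [cut_a, cut_b) (segment coordinates) from segment index `si`;
# returns the retained piece(s) in segment-coordinate order
segment_cutout <- function(asm, si, cut_a, cut_b) {
  s <- asm$segments[si, , drop = FALSE]
  if (is.na(s$sequence)) {
    stop("segment '", s$name, "' has no stored sequence; cannot erase into it")
  }
  old_name <- s$name
  slice <- function(from, to) {        # 0-based half-open
    list(seq = substr(s$sequence, from + 1L, to),
         qual = if (is.na(s$qualities)) NA_character_ else
           substr(s$qualities, from + 1L, to))
  }
  keep_spans <- list()
  if (cut_a > 0L) keep_spans$left <- c(0L, cut_a)
  if (cut_b < s$length) keep_spans$right <- c(cut_b, s$length)
  asm$segments <- asm$segments[-si, , drop = FALSE]
  keep <- list()
  suffixes <- if (length(keep_spans) == 2L) c(".1", ".2") else ""
  for (i in seq_along(keep_spans)) {
    sp <- keep_spans[[i]]
    part <- slice(sp[1], sp[2])
    nm <- unique_seg_name(asm, paste0(old_name, suffixes[i]))
    asm <- add_segment(asm, nm, sequence = part$seq, qualities = part$qual,
                       tags = s$tags[[1]])
    keep[[i]] <- list(uid = asm$segments$uid[nrow(asm$segments)], name = nm)
  }
  list(asm = asm, keep = keep, old_name = old_name)
}

sak_op_rvcp <- function(asm, name) {
  pu <- path_uid(asm, name)
  if (!is.na(pu)) {
    k <- match(pu, asm$paths$uid)
    asm <- set_path_elements(asm, k, rc_elements(asm$paths$elements[[k]]))
    return(list(asm = asm,
                effect = sprintf("reverse-complemented scaffold %s", name),
                created = character(), deleted = character()))
  }
  suid <- resolve_segment(asm, name)
  i <- match(suid, asm$segments$uid)
  if (is.na(asm$segments$sequence[i])) {
    stop("segment '", name, "' has no stored sequence")
  }
  asm$segments$sequence[i] <- revcomp(asm$segments$sequence[i])
  if (!is.na(asm$segments$qualities[i])) {
    asm$segments$qualities[i] <- stringi::stri_reverse(asm$segments$qualities[i])
  }
  list(asm = asm, effect = sprintf("reverse-complemented segment %s", name),
       created = character(), deleted = character())
}

sak_op_invert <- function(asm, segment) {
  suid <- resolve_segment(asm, segment)
  loc <- locate_segment(asm, suid)
  if (is.null(loc)) stop("segment '", segment, "' is in no scaffold")
  el <- asm$paths$elements[[loc$path]]
  el$orient[loc$pos] <- if (el$orient[loc$pos] == "+") "-" else "+"
  asm <- set_path_elements(asm, loc$path, el)
  list(asm = asm,
       effect = sprintf("inverted %s within %s", segment,
                        asm$paths$name[loc$path]),
       created = character(), deleted = character())
}

sak_op_trim_ns <- function(asm, scaffold = NULL) {
  targets <- if (is.null(scaffold)) seq_len(nrow(asm$paths)) else
    match(resolve_scaffold(asm, scaffold), asm$paths$uid)
  deleted <- character()
  dropped_paths <- integer()
  for (k in targets) {
    el <- asm$paths$elements[[k]]
    while (nrow(el) > 0L && el$kind[1] == "gap") {
      deleted <- c(deleted, asm$gaps$name[match(el$uid[1], asm$gaps$uid)])
      asm <- delete_gap_records(asm, el$uid[1])
      el <- el[-1, , drop = FALSE]
    }
    while (nrow(el) > 0L && el$kind[nrow(el)] == "gap") {
      deleted <- c(deleted,
                   asm$gaps$name[match(el$uid[nrow(el)], asm$gaps$uid)])
      asm <- delete_gap_records(asm, el$uid[nrow(el)])
      el <- el[-nrow(el), , drop = FALSE]
    }
    if (nrow(el) == 0L) {
      dropped_paths <- c(dropped_paths, k)
      deleted <- c(deleted, asm$paths$name[k])
    } else {
      asm$paths$elements[[k]] <- el
    }
  }
  if (length(dropped_paths)) {
    asm$paths <- asm$paths[-dropped_paths, , drop = FALSE]
  }
  list(asm = asm,
       effect = sprintf("trimmed terminal gaps (%d removed)%s",
                        length(deleted),
                        if (is.null(scaffold)) "" else paste0(" of ", scaffold)),
       created = character(), deleted = deleted)
}

sak_op_rename <- function(asm, old, new) {
  pu <- path_uid(asm, old)
  if (!is.na(pu)) {
    if (new %in% asm$paths$name) stop("scaffold name '", new, "' already in use")
    asm$paths$name[match(pu, asm$paths$uid)] <- new
    return(list(asm = asm,
                effect = sprintf("renamed scaffold %s to %s", old, new),
                created = new, deleted = old))
  }
  suid <- resolve_segment(asm, old)
  if (new %in% asm$segments$name) stop("segment name '", new, "' already in use")
  asm$segments$name[match(suid, asm$segments$uid)] <- new
  list(asm = asm, effect = sprintf("renamed segment %s to %s", old, new),
       created = new, deleted = old)
}

# ---- exported single-operation wrappers -----------------------------------

#' Individual SAK edit operations
#'
#' Thin wrappers over the script verbs for programmatic use; each returns
#' the edited assembly. [sak_execute()] offers the same operations with
#' change logging and transactional semantics.
#'
#' @inheritParams add_segment
#' @param a,b Path end specs `name[+-]` (`-` reverse-complements that
#'   scaffold before joining).
#' @param gap_len Gap length in bp, or `"*"` for unknown.
#' @param new_name Name for the joined scaffold (default: first scaffold's).
#' @return The edited assembly.
#' @export
sak_join <- function(asm, a, b, gap_len = "*", new_name = NULL) {
  sak_op_join(asm, a, b, gap_len, new_name)$asm
}

#' @rdname sak_join
#' @param seg1,seg2 Names of two segments adjacent across one gap.
#' @export
sak_split <- function(asm, seg1, seg2) sak_op_split(asm, seg1, seg2)$asm

#' @rdname sak_join
#' @param segment Segment name.
#' @export
sak_excise <- function(asm, segment, gap_len = NULL) {
  sak_op_excise(asm, segment, gap_len)$asm
}

#' @rdname sak_join
#' @export
sak_remove <- function(asm, segment) sak_op_remove(asm, segment)$asm

#' @rdname sak_join
#' @param scaffold Scaffold name (`NULL` in [sak_trim_ns()] = all scaffolds).
#' @param range Coordinate range `"start-end"`, 0-based half-open.
#' @export
sak_erase <- function(asm, scaffold, range) {
  sak_op_erase(asm, scaffold, range)$asm
}

#' @rdname sak_join
#' @param name Scaffold or segment name (scaffolds take precedence).
#' @export
sak_rvcp <- function(asm, name) sak_op_rvcp(asm, name)$asm

#' @rdname sak_join
#' @export
sak_invert <- function(asm, segment) sak_op_invert(asm, segment)$asm

#' @rdname sak_join
#' @export
sak_trim_ns <- function(asm, scaffold = NULL) sak_op_trim_ns(asm, scaffold)$asm

#' @rdname sak_join
#' @param old,new Old and new element name.
#' @export
sak_rename <- function(asm, old, new) sak_op_rename(asm, old, new)$asm
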