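#' Build the bidirected assembly graph
#'
#' Nodes are segments; every gap or overlap edge attaches to a specific side
#' (head/tail) of each of its segments, so traversal direction determines
#' strand. The graph is held as a symmetric incidence table (adjacency-list
#' form): an internal edge contributes one row per attached end, a terminal
#' gap (one open side) appears once with `other_seg = NA`.
#'
#' @inheritParams add_segment
#' @param include_edges Include overlap edges as connections (default `TRUE`).
#' @return An object of class `assembly_graph`: a list with `segment_uids`
#'   and the `incidences` tibble (`seg`, `side`, `kind`, `edge_uid`,
#'   `other_seg`, `other_side`).
#' @export
build_graph <- function(asm, include_edges = TRUE) {
  inc <- list()
  g <- asm$gaps
  for (k in seq_len(nrow(g))) {
    ends <- list(c(g$seg1[k], g$side1[k]), c(g$seg2[k], g$side2[k]))
    attached <- !is.na(c(g$seg1[k], g$seg2[k]))
    for (sid in c(g$seg1[k], g$seg2[k])) {
      if (!is.na(sid) && !(sid %in% asm$segments$uid)) {
        stop("gap '", g$name[k], "' references a segment that does not exist")
      }
    }
    if (all(attached)) {
      inc[[length(inc) + 1L]] <- tibble::tibble(
        seg = c(g$seg1[k], g$seg2[k]), side = c(g$side1[k], g$side2[k]),
        kind = "gap", edge_uid = g$uid[k],
        other_seg = c(g$seg2[k], g$seg1[k]),
        other_side = c(g$side2[k], g$side1[k])
      )
    } else if (any(attached)) {
      i <- which(attached)[1]
      inc[[length(inc) + 1L]] <- tibble::tibble(
        seg = as.integer(ends[[i]][1]), side = ends[[i]][2],
        kind = "gap", edge_uid = g$uid[k],
        other_seg = NA_integer_, other_side = NA_character_
      )
    }
  }
  if (include_edges) {
    e <- asm$edges
    for (k in seq_len(nrow(e))) {
      if (!(e$seg1[k] %in% asm$segments$uid) ||
          !(e$seg2[k] %in% asm$segments$uid)) {
        stop("edge '", e$name[k], "' references a segment that does not exist")
      }
      # GFA convention: '+' on the first segment means its tail is involved,
      # '+' on the second means its head
      s1 <- if (e$orient1[k] == "+") "T" else "H"
      s2 <- if (e$orient2[k] == "+") "H" else "T"
      inc[[length(inc) + 1L]] <- tibble::tibble(
        seg = c(e$seg1[k], e$seg2[k]), side = c(s1, s2),
        kind = "overlap", edge_uid = e$uid[k],
        other_seg = c(e$seg2[k], e$seg1[k]), other_side = c(s2, s1)
      )
    }
  }
  incidences <- if (length(inc)) {
    dplyr::bind_rows(inc)
  } else {
    tibble::tibble(seg = integer(), side = character(), kind = character(),
                   edge_uid = integer(), other_seg = integer(),
                   other_side = character())
  }
  structure(
    list(segment_uids = sort(asm$segments$uid), incidences = incidences),
    class = "assembly_graph"
  )
}

#' @export
print.assembly_graph <- function(x, ...) {
  internal <- x$incidences[!is.na(x$incidences$other_seg), , drop = FALSE]
  cat(sprintf("<assembly_graph> %d nodes, %d internal connections, %d terminal gaps\n",
              length(x$segment_uids), nrow(internal) / 2,
              sum(is.na(x$incidences$other_seg))))
  invisible(x)
}

#' Walk the graph into connected components
#'
#' Depth-first traversal over the bidirected graph. Components whose every
#' segment side carries at most one internal connection (and that contain no
#' cycle) are simple paths and come back with a unique end-to-end order and
#' per-segment orientation; anything else is flagged as branching and left
#' unordered. Traversal is deterministic: start segments are taken in
#' ascending uid, neighbours in insertion order.
#'
#' @param graph An [assembly_graph][build_graph].
#' @return A tibble with one row per component: `component` (index),
#'   `segments` (list of segment uids), `branching` (logical) and `order`
#'   (list of tibbles `uid`/`orient`, `NULL` when branching).
#' @export
walk_components <- function(graph) {
  inc <- graph$incidences[!is.na(graph$incidences$other_seg), , drop = FALSE]
  # adjacency keyed by "uid:side", preserving insertion order
  key <- paste0(inc$seg, ":", inc$side)
  adj <- split(seq_len(nrow(inc)), factor(key, levels = unique(key)))
  seen <- new.env(parent = emptyenv())
  comps <- list()
  for (start in graph$segment_uids) {
    sk <- as.character(start)
    if (!is.null(seen[[sk]])) next
    # flood-fill the component
    members <- integer()
    stack <- start
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      uk <- as.character(u)
      if (!is.null(seen[[uk]])) next
      seen[[uk]] <- TRUE
      members <- c(members, u)
      nb <- inc$other_seg[inc$seg == u]
      stack <- c(stack, nb[vapply(as.character(nb),
                                  function(k) is.null(seen[[k]]), logical(1))])
    }
    members <- sort(members)
    sub <- inc[inc$seg %in% members, , drop = FALSE]
    deg <- table(paste0(sub$seg, ":", sub$side))
    n_conn <- nrow(sub) / 2
    branching <- any(deg > 1L) || n_conn >= length(members)  # cycle check
    order_tbl <- NULL
    if (!branching) {
      order_tbl <- linearize_component(members, sub)
    }
    comps[[length(comps) + 1L]] <- tibble::tibble(
      component = length(comps) + 1L, segments = list(members),
      branching = branching, order = list(order_tbl)
    )
  }
  if (length(comps)) dplyr::bind_rows(comps) else {
    tibble::tibble(component = integer(), segments = list(),
                   branching = logical(), order = list())
  }
}

# order a degree-<=1-per-side acyclic component end to end; `sub` holds its
# internal incidences (both directions)
linearize_component <- function(members, sub) {
  if (length(members) == 1L) {
    return(tibble::tibble(uid = members, orient = "+"))
  }
  # endpoints: segments with a side having no internal connection
  used_key <- paste0(sub$seg, ":", sub$side)
  endpoints <- members[vapply(members, function(u) {
    sum(sub$seg == u) == 1L
  }, logical(1))]
  start <- min(endpoints)
  first_row <- which(sub$seg == start)[1]
  exit_side <- sub$side[first_row]
  orient <- if (exit_side == "T") "+" else "-"
  uid_order <- start
  orients <- orient
  prev_edge <- sub$edge_uid[first_row]
  cur <- sub$other_seg[first_row]
  cur_enter <- sub$other_side[first_row]
  while (!is.na(cur)) {
    orients <- c(orients, if (cur_enter == "H") "+" else "-")
    uid_order <- c(uid_order, cur)
    exit_side <- if (cur_enter == "H") "T" else "H"
    nxt <- which(sub$seg == cur & sub$side == exit_side &
                   sub$edge_uid != prev_edge)
    if (length(nxt) == 0L) break
    prev_edge <- sub$edge_uid[nxt[1]]
    cur_enter <- sub$other_side[nxt[1]]
    cur <- sub$other_seg[nxt[1]]
  }
  tibble::tibble(uid = uid_order, orient = orients)
}

#' Synthesize scaffold paths for path-less inputs
#'
#' GFA inputs may define segments and gaps without ordered-group/path lines.
#' Every non-branching component connected by gap edges becomes one scaffold
#' path (terminal gaps included at the matching end); branching components
#' contribute each segment as a singleton path, with a warning. Segments
#' already covered by a path, and existing paths, are left untouched.
#'
#' @inheritParams add_segment
#' @return The assembly with every segment covered by a path.
#' @export
paths_from_graph <- function(asm) {
  placed <- unlist(lapply(asm$paths$elements,
                          function(el) el$uid[el$kind == "segment"]))
  graph <- build_graph(asm, include_edges = FALSE)
  comps <- walk_components(graph)
  counter <- 0L
  for (k in seq_len(nrow(comps))) {
    members <- comps$segments[[k]]
    if (any(members %in% placed)) next
    if (comps$branching[k]) {
      warning("branching component; emitting its ", length(members),
              " segments as singleton scaffolds", call. = FALSE)
      for (u in members) {
        nm <- unique_path_name(asm, asm$segments$name[match(u, asm$segments$uid)])
        asm <- add_path(asm, nm, path_elements("segment", u, "+"))
      }
      next
    }
    ord <- comps$order[[k]]
    el <- path_elements()
    # leading terminal gap on the entering side of the first segment
    first_enter <- if (ord$orient[1] == "+") "H" else "T"
    tg <- terminal_gap_at(asm, ord$uid[1], first_enter)
    if (!is.na(tg)) el <- tibble::add_row(el, kind = "gap", uid = tg, orient = "+")
    for (i in seq_len(nrow(ord))) {
      if (i > 1L) {
        prev_exit <- if (ord$orient[i - 1L] == "+") "T" else "H"
        guid <- connecting_gap(asm, ord$uid[i - 1L], prev_exit, ord$uid[i])
        el <- tibble::add_row(el, kind = "gap", uid = guid, orient = "+")
      }
      el <- tibble::add_row(el, kind = "segment", uid = ord$uid[i],
                            orient = ord$orient[i])
    }
    last_exit <- if (ord$orient[nrow(ord)] == "+") "T" else "H"
    tg <- terminal_gap_at(asm, ord$uid[nrow(ord)], last_exit)
    if (!is.na(tg)) el <- tibble::add_row(el, kind = "gap", uid = tg, orient = "+")
    counter <- counter + 1L
    nm <- if (nrow(ord) == 1L) {
      asm$segments$name[match(ord$uid[1], asm$segments$uid)]
    } else {
      paste0("scaffold_", counter)
    }
    asm <- add_path(asm, unique_path_name(asm, nm), el)
    asm <- refresh_path_gaps(asm, asm$paths$uid[nrow(asm$paths)])
  }
  asm
}

# gap with exactly one attached end at (seg, side), or NA
terminal_gap_at <- function(asm, seg, side) {
  g <- asm$gaps
  open1 <- is.na(g$seg1)
  open2 <- is.na(g$seg2)
  hit <- (open2 & !open1 & g$seg1 == seg & g$side1 == side) |
    (open1 & !open2 & g$seg2 == seg & g$side2 == side)
  hit[is.na(hit)] <- FALSE
  if (any(hit)) g$uid[which(hit)[1]] else NA_integer_
}

# the gap connecting (seg a at side) to segment b
connecting_gap <- function(asm, a, side, b) {
  g <- asm$gaps
  hit <- (!is.na(g$seg1) & !is.na(g$seg2)) &
    ((g$seg1 == a & g$side1 == side & g$seg2 == b) |
       (g$seg2 == a & g$side2 == side & g$seg1 == b))
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) {
    stop("no gap connects segments ", a, " and ", b)
  }
  g$uid[which(hit)[1]]
}

unique_path_name <- function(asm, name) {
  if (!(name %in% asm$paths$name)) return(name)
  i <- 1L
  repeat {
    cand <- paste0(name, "_", i)
    if (!(cand %in% asm$paths$name)) return(cand)
    i <- i + 1L
  }
}
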