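# Assembly summary statistics: Nx/Lx (and NGx/LGx against an expected genome
# size), auN, base composition, and the full three-tier report
# (scaffold / contig / gap).

#' Nx and Lx contiguity statistics
#'
#' Nx is the length of the shortest sequence in the minimal set of longest
#' sequences whose summed length reaches at least `x` percent of
#' `reference_total`; Lx is the number of sequences in that set. With the
#' assembly total as reference this is the classic N50/L50 family; with an
#' expected genome size it is NGx/LGx. Ties at exact thresholds take the
#' first qualifying prefix in descending order ("\eqn{\ge} half"
#' convention).
#'
#' @param lengths Positive sequence lengths (bp).
#' @param x Threshold percentage in (0, 100].
#' @param reference_total Reference total (bp); defaults to `sum(lengths)`.
#' @return A one-row tibble `x`/`nx`/`lx`; `nx`/`lx` are `NA` when `x`% of
#'   the reference exceeds the summed lengths (NGx undefined).
#' @export
#' @examples
#' nx(c(10, 8, 6, 4, 2), 50)            # N50 = 8, L50 = 2
#' nx(c(10, 8, 6, 4, 2), 50, 40)        # NG50 = 6, LG50 = 3
nx <- function(lengths, x = 50, reference_total = sum(lengths)) {
  if (length(lengths) == 0L || any(lengths <= 0)) {
    stop("lengths must be non-empty and positive")
  }
  if (!is.numeric(reference_total) || reference_total <= 0) {
    stop("reference_total must be positive")
  }
  if (x <= 0 || x > 100) stop("x must be in (0, 100]")
  sorted <- sort(as.numeric(lengths), decreasing = TRUE)
  target <- x / 100 * reference_total
  csum <- cumsum(sorted)
  idx <- which(csum >= target)
  if (length(idx) == 0L) {
    return(tibble::tibble(x = x, nx = NA_real_, lx = NA_integer_))
  }
  tibble::tibble(x = x, nx = sorted[idx[1]], lx = idx[1])
}

#' Area under the Nx curve (auN)
#'
#' \eqn{auN = \sum_i L_i^2 / \sum_i L_i}: the expected Nx value over a
#' uniformly random x, a contiguity metric insensitive to the 50% threshold.
#' Reported to 2 decimals.
#'
#' @param lengths Positive sequence lengths (bp).
#' @return auN in bp (2 decimals); `NA` for an empty set.
#' @export
#' @examples
#' aun(c(10, 8, 6, 4, 2))  # 220/30 = 7.33
aun <- function(lengths) {
  if (length(lengths) == 0L) return(NA_real_)
  lengths <- as.numeric(lengths)
  round(sum(lengths^2) / sum(lengths), 2)
}

#' Base composition of an assembly
#'
#' Counts are taken over segment sequences only (gap Ns are accounted as gap
#' length, not composition). GC is `100 (G+C) / (A+C+G+T)`,
#' case-insensitive; N and other IUPAC ambiguity codes are excluded from the
#' GC denominator, with non-N ambiguity codes tallied as `other`. Lowercase
#' (soft-masked) bases count both in their base tally and in `soft_masked`.
#'
#' @inheritParams add_segment
#' @return A list with `base_counts` (named: A, C, G, T, N, other),
#'   `gc_content` (percent, 2 decimals; `NA` when no unambiguous bases) and
#'   `soft_masked`.
#' @export
base_composition <- function(asm) {
  seqs <- asm$segments$sequence
  seqs <- seqs[!is.na(seqs)]
  count_set <- function(chars) {
    if (length(seqs) == 0L) return(0)
    sum(stringr::str_count(seqs, stringr::fixed(chars[1]))) +
      sum(stringr::str_count(seqs, stringr::fixed(chars[2])))
  }
  counts <- c(
    A = count_set(c("A", "a")), C = count_set(c("C", "c")),
    G = count_set(c("G", "g")), T = count_set(c("T", "t")),
    N = count_set(c("N", "n"))
  )
  total_chars <- if (length(seqs)) sum(nchar(seqs)) else 0
  counts <- c(counts, other = total_chars - sum(counts))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  gc <- if (acgt > 0) round(100 * sum(counts[c("G", "C")]) / acgt, 2) else NA_real_
  soft <- if (length(seqs)) sum(stringr::str_count(seqs, "[a-z]")) else 0
  list(base_counts = counts, gc_content = gc, soft_masked = soft)
}

#' Full assembly summary-statistics report
#'
#' Computes the three-tier report: scaffolds (linearized path lengths),
#' contigs (segment lengths) and gaps (distances, unknown gaps at the
#' placeholder length), with counts, totals, largest and mean lengths, N50 /
#' L50 per tier, NG50 / LG50 when a genome size is supplied, auN per tier,
#' base composition, and graph element counts including connected
#' components.
#'
#' @inheritParams add_segment
#' @param genome_size Optional expected genome size (bp) enabling NG50/LG50.
#' @param unknown_gap_size Placeholder length for unknown gaps (bp).
#' @return An object of class `assembly_stats`. Use `print()` for the
#'   key: value report, [tidy()][generics::tidy] / [glance()][generics::glance]
#'   for tibbles, and [autoplot()][ggplot2::autoplot] for the Nx curve.
#' @export
summarize_assembly <- function(asm, genome_size = NULL,
                               unknown_gap_size = 100L) {
  scaf_len <- as.numeric(path_lengths(asm, unknown_gap_size))
  contig_len <- as.numeric(asm$segments$length)
  gap_len <- as.numeric(gap_effective_length(asm$gaps$distance,
                                             unknown_gap_size))
  tier <- function(lens, ref = sum(lens)) {
    if (length(lens) == 0L || sum(lens) == 0) {
      return(list(n50 = NA_real_, l50 = NA_integer_, aun = NA_real_))
    }
    pos <- lens[lens > 0]
    r <- nx(pos, 50, ref)
    list(n50 = r$nx, l50 = r$lx, aun = aun(pos))
  }
  st <- tier(scaf_len)
  ct <- tier(contig_len)
  ng <- list(scaffold = list(n50 = NA_real_, l50 = NA_integer_),
             contig = list(n50 = NA_real_, l50 = NA_integer_))
  if (!is.null(genome_size)) {
    if (length(scaf_len) && any(scaf_len > 0)) {
      r <- nx(scaf_len[scaf_len > 0], 50, genome_size)
      ng$scaffold <- list(n50 = r$nx, l50 = r$lx)
    }
    if (length(contig_len) && any(contig_len > 0)) {
      r <- nx(contig_len[contig_len > 0], 50, genome_size)
      ng$contig <- list(n50 = r$nx, l50 = r$lx)
    }
  }
  comp <- base_composition(asm)
  graph <- build_graph(asm)
  comps <- walk_components(graph)
  seg_n <- unname(comp$base_counts["N"])
  res <- list(
    n_scaffolds = length(scaf_len),
    n_contigs = length(contig_len),
    n_gaps = length(gap_len),
    n_unknown_gaps = sum(is.na(asm$gaps$distance)),
    total_scaffold_len = sum(scaf_len),
    total_contig_len = sum(contig_len),
    total_gap_len = sum(gap_len),
    largest_scaffold = if (length(scaf_len)) max(scaf_len) else 0,
    largest_contig = if (length(contig_len)) max(contig_len) else 0,
    largest_gap = if (length(gap_len)) max(gap_len) else 0,
    mean_scaffold_len = if (length(scaf_len)) round(mean(scaf_len), 2) else 0,
    mean_contig_len = if (length(contig_len)) round(mean(contig_len), 2) else 0,
    mean_gap_len = if (length(gap_len)) round(mean(gap_len), 2) else 0,
    scaffold_n50 = st$n50, scaffold_l50 = st$l50, scaffold_aun = st$aun,
    contig_n50 = ct$n50, contig_l50 = ct$l50, contig_aun = ct$aun,
    scaffold_ng50 = ng$scaffold$n50, scaffold_lg50 = ng$scaffold$l50,
    contig_ng50 = ng$contig$n50, contig_lg50 = ng$contig$l50,
    genome_size = if (is.null(genome_size)) NA_real_ else genome_size,
    base_counts = comp$base_counts,
    n_count = seg_n + sum(gap_len),
    gc_content = comp$gc_content,
    soft_masked = comp$soft_masked,
    graph_segments = nrow(asm$segments),
    graph_edges = nrow(asm$edges),
    graph_gaps = nrow(asm$gaps),
    graph_paths = nrow(asm$paths),
    graph_components = nrow(comps),
    scaffold_lengths = scaf_len,
    contig_lengths = contig_len
  )
  structure(res, class = "assembly_stats")
}

stats_fields <- function(x) {
  flat <- c(
    "n_scaffolds", "n_contigs", "n_gaps", "n_unknown_gaps",
    "total_scaffold_len", "total_contig_len", "total_gap_len",
    "largest_scaffold", "largest_contig", "largest_gap",
    "mean_scaffold_len", "mean_contig_len", "mean_gap_len",
    "scaffold_n50", "scaffold_l50", "scaffold_aun",
    "contig_n50", "contig_l50", "contig_aun",
    "scaffold_ng50", "scaffold_lg50", "contig_ng50", "contig_lg50",
    "gc_content", "soft_masked", "n_count",
    "graph_segments", "graph_edges", "graph_gaps", "graph_paths",
    "graph_components"
  )
  vals <- vapply(flat, function(f) as.numeric(x[[f]]), numeric(1))
  base <- x$base_counts
  c(vals,
    stats::setNames(as.numeric(base),
                    paste0("base_", c("a", "c", "g", "t", "n", "other"))))
}

#' @export
print.assembly_stats <- function(x, ...) {
  vals <- stats_fields(x)
  show <- !(names(vals) %in%
              c("scaffold_ng50", "scaffold_lg50",
                "contig_ng50", "contig_lg50")) | !is.na(x$genome_size)
  for (nm in names(vals)[show]) {
    v <- vals[[nm]]
    out <- if (is.na(v)) "NA"
           else if (v == round(v)) format(v, scientific = FALSE)
           else format(round(v, 2), nsmall = 2, scientific = FALSE)
    cat(nm, ": ", out, "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an assembly-statistics report
#'
#' @param x An `assembly_stats` object.
#' @param ... Unused.
#' @return `tidy()`: a long tibble `metric`/`value`; `glance()`: a one-row
#'   wide tibble, suitable for TSV export of many assemblies.
#' @export
tidy.assembly_stats <- function(x, ...) {
  vals <- stats_fields(x)
  tibble::tibble(metric = names(vals), value = unname(vals))
}

#' @rdname tidy.assembly_stats
#' @export
glance.assembly_stats <- function(x, ...) {
  vals <- stats_fields(x)
  tibble::as_tibble(as.list(vals))
}

#' Nx curve plot for an assembly report
#'
#' Draws Nx against x (1..100) for the scaffold and contig tiers; auN is the
#' area under each curve (divided by 100).
#'
#' @param object An `assembly_stats` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.assembly_stats <- function(object, ...) {
  curve <- function(lens, tier) {
    lens <- lens[lens > 0]
    if (length(lens) == 0L) return(NULL)
    xs <- 1:100
    ns <- vapply(xs, function(xx) nx(lens, xx)$nx, numeric(1))
    tibble::tibble(x = xs, nx = ns, tier = tier)
  }
  df <- dplyr::bind_rows(curve(object$scaffold_lengths, "scaffold"),
                         curve(object$contig_lengths, "contig"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$nx,
                                   colour = .data$tier)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "x (%)", y = "Nx (bp)", colour = NULL,
                  title = "Nx curve") +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.assembly <- function(object, ...) {
  lens <- path_lengths(object)
  df <- tibble::tibble(name = names(lens), length = as.numeric(lens))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "scaffold length (bp)", y = "count") +
    ggplot2::theme_minimal()
}

#' Per-scaffold statistics table
#'
#' One row per scaffold, in assembly order; column sums match the
#' corresponding report totals.
#'
#' @inheritParams summarize_assembly
#' @return A tibble `name`, `length`, `n_contigs`, `n_gaps`, `gap_bp`, `gc`.
#' @export
per_sequence_stats <- function(asm, unknown_gap_size = 100L) {
  rows <- lapply(seq_len(nrow(asm$paths)), function(k) {
    el <- asm$paths$elements[[k]]
    segs <- el$uid[el$kind == "segment"]
    gaps <- el$uid[el$kind == "gap"]
    gap_bp <- sum(gap_effective_length(
      asm$gaps$distance[match(gaps, asm$gaps$uid)], unknown_gap_size))
    seqs <- asm$segments$sequence[match(segs, asm$segments$uid)]
    seqs <- seqs[!is.na(seqs)]
    gc <- if (length(seqs)) {
      up <- toupper(paste0(seqs, collapse = ""))
      acgt <- sum(stringr::str_count(up, c("A", "C", "G", "T")))
      if (acgt > 0) {
        round(100 * sum(stringr::str_count(up, c("G", "C"))) / acgt, 2)
      } else NA_real_
    } else NA_real_
    seg_len <- sum(asm$segments$length[match(segs, asm$segments$uid)])
    tibble::tibble(
      name = asm$paths$name[k],
      length = as.numeric(seg_len + gap_bp),
      n_contigs = length(segs), n_gaps = length(gaps),
      gap_bp = as.numeric(gap_bp), gc = gc
    )
  })
  if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(name = character(), length = numeric(),
                   n_contigs = integer(), n_gaps = integer(),
                   gap_bp = numeric(), gc = numeric())
  }
}
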