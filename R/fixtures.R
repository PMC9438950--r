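# Seeded synthetic-assembly generator. Emits an assembly with known
# ground-truth statistics computed from the generation bookkeeping by naive
# inline arithmetic — deliberately independent of the stats module, so the
# two can be checked against each other.

#' Generate a synthetic assembly with ground-truth statistics
#'
#' Scaffold composition follows the distributions typical of long-read
#' vertebrate-scale assemblies, scaled down: contig lengths are log-normal,
#' gaps per scaffold Poisson, gap lengths log-normal (minimum 1 bp so every
#' gap is visible in linear formats), with optional unknown-size gaps,
#' terminal gaps and per-base qualities. The same seed always yields a
#' byte-identical assembly.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param contig_meanlog,contig_sdlog Log-normal parameters for contig
#'   length (bp); defaults centre near 3 kbp.
#' @param gaps_per_scaffold Poisson mean for the internal gap count.
#' @param gap_meanlog,gap_sdlog Log-normal parameters for sized gap length.
#' @param unknown_gap_fraction Fraction of internal gaps with unknown size.
#' @param terminal_gap_prob Probability of a terminal gap at each scaffold
#'   end.
#' @param gc GC fraction used to bias base sampling.
#' @param with_qualities Attach random Phred qualities (FASTQ-style).
#' @param unknown_gap_size Placeholder length for unknown gaps in the
#'   ground-truth arithmetic (bp).
#' @param seed Integer seed; all randomness is confined to this function.
#' @return A list with `assembly` and `truth` (a list of summary-statistic
#'   fields computed from the generation bookkeeping).
#' @export
generate_fixture <- function(n_scaffolds = 10, contig_meanlog = 8,
                             contig_sdlog = 1, gaps_per_scaffold = 2,
                             gap_meanlog = 4, gap_sdlog = 0.7,
                             unknown_gap_fraction = 0,
                             terminal_gap_prob = 0.15, gc = 0.42,
                             with_qualities = FALSE, unknown_gap_size = 100L,
                             seed = 1L) {
  stopifnot(n_scaffolds >= 1, gc > 0, gc < 1)
  withr::with_seed(as.integer(seed), {
    asm <- new_assembly()
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    base_tally <- c(A = 0, C = 0, G = 0, T = 0)
    scaf_lens <- numeric(n_scaffolds)
    contig_lens <- numeric(0)
    gap_lens <- numeric(0)
    n_unknown <- 0L
    for (s in seq_len(n_scaffolds)) {
      sc_name <- paste0("scaf", s)
      n_gaps_i <- stats::rpois(1, gaps_per_scaffold)
      n_contigs_i <- n_gaps_i + 1L
      el <- path_elements()
      lead <- stats::runif(1) < terminal_gap_prob
      trail <- stats::runif(1) < terminal_gap_prob
      this_len <- 0
      if (lead) {
        d <- max(1L, as.integer(round(stats::rlnorm(1, gap_meanlog, gap_sdlog))))
        asm <- add_gap(asm, distance = d)
        el <- tibble::add_row(el, kind = "gap",
                              uid = asm$gaps$uid[nrow(asm$gaps)], orient = "+")
        gap_lens <- c(gap_lens, d)
        this_len <- this_len + d
      }
      for (ci in seq_len(n_contigs_i)) {
        len <- max(1L, as.integer(round(stats::rlnorm(1, contig_meanlog,
                                                      contig_sdlog))))
        bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                        prob = probs)
        tb <- table(factor(bases, levels = c("A", "C", "G", "T")))
        base_tally <- base_tally + as.numeric(tb)
        qual <- if (with_qualities) {
          paste0(sample(strsplit("#5:ABFIJ", "")[[1]], len, replace = TRUE),
                 collapse = "")
        } else NA_character_
        asm <- add_segment(asm, paste0(sc_name, ".", ci),
                           sequence = paste0(bases, collapse = ""),
                           qualities = qual)
        el <- tibble::add_row(el, kind = "segment",
                              uid = asm$segments$uid[nrow(asm$segments)],
                              orient = "+")
        contig_lens <- c(contig_lens, len)
        this_len <- this_len + len
        if (ci < n_contigs_i) {
          unknown <- stats::runif(1) < unknown_gap_fraction
          if (unknown) {
            n_unknown <- n_unknown + 1L
            asm <- add_gap(asm, distance = NA_integer_)
            gap_lens <- c(gap_lens, unknown_gap_size)
            this_len <- this_len + unknown_gap_size
          } else {
            d <- max(1L, as.integer(round(stats::rlnorm(1, gap_meanlog,
                                                        gap_sdlog))))
            asm <- add_gap(asm, distance = d)
            gap_lens <- c(gap_lens, d)
            this_len <- this_len + d
          }
          el <- tibble::add_row(el, kind = "gap",
                                uid = asm$gaps$uid[nrow(asm$gaps)],
                                orient = "+")
        }
      }
      if (trail) {
        d <- max(1L, as.integer(round(stats::rlnorm(1, gap_meanlog, gap_sdlog))))
        asm <- add_gap(asm, distance = d)
        el <- tibble::add_row(el, kind = "gap",
                              uid = asm$gaps$uid[nrow(asm$gaps)], orient = "+")
        gap_lens <- c(gap_lens, d)
        this_len <- this_len + d
      }
      asm <- add_path(asm, sc_name, el)
      asm <- refresh_path_gaps(asm, asm$paths$uid[nrow(asm$paths)])
      scaf_lens[s] <- this_len
    }
    # naive ground-truth arithmetic, independent of the stats module
    naive_n50 <- function(lens) {
      lens <- sort(lens, decreasing = TRUE)
      tot <- sum(lens)
      run <- 0
      for (i in seq_along(lens)) {
        run <- run + lens[i]
        if (run >= tot / 2) return(list(n50 = lens[i], l50 = i))
      }
      list(n50 = NA_real_, l50 = NA_integer_)
    }
    st <- naive_n50(scaf_lens)
    ct <- naive_n50(contig_lens)
    truth <- list(
      n_scaffolds = n_scaffolds,
      n_contigs = length(contig_lens),
      n_gaps = length(gap_lens),
      n_unknown_gaps = n_unknown,
      total_scaffold_len = sum(contig_lens) + sum(gap_lens),
      total_contig_len = sum(contig_lens),
      total_gap_len = sum(gap_lens),
      largest_scaffold = max(scaf_lens),
      largest_contig = max(contig_lens),
      largest_gap = if (length(gap_lens)) max(gap_lens) else 0,
      scaffold_n50 = st$n50, scaffold_l50 = st$l50,
      contig_n50 = ct$n50, contig_l50 = ct$l50,
      scaffold_aun = round(sum(scaf_lens^2) / sum(scaf_lens), 2),
      contig_aun = round(sum(contig_lens^2) / sum(contig_lens), 2),
      gc_content = round(100 * (base_tally[["G"]] + base_tally[["C"]]) /
                           sum(base_tally), 2),
      base_counts = base_tally
    )
    list(assembly = asm, truth = truth)
  })
}
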