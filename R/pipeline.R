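# The end-to-end pipeline behind the command-line entry point. Stages run
# in a fixed order: read -> selection -> graph build / path synthesis -> SAK
# -> sort -> statistics report -> optional sequence/AGP/BED/sizes output.

#' Run the full assembly-processing pipeline
#'
#' @param input Input assembly file (FASTA/FASTQ/GFA1/GFA2, plain or gzip).
#' @param output Output file for the converted assembly (`NULL` = none;
#'   `.gz` suffix gzips sequence formats).
#' @param out_format One of `"fasta"`, `"fastq"`, `"gfa"`, `"gfa1"`,
#'   `"gfa2"`, `"agp"`, `"bed"`, `"sizes"`; default keeps the input kind.
#' @param genome_size Optional expected genome size (bp) for NG50/LG50.
#' @param include_list,exclude_list Scaffold name vectors, or paths to
#'   one-name-per-line files.
#' @param include_bed,exclude_bed BED interval tibbles, or paths to BED3
#'   files.
#' @param sort_by,sort_descending,sort_list Scaffold sorting (see
#'   [sort_assembly()]); `sort_list` may be a file of names.
#' @param sak SAK script text or path to a script file.
#' @param sak_log Path for the change-log TSV (`NULL` = not written).
#' @param report `"summary"`, `"tabular"`, `"per_sequence"` or `"none"`.
#' @param line_width FASTA wrap width.
#' @param unknown_gap_size Placeholder N count for unknown gaps.
#' @param bed_feature Feature tier for `out_format = "bed"`.
#' @param sizes_tier Tier for `out_format = "sizes"`.
#' @param strict Unknown selection names are errors.
#' @param quiet Suppress the printed report (still returned).
#' @return Invisibly, a list with `assembly`, `stats` and (when a SAK script
#'   ran) `log`.
#' @export
run_pipeline <- function(input, output = NULL, out_format = NULL,
                         genome_size = NULL,
                         include_list = NULL, exclude_list = NULL,
                         include_bed = NULL, exclude_bed = NULL,
                         sort_by = "input", sort_descending = FALSE,
                         sort_list = NULL, sak = NULL, sak_log = NULL,
                         report = c("summary", "tabular", "per_sequence",
                                    "none"),
                         line_width = 60L, unknown_gap_size = 100L,
                         bed_feature = "gaps", sizes_tier = "scaffold",
                         strict = FALSE, quiet = FALSE) {
  report <- match.arg(report)
  if (!file.exists(input)) stop("input file not found: ", input)
  read_name_list <- function(x) {
    if (is.null(x) || !is.character(x)) return(x)
    if (length(x) == 1L && file.exists(x)) {
      ln <- readLines(x, warn = FALSE)
      trimws(ln[nzchar(trimws(ln))])
    } else x
  }
  read_bed3 <- function(x) {
    if (is.null(x) || is.data.frame(x)) return(x)
    ln <- readLines(x, warn = FALSE)
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    parts <- strsplit(ln, "\t", fixed = TRUE)
    tibble::tibble(
      chrom = vapply(parts, `[`, "", 1L),
      start = as.integer(vapply(parts, `[`, "", 2L)),
      end = as.integer(vapply(parts, `[`, "", 3L))
    )
  }
  dialect <- detect_format(input)
  asm <- read_assembly(input)
  asm <- apply_selection(asm,
                         include_names = read_name_list(include_list),
                         exclude_names = read_name_list(exclude_list),
                         include_bed = read_bed3(include_bed),
                         exclude_bed = read_bed3(exclude_bed),
                         strict = strict,
                         unknown_gap_size = unknown_gap_size)
  log <- NULL
  if (!is.null(sak)) {
    script <- if (length(sak) == 1L && file.exists(sak)) {
      parse_sak(sak, is_file = TRUE)
    } else {
      parse_sak(sak)
    }
    res <- sak_execute(asm, script, unknown_gap_size = unknown_gap_size)
    asm <- res$assembly
    log <- res$log
    if (!is.null(sak_log)) {
      utils::write.table(log, sak_log, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  if (!is.null(sort_list)) {
    asm <- sort_assembly(asm, by = "list",
                         custom_order = read_name_list(sort_list))
  } else if (!identical(sort_by, "input")) {
    asm <- sort_assembly(asm, by = sort_by, descending = sort_descending)
  }
  stats <- summarize_assembly(asm, genome_size = genome_size,
                              unknown_gap_size = unknown_gap_size)
  if (!quiet) {
    if (report == "summary") {
      print(stats)
    } else if (report == "tabular") {
      g <- glance(stats)
      cat(paste(names(g), collapse = "\t"), "\n", sep = "")
      cat(paste(unlist(g), collapse = "\t"), "\n", sep = "")
    } else if (report == "per_sequence") {
      tbl <- per_sequence_stats(asm, unknown_gap_size)
      cat(paste(names(tbl), collapse = "\t"), "\n", sep = "")
      for (i in seq_len(nrow(tbl))) {
        cat(paste(unlist(tbl[i, ]), collapse = "\t"), "\n", sep = "")
      }
    }
  }
  if (!is.null(output)) {
    fmt <- out_format
    if (is.null(fmt)) fmt <- dialect$kind
    if (fmt == "gfa") fmt <- "gfa2"
    switch(fmt,
      fasta = write_fasta(asm, output, line_width = line_width,
                          unknown_gap_size = unknown_gap_size),
      fastq = write_fastq(asm, output, unknown_gap_size = unknown_gap_size),
      gfa1 = write_gfa(asm, output, version = 1L),
      gfa2 = write_gfa(asm, output, version = 2L),
      agp = write_agp(asm, output, unknown_gap_size = unknown_gap_size),
      bed = write_bed(asm, output, feature = bed_feature,
                      unknown_gap_size = unknown_gap_size),
      sizes = write_sizes(asm, output, tier = sizes_tier,
                          unknown_gap_size = unknown_gap_size),
      stop("unknown output format: ", fmt)
    )
  }
  invisible(list(assembly = asm, stats = stats, log = log))
}
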