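#' Standard-format exporters
#'
#' All exporters are pure functions from tibbles to text and are
#' byte-deterministic for a fixed input: fixed column sets, fixed ordering
#' (start, then ID), no locale-dependent formatting. Coordinates stay
#' 1-based closed everywhere except the BED exporter, which converts to
#' 0-based half-open at this boundary only.
#'
#' @name exporters
NULL

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

strand_chr <- function(s) ifelse(is.na(s), ".", ifelse(s < 0, "-", "+"))

#' Export genes (with their transcripts and exons) as GFF3
#'
#' Child transcript and exon rows are loaded through the handle — an export
#' is an explicit access, so the usual lazy-loading queries run here.
#'
#' @param db A core `bound_database`.
#' @param genes Gene tibble from [genes_in_region()].
#' @return GFF3 text (one string, trailing newline).
#' @export
export_gff3 <- function(db, genes) {
  lines <- "##gff-version 3"
  genes <- arrange(genes, .data$start, .data$stable_id)
  src <- "releasewise"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, paste(
      g$region, src, "gene", g$start, g$end, ".", strand_chr(g$strand), ".",
      paste0("ID=", gff3_escape(g$stable_id),
             ";Name=", gff3_escape(g$display_name),
             ";biotype=", gff3_escape(g$biotype)),
      sep = "\t"))
    trs <- transcripts_of_gene(db, g$stable_id)
    trs <- arrange(trs, .data$start, .data$stable_id)
    for (j in seq_len(nrow(trs))) {
      t <- trs[j, ]
      coding <- !is.null(translation_of_transcript(db, t$stable_id))
      lines <- c(lines, paste(
        t$region, src, if (coding) "mRNA" else "transcript",
        t$start, t$end, ".", strand_chr(t$strand), ".",
        paste0("ID=", gff3_escape(t$stable_id),
               ";Parent=", gff3_escape(g$stable_id)),
        sep = "\t"))
      exons <- exons_of_transcript(db, t$stable_id)
      exons <- arrange(exons, .data$start, .data$stable_id)
      for (k in seq_len(nrow(exons))) {
        e <- exons[k, ]
        lines <- c(lines, paste(
          e$region, src, "exon", e$start, e$end, ".",
          strand_chr(e$strand), ".",
          paste0("ID=", gff3_escape(e$stable_id),
                 ";Parent=", gff3_escape(t$stable_id)),
          sep = "\t"))
      }
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Export features as BED6
#'
#' Converts to BED's 0-based half-open coordinates; strandless features get
#' `.`.
#'
#' @param features Tibble with `region`, `start`, `end`, `strand` and
#'   `stable_id` (or `name`) columns.
#' @return BED text.
#' @export
export_bed <- function(features) {
  if (nrow(features) == 0) return("")
  nm <- if ("stable_id" %in% names(features)) features$stable_id else
    features$name
  f <- features[order(features$start, nm), ]
  nm <- if ("stable_id" %in% names(f)) f$stable_id else f$name
  lines <- paste(f$region, f$start - 1L, f$end, nm, 0L,
                 strand_chr(f$strand), sep = "\t")
  if (length(lines) == 0) return("")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Export a single sequence as FASTA
#'
#' @param name Record name.
#' @param seq DNA string over `{A, C, G, T, N}`.
#' @param width Wrap width in bases.
#' @return FASTA text.
#' @export
export_fasta <- function(name, seq, width = 60L) {
  header <- paste0(">", name)
  if (!nzchar(seq)) return(paste0(header, "\n"))
  starts <- seq(1L, nchar(seq), by = width)
  body <- vapply(starts, function(s) substr(seq, s, min(nchar(seq), s + width - 1L)),
                 character(1))
  paste0(paste(c(header, body), collapse = "\n"), "\n")
}

#' Export a tibble as TSV
#'
#' Header row, tab separators, no quoting, no locale formatting.
#'
#' @param x A data frame.
#' @return TSV text.
#' @export
export_tsv <- function(x) {
  fmt <- function(v) {
    out <- as.character(v)
    out[is.na(out)] <- ""
    out
  }
  rows <- c(paste(names(x), collapse = "\t"),
            vapply(seq_len(nrow(x)), function(i) {
              paste(vapply(x[i, ], fmt, character(1)), collapse = "\t")
            }, character(1)))
  paste0(paste(rows, collapse = "\n"), "\n")
}

#' Plot a gene's location across releases
#'
#' One horizontal segment per release at the coordinates the release's
#' assembly gives the gene — the through-time view of annotation drift.
#'
#' @param history Tibble from [gene_across_releases()].
#' @return A ggplot object.
#' @export
plot_gene_history <- function(history) {
  ggplot2::ggplot(history, ggplot2::aes(
    x = .data$start, xend = .data$end,
    y = factor(.data$release), yend = factor(.data$release))) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::labs(x = "position (bp)", y = "release",
                  title = unique(history$region)) +
    ggplot2::theme_minimal()
}
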