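#' Project a location through assembly blocks
#'
#' An assembly block states that `asm_region[asm_start..asm_end]` is built
#' from `cmp_region[cmp_start..cmp_end]` in orientation `ori`; with
#' `ori = -1` the first assembled base corresponds to `cmp_end` (AGP-style).
#' Projection clips the query against each overlapping block and emits the
#' corresponding component interval with strand `strand * ori`; positions
#' covered by no block become gap segments. Segments come back in ascending
#' assembled-coordinate order and their lengths sum to the query length.
#'
#' @param start,end Query interval on the assembled region (1-based closed).
#' @param blocks Tibble of this region's assembly rows with columns
#'   `asm_start`, `asm_end`, `cmp_region`, `cmp_start`, `cmp_end`, `ori`.
#' @param strand Query strand, `+1` or `-1`.
#' @return Tibble of segments with columns `kind` (`"MAPPED"`/`"GAP"`),
#'   `cmp_region` (`NA` for gaps), `start`, `end`, `strand`, `length`.
#' @export
project_location <- function(start, end, blocks, strand = 1L) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1 || start > end) {
    rw_abort("input_error",
             paste0("invalid query interval ", start, "-", end))
  }
  b <- blocks[blocks$asm_end >= start & blocks$asm_start <= end, , drop = FALSE]
  b <- b[order(b$asm_start), , drop = FALSE]
  segs <- list()
  gap <- function(n) tibble(kind = "GAP", cmp_region = NA_character_,
                            start = NA_integer_, end = NA_integer_,
                            strand = NA_integer_, length = as.integer(n))
  pos <- start
  for (i in seq_len(nrow(b))) {
    blk <- b[i, ]
    if (blk$asm_start > pos) {
      segs[[length(segs) + 1]] <- gap(blk$asm_start - pos)
      pos <- blk$asm_start
    }
    cs <- max(pos, blk$asm_start); ce <- min(end, blk$asm_end)
    o1 <- cs - blk$asm_start; o2 <- ce - blk$asm_start
    if (blk$ori == 1L) {
      c_start <- blk$cmp_start + o1; c_end <- blk$cmp_start + o2
    } else {
      c_start <- blk$cmp_end - o2; c_end <- blk$cmp_end - o1
    }
    segs[[length(segs) + 1]] <- tibble(
      kind = "MAPPED", cmp_region = as.character(blk$cmp_region),
      start = as.integer(c_start), end = as.integer(c_end),
      strand = as.integer(strand * blk$ori),
      length = as.integer(ce - cs + 1L))
    pos <- ce + 1L
  }
  if (pos <= end) segs[[length(segs) + 1]] <- gap(end - pos + 1L)
  out <- bind_rows(segs)
  stopifnot(sum(out$length) == end - start + 1L)
  out
}

#' Swap the roles of assembled and component regions in assembly blocks
#'
#' Useful for projecting a component interval back up to the assembled
#' region. Orientation is symmetric, so `ori` is unchanged.
#'
#' @param blocks Assembly-block tibble with `asm_region` and `cmp_region`
#'   name columns.
#' @return Block tibble with asm and cmp columns exchanged.
#' @export
invert_blocks <- function(blocks) {
  tibble(
    asm_region = blocks$cmp_region, asm_start = blocks$cmp_start,
    asm_end = blocks$cmp_end, cmp_region = blocks$asm_region,
    cmp_start = blocks$asm_start, cmp_end = blocks$asm_end,
    ori = blocks$ori)
}

# Standard-code translation of a CDS; trailing stop trimmed, internal stop
# rejected. Shared by translate_cds() and kept free of database concerns.
translate_cds_string <- function(cds) {
  if (nchar(cds) %% 3 != 0) {
    rw_abort("data_integrity_error", paste0(
      "coding sequence length ", nchar(cds), " is not divisible by 3"))
  }
  if (grepl("N", cds, fixed = TRUE)) {
    rw_abort("data_integrity_error",
             "coding sequence contains ambiguous bases (N)")
  }
  pep <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE))
  if (endsWith(pep, "*")) pep <- substr(pep, 1, nchar(pep) - 1)
  if (grepl("*", pep, fixed = TRUE)) {
    rw_abort("data_integrity_error",
             "internal stop codon in coding sequence")
  }
  pep
}
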