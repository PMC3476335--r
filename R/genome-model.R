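#' Locations, mappings and sequence primitives
#'
#' Coordinates throughout the package are 1-based, fully closed intervals
#' (Ensembl convention); strand is `+1` or `-1`. A *feature mapping* pairs a
#' span in a feature's own coordinates (1 at its 5' end, on its own strand)
#' with a [location()] on a sequence region; genes map onto chromosomes,
#' and a chromosome carries the ordered inverse mappings of its genes.
#'
#' @name genome-model
NULL

#' Construct a location
#'
#' @param region Region name (string).
#' @param start,end 1-based inclusive coordinates.
#' @param strand `+1` or `-1`.
#' @param region_length Optional region length, enabling the upper-bound
#'   check in [validate_location()].
#' @return One-row tibble with columns `region`, `start`, `end`, `strand`
#'   and `region_length`.
#' @export
location <- function(region, start, end, strand = 1L, region_length = NA) {
  tibble(region = as.character(region), start = as.integer(start),
         end = as.integer(end), strand = as.integer(strand),
         region_length = as.integer(region_length))
}

#' Validate a location against its invariants
#'
#' Checks `1 <= start <= end <= region_length` (the upper bound only when
#' the length is known) and `strand` in `{+1, -1}`. Never raises: violations
#' are returned.
#'
#' @param loc Location tibble row (see [location()]).
#' @return Character vector of violations; empty when the location is valid.
#' @export
validate_location <- function(loc) {
  v <- character(0)
  if (loc$start < 1) v <- c(v, "start < 1")
  if (loc$start > loc$end) v <- c(v, "start > end")
  if (!is.na(loc$region_length) && loc$end > loc$region_length) {
    v <- c(v, paste0("end ", loc$end, " > region length ", loc$region_length))
  }
  if (!loc$strand %in% c(1L, -1L)) v <- c(v, "strand not in {+1, -1}")
  v
}

assert_valid_location <- function(loc) {
  v <- validate_location(loc)
  if (length(v)) {
    rw_abort("input_error", paste0(
      "invalid location ", loc$region, ":", loc$start, "-", loc$end, ":",
      loc$strand, " (", paste(v, collapse = "; "), ")"))
  }
  invisible(loc)
}

#' Construct a feature mapping
#'
#' @param source_ref Identifier of the mapped feature.
#' @param source_start,source_end Span in the feature's own coordinates
#'   (1-based at the feature's 5' end).
#' @param source_strand Strand of the span in feature coordinates.
#' @param source_length Length of the source feature; defaults to
#'   `source_end` (a span never extends past its feature).
#' @param target Location of the feature on the target region.
#' @return One-row mapping tibble.
#' @export
feature_mapping <- function(source_ref, source_start, source_end,
                            target, source_strand = 1L,
                            source_length = NA) {
  stopifnot((source_end - source_start) == (target$end - target$start))
  if (is.na(source_length)) source_length <- source_end
  tibble(
    source_ref = source_ref, source_start = as.integer(source_start),
    source_end = as.integer(source_end),
    source_strand = as.integer(source_strand),
    source_region_length = as.integer(source_length),
    target_ref = target$region, target_start = target$start,
    target_end = target$end, target_strand = target$strand,
    target_region_length = target$region_length)
}

#' Invert a feature mapping
#'
#' Swaps source and target roles: the inverse maps the region span onto the
#' feature's own coordinates. Relative strand is preserved — the inverse
#' target strand is the product of the original strands — so inversion is
#' an involution.
#'
#' @param m One-row mapping tibble from [feature_mapping()].
#' @return One-row mapping tibble with roles swapped.
#' @export
invert_mapping <- function(m) {
  stopifnot(nrow(m) == 1)
  tibble(
    source_ref = m$target_ref, source_start = m$target_start,
    source_end = m$target_end, source_strand = 1L,
    source_region_length = m$target_region_length,
    target_ref = m$source_ref, target_start = m$source_start,
    target_end = m$source_end,
    target_strand = m$source_strand * m$target_strand,
    target_region_length = m$source_region_length)
}

#' Mappings of a gene set onto its region
#'
#' @param genes Gene tibble as returned by [genes_in_region()].
#' @return Mapping tibble, one row per gene: feature-local span 1..width
#'   mapped to the gene's location on the region.
#' @export
feature_mappings <- function(genes) {
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    feature_mapping(
      g$stable_id, 1L, g$end - g$start + 1L,
      location(g$region, g$start, g$end, g$strand, g$region_length))
  })
}

#' Ordered inverse mappings on a region
#'
#' The region's view of its features: each gene's mapping inverted, ordered
#' by position on the region.
#'
#' @param genes Gene tibble as returned by [genes_in_region()].
#' @return Mapping tibble ordered by `source_start` (position on the region).
#' @export
inverse_mappings <- function(genes) {
  m <- feature_mappings(genes)
  inv <- purrr::map_dfr(seq_len(nrow(m)), function(i) invert_mapping(m[i, ]))
  arrange(inv, .data$source_start, .data$target_ref)
}

#' Reverse complement of a DNA string
#'
#' Alphabet `{A, C, G, T, N}`, case-insensitive input, uppercase output.
#'
#' @param seq DNA string.
#' @return The reverse complement.
#' @examples
#' reverse_complement("AAAACCCC") # "GGGGTTTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (!nzchar(seq)) return("")
  up <- toupper(seq)
  if (grepl("[^ACGTN]", up)) {
    rw_abort("input_error",
             "sequence contains characters outside {A, C, G, T, N}")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(up)))
}
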