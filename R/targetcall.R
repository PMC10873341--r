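#' Scan barcoded reads for junction k-mers
#'
#' A read supports a junction when the junction's breakpoint-spanning
#' k-mer (or, by default, its reverse complement as well) occurs within
#' the read with at most `max_mismatch` mismatches. Supporting reads are
#' accumulated per (barcode, junction); UMI-deduplicated molecule counts
#' are reported alongside. Wild-type reads never cross the breakpoint
#' and therefore cannot contain the k-mer.
#'
#' @param reads A tibble with columns `sequence`, `barcode`, `umi`
#'   (as produced by [simulate_targeted_reads()] or [read_tagged_fastq()]).
#' @param junctions A [build_junction_kmer()] spec or list of specs.
#' @param max_mismatch Maximum Hamming mismatches allowed in the k-mer
#'   occurrence (default 0 = exact).
#' @param search_reverse_complement Also search the reverse-complement
#'   strand (default `TRUE`).
#'
#' @return A `fusion_call_table` tibble: barcode, junction,
#'   supporting_read_count, supporting_umi_count. Barcodes with zero
#'   support for a junction are included (count 0) so the table is
#'   complete over observed barcodes.
#' @export
scan_reads <- function(reads, junctions, max_mismatch = 0,
                       search_reverse_complement = TRUE) {
  if (inherits(junctions, "junction_spec")) junctions <- list(junctions)
  need <- c("sequence", "barcode", "umi")
  if (!all(need %in% names(reads))) {
    abort("`reads` needs columns sequence, barcode, umi.")
  }
  tagged <- !is.na(reads$barcode) & reads$barcode != "" &
    !is.na(reads$umi) & reads$umi != ""
  n_skipped <- sum(!tagged)
  if (n_skipped > 0) {
    message(sprintf("skipped %d untagged read(s).", n_skipped))
    reads <- reads[tagged, ]
  }
  barcodes <- sort(unique(reads$barcode))

  per_junction <- map(junctions, function(spec) {
    pats <- spec$junction_kmer
    if (search_reverse_complement) pats <- c(pats, revcomp(pats))
    hit <- rep(FALSE, nrow(reads))
    for (p in pats) {
      hit <- hit | if (max_mismatch == 0) {
        stringr::str_detect(reads$sequence, stringr::fixed(p))
      } else {
        hamming_hit(reads$sequence, p, max_mismatch)
      }
    }
    sup <- reads[hit, c("barcode", "umi")]
    rc <- sup |> count(.data$barcode, name = "supporting_read_count")
    uc <- sup |> distinct(.data$barcode, .data$umi) |>
      count(.data$barcode, name = "supporting_umi_count")
    tibble(barcode = barcodes, junction = spec$name) |>
      left_join(rc, by = "barcode") |>
      left_join(uc, by = "barcode") |>
      mutate(supporting_read_count = dplyr::coalesce(.data$supporting_read_count, 0L),
             supporting_umi_count = dplyr::coalesce(.data$supporting_umi_count, 0L))
  })
  out <- bind_rows(per_junction)
  structure(out, class = c("fusion_call_table", class(out)))
}

# sliding Hamming comparison: does `pattern` occur in each sequence with
# <= max_mismatch substitutions?
hamming_hit <- function(seqs, pattern, max_mismatch) {
  k <- nchar(pattern)
  pb <- strsplit(pattern, "")[[1]]
  vapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(FALSE)
    sb <- strsplit(s, "")[[1]]
    for (off in 0:(L - k)) {
      if (sum(sb[(off + 1):(off + k)] != pb) <= max_mismatch) return(TRUE)
    }
    FALSE
  }, TRUE, USE.NAMES = FALSE)
}

#' Call fusion/ITD-positive cells
#'
#' A cell is positive for a junction when its supporting count is
#' strictly greater than `threshold` — at the default 3, "more than
#' three" reads, i.e. four or more.
#'
#' @param table A [scan_reads()] result.
#' @param threshold Count that must be exceeded (default 3).
#' @param use_umi Use UMI-deduplicated molecule counts instead of raw
#'   read counts (default `FALSE`: raw reads).
#'
#' @return Tibble: barcode, junction, count, positive.
#' @export
call_positive_cells <- function(table, threshold = 3, use_umi = FALSE) {
  if (threshold < 0) abort("`threshold` must be >= 0.")
  if (nrow(table) == 0) {
    return(tibble(barcode = character(), junction = character(),
                  count = integer(), positive = logical()))
  }
  cnt <- if (use_umi) table$supporting_umi_count else table$supporting_read_count
  tibble(barcode = table$barcode, junction = table$junction,
         count = cnt, positive = cnt > threshold)
}
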