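#' Build an exact-match genome index
#'
#' Stores the chromosome sequences together with their reverse complements
#' so that tag queries can be answered on both strands. Matching is exact
#' (zero mismatches), which keeps the mapper a clean, fully deterministic
#' stand-in for a short-read aligner at toy-genome scale; `max_mismatch`
#' is reserved for interface stability and must currently be 0.
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   tibble with `name` and `sequence` columns (e.g. from [read_fasta()]).
#' @param max_mismatch Reserved; only 0 is supported.
#' @return A `genome_index` object.
#' @export
genome_index <- function(genome, max_mismatch = 0) {
  if (is.data.frame(genome)) {
    genome <- stats::setNames(genome$sequence, genome$name)
  }
  if (length(genome) == 0) rlang::abort("genome is empty")
  if (max_mismatch != 0) {
    rlang::abort("only exact matching (max_mismatch = 0) is implemented")
  }
  genome <- toupper(genome)
  structure(
    list(
      chrom = names(genome),
      seq = unname(genome),
      length = nchar(unname(genome))
    ),
    class = "genome_index"
  )
}

# All (possibly overlapping) 1-based start positions of `pattern` in
# `subject`, via a zero-width lookahead so self-overlapping hits are kept.
all_starts <- function(pattern, subject) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (hits[1] == -1) integer() else as.integer(hits)
}

#' Map tags to the genome on both strands
#'
#' Returns every exact occurrence of each tag: on the sense strand the tag
#' equals the genome substring; on the antisense strand it equals the
#' reverse complement of the substring. Hits are sorted by tag, then
#' (chromosome, start, strand); a tag with no rows is unmapped.
#'
#' @param tags Character vector of tag sequences, or a [tag_library].
#' @param index A [genome_index()].
#' @return Tibble with columns `tag`, `chrom`, `start`, `end` (1-based,
#'   inclusive) and `strand` (`+` sense / `-` antisense).
#' @examples
#' idx <- genome_index(c(chrA = "ACGTACGT"))
#' map_tags("ACGT", idx)
#' @export
map_tags <- function(tags, index) {
  if (inherits(tags, "tag_library") || is.data.frame(tags)) {
    tags <- tags$sequence
  }
  tags <- as_dna(unique(tags))
  check_alphabet(tags, what = "tag")
  if (length(tags) == 0) {
    return(tibble::tibble(tag = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  rc <- revcomp(tags)
  res <- purrr::map(seq_along(tags), function(i) {
    len <- nchar(tags[i])
    per_chrom <- purrr::map(seq_along(index$chrom), function(c) {
      s <- all_starts(tags[i], index$seq[c])
      a <- all_starts(rc[i], index$seq[c])
      tibble::tibble(
        tag = tags[i],
        chrom = index$chrom[c],
        start = c(s, a),
        end = c(s, a) + len - 1L,
        strand = rep(c("+", "-"), c(length(s), length(a)))
      )
    })
    dplyr::bind_rows(per_chrom)
  })
  out <- dplyr::bind_rows(res)
  dplyr::arrange(out, tag, chrom, start, strand)
}

#' Summarize genome mapping for a tag library
#'
#' Computes the unique (distinct sequences) and total (read-weighted)
#' mapped fractions, plus per-chromosome sense/antisense read tallies. A
#' multi-mapping tag counts once towards the mapped fractions but its
#' reads are tallied at every locus in the per-chromosome table.
#' Percentages are kept at full precision; report formatting rounds them
#' half-up to one decimal.
#'
#' @param hits Hit table from [map_tags()] for every tag of `library`.
#' @param library The [tag_library] the hits were computed from.
#' @return A `mapping_summary` list: `unique_total`, `unique_mapped`,
#'   `reads_total`, `reads_mapped`, `pct_unique`, `pct_reads` and
#'   `per_chromosome` (tibble `chrom`, `sense`, `antisense` read counts).
#' @export
mapping_summary <- function(hits, library) {
  mapped_seqs <- unique(hits$tag)
  unique_total <- nrow(library)
  unique_mapped <- sum(library$sequence %in% mapped_seqs)
  reads_total <- total_clean(library)
  reads_mapped <- sum(library$count[library$sequence %in% mapped_seqs])
  per_chrom <- hits |>
    dplyr::inner_join(
      tibble::as_tibble(library)[c("sequence", "count")],
      by = c(tag = "sequence")
    ) |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(
      sense = sum(count[strand == "+"]),
      antisense = sum(count[strand == "-"]),
      .groups = "drop"
    )
  structure(
    list(
      library_id = attr(library, "library_id"),
      unique_total = unique_total,
      unique_mapped = unique_mapped,
      reads_total = reads_total,
      reads_mapped = reads_mapped,
      pct_unique = mapping_percentage(unique_mapped, unique_total),
      pct_reads = mapping_percentage(reads_mapped, reads_total),
      per_chromosome = per_chrom
    ),
    class = "mapping_summary"
  )
}

#' Mapped percentage
#'
#' `100 * mapped / total`, the mapped-fraction definition used in the
#' unique/total mapping summaries; exact, with rounding left to report
#' formatting (one decimal, half-up).
#'
#' @param mapped,total Non-negative counts (`total > 0` unless
#'   `mapped == 0`).
#' @return Numeric percentage(s).
#' @examples
#' round_half_up(mapping_percentage(539279, 1034806), 1)
#' @export
mapping_percentage <- function(mapped, total) {
  stopifnot(all(mapped >= 0), all(total >= 0), all(mapped <= total | total == 0))
  ifelse(total == 0, 0, 100 * mapped / total)
}

#' @export
glance.mapping_summary <- function(x, ...) {
  tibble::tibble(
    library_id = x$library_id,
    unique_total = x$unique_total,
    unique_mapped = x$unique_mapped,
    reads_total = x$reads_total,
    reads_mapped = x$reads_mapped,
    pct_unique = x$pct_unique,
    pct_reads = x$pct_reads
  )
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat(sprintf(
    "<mapping_summary%s>\n  unique: %d / %d mapped (%.1f%%)\n  reads:  %d / %d mapped (%.1f%%)\n",
    if (is.null(x$library_id)) "" else paste0(" ", x$library_id),
    x$unique_mapped, x$unique_total, round_half_up(x$pct_unique, 1),
    x$reads_mapped, x$reads_total, round_half_up(x$pct_reads, 1)
  ))
  invisible(x)
}
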