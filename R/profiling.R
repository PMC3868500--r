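#' Count known miRNAs in a tag library
#'
#' Assigns a tag to a mature miRNA if and only if it equals the mature
#' sequence exactly (after U/T normalization); assigned read counts are
#' summed per miRNA and every other tag is kept aside as "unannotated" for
#' the seed-edit stage. Duplicate mature sequences in the reference are an
#' error, since assignment would be ambiguous.
#'
#' @param library A [tag_library].
#' @param reference Mature-miRNA tibble with `name` and `sequence`
#'   columns (U or T alphabet).
#' @return Tibble with `mirna` and `count` (one row per reference miRNA,
#'   zeros included), with attributes `unannotated` (tibble of unassigned
#'   tags with counts) and `total_clean`.
#' @export
count_known <- function(library, reference) {
  if (nrow(reference) == 0) rlang::abort("reference is empty")
  ref_seq <- as_dna(reference$sequence)
  dup <- duplicated(ref_seq) | duplicated(ref_seq, fromLast = TRUE)
  if (any(dup)) {
    rlang::abort(sprintf(
      "duplicate mature sequences in reference: %s",
      paste(reference$name[dup], collapse = ", ")
    ))
  }
  idx <- match(library$sequence, ref_seq)
  counts <- rep(0L, nrow(reference))
  hit <- !is.na(idx)
  if (any(hit)) {
    agg <- rowsum(library$count[hit], idx[hit])
    counts[as.integer(rownames(agg))] <- as.integer(agg)
  }
  structure(
    tibble::tibble(mirna = reference$name, count = counts),
    unannotated = tibble::as_tibble(library[!hit, c("sequence", "count")]),
    total_clean = total_clean(library)
  )
}

#' Build the two-library miRNA count table
#'
#' Pairs the per-miRNA counts of the control (NC) and case (MN) libraries;
#' the library clean totals N1 (NC) and N2 (MN) ride along as attributes
#' and feed the per-million normalization and the Audic-Claverie test.
#'
#' @param library_nc,library_mn [tag_library] objects for the NC and MN
#'   libraries.
#' @param reference Mature-miRNA tibble (`name`, `sequence`).
#' @return Tibble of class `count_table` with `mirna`, `count_nc`,
#'   `count_mn`; attributes `n1`, `n2`, `unannotated_nc`, `unannotated_mn`.
#' @export
count_table <- function(library_nc, library_mn, reference) {
  nc <- count_known(library_nc, reference)
  mn <- count_known(library_mn, reference)
  out <- tibble::tibble(
    mirna = nc$mirna,
    count_nc = nc$count,
    count_mn = mn$count
  )
  structure(
    out,
    n1 = attr(nc, "total_clean"),
    n2 = attr(mn, "total_clean"),
    unannotated_nc = attr(nc, "unannotated"),
    unannotated_mn = attr(mn, "unannotated"),
    class = c("count_table", class(out))
  )
}

#' Per-position base composition of tags
#'
#' For each position p up to `max_position`, the count-weighted percentage
#' of each base among tags of length >= p:
#' `100 * reads with base b at p / reads covering p`. Positions covered by
#' no tag are omitted. Values are exact; report formatting rounds half-up
#' to two decimals. Bases are reported in the RNA alphabet (A/U/C/G).
#'
#' @param tags A [tag_library], a tibble with `sequence`/`count`, or a
#'   character vector (unit counts).
#' @param max_position Last position to tabulate (default 24, the span of
#'   a long mature miRNA).
#' @param group Optional label stored in the `group` attribute.
#' @return Tibble with columns `position`, `A`, `U`, `C`, `G` summing to
#'   100 per row (up to floating-point rounding).
#' @examples
#' base_composition(c("TAGC", "TAGG"))
#' @export
base_composition <- function(tags, max_position = 24, group = NULL) {
  if (max_position < 1) rlang::abort("max_position must be >= 1")
  if (is.character(tags)) tags <- collapse_tags(tags)
  seqs <- as_rna(tags$sequence)
  counts <- tags$count
  rows <- purrr::map(seq_len(max_position), function(p) {
    covered <- nchar(seqs) >= p
    if (!any(covered & counts > 0)) return(NULL)
    b <- factor(substr(seqs[covered], p, p), levels = c("A", "U", "C", "G"))
    w <- tapply(counts[covered], b, sum, default = 0)
    tibble::tibble(
      position = p,
      A = 100 * w[["A"]] / sum(w), U = 100 * w[["U"]] / sum(w),
      C = 100 * w[["C"]] / sum(w), G = 100 * w[["G"]] / sum(w)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "group") <- group
  out
}

#' Dominant base at a composition position
#'
#' Arg-max base of a [base_composition()] row; exact ties are broken in
#' the fixed order A < U < C < G and flagged.
#'
#' @param composition A [base_composition()] tibble.
#' @param position Position to query (must be covered).
#' @return Tibble with `position`, `base`, `percentage`, `tie`.
#' @examples
#' bc <- tibble::tibble(position = 1, A = 0.90, U = 96.61, C = 2.40, G = 0.09)
#' dominant_base(bc, 1)
#' @export
dominant_base <- function(composition, position) {
  row <- composition[composition$position == position, , drop = FALSE]
  if (nrow(row) != 1) {
    rlang::abort(sprintf("position %d is not covered", position))
  }
  vals <- unlist(row[c("A", "U", "C", "G")])
  top <- which(vals == max(vals))
  tibble::tibble(
    position = as.integer(position),
    base = names(vals)[top[1]],
    percentage = unname(vals[top[1]]),
    tie = length(top) > 1
  )
}
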