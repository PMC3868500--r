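#' Construct a collapsed tag library
#'
#' A tag library is the package's central container for one sequencing
#' library after cleaning: a tibble of unique tag sequences with read
#' counts, carrying the library label and the clean-read total N (the
#' normalization denominator of the differential stage) as attributes.
#'
#' @param sequences Character vector of tag sequences (U is normalized to
#'   T; one entry per unique tag).
#' @param counts Integer read counts, same length as `sequences`.
#' @param library_id Library label.
#' @return A tibble of class `tag_library` with columns `sequence`,
#'   `count`, attributes `library_id` and `total_clean`.
#' @export
tag_library <- function(sequences, counts, library_id = "lib") {
  sequences <- as_dna(sequences)
  counts <- as.integer(counts)
  stopifnot(length(sequences) == length(counts), all(counts >= 0))
  if (anyDuplicated(sequences)) rlang::abort("duplicate tag sequences")
  out <- tibble::tibble(sequence = sequences, count = counts)
  out <- dplyr::arrange(out, dplyr::desc(count), sequence)
  structure(
    out,
    library_id = library_id,
    total_clean = sum(counts),
    class = c("tag_library", class(out))
  )
}

#' @rdname tag_library
#' @param x Object to query.
#' @export
total_clean <- function(x) attr(x, "total_clean") %||% sum(x$count)

#' Filter reads on base quality
#'
#' Retains reads whose mean Phred score is at least `min_mean_quality` and
#' whose fraction of N bases is at most `max_n_fraction` -- the cleaning
#' rule applied before adaptor trimming. Malformed records (quality length
#' differing from sequence length) raise an error naming the record.
#'
#' @param reads Tibble with `sequence` and `quality` (Phred+33) columns.
#' @param min_mean_quality Minimum mean Phred score (default 20).
#' @param max_n_fraction Maximum tolerated fraction of N bases
#'   (default 0.1).
#' @return The retained reads, with attribute `n_removed`.
#' @examples
#' reads <- tibble::tibble(
#'   id = c("a", "b"),
#'   sequence = c("ACGT", "ACGT"),
#'   quality = c("IIII", "!!!!")
#' )
#' filter_low_quality(reads)
#' @export
filter_low_quality <- function(reads, min_mean_quality = 20,
                               max_n_fraction = 0.1) {
  bad <- which(nchar(reads$quality) != nchar(reads$sequence))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "read %d: quality length does not match sequence length", bad[1]
    ))
  }
  if (nrow(reads) == 0) {
    return(structure(reads, n_removed = 0L))
  }
  mean_q <- phred_means(reads$quality)
  n_frac <- stringr::str_count(toupper(reads$sequence), "N") /
    nchar(reads$sequence)
  keep <- mean_q >= min_mean_quality & n_frac <= max_n_fraction
  structure(reads[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Trim the 3' adaptor from read sequences
#'
#' Locates the leftmost exact occurrence of the adaptor's first
#' `seed_length` nt in each read and keeps the prefix before it when its
#' length falls within `[min_insert, max_insert]`. Reads are otherwise
#' assigned a discard reason: `no_adaptor`, `too_short` or `too_long`.
#'
#' @param sequences Character vector of read sequences.
#' @param adaptor_3p 3' adaptor sequence (at least `seed_length` nt).
#' @param min_insert,max_insert Accepted insert length bounds in nt
#'   (defaults 18-30, the typical mature-miRNA range).
#' @param seed_length Length of the adaptor prefix matched exactly
#'   (default 8).
#' @return Tibble with columns `sequence`, `insert` (NA when discarded)
#'   and `status` (`clean`/`no_adaptor`/`too_short`/`too_long`).
#' @examples
#' trim_adaptor_3p(c("ACGTACGTACGTACGTACGTTCGTATGCCGTCTAA", "ACGTACGT"),
#'                 adaptor_3p = "TCGTATGCCGTCT", min_insert = 18)
#' @export
trim_adaptor_3p <- function(sequences, adaptor_3p, min_insert = 18,
                            max_insert = 30, seed_length = 8) {
  adaptor_3p <- as_dna(adaptor_3p)
  if (nchar(adaptor_3p) < seed_length) {
    rlang::abort("adaptor_3p is shorter than the match seed length")
  }
  seed <- substr(adaptor_3p, 1, seed_length)
  sequences <- toupper(sequences)
  pos <- as.integer(regexpr(seed, sequences, fixed = TRUE))
  insert_len <- pos - 1L
  status <- dplyr::case_when(
    pos < 0 ~ "no_adaptor",
    insert_len < min_insert ~ "too_short",
    insert_len > max_insert ~ "too_long",
    TRUE ~ "clean"
  )
  tibble::tibble(
    sequence = sequences,
    insert = ifelse(status == "clean", substr(sequences, 1, insert_len),
                    NA_character_),
    status = status
  )
}

#' Remove 5' adaptor ligation contaminants
#'
#' Drops tags whose prefix matches the first `seed_length` nt of the 5'
#' adaptor (artifacts of adaptor-adaptor ligation).
#'
#' @param tags Character vector of trimmed tag sequences.
#' @param adaptor_5p 5' adaptor sequence.
#' @param seed_length Prefix length matched exactly (default 8).
#' @return The retained tags, with attribute `n_removed`.
#' @export
remove_5p_contaminants <- function(tags, adaptor_5p, seed_length = 8) {
  seed <- substr(as_dna(adaptor_5p), 1, seed_length)
  drop <- startsWith(toupper(tags), seed)
  structure(tags[!drop], n_removed = sum(drop))
}

#' Collapse tags into a unique-sequence library
#'
#' De-duplicates tags by exact sequence identity, summing read counts, and
#' returns a [tag_library]. Accepts either one sequence per read or an
#' already (partially) collapsed `sequence`/`count` table; collapsing a
#' collapsed library is the identity.
#'
#' @param tags Character vector of tag sequences (one per read) or a
#'   tibble with `sequence` and `count` columns.
#' @param library_id Library label.
#' @return A [tag_library].
#' @examples
#' collapse_tags(c("ACGT", "ACGT", "GGCC"))
#' @export
collapse_tags <- function(tags, library_id = "lib") {
  if (is.data.frame(tags)) {
    df <- tibble::tibble(sequence = as_dna(tags$sequence),
                         count = as.integer(tags$count))
  } else {
    df <- tibble::tibble(sequence = as_dna(tags), count = 1L)
  }
  agg <- dplyr::summarise(dplyr::group_by(df, sequence),
                          count = sum(count), .groups = "drop")
  tag_library(agg$sequence, agg$count, library_id = library_id)
}

#' Read-length histogram of a tag library
#'
#' @param library A [tag_library].
#' @return Tibble with `length` (nt) and `count` (reads).
#' @export
length_histogram <- function(library) {
  dplyr::count(
    dplyr::mutate(tibble::as_tibble(library), length = nchar(sequence)),
    length, wt = count, name = "count"
  )
}

#' Clean a raw read library end to end
#'
#' Runs the full data-cleansing stage: base-quality filtering, 3' adaptor
#' trimming with insert-length bounds, optional 5' adaptor contaminant
#' removal, and collapsing into a unique-tag library. The report accounts
#' for every input read (reads in = clean + removed by reason).
#'
#' @inheritParams filter_low_quality
#' @inheritParams trim_adaptor_3p
#' @param adaptor_5p Optional 5' adaptor; when supplied, matching tags are
#'   removed.
#' @param library_id Library label for the resulting [tag_library].
#' @return List with `library` (a [tag_library]) and `report` (tibble
#'   `reason`, `reads`, including the `input` and `clean` totals).
#' @export
clean_reads <- function(reads, adaptor_3p, adaptor_5p = NULL,
                        min_mean_quality = 20, max_n_fraction = 0.1,
                        min_insert = 18, max_insert = 30, seed_length = 8,
                        library_id = "lib") {
  n_in <- nrow(reads)
  kept <- filter_low_quality(reads, min_mean_quality, max_n_fraction)
  n_lowq <- attr(kept, "n_removed")
  trimmed <- trim_adaptor_3p(kept$sequence, adaptor_3p,
                             min_insert, max_insert, seed_length)
  tally <- table(factor(trimmed$status,
                        c("clean", "no_adaptor", "too_short", "too_long")))
  tags <- trimmed$insert[trimmed$status == "clean"]
  n_adapt5 <- 0L
  if (!is.null(adaptor_5p)) {
    tags <- remove_5p_contaminants(tags, adaptor_5p, seed_length)
    n_adapt5 <- attr(tags, "n_removed")
  }
  lib <- collapse_tags(as.character(tags), library_id = library_id)
  report <- tibble::tibble(
    reason = c("input", "low_quality", "no_adaptor", "too_short",
               "too_long", "adaptor_5p", "clean"),
    reads = c(n_in, n_lowq, tally[["no_adaptor"]], tally[["too_short"]],
              tally[["too_long"]], n_adapt5, total_clean(lib))
  )
  stopifnot(sum(report$reads[-c(1, 7)]) + total_clean(lib) == n_in)
  list(library = lib, report = report)
}

#' @export
glance.tag_library <- function(x, ...) {
  tibble::tibble(
    library_id = attr(x, "library_id"),
    n_unique = nrow(x),
    total_clean = total_clean(x)
  )
}
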