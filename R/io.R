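#' Read and write FASTA sequence sets as tibbles
#'
#' Thin wrappers around Biostrings that keep the package's tibble-first
#' interface: a sequence set is a tibble with `name` and `sequence`
#' columns. U is normalized to T on input.
#'
#' @param path File path.
#' @return `read_fasta()` returns a tibble with columns `name`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble::tibble(name = names(x), sequence = as_dna(as.character(x)))
}

#' @rdname read_fasta
#' @param seqs Tibble with `name` and `sequence` columns, or a named
#'   character vector.
#' @param rna Render sequences in the RNA alphabet (default DNA).
#' @return `write_fasta()` returns `path` invisibly.
#' @export
write_fasta <- function(seqs, path, rna = FALSE) {
  if (!is.data.frame(seqs)) {
    seqs <- tibble::tibble(name = names(seqs), sequence = unname(seqs))
  }
  s <- if (rna) as_rna(seqs$sequence) else as_dna(seqs$sequence)
  x <- Biostrings::BStringSet(s)
  names(x) <- seqs$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write FASTQ reads as tibbles
#'
#' Reads are tibbles with `id`, `sequence` and `quality` (Phred+33)
#' columns, the raw-read representation used by [filter_low_quality()] and
#' [clean_reads()].
#'
#' @param path File path.
#' @return `read_fastq()` returns a tibble with columns `id`, `sequence`,
#'   `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    id = names(x),
    sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' @rdname read_fastq
#' @param reads Tibble with `id`, `sequence`, `quality` columns.
#' @return `write_fastq()` returns `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality)
  )
  invisible(path)
}

#' Read and write collapsed tag tables
#'
#' The on-disk form of a tag library is a two-column TSV
#' (`sequence<TAB>count`).
#'
#' @param path File path.
#' @param library_id Library label attached to the returned tag library.
#' @return `read_tag_table()` returns a [tag_library] tibble.
#' @export
read_tag_table <- function(path, library_id = basename(path)) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sequence = readr::col_character(),
    count = readr::col_integer()
  ))
  tag_library(x$sequence, x$count, library_id = library_id)
}

#' @rdname read_tag_table
#' @param library A [tag_library] (or any tibble with `sequence`, `count`).
#' @return `write_tag_table()` returns `path` invisibly.
#' @export
write_tag_table <- function(library, path) {
  readr::write_tsv(library[c("sequence", "count")], path)
  invisible(path)
}

#' Paths to bundled example summary tables
#'
#' The package ships, under `inst/extdata/`, the published summary tables
#' of a two-library small-RNA profiling study of membranous nephropathy
#' (MN) versus normal controls (NC): genome-mapping counts, top fold
#' changes, per-position base composition, seed-edit percentages, and qPCR
#' Ct values. They serve as worked-example inputs and as regression
#' fixtures.
#'
#' @param file Name of the example file; with no argument, lists the
#'   available files.
#' @return A path (or a character vector of file names).
#' @examples
#' smallrnadx_example()
#' readr::read_tsv(smallrnadx_example("mn_qpcr_ct.tsv"), show_col_types = FALSE)
#' @export
smallrnadx_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "smallrnadx")))
  }
  path <- system.file("extdata", file, package = "smallrnadx")
  if (path == "") rlang::abort(sprintf("no example file '%s'", file))
  path
}
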