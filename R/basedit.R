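#' Find candidate seed-region base edits
#'
#' Aligns tags to mature miRNAs of the same length and reports every pair
#' differing at exactly one position, when that position lies in the seed
#' region (positions `seed_start`-`seed_end` on the mature miRNA, default
#' 2-8). Tags that match some mature sequence exactly are never reported
#' (exactness trumps edit); a tag hitting several miRNAs is reported for
#' each and flagged `multi`. Equal-length comparison only -- no indels or
#' shifted alignments.
#'
#' @param tags Character vector of tag sequences, or a tibble with a
#'   `sequence` column (e.g. the `unannotated` attribute of
#'   [count_known()]).
#' @param reference Mature-miRNA tibble (`name`, `sequence`).
#' @param seed_start,seed_end Seed-region bounds, 1-based on the mature
#'   miRNA (defaults 2 and 8).
#' @return Tibble with `tag`, `mirna`, `position`, `ref_base`, `obs_base`
#'   (RNA alphabet), `multi`.
#' @export
find_seed_edits <- function(tags, reference, seed_start = 2, seed_end = 8) {
  if (nrow(reference) == 0) rlang::abort("reference is empty")
  if (is.data.frame(tags)) tags <- tags$sequence
  tags <- as_dna(tags)
  ref_seq <- as_dna(reference$sequence)
  empty <- tibble::tibble(
    tag = character(), mirna = character(), position = integer(),
    ref_base = character(), obs_base = character(), multi = logical()
  )
  if (length(tags) == 0) return(empty)
  tags <- unique(tags[!(tags %in% ref_seq)])
  if (length(tags) == 0) return(empty)

  hits <- list()
  for (len in unique(nchar(ref_seq))) {
    t_len <- tags[nchar(tags) == len]
    if (length(t_len) == 0) next
    tm <- matrix(unlist(strsplit(t_len, "")), nrow = len) # len x ntags
    for (r in which(nchar(ref_seq) == len)) {
      rv <- strsplit(ref_seq[r], "")[[1]]
      mm <- tm != rv
      nmm <- colSums(mm)
      cand <- which(nmm == 1)
      if (length(cand) == 0) next
      pos <- apply(mm[, cand, drop = FALSE], 2, which)
      inseed <- pos >= seed_start & pos <= seed_end
      if (!any(inseed)) next
      j <- cand[inseed]
      p <- pos[inseed]
      hits[[length(hits) + 1]] <- tibble::tibble(
        tag = t_len[j],
        mirna = reference$name[r],
        position = as.integer(p),
        ref_base = as_rna(rv[p]),
        obs_base = as_rna(tm[cbind(p, j)])
      )
    }
  }
  if (length(hits) == 0) return(empty)
  out <- dplyr::bind_rows(hits)
  out <- dplyr::mutate(
    dplyr::group_by(out, tag),
    multi = dplyr::n() > 1
  ) |> dplyr::ungroup()
  dplyr::arrange(out, tag, mirna)
}

#' Seed-edit percentage
#'
#' `100 * edited / (edited + exact)`: the fraction of a miRNA's reads
#' carrying a single seed-region substitution, among the miRNA's edited
#' plus exact reads.
#'
#' @param edited,exact Read counts; `edited + exact` must be positive.
#' @return Percentage (vectorized), full precision.
#' @examples
#' edit_percentage(5, 5)
#' @export
edit_percentage <- function(edited, exact) {
  stopifnot(all(edited >= 0), all(exact >= 0))
  if (any(edited + exact == 0)) {
    rlang::abort("edited + exact must be positive (omit uncovered miRNAs)")
  }
  100 * edited / (edited + exact)
}

#' Seed-edit ratio and class
#'
#' The case/control edit ratio `pct_mn / pct_nc`, rounded half-up to two
#' decimals, classified against 1.00: `gt1` (edits more common in MN),
#' `eq1`, `lt1`. Classification happens on the rounded ratio, so a pair
#' like 100.00/99.55 lands in the `eq1` class. `pct_nc = 0` yields an
#' undefined ratio (`NA`, class `undefined`), excluded from the
#' three-class partition.
#'
#' @param pct_mn,pct_nc Seed-edit percentages in the MN and NC groups.
#' @return Tibble with `ratio` (2-decimal) and `edit_class`
#'   (factor `gt1`/`eq1`/`lt1`/`undefined`).
#' @examples
#' edit_ratio(10.64, 11.48)
#' @export
edit_ratio <- function(pct_mn, pct_nc) {
  stopifnot(all(pct_mn >= 0), all(pct_nc >= 0))
  ratio <- ifelse(pct_nc > 0, round_half_up(pct_mn / pct_nc, 2), NA_real_)
  cls <- dplyr::case_when(
    is.na(ratio) ~ "undefined",
    ratio > 1 ~ "gt1",
    ratio < 1 ~ "lt1",
    TRUE ~ "eq1"
  )
  tibble::tibble(
    ratio = ratio,
    edit_class = factor(cls, levels = c("gt1", "eq1", "lt1", "undefined"))
  )
}

#' Per-miRNA seed-edit summary for two libraries
#'
#' For each mature miRNA and each library, tallies exact reads (tags equal
#' to the mature sequence) and seed-edited reads (tags one seed-region
#' substitution away, via [find_seed_edits()]); computes the edit
#' percentage per group, the MN/NC ratio and its class. Only miRNAs
#' observed (exact or edited) in both groups are classified, mirroring a
#' common-to-both-groups analysis; denominators are read counts by
#' default, or distinct tags with `by_reads = FALSE`.
#'
#' @param library_mn,library_nc [tag_library] objects for the MN and NC
#'   libraries.
#' @param reference Mature-miRNA tibble (`name`, `sequence`).
#' @param seed_start,seed_end Seed-region bounds (defaults 2 and 8).
#' @param by_reads Count reads (default) or distinct tags.
#' @return Tibble of class `edit_summary`: `mirna`, `edited_mn`,
#'   `exact_mn`, `pct_mn`, `edited_nc`, `exact_nc`, `pct_nc`, `ratio`,
#'   `edit_class`; attribute `n_common`.
#' @export
seed_edit_summary <- function(library_mn, library_nc, reference,
                              seed_start = 2, seed_end = 8,
                              by_reads = TRUE) {
  tally_one <- function(library) {
    weight <- if (by_reads) library$count else rep(1L, nrow(library))
    ref_seq <- as_dna(reference$sequence)
    exact <- stats::setNames(rep(0, nrow(reference)), reference$name)
    idx <- match(library$sequence, ref_seq)
    hitex <- !is.na(idx)
    if (any(hitex)) {
      agg <- rowsum(weight[hitex], reference$name[idx[hitex]])
      exact[rownames(agg)] <- agg
    }
    unann <- library[!hitex, , drop = FALSE]
    hits <- find_seed_edits(unann$sequence, reference, seed_start, seed_end)
    edited <- stats::setNames(rep(0, nrow(reference)), reference$name)
    if (nrow(hits) > 0) {
      w <- (if (by_reads) unann$count else rep(1L, nrow(unann)))[
        match(hits$tag, unann$sequence)]
      agg <- rowsum(w, hits$mirna)
      edited[rownames(agg)] <- agg
    }
    tibble::tibble(mirna = reference$name, exact = unname(exact),
                   edited = unname(edited))
  }
  mn <- tally_one(library_mn)
  nc <- tally_one(library_nc)
  out <- tibble::tibble(
    mirna = mn$mirna,
    edited_mn = mn$edited, exact_mn = mn$exact,
    edited_nc = nc$edited, exact_nc = nc$exact
  ) |>
    dplyr::filter(edited_mn + exact_mn > 0, edited_nc + exact_nc > 0) |>
    dplyr::mutate(
      pct_mn = edit_percentage(edited_mn, exact_mn),
      pct_nc = edit_percentage(edited_nc, exact_nc)
    )
  rc <- edit_ratio(out$pct_mn, out$pct_nc)
  out$ratio <- rc$ratio
  out$edit_class <- rc$edit_class
  out <- out[c("mirna", "edited_mn", "exact_mn", "pct_mn",
               "edited_nc", "exact_nc", "pct_nc", "ratio", "edit_class")]
  structure(out, n_common = nrow(out),
            class = c("edit_summary", class(out)))
}

#' Partition classified miRNAs by edit-ratio class
#'
#' Counts the `gt1` / `eq1` / `lt1` classes; undefined ratios are
#' excluded. The three counts always partition the classified set.
#'
#' @param summary An [edit_ratio()] result, a [seed_edit_summary()], or
#'   any tibble with an `edit_class` column.
#' @return Tibble with one row: `n_gt1`, `n_eq1`, `n_lt1`, `n_classified`.
#' @export
edit_partition <- function(summary) {
  cls <- summary$edit_class
  cls <- cls[!is.na(cls) & cls != "undefined"]
  tibble::tibble(
    n_gt1 = sum(cls == "gt1"),
    n_eq1 = sum(cls == "eq1"),
    n_lt1 = sum(cls == "lt1"),
    n_classified = length(cls)
  )
}

#' @export
glance.edit_summary <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_common = attr(x, "n_common")),
                   edit_partition(x))
}
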