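# Shared fixtures: all synthetic, built in code at test time.

FIX_ADAPTOR3 <- "TCGTATGCCGTCT"
FIX_ADAPTOR5 <- "GTTCAGAGTTCTA"

# A deterministic mature-miRNA reference of distinct 20-22mers.
tiny_reference <- function(n = 5) {
  set.seed(4242)
  tibble::tibble(
    name = sprintf("mir-%02d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 20 + (i %% 3), replace = TRUE),
            collapse = "")
    }, "")
  )
}

# Assemble a raw read from an insert: insert + 3' adaptor + filler,
# truncated/padded to `read_length`, with uniform quality `q`.
make_read <- function(insert, read_length = 50, q = 35,
                      adaptor = FIX_ADAPTOR3) {
  seq <- substr(paste0(insert, adaptor, strrep("A", read_length)),
                1, read_length)
  list(sequence = seq, quality = strrep(intToUtf8(33 + q), nchar(seq)))
}

make_reads <- function(inserts, read_length = 50, q = 35,
                       adaptor = FIX_ADAPTOR3) {
  rs <- lapply(inserts, make_read, read_length = read_length, q = q,
               adaptor = adaptor)
  tibble::tibble(
    id = sprintf("r%04d", seq_along(rs)),
    sequence = vapply(rs, `[[`, "", "sequence"),
    quality = vapply(rs, `[[`, "", "quality")
  )
}

# Substitute one base at `pos`, deterministically picking a different base.
mutate_at <- function(seq, pos) {
  old <- substr(seq, pos, pos)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(seq, pos, pos) <- new
  seq
}

read_example <- function(file) {
  readr::read_tsv(smallrnadx_example(file), show_col_types = FALSE)
}

# Hamming-distance oracle over equal-length sequences.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Brute-force seed-edit oracle: every (tag, mature) pair at Hamming
# distance exactly 1 with the mismatch inside the seed region.
oracle_seed_hits <- function(tags, ref, seed_start = 2, seed_end = 8) {
  out <- list()
  for (tg in unique(tags)) {
    if (tg %in% ref$sequence) next # exactness trumps edit
    for (r in seq_len(nrow(ref))) {
      if (nchar(tg) != nchar(ref$sequence[r])) next
      if (hamming(tg, ref$sequence[r]) != 1) next
      pos <- which(strsplit(tg, "")[[1]] != strsplit(ref$sequence[r], "")[[1]])
      if (pos >= seed_start && pos <= seed_end) {
        out[[length(out) + 1]] <- tibble::tibble(
          tag = tg, mirna = ref$name[r], position = as.integer(pos)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(tag = character(), mirna = character(),
                          position = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), tag, mirna)
}
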