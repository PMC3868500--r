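test_that("quality filter applies the mean-Phred / N-fraction rule", {
  reads <- tibble::tibble(
    id = c("bad", "good"),
    sequence = c("ACGT", "ACGT"),
    quality = c("!!!!", "IIII") # Phred 0 vs 40
  )
  kept <- filter_low_quality(reads, min_mean_quality = 20)
  expect_identical(kept$id, "good")
  expect_identical(attr(kept, "n_removed"), 1L)

  # N-rich read removed even at high quality
  reads_n <- tibble::tibble(id = "n", sequence = "ANNNNNNGT",
                            quality = strrep("I", 9))
  expect_equal(nrow(filter_low_quality(reads_n, max_n_fraction = 0.1)), 0)
})

test_that("quality filter matches a read-by-read oracle on a mixed stream", {
  set.seed(101)
  n <- 100
  len <- 30
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                prob = c(0.23, 0.23, 0.23, 0.23, 0.08))
    paste(s, collapse = "")
  }, "")
  quals <- vapply(seq_len(n), function(i) {
    intToUtf8(33 + sample(0:40, len, replace = TRUE))
  }, "")
  reads <- tibble::tibble(id = as.character(seq_len(n)),
                          sequence = seqs, quality = quals)
  kept <- filter_low_quality(reads, min_mean_quality = 20,
                             max_n_fraction = 0.1)
  oracle_keep <- vapply(seq_len(n), function(i) {
    q <- utf8ToInt(quals[i]) - 33
    nn <- sum(strsplit(seqs[i], "")[[1]] == "N")
    mean(q) >= 20 && nn / len <= 0.1
  }, TRUE)
  expect_identical(kept$id, reads$id[oracle_keep])
  expect_identical(attr(kept, "n_removed"), sum(!oracle_keep))
})

test_that("malformed reads are reported by record index", {
  reads <- tibble::tibble(id = c("a", "b"), sequence = c("ACGT", "ACGT"),
                          quality = c("IIII", "III"))
  expect_error(filter_low_quality(reads), "read 2")
})

test_that("3' adaptor trimming returns the insert or a discard reason", {
  insert <- strrep("AC", 10) # 20 nt
  read <- paste0(insert, FIX_ADAPTOR3, "GGGG")
  out <- trim_adaptor_3p(c(read, paste0(FIX_ADAPTOR3, "AAAA"), strrep("G", 40)),
                         FIX_ADAPTOR3)
  expect_identical(out$status, c("clean", "too_short", "no_adaptor"))
  expect_identical(out$insert[1], insert)
  expect_true(all(is.na(out$insert[2:3])))

  long <- paste0(strrep("A", 35), FIX_ADAPTOR3)
  expect_identical(trim_adaptor_3p(long, FIX_ADAPTOR3)$status, "too_long")
  expect_error(trim_adaptor_3p("ACGT", "ACGTA", seed_length = 8), "seed")
})

test_that("leftmost adaptor occurrence wins", {
  # adaptor seed appears twice; the insert must stop at the first
  read <- paste0(strrep("C", 20), FIX_ADAPTOR3, strrep("T", 3), FIX_ADAPTOR3)
  out <- trim_adaptor_3p(read, FIX_ADAPTOR3)
  expect_identical(out$insert, strrep("C", 20))
})

test_that("5' adaptor contaminants are removed by prefix seed", {
  tags <- c(paste0(substr(FIX_ADAPTOR5, 1, 8), "ACGTACGTAC"),
            strrep("ACGT", 5))
  kept <- remove_5p_contaminants(tags, FIX_ADAPTOR5)
  expect_identical(as.character(kept), strrep("ACGT", 5))
  expect_identical(attr(kept, "n_removed"), 1L)
  expect_length(remove_5p_contaminants(character(), FIX_ADAPTOR5), 0)
})

test_that("collapsing counts identical tags and conserves totals", {
  lib <- collapse_tags(c("ACGT", "ACGT", "GGCC"))
  expect_identical(lib$sequence, c("ACGT", "GGCC"))
  expect_identical(lib$count, c(2L, 1L))
  expect_identical(total_clean(lib), 3L)

  empty <- collapse_tags(character())
  expect_equal(nrow(empty), 0)
  expect_identical(total_clean(empty), 0L)
})

test_that("collapsing matches an independent counting oracle and is idempotent", {
  set.seed(77)
  tags <- vapply(sample(1:50, 1e4, replace = TRUE), function(i) {
    set.seed(i)
    paste(sample(c("A", "C", "G", "T"), 18, replace = TRUE), collapse = "")
  }, "")
  lib <- collapse_tags(tags)
  oracle <- table(tags)
  expect_identical(total_clean(lib), length(tags))
  expect_setequal(lib$sequence, names(oracle))
  expect_identical(lib$count[match(names(oracle), lib$sequence)],
                   as.integer(oracle))
  # idempotence: collapsing the collapsed library changes nothing
  lib2 <- collapse_tags(tibble::as_tibble(lib), library_id = "lib")
  expect_identical(tibble::as_tibble(lib2), tibble::as_tibble(lib))
})

test_that("U-containing tags are normalized to a single DNA alphabet", {
  lib <- collapse_tags(c("UAGC", "TAGC"))
  expect_identical(lib$sequence, "TAGC")
  expect_identical(lib$count, 2L)
})

test_that("end-to-end cleaning accounts for every input read", {
  inserts <- c(strrep("AG", 10), strrep("AG", 10), strrep("CT", 11))
  reads <- make_reads(inserts)
  # add one low-quality read, one adaptor dimer, one adaptor-free read
  extra <- tibble::tibble(
    id = c("lq", "dim", "na"),
    sequence = c(strrep("A", 50),
                 make_read(FIX_ADAPTOR3, adaptor = "")$sequence,
                 strrep("GA", 25)),
    quality = c(strrep("!", 50), strrep("I", 50), strrep("I", 50))
  )
  res <- clean_reads(dplyr::bind_rows(reads, extra),
                     adaptor_3p = FIX_ADAPTOR3, adaptor_5p = FIX_ADAPTOR5)
  rep <- res$report
  expect_identical(rep$reads[rep$reason == "input"], 6L)
  expect_identical(rep$reads[rep$reason == "low_quality"], 1L)
  expect_identical(rep$reads[rep$reason == "too_short"], 1L)
  expect_identical(rep$reads[rep$reason == "no_adaptor"], 1L)
  expect_identical(rep$reads[rep$reason == "clean"], 3L)
  expect_identical(total_clean(res$library), 3L)
  expect_identical(sort(res$library$sequence),
                   sort(unique(c(strrep("AG", 10), strrep("CT", 11)))))
})

test_that("length histogram weights by read count", {
  lib <- tag_library(c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTACGTAC"),
                     c(5L, 2L))
  h <- length_histogram(lib)
  expect_identical(h$count[h$length == 18], 5L)
  expect_identical(h$count[h$length == 22], 2L)
})
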