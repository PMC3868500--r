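#' Configuration for the synthetic two-library experiment
#'
#' Bundles every knob of the synthetic-data generator: a toy genome, a set
#' of planted mature miRNAs, and two raw read libraries (control `NC`,
#' case `MN`) with known per-miRNA abundance effects, seed edits and
#' contamination. All downstream stages can then be validated against the
#' recorded ground truth.
#'
#' @param n_chromosomes Number of toy chromosomes (>= 1).
#' @param chrom_length Length of each chromosome in nt (>= 100).
#' @param n_mirnas Number of mature miRNAs planted in the genome.
#' @param mirna_length_range Length range of planted mature miRNAs in nt.
#' @param library_depths Named integer vector `c(NC = ..., MN = ...)`:
#'   exact number of raw reads emitted per library.
#' @param log2_effects Named numeric vector of planted log2 MN/NC
#'   abundance effects; miRNAs not named get effect 0. Names must match
#'   planted miRNA names (`syn-miR-001`, ...).
#' @param seed_edit_rate Per-read probability, in each library, that a
#'   miRNA read carries a single substitution at a uniformly chosen seed
#'   position (2-8).
#' @param contamination_rate Fraction of reads that are contaminants
#'   (adaptor dimers, low-quality reads, N-rich reads, or random inserts
#'   lacking the adaptor).
#' @param adaptor_3p 3' adaptor appended after each insert.
#' @param adaptor_5p 5' adaptor used to simulate (and later remove)
#'   ligation contaminants.
#' @param read_length Raw read length in nt; inserts are padded with the
#'   3' adaptor and random filler up to this length.
#' @param rng_seed Integer seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(n_mirnas = 5, library_depths = c(NC = 500, MN = 500))
#' cfg$n_mirnas
#' @export
sim_config <- function(n_chromosomes = 3,
                       chrom_length = 10000,
                       n_mirnas = 50,
                       mirna_length_range = c(18, 24),
                       library_depths = c(NC = 1e5, MN = 1e5),
                       log2_effects = numeric(),
                       seed_edit_rate = 0.02,
                       contamination_rate = 0.05,
                       adaptor_3p = "TCGTATGCCGTCT",
                       adaptor_5p = "GTTCAGAGTTCTA",
                       read_length = 50,
                       rng_seed = 1) {
  stopifnot(
    n_chromosomes >= 1, chrom_length >= 100, n_mirnas >= 0,
    length(mirna_length_range) == 2,
    mirna_length_range[1] >= 16, mirna_length_range[2] >= mirna_length_range[1],
    mirna_length_range[2] <= read_length,
    length(library_depths) == 2, all(library_depths > 0)
  )
  if (is.null(names(library_depths))) names(library_depths) <- c("NC", "MN")
  if (seed_edit_rate < 0 || seed_edit_rate > 1) {
    rlang::abort("seed_edit_rate must be in [0, 1]")
  }
  if (contamination_rate < 0 || contamination_rate > 1) {
    rlang::abort("contamination_rate must be in [0, 1]")
  }
  if (nchar(adaptor_3p) < 8) rlang::abort("adaptor_3p must be at least 8 nt")
  check_alphabet(as_dna(adaptor_3p), what = "adaptor_3p")
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length = as.integer(chrom_length),
      n_mirnas = as.integer(n_mirnas),
      mirna_length_range = as.integer(mirna_length_range),
      library_depths = as.integer(library_depths) |>
        stats::setNames(names(library_depths)),
      log2_effects = log2_effects,
      seed_edit_rate = seed_edit_rate,
      contamination_rate = contamination_rate,
      adaptor_3p = as_dna(adaptor_3p),
      adaptor_5p = as_dna(adaptor_5p),
      read_length = as.integer(read_length),
      rng_seed = as.integer(rng_seed)
    ),
    class = "sim_config"
  )
}

random_dna <- function(n, length) {
  if (n == 0) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * length, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate a toy genome
#'
#' Uniform-random chromosome sequences over A/C/G/T, deterministic for a
#' fixed seed. A stand-in reference for exercising the exact-match mapper.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param chrom_length Chromosome length in nt (>= 100).
#' @param rng_seed Integer seed.
#' @return Named character vector of chromosome sequences (`chr1`, ...).
#' @examples
#' g <- simulate_genome(2, 500, rng_seed = 7)
#' nchar(g)
#' @export
simulate_genome <- function(n_chromosomes, chrom_length, rng_seed = 1) {
  if (n_chromosomes < 1 || chrom_length < 100) {
    rlang::abort("need n_chromosomes >= 1 and chrom_length >= 100")
  }
  with_rng(rng_seed, {
    stats::setNames(
      random_dna(n_chromosomes, chrom_length),
      paste0("chr", seq_len(n_chromosomes))
    )
  })
}

#' Plant mature miRNAs in a toy genome
#'
#' Chooses non-overlapping genomic sites and records, for each planted
#' miRNA, its mature sequence (the genome substring on the sense strand,
#' or its reverse complement on the antisense strand) together with the
#' coordinates. Sites whose mature sequence would start with the 5'
#' adaptor seed, or duplicate an already planted sequence, are resampled
#' so the cleaning and counting stages remain exactly invertible on
#' synthetic data.
#'
#' @param genome Named character vector from [simulate_genome()].
#' @param config A [sim_config()].
#' @return List with `reference` (tibble `name`, `sequence`) and
#'   `positions` (tibble `name`, `chrom`, `start` (1-based), `strand`).
#' @export
plant_mirnas <- function(genome, config) {
  n <- config$n_mirnas
  if (n == 0) {
    return(list(
      reference = tibble::tibble(name = character(), sequence = character()),
      positions = tibble::tibble(
        name = character(), chrom = character(),
        start = integer(), strand = character()
      )
    ))
  }
  seed5 <- substr(config$adaptor_5p, 1, 8)
  with_rng(config$rng_seed + 1L, {
    occupied <- lapply(genome, function(...) integer())
    out <- vector("list", n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(2000)) {
        len <- sample(config$mirna_length_range[1]:config$mirna_length_range[2], 1)
        chrom <- sample(names(genome), 1)
        start <- sample.int(nchar(genome[[chrom]]) - len + 1, 1)
        span <- start:(start + len - 1)
        if (any(span %in% occupied[[chrom]])) next
        strand <- sample(c("+", "-"), 1)
        seq <- substr(genome[[chrom]], start, start + len - 1)
        if (strand == "-") seq <- revcomp(seq)
        if (startsWith(seq, seed5)) next
        if (i > 1 && seq %in% vapply(out[seq_len(i - 1)], `[[`, "", "sequence")) next
        occupied[[chrom]] <- c(occupied[[chrom]], span)
        out[[i]] <- list(
          name = sprintf("syn-miR-%03d", i), sequence = seq,
          chrom = chrom, start = start, strand = strand
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        rlang::abort("insufficient genome space to place non-overlapping miRNAs")
      }
    }
    ref <- tibble::tibble(
      name = vapply(out, `[[`, "", "name"),
      sequence = vapply(out, `[[`, "", "sequence")
    )
    pos <- tibble::tibble(
      name = ref$name,
      chrom = vapply(out, `[[`, "", "chrom"),
      start = vapply(out, function(o) as.integer(o$start), 1L),
      strand = vapply(out, `[[`, "", "strand")
    )
    list(reference = ref, positions = pos)
  })
}

# Build quality strings with per-base Phred scores sampled from `range`.
random_quals <- function(n, length, range) {
  if (n == 0) return(character())
  chars <- intToUtf8(33L + range, multiple = TRUE)
  m <- matrix(sample(chars, n * length, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Apply a single random substitution at a seed position (2-8) of each tag.
apply_seed_edits <- function(tags, positions) {
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(tags)) {
    p <- positions[i]
    old <- substr(tags[i], p, p)
    new <- sample(setdiff(bases, old), 1)
    substr(tags[i], p, p) <- new
  }
  tags
}

#' Simulate the two raw read libraries
#'
#' Emits exactly `library_depths` reads per library. miRNA reads are drawn
#' multinomially from a fixed abundance vector (equal weights by default),
#' scaled by `2^log2_effect` in the MN library, so expected per-miRNA
#' count ratios follow the planted effects up to the compositional
#' renormalization inherent to fixed-depth sampling. A configured fraction
#' of miRNA reads carries a single planted seed-region substitution
#' (position 2-8). Each insert is padded with the 3' adaptor plus random
#' filler to `read_length` and given high Phred qualities; contaminant
#' reads are a uniform mix of adaptor dimers, low-quality reads, N-rich
#' reads and random adaptor-free inserts.
#'
#' @param reference Mature-miRNA tibble (`name`, `sequence`) from
#'   [plant_mirnas()].
#' @param config A [sim_config()].
#' @param abundance_weights Optional named positive weights per miRNA
#'   (default: equal).
#' @return List with `reads` (list of `NC`/`MN` read tibbles) and `truth`
#'   (tibble `mirna`, `library`, `count`, `edited_count`).
#' @export
simulate_libraries <- function(reference, config, abundance_weights = NULL) {
  n <- nrow(reference)
  if (n == 0) rlang::abort("reference is empty; plant at least one miRNA")
  eff <- config$log2_effects
  unknown <- setdiff(names(eff), reference$name)
  if (length(unknown) > 0) {
    rlang::abort(sprintf(
      "log2_effects name miRNAs absent from the reference: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  w <- rep(1, n)
  if (!is.null(abundance_weights)) {
    stopifnot(all(reference$name %in% names(abundance_weights)))
    w <- unname(abundance_weights[reference$name])
    stopifnot(all(w > 0))
  }
  e <- stats::setNames(rep(0, n), reference$name)
  e[names(eff)] <- eff

  with_rng(config$rng_seed + 2L, {
    libs <- lapply(names(config$library_depths), function(lib) {
      depth <- config$library_depths[[lib]]
      weights <- if (lib == "MN") w * 2^e else w
      n_contam <- stats::rbinom(1, depth, config$contamination_rate)
      n_mirna <- depth - n_contam

      assign_idx <- sample.int(n, n_mirna, replace = TRUE, prob = weights)
      tags <- reference$sequence[assign_idx]
      edited <- stats::runif(n_mirna) < config$seed_edit_rate
      if (any(edited)) {
        pos <- sample(2:8, sum(edited), replace = TRUE)
        tags[edited] <- apply_seed_edits(tags[edited], pos)
      }
      filler_len <- config$read_length
      filler <- random_dna(n_mirna, filler_len)
      seqs <- substr(paste0(tags, config$adaptor_3p, filler),
                     1, config$read_length)
      quals <- random_quals(n_mirna, config$read_length, 30:40)

      if (n_contam > 0) {
        kind <- sample(c("dimer", "lowq", "nrich", "noadapt"),
                       n_contam, replace = TRUE)
        cseq <- character(n_contam)
        cqual <- character(n_contam)
        for (k in unique(kind)) {
          idx <- which(kind == k)
          m <- length(idx)
          cseq[idx] <- switch(k,
            dimer = substr(
              paste0(config$adaptor_3p, random_dna(m, config$read_length)),
              1, config$read_length
            ),
            lowq = random_dna(m, config$read_length),
            nrich = {
              s <- random_dna(m, config$read_length)
              nn <- ceiling(0.2 * config$read_length)
              substr(s, 1, nn) <- strrep("N", nn)
              s
            },
            noadapt = random_dna(m, config$read_length)
          )
          cqual[idx] <- random_quals(
            m, config$read_length,
            if (k == "lowq") 2:15 else 30:40
          )
        }
        seqs <- c(seqs, cseq)
        quals <- c(quals, cqual)
      }

      truth <- tibble::tibble(
        mirna = reference$name,
        library = lib,
        count = as.integer(tabulate(assign_idx, nbins = n)),
        edited_count = as.integer(tabulate(assign_idx[edited], nbins = n))
      )
      reads <- tibble::tibble(
        id = sprintf("%s_%07d", lib, seq_along(seqs)),
        sequence = seqs,
        quality = quals
      )
      list(reads = reads, truth = truth)
    })
    names(libs) <- names(config$library_depths)
    list(
      reads = lapply(libs, `[[`, "reads"),
      truth = dplyr::bind_rows(lapply(libs, `[[`, "truth"))
    )
  })
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper chaining [simulate_genome()], [plant_mirnas()] and
#' [simulate_libraries()]; everything is a deterministic function of the
#' configuration.
#'
#' @param config A [sim_config()].
#' @param abundance_weights Passed to [simulate_libraries()].
#' @return List with `genome`, `reference`, `positions`, `reads`
#'   (`$NC`, `$MN`) and `truth`.
#' @examples
#' sim <- simulate_experiment(sim_config(
#'   n_mirnas = 5, library_depths = c(NC = 300, MN = 300)
#' ))
#' names(sim)
#' @export
simulate_experiment <- function(config, abundance_weights = NULL) {
  genome <- simulate_genome(config$n_chromosomes, config$chrom_length,
                            rng_seed = config$rng_seed)
  planted <- plant_mirnas(genome, config)
  libs <- simulate_libraries(planted$reference, config, abundance_weights)
  list(
    genome = genome,
    reference = planted$reference,
    positions = planted$positions,
    reads = libs$reads,
    truth = libs$truth,
    config = config
  )
}
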