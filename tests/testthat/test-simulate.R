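test_that("genome generation is deterministic, sized and DNA-only", {
  g1 <- simulate_genome(3, 500, rng_seed = 7)
  g2 <- simulate_genome(3, 500, rng_seed = 7)
  expect_identical(g1, g2)
  expect_length(g1, 3)
  expect_true(all(nchar(g1) == 500))
  expect_true(all(grepl("^[ACGT]+$", g1)))
  expect_false(identical(g1, simulate_genome(3, 500, rng_seed = 8)))
  expect_error(simulate_genome(0, 500), "n_chromosomes")
  expect_error(simulate_genome(1, 10), "chrom_length")
})

test_that("planted miRNAs are genome substrings at their recorded loci", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 2000, n_mirnas = 12,
                    rng_seed = 11)
  g <- simulate_genome(cfg$n_chromosomes, cfg$chrom_length, cfg$rng_seed)
  planted <- plant_mirnas(g, cfg)
  expect_equal(nrow(planted$reference), 12)
  expect_false(anyDuplicated(planted$reference$name) > 0)
  for (i in seq_len(12)) {
    p <- planted$positions[i, ]
    len <- nchar(planted$reference$sequence[i])
    sub <- substr(g[[p$chrom]], p$start, p$start + len - 1)
    expected <- if (p$strand == "+") sub else revcomp(sub)
    expect_identical(planted$reference$sequence[i], expected)
  }
  # different seeds move the placements
  cfg2 <- sim_config(n_chromosomes = 2, chrom_length = 2000, n_mirnas = 12,
                     rng_seed = 12)
  g2 <- simulate_genome(2, 2000, 12)
  expect_false(identical(plant_mirnas(g2, cfg2)$positions, planted$positions))
})

test_that("zero miRNAs yields empty reference and truth", {
  cfg <- sim_config(n_mirnas = 0, rng_seed = 1)
  g <- simulate_genome(1, 500, 1)
  planted <- plant_mirnas(g, cfg)
  expect_equal(nrow(planted$reference), 0)
  expect_equal(nrow(planted$positions), 0)
})

test_that("a cramped genome cannot host the requested miRNAs", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 100, n_mirnas = 20,
                    rng_seed = 3)
  g <- simulate_genome(1, 100, 3)
  expect_error(plant_mirnas(g, cfg), "insufficient genome space")
})

test_that("library simulation conserves depth and truth accounting", {
  cfg <- sim_config(
    n_mirnas = 8, library_depths = c(NC = 4000, MN = 3000),
    log2_effects = c("syn-miR-001" = 1), seed_edit_rate = 0.1,
    contamination_rate = 0.1, rng_seed = 5
  )
  sim <- simulate_experiment(cfg)
  expect_identical(nrow(sim$reads$NC), 4000L)
  expect_identical(nrow(sim$reads$MN), 3000L)
  expect_true(all(nchar(sim$reads$NC$sequence) == cfg$read_length))
  tr <- sim$truth
  expect_true(all(tr$edited_count <= tr$count))
  expect_lte(sum(tr$count[tr$library == "NC"]), 4000)
  expect_lte(sum(tr$count[tr$library == "MN"]), 3000)
  # byte-identical rerun under the same config
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$genome, sim2$genome)
})

test_that("unknown effect names are rejected", {
  cfg <- sim_config(n_mirnas = 3, log2_effects = c(nope = 2), rng_seed = 2,
                    library_depths = c(NC = 100, MN = 100))
  g <- simulate_genome(3, 10000, 2)
  planted <- plant_mirnas(g, cfg)
  expect_error(simulate_libraries(planted$reference, cfg), "nope")
})

test_that("without contamination every read survives cleaning", {
  cfg <- sim_config(n_mirnas = 6, library_depths = c(NC = 2000, MN = 2000),
                    contamination_rate = 0, rng_seed = 9)
  sim <- simulate_experiment(cfg)
  cl <- clean_reads(sim$reads$NC, adaptor_3p = cfg$adaptor_3p,
                    adaptor_5p = cfg$adaptor_5p, library_id = "NC")
  expect_identical(total_clean(cl$library), 2000L)
  expect_identical(sum(sim$truth$count[sim$truth$library == "NC"]), 2000L)
})

test_that("without seed edits no miRNA shows edited tags", {
  cfg <- sim_config(n_mirnas = 6, library_depths = c(NC = 2000, MN = 2000),
                    contamination_rate = 0, seed_edit_rate = 0, rng_seed = 13)
  sim <- simulate_experiment(cfg)
  libs <- lapply(c(NC = "NC", MN = "MN"), function(l) {
    clean_reads(sim$reads[[l]], cfg$adaptor_3p, cfg$adaptor_5p,
                library_id = l)$library
  })
  es <- seed_edit_summary(libs$MN, libs$NC, sim$reference)
  expect_true(all(es$edited_mn == 0))
  expect_true(all(es$edited_nc == 0))
  expect_true(all(sim$truth$edited_count == 0))
})

test_that("planted log2 effects shift simulated counts as configured", {
  cfg <- sim_config(
    n_mirnas = 10, library_depths = c(NC = 20000, MN = 20000),
    log2_effects = c("syn-miR-003" = 2), contamination_rate = 0,
    seed_edit_rate = 0, rng_seed = 21
  )
  sim <- simulate_experiment(cfg)
  tr <- tidyr::pivot_wider(sim$truth[c("mirna", "library", "count")],
                           names_from = library, values_from = count)
  est <- log2((tr$MN / sum(tr$MN)) / (tr$NC / sum(tr$NC)))
  expect_lt(abs(est[tr$mirna == "syn-miR-003"] -
                  (2 + log2(10 / 13))), 0.3) # planted effect + renormalization
  expect_true(all(abs(est[tr$mirna != "syn-miR-003"] - log2(10 / 13)) < 0.3))
})

test_that("config validation rejects out-of-range rates and depths", {
  expect_error(sim_config(contamination_rate = 1.5), "contamination_rate")
  expect_error(sim_config(seed_edit_rate = -0.1), "seed_edit_rate")
  expect_error(sim_config(library_depths = c(NC = 0, MN = 10)))
  expect_error(sim_config(adaptor_3p = "ACGT"), "adaptor_3p")
})
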