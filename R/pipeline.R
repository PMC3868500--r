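#' Build the miRNA-by-pair fold-change matrix
#'
#' Rows are miRNAs, columns are sample-pair labels, cells the log2 fold
#' change of that pair's differential analysis. A cell is missing (`NA`)
#' exactly when the miRNA was unexpressed (count floored to the absence
#' value) in at least one member of the pair, so absence never masquerades
#' as an extreme fold change. Row order is the order of first appearance;
#' column order is the input order.
#'
#' @param de_list Named list of [diff_expression()] results (or tibbles
#'   with `mirna`, `log2_fc`, `floored_nc`, `floored_mn`), one per sample
#'   pair; names are the pair labels.
#' @return Numeric matrix with miRNA rownames and pair-label colnames.
#' @export
build_pair_matrix <- function(de_list) {
  if (length(de_list) == 0) rlang::abort("need at least one pair")
  labels <- names(de_list)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    rlang::abort("de_list must have unique, non-empty pair labels")
  }
  mirnas <- unique(unlist(lapply(de_list, function(d) d$mirna)))
  mat <- matrix(NA_real_, nrow = length(mirnas), ncol = length(labels),
                dimnames = list(mirnas, labels))
  for (j in seq_along(de_list)) {
    d <- de_list[[j]]
    expressed <- !(d$floored_nc | d$floored_mn)
    mat[d$mirna[expressed], j] <- d$log2_fc[expressed]
  }
  mat
}

# Pairwise-complete distance between the columns of `m` (observations in
# columns). Euclidean distances are rescaled by sqrt(p / shared) as in
# stats::dist, so complete data reproduces dist() exactly.
pairwise_dist <- function(m, distance, what) {
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- stats::complete.cases(m[, i], m[, j])
      if (!any(shared)) {
        rlang::abort(sprintf(
          "%ss '%s' and '%s' share no non-missing entries",
          what, colnames(m)[i], colnames(m)[j]
        ))
      }
      if (distance == "euclidean") {
        dif <- m[shared, i] - m[shared, j]
        d[i, j] <- sqrt(sum(dif^2) * nrow(m) / sum(shared))
      } else {
        r <- stats::cor(m[shared, i], m[shared, j])
        if (is.na(r)) r <- 0 # zero-variance columns: treat as uncorrelated
        d[i, j] <- 1 - r
      }
      d[j, i] <- d[i, j]
    }
  }
  stats::as.dist(d)
}

#' Hierarchically cluster the pair matrix
#'
#' Clusters both miRNAs (rows) and sample pairs (columns) of a
#' [build_pair_matrix()] matrix with agglomerative clustering
#' ([stats::hclust()]). Distances are computed pairwise-complete over
#' non-missing cells, so missing markers never leak into a distance; any
#' two rows (or columns) sharing no observed cell raise an error naming
#' them. Merge heights are non-decreasing for both supported linkages.
#'
#' @param matrix Numeric matrix from [build_pair_matrix()] (>= 2 rows and
#'   >= 2 columns).
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return List of class `pair_clustering`: `matrix`, `row_hclust`,
#'   `col_hclust`, `row_order`, `col_order`, `distance`, `linkage`.
#' @export
cluster_pairs <- function(matrix, distance = c("euclidean", "correlation"),
                          linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (nrow(matrix) < 2 || ncol(matrix) < 2) {
    rlang::abort("need at least 2 rows and 2 columns to cluster")
  }
  row_h <- stats::hclust(pairwise_dist(t(matrix), distance, "row"),
                         method = linkage)
  col_h <- stats::hclust(pairwise_dist(matrix, distance, "column"),
                         method = linkage)
  structure(
    list(
      matrix = matrix,
      row_hclust = row_h,
      col_hclust = col_h,
      row_order = rownames(matrix)[row_h$order],
      col_order = colnames(matrix)[col_h$order],
      distance = distance,
      linkage = linkage
    ),
    class = "pair_clustering"
  )
}

#' @export
tidy.pair_clustering <- function(x, ...) {
  m <- x$matrix[x$row_order, x$col_order, drop = FALSE]
  tibble::as_tibble(m, rownames = "mirna") |>
    tidyr::pivot_longer(-mirna, names_to = "pair", values_to = "log2_fc")
}

#' @export
glance.pair_clustering <- function(x, ...) {
  tibble::tibble(
    n_mirnas = nrow(x$matrix),
    n_pairs = ncol(x$matrix),
    n_missing = sum(is.na(x$matrix)),
    distance = x$distance,
    linkage = x$linkage
  )
}

#' Run the whole two-library analysis on synthetic data
#'
#' Chains every stage on a seeded synthetic experiment: simulate, clean
#' both libraries, map clean tags to the toy genome, count known miRNAs,
#' compute base composition, run the differential analysis, summarize
#' seed edits, optionally quantify a supplied qPCR Ct table and check
#' concordance, and build the NC-vs-MN pair matrix (clustering applies
#' when several pairs are supplied to [cluster_pairs()] separately). A
#' manifest records the seed, parameters and per-stage conservation
#' checks; the run is a deterministic function of the configuration.
#'
#' @param config A [sim_config()].
#' @param qpcr_ct Optional Ct tibble for [qpcr_quantify()].
#' @param outdir Optional directory; when given, all tables are written
#'   as TSV, references as FASTA, and the manifest as JSON.
#' @param p_threshold,fc_threshold,mode Passed to [diff_expression()].
#' @param min_mean_quality,max_n_fraction,min_insert,max_insert Passed to
#'   [clean_reads()].
#' @return List of class `smallrna_pipeline` with elements `sim`,
#'   `libraries`, `clean_reports`, `mapping`, `counts`, `composition`,
#'   `de`, `edits`, `qpcr`, `concordance`, `pair_matrix`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), qpcr_ct = NULL,
                         outdir = NULL,
                         p_threshold = 0.01, fc_threshold = 1,
                         mode = "point",
                         min_mean_quality = 20, max_n_fraction = 0.1,
                         min_insert = 18, max_insert = 30) {
  sim <- simulate_experiment(config)

  cleaned <- lapply(c(NC = "NC", MN = "MN"), function(lib) {
    clean_reads(
      sim$reads[[lib]],
      adaptor_3p = config$adaptor_3p, adaptor_5p = config$adaptor_5p,
      min_mean_quality = min_mean_quality, max_n_fraction = max_n_fraction,
      min_insert = min_insert, max_insert = max_insert,
      library_id = lib
    )
  })
  libs <- lapply(cleaned, `[[`, "library")
  reports <- lapply(cleaned, `[[`, "report")

  idx <- genome_index(sim$genome)
  mapping <- lapply(libs, function(l) mapping_summary(map_tags(l, idx), l))

  counts <- count_table(libs$NC, libs$MN, sim$reference)
  composition <- lapply(c(NC = "NC", MN = "MN"), function(lib) {
    exact <- libs[[lib]][libs[[lib]]$sequence %in% as_dna(sim$reference$sequence), ]
    base_composition(exact, max_position = max(nchar(sim$reference$sequence)),
                     group = lib)
  })
  de <- diff_expression(counts, p_threshold = p_threshold,
                        fc_threshold = fc_threshold, mode = mode)
  edits <- seed_edit_summary(libs$MN, libs$NC, sim$reference)

  qpcr <- NULL
  conc <- NULL
  if (!is.null(qpcr_ct)) {
    qpcr <- qpcr_quantify(qpcr_ct)
    conc <- concordance(qpcr, de)
  }
  pair_matrix <- build_pair_matrix(list(MN_vs_NC = de))

  checks <- list(
    reads_conserved_nc = sum(reports$NC$reads[-c(1, 7)]) +
      total_clean(libs$NC) == nrow(sim$reads$NC),
    reads_conserved_mn = sum(reports$MN$reads[-c(1, 7)]) +
      total_clean(libs$MN) == nrow(sim$reads$MN),
    counts_conserved_nc = sum(counts$count_nc) +
      sum(attr(counts, "unannotated_nc")$count) == total_clean(libs$NC),
    counts_conserved_mn = sum(counts$count_mn) +
      sum(attr(counts, "unannotated_mn")$count) == total_clean(libs$MN),
    de_partition = sum(table(de$call)) == nrow(de),
    edit_partition = edit_partition(edits)$n_classified ==
      sum(edits$edit_class != "undefined")
  )
  manifest <- list(
    package = "smallrnadx",
    version = as.character(utils::packageVersion("smallrnadx")),
    rng_seed = config$rng_seed,
    parameters = list(
      n_chromosomes = config$n_chromosomes,
      chrom_length = config$chrom_length,
      n_mirnas = config$n_mirnas,
      library_depths = as.list(config$library_depths),
      seed_edit_rate = config$seed_edit_rate,
      contamination_rate = config$contamination_rate,
      p_threshold = p_threshold, fc_threshold = fc_threshold, mode = mode,
      min_mean_quality = min_mean_quality, max_n_fraction = max_n_fraction,
      min_insert = min_insert, max_insert = max_insert
    ),
    stages = list(
      clean = lapply(reports, function(r) stats::setNames(r$reads, r$reason)),
      mapping = lapply(mapping, function(m) glance(m)),
      de = glance(de),
      edits = edit_partition(edits)
    ),
    conservation = checks
  )
  out <- structure(
    list(
      sim = sim, libraries = libs, clean_reports = reports,
      mapping = mapping, counts = counts, composition = composition,
      de = de, edits = edits, qpcr = qpcr, concordance = conc,
      pair_matrix = pair_matrix, manifest = manifest
    ),
    class = "smallrna_pipeline"
  )
  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

#' Write pipeline outputs to a directory
#'
#' Emits every table as TSV, the genome and mature reference as FASTA,
#' and the manifest as JSON. Rerunning with the same configuration
#' produces byte-identical files.
#'
#' @param pipeline A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline <- function(pipeline, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_fasta(pipeline$sim$genome, p("genome.fa"))
  write_fasta(pipeline$sim$reference, p("mature_mirnas.fa"), rna = TRUE)
  for (lib in names(pipeline$libraries)) {
    write_tag_table(pipeline$libraries[[lib]],
                    p(sprintf("tags_%s.tsv", lib)))
    readr::write_tsv(pipeline$clean_reports[[lib]],
                     p(sprintf("cleaning_%s.tsv", lib)))
    readr::write_tsv(pipeline$mapping[[lib]]$per_chromosome,
                     p(sprintf("per_chromosome_%s.tsv", lib)))
    readr::write_tsv(pipeline$composition[[lib]],
                     p(sprintf("base_composition_%s.tsv", lib)))
  }
  readr::write_tsv(tibble::as_tibble(pipeline$counts), p("counts.tsv"))
  readr::write_tsv(tibble::as_tibble(pipeline$de), p("diff_expression.tsv"))
  readr::write_tsv(tibble::as_tibble(pipeline$edits), p("seed_edits.tsv"))
  if (!is.null(pipeline$qpcr)) {
    readr::write_tsv(tibble::as_tibble(pipeline$qpcr), p("qpcr.tsv"))
    readr::write_tsv(tibble::as_tibble(pipeline$concordance),
                     p("concordance.tsv"))
  }
  pm <- tibble::as_tibble(pipeline$pair_matrix, rownames = "mirna")
  readr::write_tsv(pm, p("pair_matrix.tsv"))
  jsonlite::write_json(pipeline$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.smallrna_pipeline <- function(x, ...) {
  g <- glance(x$de)
  cat(sprintf(
    "<smallrna_pipeline> %d miRNAs | NC %d / MN %d clean reads | %d up, %d down\n",
    g$n_mirnas, g$n1, g$n2, g$n_up, g$n_down
  ))
  invisible(x)
}
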