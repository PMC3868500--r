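#' Delta-Ct against a reference gene
#'
#' `ct_target - ct_ref` within one group, the first step of the
#' 2^-ddCt relative quantification.
#'
#' @param ct_target,ct_ref Threshold-cycle values (finite, positive).
#' @return Delta-Ct in cycles, full precision.
#' @examples
#' delta_ct(21.61, 10.88)
#' @export
delta_ct <- function(ct_target, ct_ref) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_ref))) {
    rlang::abort("Ct values must be finite")
  }
  if (any(ct_target <= 0) || any(ct_ref <= 0)) {
    rlang::abort("Ct values must be positive")
  }
  ct_target - ct_ref
}

#' Delta-delta-Ct ratio
#'
#' `ddct = dct_mn - dct_nc`; the relative expression of the case group
#' versus the control group is `2^-ddct`, and its log2 is `-ddct`. Values
#' are exact; report columns round half-up to two decimals.
#'
#' @param dct_mn,dct_nc Delta-Ct of the case (MN) and control (NC)
#'   groups.
#' @return Tibble with `ddct`, `ratio` (2^-ddct), `log2_ratio` (-ddct).
#' @examples
#' ddct_ratio(15.79, 10.73)
#' @export
ddct_ratio <- function(dct_mn, dct_nc) {
  ddct <- dct_mn - dct_nc
  tibble::tibble(ddct = ddct, ratio = 2^(-ddct), log2_ratio = -ddct)
}

#' 2^-ddCt quantification of a Ct table
#'
#' Takes one row per (miRNA, group) with the target and reference-gene Ct
#' values, averages replicate rows (mean by default, optionally median),
#' and derives delta-Ct per group, delta-delta-Ct, the 2^-ddCt ratio and
#' its log2. The reference gene is whatever was measured in `ct_ref`
#' (typically U6 for miRNA assays).
#'
#' @param ct Tibble with columns `mirna`, `group`, `ct_ref`, `ct_target`.
#' @param case,control Group labels (defaults `"MN"`, `"NC"`).
#' @param summarize Replicate summary: `"mean"` (default) or `"median"`.
#' @return Tibble of class `qpcr_result`: `mirna`, `dct_nc`, `dct_mn`,
#'   `ddct`, `ratio`, `log2_ratio`.
#' @export
qpcr_quantify <- function(ct, case = "MN", control = "NC",
                          summarize = c("mean", "median")) {
  summarize <- match.arg(summarize)
  fun <- if (summarize == "mean") mean else stats::median
  missing <- setdiff(c(case, control), unique(ct$group))
  if (length(missing) > 0) {
    rlang::abort(sprintf("groups absent from Ct table: %s",
                         paste(missing, collapse = ", ")))
  }
  per_group <- ct |>
    dplyr::filter(group %in% c(case, control)) |>
    dplyr::group_by(mirna, group) |>
    dplyr::summarise(dct = fun(delta_ct(ct_target, ct_ref)),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(per_group, names_from = group,
                             values_from = dct)
  incomplete <- is.na(wide[[case]]) | is.na(wide[[control]])
  if (any(incomplete)) {
    rlang::abort(sprintf("miRNAs measured in only one group: %s",
                         paste(wide$mirna[incomplete], collapse = ", ")))
  }
  dd <- ddct_ratio(wide[[case]], wide[[control]])
  out <- tibble::tibble(
    mirna = wide$mirna,
    dct_nc = wide[[control]],
    dct_mn = wide[[case]],
    ddct = dd$ddct,
    ratio = dd$ratio,
    log2_ratio = dd$log2_ratio
  )
  structure(out, class = c("qpcr_result", class(out)))
}

#' qPCR versus sequencing direction concordance
#'
#' Compares the sign of the qPCR log2 ratio with the sign of the
#' sequencing log2 fold change for every miRNA shared between the two
#' tables.
#'
#' @param qpcr A [qpcr_quantify()] result (needs `mirna`, `log2_ratio`).
#' @param de A [diff_expression()] result or any tibble with `mirna` and
#'   `log2_fc`.
#' @return Tibble with `mirna`, `qpcr_log2`, `seq_log2fc`, `concordant`;
#'   attribute `fraction_concordant`.
#' @export
concordance <- function(qpcr, de) {
  shared <- intersect(qpcr$mirna, de$mirna)
  if (length(shared) == 0) {
    rlang::abort("no shared miRNA names between qPCR and sequencing tables")
  }
  out <- tibble::tibble(
    mirna = shared,
    qpcr_log2 = qpcr$log2_ratio[match(shared, qpcr$mirna)],
    seq_log2fc = de$log2_fc[match(shared, de$mirna)]
  ) |>
    dplyr::mutate(concordant = sign(qpcr_log2) == sign(seq_log2fc))
  structure(out, fraction_concordant = mean(out$concordant),
            class = c("concordance_table", class(out)))
}

#' @export
glance.concordance_table <- function(x, ...) {
  tibble::tibble(
    n_shared = nrow(x),
    n_concordant = sum(x$concordant),
    fraction_concordant = attr(x, "fraction_concordant")
  )
}

#' @export
glance.qpcr_result <- function(x, ...) {
  tibble::tibble(
    n_mirnas = nrow(x),
    n_up = sum(x$log2_ratio > 0),
    n_down = sum(x$log2_ratio < 0)
  )
}
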