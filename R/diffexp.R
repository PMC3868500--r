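#' Per-million normalization with an absence floor
#'
#' `count / total_clean * 1e6`, floored at `floor` (default 0.01) so that
#' miRNAs absent from one library still have a defined fold change; the
#' floor is the convention used when publishing two-library miRNA tables
#' where absent entries print as 0.01.
#'
#' @param count Non-negative integer counts.
#' @param total_clean Clean-read total N of the library (> 0).
#' @param floor Lower bound applied to the normalized value.
#' @return Normalized expression in reads per million, floored.
#' @examples
#' normalize_expression(c(1000, 0), 1e6)
#' @export
normalize_expression <- function(count, total_clean, floor = 0.01) {
  if (any(count < 0)) rlang::abort("counts must be non-negative")
  if (any(total_clean <= 0)) rlang::abort("total_clean must be positive")
  pmax(count / total_clean * 1e6, floor)
}

#' Log2 fold change of normalized expression
#'
#' `log2(norm_mn / norm_nc)`; both arguments must be positive, which the
#' normalization floor guarantees. Antisymmetric in its arguments.
#'
#' @param norm_mn,norm_nc Normalized expression in the case (MN) and
#'   control (NC) libraries.
#' @return Log2 fold change at full precision.
#' @examples
#' fold_change(13344.793, 26.5605)
#' @export
fold_change <- function(norm_mn, norm_nc) {
  if (any(norm_mn <= 0) || any(norm_nc <= 0)) {
    rlang::abort("normalized expressions must be positive (apply the floor first)")
  }
  log2(norm_mn / norm_nc)
}

#' Audic-Claverie point probability
#'
#' The probability of observing `y` reads of a tag in a library of `n2`
#' clean reads given `x` reads in a library of `n1` clean reads:
#' \deqn{P(y|x) = (N_2/N_1)^y \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}
#' Evaluated in log space with log-gamma so it neither overflows nor
#' underflows for library totals up to 10^7. Symmetric under swapping
#' `(x, n1)` with `(y, n2)`.
#'
#' @param x,y Observed counts in the two libraries (non-negative).
#' @param n1,n2 Clean-read totals of the libraries holding `x` and `y`.
#' @param log Return the log probability.
#' @return Probability in (0, 1] (vectorized).
#' @examples
#' ac_point_prob(1, 1, 100, 100) # 0.25
#' @export
ac_point_prob <- function(x, y, n1, n2, log = FALSE) {
  stopifnot(all(x >= 0), all(y >= 0), all(n1 > 0), all(n2 > 0))
  r <- n2 / n1
  lp <- y * base::log(r) + lgamma(x + y + 1) - lgamma(x + 1) -
    lgamma(y + 1) - (x + y + 1) * log1p(r)
  if (log) lp else exp(lp)
}

#' Audic-Claverie p-value
#'
#' `mode = "point"` returns the point probability exactly as the formula
#' is usually printed. `mode = "tail"` returns the minimal-likelihood
#' exact p-value: the sum of `P(y'|x)` over every outcome `y'` no more
#' probable than the observed one (`P(y'|x) <= P(y|x)`), capped at 1 --
#' the classic two-sided convention for exact count tests, and
#' conservative under the null. Conditional on `x`, the point
#' probabilities over `y'` form a negative binomial with `x + 1`
#' successes and success probability `n1/(n1+n2)`; the pmf is unimodal,
#' so the sum is two negative-binomial tails whose cut points are found
#' by bisection and evaluated through the regularized incomplete beta
#' function. A direct term-by-term summation oracle verifies this in the
#' test suite.
#'
#' @inheritParams ac_point_prob
#' @param mode `"point"` (default) or `"tail"`.
#' @return p-value in (0, 1] (vectorized).
#' @examples
#' ac_pvalue(2, 5, 100, 100, mode = "tail")
#' @export
ac_pvalue <- function(x, y, n1, n2, mode = c("point", "tail")) {
  mode <- match.arg(mode)
  if (mode == "point") return(ac_point_prob(x, y, n1, n2))
  stopifnot(all(x >= 0), all(y >= 0), all(n1 > 0), all(n2 > 0))
  len <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(as.numeric(x), len); y <- rep_len(as.numeric(y), len)
  n1 <- rep_len(as.numeric(n1), len); n2 <- rep_len(as.numeric(n2), len)
  p0 <- n1 / (n1 + n2)
  lp <- function(k) ac_point_prob(x, k, n1, n2, log = TRUE)
  # borderline ties (log-space epsilon) count as "no more probable"
  thr <- lp(y) + 1e-9
  mode_y <- floor(x * n2 / n1) # mode of the NB pmf over y'
  p_le <- function(k) ifelse(k < 0, 0, stats::pbeta(p0, x + 1, k + 1))
  p_ge <- function(k) ifelse(k <= 0, 1,
                             stats::pbeta(p0, x + 1, pmax(k, 1),
                                          lower.tail = FALSE))
  out <- numeric(len)

  hi_side <- y >= mode_y
  # observed on/right of the mode: include [y, Inf) plus the left tail
  # [0, a] with a = largest k <= min(mode, y-1) whose pmf <= pmf(y)
  if (any(hi_side)) {
    i <- which(hi_side)
    upper <- p_ge(y[i])
    hi <- pmin(mode_y[i], y[i] - 1)
    a <- bisect_last_le(lp, thr, i, hi)
    out[i] <- upper + p_le(a)
  }
  # observed left of the mode: include [0, y] plus the right tail
  # [b, Inf) with b = smallest k >= mode whose pmf <= pmf(y)
  if (any(!hi_side)) {
    i <- which(!hi_side)
    lower <- p_le(y[i])
    sd_nb <- sqrt((x[i] + 1) * (1 - p0[i])) / p0[i]
    hi <- ceiling(mode_y[i] + 20 * sd_nb + 100)
    b <- bisect_first_le(lp, thr, i, mode_y[i], hi)
    out[i] <- lower + p_ge(b)
  }
  pmin(out, 1)
}

# Vectorized bisection helpers over the unimodal NB log-pmf. `lp` takes a
# vector of counts aligned with the full problem; `idx` selects the
# subproblem. Both return one cut point per element of `idx`.

# largest k in [0, hi] with lp(k) <= thr (lp increasing there); -1 if none
bisect_last_le <- function(lp, thr, idx, hi) {
  lo <- rep(0, length(idx))
  none <- hi < 0
  hi[none] <- 0
  full_k <- function(k) {
    v <- numeric(length(thr))
    v[idx] <- k
    lp(v)[idx]
  }
  while (any(lo < hi)) {
    mid <- ceiling((lo + hi) / 2)
    ok <- full_k(mid) <= thr[idx]
    hi <- ifelse(lo < hi & !ok, mid - 1, hi)
    lo <- ifelse(lo < hi & ok, pmax(lo, mid), lo)
    hi <- pmax(hi, lo)
  }
  res <- ifelse(full_k(lo) <= thr[idx], lo, -1)
  ifelse(none, -1, res)
}

# smallest k in [lo0, hi] with lp(k) <= thr (lp decreasing there)
bisect_first_le <- function(lp, thr, idx, lo0, hi) {
  lo <- lo0
  full_k <- function(k) {
    v <- numeric(length(thr))
    v[idx] <- k
    lp(v)[idx]
  }
  while (any(lo < hi)) {
    mid <- floor((lo + hi) / 2)
    ok <- full_k(mid) <= thr[idx]
    hi <- ifelse(lo < hi & ok, mid, hi)
    lo <- ifelse(lo < hi & !ok, mid + 1, lo)
  }
  lo
}

#' Exact Audic-Claverie point probability (big-rational)
#'
#' Evaluates the point formula with exact integer arithmetic:
#' `choose(x+y, x) * n2^y * n1^(x+1) / (n1+n2)^(x+y+1)`, carried out on
#' arbitrary-precision integers (base-1e7 limbs), then converted to
#' double. Slow but exact; intended as an oracle for small instances
#' (counts up to ~10^4), independent of the log-gamma path.
#'
#' @inheritParams ac_point_prob
#' @return Probability as a double accurate to ~1e-15 relative error.
#' @export
ac_point_exact <- function(x, y, n1, n2) {
  stopifnot(length(x) == 1, x >= 0, y >= 0, n1 > 0, n2 > 0,
            x == floor(x), y == floor(y), n1 == floor(n1), n2 == floor(n2))
  # numerator: C(x+y, x) * n2^y * n1^(x+1); denominator: (n1+n2)^(x+y+1)
  num <- big_from(1)
  for (i in seq_len(x)) { # C(x+y, x) built as prod (y+i)/i, exact at each step
    num <- big_mul_small(num, y + i)
    num <- big_div_small(num, i)
  }
  num <- big_mul_pow(num, n2, y)
  num <- big_mul_pow(num, n1, x + 1)
  den <- big_mul_pow(big_from(1), n1 + n2, x + y + 1)
  big_ratio(num, den)
}

# --- minimal non-negative big-integer arithmetic on base-1e7 limbs ------
# Limbs are little-endian doubles < 1e7; products with small multipliers
# stay below 2^53 so all carries are exact.

big_from <- function(n) {
  stopifnot(n >= 0, n < 1e14)
  v <- c(n %% 1e7, n %/% 1e7)
  if (v[2] == 0) v[1] else v
}

big_carry <- function(v) {
  repeat {
    carry <- v %/% 1e7
    if (all(carry == 0)) break
    v <- v - carry * 1e7
    v <- v + c(0, carry)[seq_along(v)]
    if (carry[length(carry)] > 0) v <- c(v, carry[length(carry)])
  }
  while (length(v) > 1 && v[length(v)] == 0) v <- v[-length(v)]
  v
}

big_mul_small <- function(v, s) {
  stopifnot(s >= 0, s < 1e7)
  big_carry(v * s)
}

big_mul_pow <- function(v, base, exp) {
  # multiply by base^exp with base possibly up to ~1e9: split into limbs
  if (exp == 0) return(v)
  for (k in seq_len(exp)) {
    b <- base
    acc <- NULL
    shift <- 0
    while (b > 0) {
      part <- big_mul_small(v, b %% 1e7)
      part <- c(rep(0, shift), part)
      acc <- if (is.null(acc)) part else big_add(acc, part)
      b <- b %/% 1e7
      shift <- shift + 1
    }
    v <- acc
  }
  v
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_carry(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

big_div_small <- function(v, s) {
  stopifnot(s >= 1, s < 1e7)
  out <- numeric(length(v))
  rem <- 0
  for (i in rev(seq_along(v))) {
    cur <- rem * 1e7 + v[i]
    out[i] <- cur %/% s
    rem <- cur %% s
  }
  if (rem != 0) rlang::abort("non-exact big integer division")
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_ratio <- function(num, den) {
  # leading three limbs give a ~1e21 mantissa: 15+ significant digits
  lead <- function(v) {
    k <- length(v)
    take <- v[seq(k, max(1, k - 2))] # leading limbs, most significant first
    m <- sum(take / 1e7^(seq_along(take) - 1))
    list(mantissa = m, exp = k - 1)
  }
  a <- lead(num)
  b <- lead(den)
  (a$mantissa / b$mantissa) * 10^(7 * (a$exp - b$exp))
}

# ------------------------------------------------------------------------

#' Call differential expression
#'
#' Applies the joint rule: `up` when `log2_fc >= fc_threshold` and
#' `p <= p_threshold`; `down` when `log2_fc <= -fc_threshold` and
#' `p <= p_threshold`; otherwise `unchanged`.
#'
#' @param log2_fc Log2 fold changes (MN over NC).
#' @param p_value Audic-Claverie p-values.
#' @param p_threshold Significance threshold (default 0.01).
#' @param fc_threshold Absolute log2 fold-change threshold (default 1;
#'   set to 0 for a pure p-value rule).
#' @return Factor with levels `up`, `down`, `unchanged`.
#' @export
call_differential <- function(log2_fc, p_value, p_threshold = 0.01,
                              fc_threshold = 1) {
  factor(
    dplyr::case_when(
      p_value <= p_threshold & log2_fc >= fc_threshold ~ "up",
      p_value <= p_threshold & log2_fc <= -fc_threshold ~ "down",
      TRUE ~ "unchanged"
    ),
    levels = c("up", "down", "unchanged")
  )
}

#' Two-library differential expression analysis
#'
#' Runs the full four-step procedure on a miRNA count table: per-million
#' normalization with the 0.01 absence floor, log2 fold change (MN/NC),
#' the Audic-Claverie probability, and up/down/unchanged calling. A
#' Benjamini-Hochberg adjusted column is emitted as supplementary output
#' only; calls use the raw p-values, matching the single-library-pair
#' design this analysis addresses.
#'
#' @param counts A [count_table()], or any tibble with `mirna`,
#'   `count_nc`, `count_mn` columns.
#' @param n1,n2 Clean-read totals of the NC and MN libraries; taken from
#'   the count-table attributes when omitted.
#' @param p_threshold,fc_threshold Calling thresholds
#'   (see [call_differential()]).
#' @param mode Audic-Claverie mode, `"point"` (the formula as usually
#'   printed; default) or `"tail"` (see [ac_pvalue()]).
#' @param floor Normalization floor (default 0.01).
#' @return Tibble of class `de_result` with columns `mirna`, `count_nc`,
#'   `count_mn`, `norm_nc`, `norm_mn`, `floored_nc`, `floored_mn`,
#'   `log2_fc`, `p_value`, `p_adj`, `call`.
#' @export
diff_expression <- function(counts, n1 = NULL, n2 = NULL,
                            p_threshold = 0.01, fc_threshold = 1,
                            mode = c("point", "tail"), floor = 0.01) {
  mode <- match.arg(mode)
  n1 <- n1 %||% attr(counts, "n1")
  n2 <- n2 %||% attr(counts, "n2")
  if (is.null(n1) || is.null(n2)) {
    rlang::abort("supply n1 and n2 (library clean totals)")
  }
  out <- tibble::as_tibble(counts[c("mirna", "count_nc", "count_mn")]) |>
    dplyr::mutate(
      norm_nc = normalize_expression(count_nc, n1, floor),
      norm_mn = normalize_expression(count_mn, n2, floor),
      floored_nc = count_nc / n1 * 1e6 < floor,
      floored_mn = count_mn / n2 * 1e6 < floor,
      log2_fc = fold_change(norm_mn, norm_nc),
      p_value = ac_pvalue(count_nc, count_mn, n1, n2, mode = mode),
      p_adj = stats::p.adjust(p_value, method = "BH"),
      call = call_differential(log2_fc, p_value, p_threshold, fc_threshold)
    )
  structure(
    out,
    n1 = n1, n2 = n2,
    p_threshold = p_threshold, fc_threshold = fc_threshold, mode = mode,
    class = c("de_result", class(out))
  )
}

#' Top up- and downregulated miRNAs
#'
#' Ranks called records by fold change: the top `n` upregulated by
#' descending `log2_fc` and the top `n` downregulated by ascending
#' `log2_fc`, ties broken by p-value then name.
#'
#' @param de A [diff_expression()] result.
#' @param n Number of records per direction.
#' @return List with tibbles `up` and `down`.
#' @export
top_tables <- function(de, n = 20) {
  if (n < 0) rlang::abort("n must be non-negative")
  up <- de |>
    dplyr::filter(call == "up") |>
    dplyr::arrange(dplyr::desc(log2_fc), p_value, mirna) |>
    utils::head(n)
  down <- de |>
    dplyr::filter(call == "down") |>
    dplyr::arrange(log2_fc, p_value, mirna) |>
    utils::head(n)
  list(up = tibble::as_tibble(up), down = tibble::as_tibble(down))
}

#' @export
tidy.de_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    n_mirnas = nrow(x),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    n_unchanged = sum(x$call == "unchanged"),
    n1 = attr(x, "n1"),
    n2 = attr(x, "n2"),
    p_threshold = attr(x, "p_threshold"),
    fc_threshold = attr(x, "fc_threshold"),
    mode = attr(x, "mode")
  )
}
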