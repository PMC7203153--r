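#' Two-proportion z-test (pooled)
#'
#' Tests equality of two population proportions with the pooled
#' standard error: `phat = (x1+x2)/(n1+n2)`,
#' `z = (x1/n1 - x2/n2) / sqrt(phat (1-phat) (1/n1 + 1/n2))`,
#' `p = 2 (1 - Phi(|z|))`. Equivalent to the 2x2 chi-squared test
#' without continuity correction (`z^2 = X^2`).
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List: `z`, `p`, `degenerate`. When the pooled proportion is
#'   0 or 1 the statistic is undefined; `degenerate = TRUE` with `z` and
#'   `p` both `NA`.
#' @examples
#' two_proportion_ztest(30, 100, 10, 100)   # z = 3.536
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  phat <- (x1 + x2) / (n1 + n2)
  if (phat <= 0 || phat >= 1)
    return(list(z = NA_real_, p = NA_real_, degenerate = TRUE))
  z <- (x1 / n1 - x2 / n2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  # 2*pnorm(-|z|) == 2*(1 - pnorm(|z|)) but keeps precision in the far tail
  list(z = z, p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Normal-approximation guard for a proportion
#'
#' The z-test on proportions assumes the sampling distribution of the
#' sample proportion is approximately normal; the usual operational rule
#' is `n*phat >= 5` and `n*(1-phat) >= 5`. Residues too rare in the
#' subset fail this guard and their enrichment is reported without a
#' p-value.
#'
#' @param x Count of the residue (or class) in the sample.
#' @param n Total residues in the sample.
#' @return Logical.
#' @export
normal_approx_ok <- function(x, n) {
  stopifnot(n > 0, x >= 0, x <= n)
  x >= 5 && (n - x) >= 5
}

# pooled residue (or class) counts over all positions of all sequences
pooled_counts <- function(seqs, grouping, scheme) {
  chars <- unlist(lapply(seqs, seq_chars), use.names = FALSE)
  if (grouping == "residue") {
    keys <- AA_CANONICAL
    counts <- vapply(keys, function(a) sum(chars == a), integer(1))
  } else {
    keys <- unique(unname(scheme$classes))
    counts <- vapply(keys, function(cl)
      sum(chars %in% names(scheme$classes)[scheme$classes == cl]),
      integer(1))
  }
  list(keys = keys, counts = counts, n = length(chars))
}

#' Residue or residue-class enrichment of a binder subset
#'
#' Compares pooled residue occurrence (over all positions of all
#' sequences) between a subset of binders and the full library with a
#' two-tailed two-proportion z-test per residue or class. Rows whose
#' subset counts fail the normal-approximation guard are reported with
#' `testable = FALSE` and no p-value, mirroring the practice of not
#' testing residues too rare in the sample population.
#'
#' @param subset_seqs Character vector of subset sequences; each must
#'   occur in `library_seqs`.
#' @param library_seqs Character vector of library sequences.
#' @param grouping `"residue"` (20 rows) or `"class"` (one row per
#'   class of `scheme`).
#' @param scheme Residue classification scheme for `grouping = "class"`.
#' @param adjust Optional multiple-testing correction applied to the
#'   testable p-values, e.g. `"BH"`; default `"none"`.
#' @return Data frame of class `"enrichment_table"`: `key`,
#'   `subset_count`, `subset_n`, `library_count`, `library_n`,
#'   `subset_prop`, `library_prop`, `z`, `p`, `testable`, `direction`
#'   (`"increase"`, `"decrease"` or `"none"`, matching the sign of `z`).
#' @export
compositional_enrichment <- function(subset_seqs, library_seqs,
                                     grouping = c("class", "residue"),
                                     scheme = residue_class_scheme(),
                                     adjust = "none") {
  grouping <- match.arg(grouping)
  if (length(subset_seqs) == 0L)
    stop("subset is empty", call. = FALSE)
  lapply(subset_seqs, assert_canonical)
  lapply(library_seqs, assert_canonical)
  extra <- setdiff(subset_seqs, library_seqs)
  if (length(extra))
    stop("subset sequence(s) absent from the library: ",
         paste(head(extra, 3), collapse = ", "), call. = FALSE)
  s <- pooled_counts(subset_seqs, grouping, scheme)
  l <- pooled_counts(library_seqs, grouping, scheme)
  rows <- lapply(seq_along(s$keys), function(i) {
    x1 <- s$counts[i]; x2 <- l$counts[i]
    testable <- normal_approx_ok(x1, s$n)
    zt <- if (testable) two_proportion_ztest(x1, s$n, x2, l$n)
          else list(z = NA_real_, p = NA_real_, degenerate = FALSE)
    if (isTRUE(zt$degenerate)) testable <- FALSE
    p1 <- x1 / s$n; p2 <- x2 / l$n
    dir <- if (!testable || p1 == p2) "none"
           else if (p1 > p2) "increase" else "decrease"
    data.frame(key = s$keys[i], subset_count = x1, subset_n = s$n,
               library_count = x2, library_n = l$n,
               subset_prop = p1, library_prop = p2,
               z = zt$z, p = zt$p, testable = testable, direction = dir)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!identical(adjust, "none")) {
    idx <- which(out$testable)
    out$p[idx] <- stats::p.adjust(out$p[idx], method = adjust)
  }
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Positional residue count matrices
#'
#' Counts each residue at each alignment position, N-terminally aligned
#' over positions 1..`window`; residues beyond `window` (e.g. position
#' 16 of a 16-mer in a 15-mer library) are dropped.
#'
#' @param seqs Character vector of sequences.
#' @param window Number of positions retained (default 15).
#' @return Integer matrix, `window` rows (positions) by 20 residue
#'   columns; each row sums to the number of sequences of at least that
#'   length.
#' @export
positional_matrix <- function(seqs, window = 15L) {
  lapply(seqs, assert_canonical)
  m <- matrix(0L, nrow = window, ncol = length(AA_CANONICAL),
              dimnames = list(position = seq_len(window),
                              residue = AA_CANONICAL))
  for (s in seqs) {
    chars <- head(seq_chars(s), window)
    for (pos in seq_along(chars))
      m[pos, chars[pos]] <- m[pos, chars[pos]] + 1L
  }
  m
}

#' Positional enrichment of a subset versus the library
#'
#' Per-position, per-residue two-proportion z-tests (subset versus
#' library), with the same normal-approximation guard as
#' [compositional_enrichment()].
#'
#' @inheritParams compositional_enrichment
#' @param window Alignment window (see [positional_matrix()]).
#' @return Data frame: `position`, `residue`, counts/proportions, `z`,
#'   `p`, `testable`, `direction`.
#' @export
positional_enrichment <- function(subset_seqs, library_seqs, window = 15L) {
  ms <- positional_matrix(subset_seqs, window)
  ml <- positional_matrix(library_seqs, window)
  ns <- rowSums(ms); nl <- rowSums(ml)
  rows <- list()
  for (pos in seq_len(window)) {
    for (a in AA_CANONICAL) {
      x1 <- ms[pos, a]; x2 <- ml[pos, a]
      testable <- ns[pos] > 0 && normal_approx_ok(x1, ns[pos])
      zt <- if (testable) two_proportion_ztest(x1, ns[pos], x2, nl[pos])
            else list(z = NA_real_, p = NA_real_)
      p1 <- x1 / ns[pos]; p2 <- x2 / nl[pos]
      dir <- if (!testable || p1 == p2) "none"
             else if (p1 > p2) "increase" else "decrease"
      rows[[length(rows) + 1L]] <-
        data.frame(position = pos, residue = a, subset_count = x1,
                   subset_n = ns[pos], library_count = x2,
                   library_n = nl[pos], subset_prop = p1,
                   library_prop = p2, z = zt$z, p = zt$p,
                   testable = testable, direction = dir)
    }
  }
  do.call(rbind, rows)
}

#' Build the high-selectivity peptide subset
#'
#' Applies the affinity-then-selectivity filter chain used to define
#' high-selectivity binders: peptides in the bottom `background_fraction`
#' of the intensity range are background/non-binding and are excluded;
#' an additional band up to `weak_fraction` of the range removes very
#' weak binders; surviving peptides with percent selectivity above
#' `selectivity_cut` form the subset.
#'
#' @param aggs Aggregated binding table for the uncompeted condition.
#' @param selectivities Selectivity table from [selectivity_table()].
#' @param background_fraction Fraction of the intensity range treated as
#'   background (default 0.20).
#' @param weak_fraction Fraction of the intensity range below which
#'   peptides are too weak for selectivity assessment (default 0.30).
#' @param selectivity_cut Percent-selectivity threshold (default 65).
#' @return Character vector of peptide ids (sorted).
#' @export
build_selectivity_subset <- function(aggs, selectivities,
                                     background_fraction = 0.20,
                                     weak_fraction = 0.30,
                                     selectivity_cut = 65) {
  stopifnot(weak_fraction >= background_fraction)
  rng <- range(aggs$grand_mean)
  cut_bg <- rng[1] + background_fraction * diff(rng)
  cut_weak <- rng[1] + weak_fraction * diff(rng)
  strong <- aggs$peptide_id[aggs$grand_mean > cut_bg &
                            aggs$grand_mean > cut_weak]
  sel <- selectivities[!is.na(selectivities$percent_selectivity) &
                       selectivities$percent_selectivity > selectivity_cut,
                       "peptide_id"]
  sort(intersect(strong, sel))
}
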