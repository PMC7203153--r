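#' Aggregate microarray spot intensities across replicates and assays
#'
#' Spots are printed in intra-assay replicate (typically triplicate) and
#' every screen is repeated as independent assays (typically three).
#' Aggregation first averages replicates within each assay, then takes
#' the grand mean of assay means; the inter-assay coefficient of
#' variation (sd of assay means over the grand mean) is the replicate
#' quality filter — peptides at or above `cv_threshold` are flagged not
#' retained and are excluded from top-binder selection downstream.
#'
#' @param spots Data frame with columns `peptide_id`, `condition_id`,
#'   `assay_id`, `replicate`, `intensity` (non-negative).
#' @param cv_threshold Retention cut on the inter-assay CV; the screen
#'   standard is 0.25 (25%).
#' @return Data frame with one row per peptide x condition: `peptide_id`,
#'   `condition_id`, `n_assays`, `grand_mean`, `intra_assay_sd` (pooled
#'   within-assay sd), `inter_assay_sd`, `inter_assay_cv`, `retained`,
#'   `reason` (`"ok"`, `"high_cv"` or `"zero_mean"`). A grand mean of
#'   zero leaves the CV undefined (`NA`) and the peptide not retained.
#' @examples
#' spots <- data.frame(peptide_id = "p1", condition_id = "CA10",
#'                     assay_id = rep(1:3, each = 3), replicate = 1:3,
#'                     intensity = rep(c(70, 100, 130), each = 3))
#' aggregate_replicates(spots)
#' @export
aggregate_replicates <- function(spots, cv_threshold = 0.25) {
  need <- c("peptide_id", "condition_id", "assay_id", "replicate", "intensity")
  miss <- setdiff(need, names(spots))
  if (length(miss))
    stop("spots table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(spots$intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  key <- interaction(spots$peptide_id, spots$condition_id, drop = TRUE)
  rows <- lapply(split(spots, key), function(d) {
    by_assay <- split(d$intensity, d$assay_id)
    means <- vapply(by_assay, mean, numeric(1))
    grand <- mean(means)
    inter_sd <- if (length(means) > 1L) sd(means) else 0
    within_var <- vapply(by_assay, function(x)
      if (length(x) > 1L) stats::var(x) else 0, numeric(1))
    cv <- if (grand > 0) inter_sd / grand else NA_real_
    retained <- !is.na(cv) && cv < cv_threshold
    data.frame(peptide_id = d$peptide_id[1], condition_id = d$condition_id[1],
               n_assays = length(means), grand_mean = grand,
               intra_assay_sd = sqrt(mean(within_var)),
               inter_assay_sd = inter_sd, inter_assay_cv = cv,
               retained = retained,
               reason = if (is.na(cv)) "zero_mean"
                        else if (retained) "ok" else "high_cv")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$condition_id, out$peptide_id), , drop = FALSE]
}

#' Select the top-binding fraction of a library
#'
#' Returns the ids of the `floor(fraction * N)` retained peptides of
#' highest grand mean, where `N` counts all peptides in `aggs` (so a
#' 762-peptide library at 5% yields 38). Ties are broken by id in
#' lexicographic order so the selection is deterministic and invariant
#' to input row order.
#'
#' @param aggs Aggregated binding table from [aggregate_replicates()]
#'   (one condition).
#' @param fraction Fraction of the library to keep, in (0, 1\].
#' @return Character vector of peptide ids (highest mean first). An
#'   empty selection (`fraction * N < 1`) warns.
#' @export
select_top_fraction <- function(aggs, fraction = 0.05) {
  stopifnot(nrow(aggs) > 0, fraction > 0, fraction <= 1)
  if (length(unique(aggs$condition_id)) > 1L)
    stop("aggs spans multiple conditions; subset to one first", call. = FALSE)
  k <- floor(fraction * nrow(aggs))
  if (k < 1L) {
    warning("fraction * N < 1: empty selection")
    return(character(0))
  }
  pool <- aggs[aggs$retained, , drop = FALSE]
  pool <- pool[order(-pool$grand_mean, pool$peptide_id), , drop = FALSE]
  head(pool$peptide_id, k)
}

#' Percent selectivity under glycan competition
#'
#' Percent selectivity is the fraction of target binding retained in the
#' presence of a stated amount of competing glycan, x100:
#' `100 * competed_mean / uncompeted_mean`. Values above 100 are allowed
#' (competition can enhance signal). Peptides whose uncompeted signal is
#' at or below `background` are not evaluable — selectivity is only
#' meaningful for peptides binding above background.
#'
#' @param uncompeted,competed One-row slices of an aggregated binding
#'   table for the same peptide, without and with competitor.
#' @param competitor_fraction Competitor-to-target ratio the competed
#'   condition used (e.g. 0.10 for 10% competing glycan); recorded in
#'   the result.
#' @param background Intensity at or below which the uncompeted signal
#'   is considered not evaluable.
#' @return Data frame: `peptide_id`, `competitor_fraction`,
#'   `percent_selectivity` (NA when not evaluable), `evaluable`.
#' @export
percent_selectivity <- function(uncompeted, competed,
                                competitor_fraction = 0.10, background = 0) {
  stopifnot(nrow(uncompeted) == 1L, nrow(competed) == 1L)
  if (uncompeted$peptide_id != competed$peptide_id)
    stop("uncompeted and competed rows refer to different peptides",
         call. = FALSE)
  ok <- uncompeted$grand_mean > background
  data.frame(peptide_id = uncompeted$peptide_id,
             competitor_fraction = competitor_fraction,
             percent_selectivity = if (ok)
               100 * competed$grand_mean / uncompeted$grand_mean
             else NA_real_,
             evaluable = ok)
}

#' Selectivity table for all peptides of a competed condition
#'
#' Vectorised wrapper around [percent_selectivity()] joining an
#' uncompeted and a competed aggregated table on `peptide_id`.
#'
#' @inheritParams percent_selectivity
#' @return Data frame with one row per peptide present in both tables.
#' @export
selectivity_table <- function(uncompeted, competed,
                              competitor_fraction = 0.10, background = 0) {
  ids <- intersect(uncompeted$peptide_id, competed$peptide_id)
  out <- lapply(ids, function(id)
    percent_selectivity(uncompeted[uncompeted$peptide_id == id, , drop = FALSE],
                        competed[competed$peptide_id == id, , drop = FALSE],
                        competitor_fraction, background))
  do.call(rbind, out)
}

#' Correlate peptide binding between two screen conditions
#'
#' @param cond_a,cond_b Paired per-peptide means (same peptide order),
#'   length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `estimate`, `n`, `method`, `ok` (`FALSE` with
#'   `estimate = NA` when either vector has zero variance).
#' @export
condition_correlation <- function(cond_a, cond_b,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(cond_a) != length(cond_b))
    stop("condition vectors must be paired (equal length)", call. = FALSE)
  if (length(cond_a) < 3L)
    stop("need at least 3 paired peptides", call. = FALSE)
  if (sd(cond_a) == 0 || sd(cond_b) == 0)
    return(list(estimate = NA_real_, n = length(cond_a), method = method,
                ok = FALSE))
  list(estimate = cor(cond_a, cond_b, method = method),
       n = length(cond_a), method = method, ok = TRUE)
}

#' Mean charge and intensity per intensity decile
#'
#' Partitions peptides into 10 equal-count bins by intensity rank
#' (decile 1 = weakest binders) and summarises each bin; used to expose
#' library-level charge dependence of binding.
#'
#' @param aggs Aggregated binding table (one condition).
#' @param charges Named numeric vector of net charges covering every
#'   peptide in `aggs`.
#' @param n_bins Number of rank bins (default 10).
#' @return Data frame: `decile`, `n`, `intensity_min`, `intensity_max`,
#'   `mean_intensity`, `mean_charge`. With fewer peptides than bins the
#'   result has fewer rows and carries attribute `short = TRUE`.
#' @export
intensity_decile_profile <- function(aggs, charges, n_bins = 10L) {
  miss <- setdiff(aggs$peptide_id, names(charges))
  if (length(miss))
    stop("charges missing for peptide(s): ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  ord <- order(aggs$grand_mean, aggs$peptide_id)
  x <- aggs[ord, , drop = FALSE]
  n <- nrow(x)
  bins <- min(n_bins, n)
  # equal-count partition: bin sizes differ by at most 1
  sizes <- rep(n %/% bins, bins) + c(rep(1L, n %% bins),
                                     rep(0L, bins - n %% bins))
  idx <- rep(seq_len(bins), sizes)
  out <- do.call(rbind, lapply(seq_len(bins), function(b) {
    d <- x[idx == b, , drop = FALSE]
    data.frame(decile = b, n = nrow(d),
               intensity_min = min(d$grand_mean),
               intensity_max = max(d$grand_mean),
               mean_intensity = mean(d$grand_mean),
               mean_charge = mean(charges[d$peptide_id]))
  }))
  if (bins < n_bins) attr(out, "short") <- TRUE
  out
}

#' Monomer concentration mass-equivalent to a polymer solution
#'
#' Converts a polymer molar concentration into the monomer molar
#' concentration of equal mass: `polymer_conc * dp * polymer_residue_mass
#' / monomer_mass`. For colominic acid of average degree of
#' polymerization 100 (residue ~300 Da) versus free Neu5Ac (309.3 Da),
#' 10 uM polymer corresponds to ~970 uM monomer.
#'
#' @param polymer_conc Polymer concentration (uM).
#' @param dp Average degree of polymerization (residues per chain).
#' @param polymer_residue_mass Mass per polymerized residue (Da).
#' @param monomer_mass Mass of the free monomer (Da).
#' @return Monomer concentration in uM.
#' @examples
#' mass_equivalent_conc(10, 100, 300, 309.3)   # ~970
#' @export
mass_equivalent_conc <- function(polymer_conc, dp, polymer_residue_mass,
                                 monomer_mass) {
  stopifnot(polymer_conc > 0, dp > 0, polymer_residue_mass > 0,
            monomer_mass > 0)
  polymer_conc * dp * polymer_residue_mass / monomer_mass
}

#' Background-adjusted binding ranks
#'
#' Subtracts paired control intensities (flooring at zero) and assigns
#' descending ranks: rank 1 is the strongest binder; ties receive the
#' average rank. Used for cell-screen comparisons where background and
#' dynamic range differ between conditions.
#'
#' @param values Named or unnamed numeric intensities.
#' @param control Optional paired control (background) intensities.
#' @return Data frame: `peptide_id` (names of `values` or indices),
#'   `adjusted`, `rank`.
#' @export
rank_binding <- function(values, control = NULL) {
  if (!is.null(control) && length(control) != length(values))
    stop("control must be paired with values", call. = FALSE)
  adjusted <- if (is.null(control)) values else pmax(values - control, 0)
  ids <- if (is.null(names(values))) as.character(seq_along(values))
         else names(values)
  data.frame(peptide_id = ids, adjusted = unname(adjusted),
             rank = rank(-adjusted, ties.method = "average"))
}
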