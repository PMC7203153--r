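#' Ionisation model for peptide charge calculations
#'
#' Two modes are supported. `"integer"` is the coarse book-keeping used
#' for library-level charge analysis: Arg and Lys count +1, Asp and Glu
#' count -1, everything else (including His and the termini) 0,
#' regardless of pH. `"titration"` evaluates Henderson-Hasselbalch
#' fractional charges from a pKa table and is the basis of the
#' isoelectric-point calculation.
#'
#' The default pKa table matches the EMBOSS `iep` defaults (N-terminus
#' 8.6, C-terminus 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5,
#' Y 10.1). Termini are excluded by default: microarray peptides from
#' protein-derived arms are N-terminally acetylated and C-terminally
#' surface-attached, so only side chains titrate.
#'
#' @param mode `"integer"` or `"titration"`.
#' @param pka_table Named numeric vector of pKa values; names from
#'   `Nterm`, `Cterm`, `C`, `D`, `E`, `H`, `K`, `R`, `Y`. All values
#'   must lie in (0, 14).
#' @param include_termini Logical; add free alpha-amino and
#'   alpha-carboxyl groups in titration mode.
#' @return A list of class `"charge_model"`.
#' @export
charge_model <- function(mode = c("integer", "titration"),
                         pka_table = c(Nterm = 8.6, Cterm = 3.6, K = 10.8,
                                       R = 12.5, H = 6.5, D = 3.9, E = 4.1,
                                       C = 8.5, Y = 10.1),
                         include_termini = FALSE) {
  mode <- match.arg(mode)
  if (any(pka_table <= 0 | pka_table >= 14))
    stop("all pKa values must lie in (0, 14)", call. = FALSE)
  structure(list(mode = mode, pka_table = pka_table,
                 include_termini = isTRUE(include_termini)),
            class = "charge_model")
}

BASIC_GROUPS <- c("K", "R", "H", "Nterm")
ACIDIC_GROUPS <- c("D", "E", "C", "Y", "Cterm")

#' Net charge of a peptide at a given pH
#'
#' In integer mode the result is `#{R,K} - #{D,E}` whatever the pH; in
#' titration mode it is the sum of Henderson-Hasselbalch fractional
#' charges, `sum_basic 1/(1+10^(pH-pKa)) - sum_acidic 1/(1+10^(pKa-pH))`,
#' over the groups present in the model's pKa table (plus the termini if
#' `include_termini`).
#'
#' @param sequence Canonical amino-acid string.
#' @param pH pH value in \[0, 14\].
#' @param model A [charge_model()].
#' @return Net charge in elementary-charge units (integer-valued in
#'   integer mode).
#' @examples
#' net_charge("KGKGKGKGKGKGKGK")   # +8
#' @export
net_charge <- function(sequence, pH = 7.4, model = charge_model()) {
  assert_canonical(sequence)
  stopifnot(inherits(model, "charge_model"), pH >= 0, pH <= 14)
  chars <- seq_chars(sequence)
  if (model$mode == "integer")
    return(sum(chars %in% c("R", "K")) - sum(chars %in% c("D", "E")))
  groups <- table(chars)
  if (model$include_termini) {
    groups <- c(groups, Nterm = 1L, Cterm = 1L)
  }
  pk <- model$pka_table
  q <- 0
  for (g in intersect(names(groups), names(pk))) {
    n <- as.numeric(groups[[g]])
    if (g %in% BASIC_GROUPS) {
      q <- q + n / (1 + 10^(pH - pk[[g]]))
    } else {
      q <- q - n / (1 + 10^(pk[[g]] - pH))
    }
  }
  q
}

# TRUE when the sequence has at least one group that titrates under `model`
has_ionizable <- function(sequence, model) {
  if (model$include_termini) return(TRUE)
  any(seq_chars(sequence) %in% names(model$pka_table))
}

#' Isoelectric point by bisection on the titration charge curve
#'
#' The titration-mode net charge is strictly decreasing in pH for any
#' sequence with at least one ionizable group, so the pI is located by
#' bisection on pH in \[0, 14\] to a pH interval below 1e-7 (which
#' leaves `|net_charge| < tol` at the root). Degenerate
#' curves return sentinels rather than numbers: `">14"` when the charge
#' is still positive at pH 14 (e.g. a pure polylysine with acetylated
#' terminus), `"<0"` when already negative at pH 0, and `"undefined"`
#' when no group titrates at all.
#'
#' @param sequence Canonical amino-acid string.
#' @param model A [charge_model()] with `mode = "titration"` (the
#'   default integer model is promoted automatically).
#' @param tol Residual-charge tolerance checked at the located pI.
#' @return Numeric pH, or one of the character sentinels `">14"`,
#'   `"<0"`, `"undefined"`.
#' @examples
#' isoelectric_point("KGKGKGKGKGKGKGK")   # ">14"
#' @export
isoelectric_point <- function(sequence, model = charge_model("titration"),
                              tol = 1e-4) {
  stopifnot(inherits(model, "charge_model"))
  if (model$mode != "titration")
    model <- charge_model("titration", pka_table = model$pka_table,
                          include_termini = model$include_termini)
  assert_canonical(sequence)
  if (!has_ionizable(sequence, model)) return("undefined")
  f <- function(pH) net_charge(sequence, pH, model)
  lo <- 0; hi <- 14
  q_lo <- f(lo); q_hi <- f(hi)
  if (q_hi > 0) return(">14")
  if (q_lo < 0) return("<0")
  # bisect on the pH interval: the charge curve is nearly flat around the
  # pI of well-separated acid/base pairs, so a charge-only stopping rule
  # would leave the pH loose even when |charge| < tol
  while (hi - lo > 1e-7) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(f(mid)) >= tol)
    warning("charge at the located pI exceeds tol; curve may be degenerate")
  mid
}

#' Residue classification scheme
#'
#' The default partition is the one used for compositional analysis of
#' binder subsets: acidic = D,E; basic = R,K; polar = H,C,N,Q,S,T;
#' aromatic = Y,F,W; nonpolar = G,A,V,I,L,M,P. (Threonine, a standard
#' polar residue, completes the partition over all 20 canonical codes.)
#'
#' @param classes Named character vector mapping each residue to a class
#'   label; must cover every canonical residue used.
#' @return A list of class `"residue_class_scheme"`.
#' @export
residue_class_scheme <- function(classes = default_residue_classes()) {
  structure(list(classes = classes), class = "residue_class_scheme")
}

#' @rdname residue_class_scheme
#' @export
default_residue_classes <- function() {
  c(D = "acidic", E = "acidic",
    R = "basic", K = "basic",
    H = "polar", C = "polar", N = "polar", Q = "polar", S = "polar",
    T = "polar",
    Y = "aromatic", F = "aromatic", W = "aromatic",
    G = "nonpolar", A = "nonpolar", V = "nonpolar", I = "nonpolar",
    L = "nonpolar", M = "nonpolar", P = "nonpolar")
}

#' Residue-class composition of a peptide
#'
#' @param sequence Canonical amino-acid string.
#' @param scheme A [residue_class_scheme()].
#' @return Data frame with one row per class (in scheme order):
#'   `class`, `count`, `fraction`. Counts sum to the sequence length and
#'   fractions to 1.
#' @export
class_composition <- function(sequence, scheme = residue_class_scheme()) {
  assert_canonical(sequence)
  stopifnot(inherits(scheme, "residue_class_scheme"))
  chars <- seq_chars(sequence)
  missing <- setdiff(unique(chars), names(scheme$classes))
  if (length(missing))
    stop("residue(s) not classified by the scheme: ",
         paste(missing, collapse = ", "), call. = FALSE)
  labels <- unique(unname(scheme$classes))
  counts <- vapply(labels, function(cl)
    sum(chars %in% names(scheme$classes)[scheme$classes == cl]), integer(1))
  data.frame(class = labels, count = counts,
             fraction = counts / length(chars), row.names = NULL)
}

#' Per-peptide property table
#'
#' Convenience wrapper computing, for every record of a library, its
#' length, integer-mode net charge at a reference pH, isoelectric point
#' (sentinels kept as strings) and residue-class counts.
#'
#' @param lib Peptide library data frame.
#' @param pH Reference pH for the charge column (default 7.4).
#' @param model Charge model used for pI (titration mode enforced).
#' @param scheme Residue classification scheme.
#' @return Data frame: `id`, `length`, `net_charge`, `pI`, then one
#'   count column per class.
#' @export
peptide_properties <- function(lib, pH = 7.4,
                               model = charge_model("titration"),
                               scheme = residue_class_scheme()) {
  validate_library(lib)
  labels <- unique(unname(scheme$classes))
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    s <- lib$sequence[i]
    comp <- class_composition(s, scheme)
    out <- data.frame(id = lib$id[i], length = nchar(s),
                      net_charge = net_charge(s, pH, charge_model("integer")),
                      pI = as.character(isoelectric_point(s, model)))
    for (j in seq_len(nrow(comp))) out[[comp$class[j]]] <- comp$count[j]
    out
  })
  do.call(rbind, rows)
}
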