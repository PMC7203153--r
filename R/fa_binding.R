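#' Blank-correct polarized intensities
#'
#' At high polymer concentrations solution viscosity scatters light
#' differently in the parallel and perpendicular planes, so matched
#' ligand-only (blank) intensities are subtracted channel-wise before
#' anisotropy is computed, flooring at zero. A point whose corrected
#' total `I_par + 2 I_perp` is zero carries no signal and is marked
#' invalid.
#'
#' @param points Data frame with columns `I_par`, `I_perp`, `blank_par`,
#'   `blank_perp` (all non-negative, blanks measured at the same ligand
#'   concentration).
#' @return The input with corrected `I_par`, `I_perp` and a logical
#'   `valid` column.
#' @export
blank_correct <- function(points) {
  need <- c("I_par", "I_perp", "blank_par", "blank_perp")
  miss <- setdiff(need, names(points))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(points$I_par < 0 | points$I_perp < 0 |
          points$blank_par < 0 | points$blank_perp < 0))
    stop("intensities must be non-negative", call. = FALSE)
  out <- points
  out$I_par <- pmax(points$I_par - points$blank_par, 0)
  out$I_perp <- pmax(points$I_perp - points$blank_perp, 0)
  out$valid <- (out$I_par + 2 * out$I_perp) > 0
  out
}

#' Fluorescence anisotropy from polarized intensities
#'
#' `r = (I_par - g I_perp) / (I_par + 2 g I_perp)`; the G factor
#' corrects instrument polarization bias (default 1). The value lies in
#' \[-0.5, 1\]; a zero denominator yields `NA`.
#'
#' @param I_par,I_perp Corrected polarized intensities.
#' @param g_factor Instrument G factor.
#' @return Numeric anisotropy vector (`NA` where undefined).
#' @examples
#' compute_anisotropy(2, 1)   # 0.25
#' @export
compute_anisotropy <- function(I_par, I_perp, g_factor = 1) {
  den <- I_par + 2 * g_factor * I_perp
  r <- (I_par - g_factor * I_perp) / den
  r[den <= 0] <- NA_real_
  r
}

#' Construct an anisotropy titration curve
#'
#' @param peptide_id Peptide label.
#' @param conc Ligand (polymer) concentrations, uM.
#' @param r Anisotropy values (each in \[-0.5, 1\] or `NA` for invalid
#'   points).
#' @param transformed Logical; `TRUE` after [baseline_transform()].
#' @return List of class `"anisotropy_curve"` with elements
#'   `peptide_id`, `conc`, `r`, `transformed`.
#' @export
anisotropy_curve <- function(peptide_id, conc, r, transformed = FALSE) {
  stopifnot(length(conc) == length(r), all(conc >= 0))
  finite <- r[!is.na(r)]
  if (any(finite < -0.5 - 1e-9 | finite > 1 + 1e-9))
    stop("anisotropy values must lie in [-0.5, 1]", call. = FALSE)
  structure(list(peptide_id = peptide_id, conc = as.numeric(conc),
                 r = as.numeric(r), transformed = isTRUE(transformed)),
            class = "anisotropy_curve")
}

#' @export
print.anisotropy_curve <- function(x, ...) {
  cat("Anisotropy titration for", x$peptide_id, "-", length(x$conc),
      "points,", sum(!is.na(x$r)), "valid",
      if (x$transformed) "(baseline-transformed)" else "", "\n")
  invisible(x)
}

#' Baseline-transform an anisotropy curve
#'
#' Subtracts the minimum anisotropy of the curve so the free-peptide
#' baseline sits at zero; the shape (all pairwise differences) is
#' unchanged and the operation is idempotent. With a free baseline in
#' the binding model the fitted K_D is unaffected; the transform exists
#' to make curves comparable on one plot.
#'
#' @param curve An [anisotropy_curve()].
#' @return The transformed curve (`transformed = TRUE`).
#' @export
baseline_transform <- function(curve) {
  stopifnot(inherits(curve, "anisotropy_curve"))
  if (all(is.na(curve$r)))
    stop("curve has no valid points", call. = FALSE)
  curve$r <- curve$r - min(curve$r, na.rm = TRUE)
  curve$transformed <- TRUE
  curve
}

# 4PL response: y0 at c = 0, y0 + bmax at saturation, midpoint kd, slope h
fourpl_response <- function(conc, y0, bmax, kd, h) {
  y <- y0 + bmax / (1 + (kd / pmax(conc, .Machine$double.xmin))^h)
  y[conc == 0] <- y0
  y
}

#' Fit the four-parameter logistic binding model
#'
#' Fits `y(c) = y0 + B_max / (1 + (K_D / c)^h)` (so `y(0) = y0` and the
#' half-saturation concentration is `K_D`) to an anisotropy titration by
#' bounded Levenberg-Marquardt least squares, with multi-start
#' initialization over geometric quartiles of the concentration range to
#' avoid local minima near the polymer solubility limit. Standard errors
#' are asymptotic (from the parameter covariance at the optimum).
#'
#' A fit is flagged unreliable when the standard error of K_D exceeds
#' K_D or that of B_max exceeds B_max (strict inequalities; a fit with
#' `se == value` is kept).
#'
#' @param curve An [anisotropy_curve()]. Fewer than 5 valid points, or
#'   positive concentrations spanning under two decades, trigger an
#'   under-determination warning.
#' @param fix_hill If `TRUE`, constrain the slope to `h = 1` (1:1
#'   binding).
#' @param n_starts Number of K_D starting values (geometric quantiles of
#'   the positive concentration range).
#' @return Object of class `"fourpl_fit"`: `peptide_id`, `y0`, `bmax`,
#'   `kd_uM`, `kd_mM`, `hill`, `se_kd_uM`, `se_kd_mM`, `se_bmax`,
#'   `r_squared`, `reliable`, `binding_potential` (B_max per mM K_D),
#'   `converged`, `message`. Non-convergent data return a flagged fit
#'   (`converged = FALSE`, `reliable = FALSE`) rather than an error.
#' @examples
#' conc <- c(0, 10^seq(0, log10(1500), length.out = 12))
#' r <- 0.01 + 0.05 / (1 + 521 / pmax(conc, 1e-12))
#' r[conc == 0] <- 0.01
#' fit_4pl(anisotropy_curve("I-P24", conc, r))
#' @export
fit_4pl <- function(curve, fix_hill = FALSE, n_starts = 4L) {
  stopifnot(inherits(curve, "anisotropy_curve"))
  ok <- !is.na(curve$r)
  conc <- curve$conc[ok]; y <- curve$r[ok]
  pos <- conc[conc > 0]
  if (sum(ok) < 5L || length(pos) < 2L ||
      log10(max(pos) / min(pos)) < 2)
    warning("titration is under-determined: <5 valid points or <2 decades ",
            "of concentration", call. = FALSE)
  failed <- function(msg) {
    structure(list(peptide_id = curve$peptide_id, y0 = NA_real_,
                   bmax = NA_real_, kd_uM = NA_real_, kd_mM = NA_real_,
                   hill = NA_real_, se_kd_uM = NA_real_, se_kd_mM = NA_real_,
                   se_bmax = NA_real_, r_squared = NA_real_,
                   reliable = FALSE, binding_potential = NA_real_,
                   converged = FALSE, message = msg),
              class = "fourpl_fit")
  }
  if (length(pos) < 2L) return(failed("not enough positive concentrations"))
  y0_start <- min(y); bmax_start <- max(diff(range(y)), 1e-4)
  kd_starts <- exp(seq(log(min(pos)), log(max(pos)),
                       length.out = max(2L, n_starts)))
  span <- diff(range(y))
  lower <- c(y0 = -0.5, bmax = 0, kd = min(pos) * 1e-3)
  upper <- c(y0 = 1, bmax = 1.5, kd = max(pos) * 1e3)
  if (!fix_hill) {
    lower <- c(lower, h = 0.1); upper <- c(upper, h = 10)
  }
  best <- NULL
  for (kd0 in kd_starts) {
    start <- list(y0 = y0_start, bmax = bmax_start, kd = kd0)
    form <- if (fix_hill)
      y ~ fourpl_response(conc, y0, bmax, kd, 1)
    else {
      start$h <- 1
      y ~ fourpl_response(conc, y0, bmax, kd, h)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) {
    # typically an all-flat curve: every residual is absorbed by y0 and
    # the Jacobian in (bmax, kd, h) is singular; report the degenerate
    # constant fit rather than erroring
    out <- failed("no start converged; degenerate constant fit")
    out$y0 <- mean(y)
    out$bmax <- 0
    out$binding_potential <- 0
    sst <- sum((y - mean(y))^2)
    out$r_squared <- if (sst > 0) 0 else NA_real_
    return(out)
  }
  fit <- best$fit
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, length(est)), names(est)))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - best$ssr / sst else NA_real_
  kd <- unname(est["kd"]); bmax <- unname(est["bmax"])
  se_kd <- unname(se["kd"]); se_bmax <- unname(se["bmax"])
  out <- structure(list(
    peptide_id = curve$peptide_id,
    y0 = unname(est["y0"]), bmax = bmax,
    kd_uM = kd, kd_mM = kd / 1000,
    hill = if (fix_hill) 1 else unname(est["h"]),
    se_kd_uM = se_kd, se_kd_mM = se_kd / 1000, se_bmax = se_bmax,
    r_squared = r2, reliable = NA, binding_potential = NA_real_,
    converged = TRUE, message = "ok"), class = "fourpl_fit")
  out$reliable <- flag_reliability(out)
  out$binding_potential <- binding_potential(out)
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit for", x$peptide_id, "- did not converge (", x$message, ")\n")
    return(invisible(x))
  }
  cat(sprintf(
    "4PL fit for %s: K_D = %.3f mM (SE %.3f), B_max = %.4f (SE %.4f),\n  h = %.2f, R^2 = %.4f, B_max/K_D = %.4f per mM [%s]\n",
    x$peptide_id, x$kd_mM, x$se_kd_mM, x$bmax, x$se_bmax, x$hill,
    x$r_squared, x$binding_potential,
    if (isTRUE(x$reliable)) "reliable" else "unreliable"))
  invisible(x)
}

#' Binding potential of a fit
#'
#' `B_max / K_D` in anisotropy units per mM: for `h = 1` this equals the
#' initial slope of the binding curve (per mM of ligand), so it ranks
#' peptides by response per unit of target at low concentration.
#'
#' @param fit A [fit_4pl()] result (converged).
#' @return Numeric ratio; `NA` for non-converged fits.
#' @export
binding_potential <- function(fit) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!fit$converged) return(NA_real_)
  fit$bmax / fit$kd_mM
}

#' Reliability flag for a 4PL fit
#'
#' A fit is unreliable when the asymptotic standard error of K_D
#' exceeds K_D or that of B_max exceeds B_max (strictly); undefined
#' standard errors also flag the fit.
#'
#' @param fit A [fit_4pl()] result.
#' @return Logical.
#' @export
flag_reliability <- function(fit) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!fit$converged) return(FALSE)
  if (is.na(fit$se_kd_uM) || is.na(fit$se_bmax)) return(FALSE)
  !(fit$se_kd_uM > fit$kd_uM || fit$se_bmax > fit$bmax)
}

#' Process a raw titration table into anisotropy curves
#'
#' Blank-corrects polarized intensities, computes anisotropies and
#' baseline-transforms each peptide's curve.
#'
#' @param titrations Data frame with columns `peptide_id`, `conc_uM`,
#'   `I_par`, `I_perp`, `blank_par`, `blank_perp` (and optionally
#'   `total_intensity`). Replicate rows at the same concentration are
#'   kept as separate points.
#' @param g_factor Instrument G factor.
#' @param transform Baseline-transform the curves (default `TRUE`).
#' @return Named list of [anisotropy_curve()] objects, one per peptide.
#' @export
process_titration <- function(titrations, g_factor = 1, transform = TRUE) {
  need <- c("peptide_id", "conc_uM", "I_par", "I_perp", "blank_par",
            "blank_perp")
  miss <- setdiff(need, names(titrations))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(split(titrations, titrations$peptide_id), function(d) {
    d <- d[order(d$conc_uM), , drop = FALSE]
    cc <- blank_correct(d)
    r <- compute_anisotropy(cc$I_par, cc$I_perp, g_factor)
    curve <- anisotropy_curve(d$peptide_id[1], d$conc_uM, r)
    if (transform) baseline_transform(curve) else curve
  })
  out[order(names(out))]
}

#' Fit report across peptides
#'
#' Runs [fit_4pl()] on each curve and assembles a per-peptide table
#' mirroring a binding-constant summary: K_D (mM), its SE, R^2, B_max,
#' its SE, the hill slope, the reliability flag and B_max/K_D.
#'
#' @param curves Named list of anisotropy curves
#'   (see [process_titration()]).
#' @param ... Passed to [fit_4pl()].
#' @return Data frame with one row per peptide.
#' @export
fa_fit_table <- function(curves, ...) {
  rows <- lapply(curves, function(cv) {
    f <- fit_4pl(cv, ...)
    data.frame(peptide_id = f$peptide_id, kd_mM = f$kd_mM,
               se_kd_mM = f$se_kd_mM, r_squared = f$r_squared,
               bmax = f$bmax, se_bmax = f$se_bmax, hill = f$hill,
               reliable = isTRUE(f$reliable),
               binding_potential = f$binding_potential,
               converged = f$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
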