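#' Specification for a synthetic microarray screen
#'
#' Defines the generative model the screen-analysis stage assumes:
#' per-peptide mean log-intensity driven by net charge through a
#' logistic dose term plus an optional per-peptide effect, independent
#' multiplicative assay scale factors, lognormal replicate noise, and
#' competitor conditions that scale each peptide's mean by a per-peptide
#' retention fraction.
#'
#' @param peptides Peptide library data frame.
#' @param charge_effect List with `baseline`, `amplitude`, `slope`,
#'   `midpoint`: mean log-intensity is
#'   `baseline + amplitude / (1 + exp(-slope * (charge - midpoint)))`.
#' @param peptide_effects Optional named numeric vector of additive
#'   log-intensity effects (e.g. planted strong binders).
#' @param selective_set Named numeric vector: retention fraction in
#'   \[0, 1\] under competitor for designated selective peptides.
#' @param default_retention Retention fraction for all other peptides.
#' @param competitor_fractions Competitor-to-target ratios to simulate
#'   as competed conditions (a condition `competed_<f>` per entry);
#'   the uncompeted condition is always generated.
#' @param n_assays,n_replicates Independent screens and intra-assay
#'   replicates (defaults 3 and 3, the screen standard).
#' @param noise_cv Intra-assay lognormal coefficient of variation.
#' @param assay_scale_sd SD of the per-assay log scale factor
#'   (inter-assay variability).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return List of class `"screen_sim_spec"`.
#' @export
screen_sim_spec <- function(peptides,
                            charge_effect = list(baseline = log(100),
                                                 amplitude = 1.0,
                                                 slope = 1.0, midpoint = 2),
                            peptide_effects = NULL,
                            selective_set = NULL,
                            default_retention = 0.30,
                            competitor_fractions = 0.10,
                            n_assays = 3L, n_replicates = 3L,
                            noise_cv = 0.05, assay_scale_sd = 0.05,
                            seed = 1L) {
  validate_library(peptides)
  stopifnot(noise_cv >= 0, assay_scale_sd >= 0, n_assays >= 1,
            n_replicates >= 1, default_retention >= 0,
            default_retention <= 1)
  if (!is.null(selective_set)) {
    stopifnot(!is.null(names(selective_set)),
              all(selective_set >= 0 & selective_set <= 1),
              all(names(selective_set) %in% peptides$id))
  }
  structure(list(peptides = peptides, charge_effect = charge_effect,
                 peptide_effects = peptide_effects,
                 selective_set = selective_set,
                 default_retention = default_retention,
                 competitor_fractions = competitor_fractions,
                 n_assays = as.integer(n_assays),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, assay_scale_sd = assay_scale_sd,
                 seed = as.integer(seed)),
            class = "screen_sim_spec")
}

#' Generate a synthetic microarray screen
#'
#' Spot intensity is
#' `exp(assay_effect + charge_mean + peptide_effect) * lognormal_noise`;
#' competed conditions scale each peptide's mean by its retention
#' fraction before noise. Assay effects are shared across conditions
#' within an assay, so at zero noise the percent selectivity of a
#' peptide equals its retention fraction x100 exactly.
#'
#' @param spec A [screen_sim_spec()].
#' @return List: `spots` (columns `peptide_id`, `condition_id`,
#'   `assay_id`, `replicate`, `intensity`) and `truth` (per-peptide
#'   `charge`, `mean_log`, `retention`).
#' @export
gen_microarray <- function(spec) {
  stopifnot(inherits(spec, "screen_sim_spec"))
  lib <- spec$peptides
  ce <- spec$charge_effect
  charge <- vapply(lib$sequence, net_charge, numeric(1),
                   model = charge_model("integer"))
  names(charge) <- lib$id
  mean_log <- ce$baseline +
    ce$amplitude / (1 + exp(-ce$slope * (charge - ce$midpoint)))
  if (!is.null(spec$peptide_effects)) {
    idx <- match(names(spec$peptide_effects), lib$id)
    if (anyNA(idx)) stop("peptide_effects names must be library ids",
                         call. = FALSE)
    mean_log[idx] <- mean_log[idx] + unname(spec$peptide_effects)
  }
  retention <- rep(spec$default_retention, nrow(lib))
  names(retention) <- lib$id
  if (!is.null(spec$selective_set))
    retention[names(spec$selective_set)] <- unname(spec$selective_set)
  spots <- local({
    set.seed(spec$seed)
    assay_effect <- rnorm(spec$n_assays, 0, spec$assay_scale_sd)
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    cond_ids <- c("uncompeted",
                  paste0("competed_", spec$competitor_fractions))
    rows <- vector("list", length(cond_ids))
    for (ci in seq_along(cond_ids)) {
      scale_log <- if (ci == 1L) rep(0, nrow(lib)) else log(retention)
      grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                          assay_id = seq_len(spec$n_assays),
                          pep = seq_len(nrow(lib)))
      mu <- assay_effect[grid$assay_id] + mean_log[grid$pep] +
        scale_log[grid$pep]
      noise <- if (spec$noise_cv > 0)
        rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, nrow(grid))
      rows[[ci]] <- data.frame(peptide_id = lib$id[grid$pep],
                               condition_id = cond_ids[ci],
                               assay_id = grid$assay_id,
                               replicate = grid$replicate,
                               intensity = exp(mu) * noise)
    }
    do.call(rbind, rows)
  })
  list(spots = spots,
       truth = data.frame(peptide_id = lib$id, charge = unname(charge),
                          mean_log = unname(mean_log),
                          retention = unname(retention)))
}

#' Specification for synthetic anisotropy titrations
#'
#' @param truth Data frame with columns `peptide_id`, `y0`, `bmax`,
#'   `kd_uM`, `hill`: the four-parameter logistic ground truth per
#'   peptide. Implied anisotropies must lie in \[-0.5, 1\].
#' @param concentrations Ligand concentrations in uM; default 0 plus 12
#'   log-spaced points over 1-1500 uM (the practical polymer solubility
#'   window).
#' @param n_replicates Independent measurements per concentration
#'   (default 3, matching the assay practice of screening each sample
#'   at least in triplicate within a titration).
#' @param noise_sd Anisotropy noise as a fraction of `bmax`: Gaussian
#'   noise is added to each polarized channel with
#'   `sd = noise_sd * bmax * T / sqrt(2)`, which perturbs the recovered
#'   anisotropy by approximately `noise_sd * bmax` (first order).
#' @param total_intensity Total fluorescence `T = I_par + 2 I_perp`
#'   (conserved by construction, matching the total-intensity control).
#' @param viscosity_artifact Add concentration-dependent, channel-
#'   asymmetric blank intensities emulating light scattering at high
#'   polymer concentration; blank correction removes it exactly.
#' @param seed Integer seed.
#' @return List of class `"titration_sim_spec"`.
#' @export
titration_sim_spec <- function(truth,
                               concentrations = c(0, 10^seq(0, log10(1500),
                                                            length.out = 12)),
                               n_replicates = 3L,
                               noise_sd = 0.03, total_intensity = 3,
                               viscosity_artifact = FALSE, seed = 1L) {
  need <- c("peptide_id", "y0", "bmax", "kd_uM", "hill")
  miss <- setdiff(need, names(truth))
  if (length(miss))
    stop("truth is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot(all(concentrations >= 0), all(truth$kd_uM > 0),
            noise_sd >= 0, total_intensity > 0, n_replicates >= 1)
  rmax <- truth$y0 + truth$bmax
  if (any(truth$y0 < -0.5 | rmax > 1))
    stop("truth implies anisotropies outside [-0.5, 1]", call. = FALSE)
  structure(list(truth = truth, concentrations = sort(concentrations),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, total_intensity = total_intensity,
                 viscosity_artifact = isTRUE(viscosity_artifact),
                 seed = as.integer(seed)),
            class = "titration_sim_spec")
}

#' Generate synthetic anisotropy titrations
#'
#' Channels are emitted as `I_par = T (1 + 2 r) / 3 + blank_par` and
#' `I_perp = T (1 - r) / 3 + blank_perp`, so blank correction followed
#' by the anisotropy formula recovers the model anisotropy exactly at
#' zero noise, and the corrected total intensity is conserved at `T`.
#'
#' @param spec A [titration_sim_spec()].
#' @return List: `titrations` (columns `peptide_id`, `conc_uM`, `I_par`,
#'   `I_perp`, `blank_par`, `blank_perp`, `total_intensity`) and
#'   `truth` (the spec's truth table).
#' @export
gen_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_sim_spec"))
  conc <- rep(spec$concentrations, each = spec$n_replicates)
  repl <- rep(seq_len(spec$n_replicates), times = length(spec$concentrations))
  Tt <- spec$total_intensity
  cmax <- max(conc, 1)
  blank_par <- if (spec$viscosity_artifact)
    0.08 * Tt * (conc / cmax)^2 else rep(0, length(conc))
  blank_perp <- if (spec$viscosity_artifact)
    0.03 * Tt * (conc / cmax)^2 else rep(0, length(conc))
  out <- local({
    set.seed(spec$seed)
    rows <- lapply(seq_len(nrow(spec$truth)), function(i) {
      tr <- spec$truth[i, ]
      r <- fourpl_response(conc, tr$y0, tr$bmax, tr$kd_uM, tr$hill)
      ip <- Tt * (1 + 2 * r) / 3
      iq <- Tt * (1 - r) / 3
      if (spec$noise_sd > 0) {
        sd_ch <- spec$noise_sd * tr$bmax * Tt / sqrt(2)
        ip <- ip + rnorm(length(conc), 0, sd_ch)
        iq <- iq + rnorm(length(conc), 0, sd_ch)
      }
      data.frame(peptide_id = tr$peptide_id, conc_uM = conc,
                 replicate = repl,
                 I_par = pmax(ip + blank_par, 0),
                 I_perp = pmax(iq + blank_perp, 0),
                 blank_par = blank_par, blank_perp = blank_perp,
                 total_intensity = Tt)
    })
    do.call(rbind, rows)
  })
  list(titrations = out, truth = spec$truth)
}

#' Generate a scripted multi-frame coordinate set
#'
#' Places `n_res_a` residues of group a on a line and `n_res_b`
#' residues of group b on a parallel line 8 Angstrom away (so no
#' unscripted pair is ever within 6 Angstrom), then, for every scripted
#' `(frame, i, j)` event, moves residue `j` of group b to 2 Angstrom
#' from residue `i` of group a in that frame. Each residue carries
#' `atoms_per_residue` atoms with small fixed offsets; optional Gaussian
#' jitter must be small enough not to break the script.
#'
#' @param n_frames Number of frames.
#' @param n_res_a,n_res_b Residues in each group.
#' @param contact_script Data frame with columns `frame`, `res_a`,
#'   `res_b` (1-based indices); a group-b residue scripted against two
#'   different group-a residues in the same frame is infeasible and is
#'   an error.
#' @param jitter_sd Per-coordinate Gaussian jitter in Angstrom
#'   (must be <= 0.3 to preserve the script's near/far separation).
#' @param atoms_per_residue Atoms per residue (>= 1).
#' @param seed Integer seed.
#' @return A [frame_set()].
#' @export
gen_frames <- function(n_frames, n_res_a, n_res_b,
                       contact_script = NULL, jitter_sd = 0.05,
                       atoms_per_residue = 3L, seed = 1L) {
  stopifnot(n_frames >= 1, n_res_a >= 1, n_res_b >= 1, jitter_sd >= 0)
  if (jitter_sd > 0.3)
    stop("jitter_sd > 0.3 A would not preserve the contact script",
         call. = FALSE)
  if (!is.null(contact_script)) {
    need <- c("frame", "res_a", "res_b")
    stopifnot(all(need %in% names(contact_script)))
    if (any(contact_script$frame < 1 | contact_script$frame > n_frames |
            contact_script$res_a < 1 | contact_script$res_a > n_res_a |
            contact_script$res_b < 1 | contact_script$res_b > n_res_b))
      stop("contact script references out-of-range frames or residues",
           call. = FALSE)
    key <- paste(contact_script$frame, contact_script$res_b)
    dup <- duplicated(key) &
      !duplicated(paste(key, contact_script$res_a))
    if (any(dup))
      stop("infeasible script: a group-b residue cannot contact two ",
           "different group-a residues in one frame", call. = FALSE)
  }
  offsets <- cbind(seq(0, by = 0.1, length.out = atoms_per_residue), 0, 0)
  res_atoms <- function(center)
    sweep(offsets, 2, center, "+")
  frames <- local({
    set.seed(as.integer(seed))
    lapply(seq_len(n_frames), function(f) {
      a <- lapply(seq_len(n_res_a), function(i)
        res_atoms(c(10 * i, 0, 0)))
      b <- lapply(seq_len(n_res_b), function(j)
        res_atoms(c(10 * j, 8, 0)))
      if (!is.null(contact_script)) {
        ev <- contact_script[contact_script$frame == f, , drop = FALSE]
        for (k in seq_len(nrow(ev)))
          b[[ev$res_b[k]]] <- res_atoms(c(10 * ev$res_a[k], 2, 0))
      }
      if (jitter_sd > 0) {
        a <- lapply(a, function(m)
          m + matrix(rnorm(length(m), 0, jitter_sd), nrow(m)))
        b <- lapply(b, function(m)
          m + matrix(rnorm(length(m), 0, jitter_sd), nrow(m)))
      }
      list(a = a, b = b)
    })
  })
  frame_set(frames)
}

#' Generate a synthetic cell-binding screen
#'
#' Emulates microarray screening of tiled peptides against two cell
#' numbers: peptides whose tile overlaps a designated parent-protein
#' region (e.g. a binding loop) receive an elevated mean in both
#' conditions; a control vector (no cells) carries background only.
#'
#' @param peptides Tiled peptide library (needs `parent_start`; the
#'   tile covers `parent_start .. parent_start + nchar(sequence) - 1`).
#' @param enriched_regions List of 2-vectors `c(start, end)` in parent
#'   residue numbering.
#' @param effect_size Mean intensity added to region-overlapping
#'   peptides (condition 1 scale).
#' @param background Mean background intensity.
#' @param noise_sd Gaussian noise SD (condition 1 scale).
#' @param scale_2 Multiplicative scale of the second condition (e.g.
#'   2.5x the cells).
#' @param seed Integer seed.
#' @return List: `cells_1`, `cells_2` (named intensity vectors),
#'   `control` (named background vector), `truth` (logical named vector
#'   of region membership).
#' @export
gen_cell_screen <- function(peptides, enriched_regions, effect_size = 50,
                            background = 20, noise_sd = 2, scale_2 = 2.5,
                            seed = 1L) {
  validate_library(peptides)
  if (any(is.na(peptides$parent_start)))
    stop("cell-screen generator needs tiled peptides with parent_start",
         call. = FALSE)
  starts <- peptides$parent_start
  ends <- starts + nchar(peptides$sequence) - 1L
  in_region <- rep(FALSE, nrow(peptides))
  for (rg in enriched_regions) {
    stopifnot(length(rg) == 2L, rg[1] <= rg[2])
    in_region <- in_region | (starts <= rg[2] & ends >= rg[1])
  }
  mu <- background + effect_size * in_region
  out <- local({
    set.seed(as.integer(seed))
    n <- nrow(peptides)
    list(cells_1 = pmax(mu + rnorm(n, 0, noise_sd), 0),
         cells_2 = pmax(scale_2 * mu + rnorm(n, 0, scale_2 * noise_sd), 0),
         control = pmax(background * 0.25 + rnorm(n, 0, noise_sd / 2), 0))
  })
  out <- lapply(out, function(v) setNames(v, peptides$id))
  c(out, list(truth = setNames(in_region, peptides$id)))
}
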