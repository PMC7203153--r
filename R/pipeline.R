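#' Pipeline configuration
#'
#' Bundles every tunable threshold of the end-to-end demo workflow with
#' its documented default. Configurations round-trip through YAML with
#' a versioned schema; unknown keys in a config file are an error
#' (fail fast rather than silently ignoring a typo).
#'
#' @param cv_threshold Inter-assay CV retention cut (default 0.25).
#' @param top_fraction Top-binder fraction (default 0.05).
#' @param background_fraction,weak_fraction Intensity-range fractions of
#'   the affinity pre-filter (defaults 0.20 and 0.30).
#' @param selectivity_cut Percent-selectivity threshold (default 65).
#' @param competitor_fraction Competitor-to-target ratio of the competed
#'   condition (default 0.10).
#' @param fix_hill Constrain the 4PL slope to 1 in anisotropy fits.
#' @param g_factor Instrument G factor for anisotropy.
#' @param contact_cutoff Contact distance in Angstrom (default 3.0).
#' @param noise_cv,assay_scale_sd Synthetic-screen noise parameters.
#' @param seed Integer master seed for the demo.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cv_threshold = 0.25, top_fraction = 0.05,
                            background_fraction = 0.20, weak_fraction = 0.30,
                            selectivity_cut = 65, competitor_fraction = 0.10,
                            fix_hill = FALSE, g_factor = 1,
                            contact_cutoff = 3.0, noise_cv = 0.05,
                            assay_scale_sd = 0.05, seed = 1L) {
  stopifnot(cv_threshold > 0, top_fraction > 0, top_fraction <= 1,
            background_fraction >= 0, background_fraction <= 1,
            weak_fraction >= background_fraction, weak_fraction <= 1,
            selectivity_cut >= 0, competitor_fraction >= 0,
            g_factor > 0, contact_cutoff > 0, noise_cv >= 0,
            assay_scale_sd >= 0)
  structure(list(schema = "psapep-config/1",
                 cv_threshold = cv_threshold, top_fraction = top_fraction,
                 background_fraction = background_fraction,
                 weak_fraction = weak_fraction,
                 selectivity_cut = selectivity_cut,
                 competitor_fraction = competitor_fraction,
                 fix_hill = isTRUE(fix_hill), g_factor = g_factor,
                 contact_cutoff = contact_cutoff, noise_cv = noise_cv,
                 assay_scale_sd = assay_scale_sd, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!identical(vals$schema, "psapep-config/1"))
    stop("unsupported config schema: ", vals$schema, call. = FALSE)
  vals$schema <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

# deterministic sub-seed derivation from the master seed (kept < 2^31)
sub_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 1000 + k) %% 2147483647)

# random canonical sequence of given length
random_sequence <- function(length, seed) {
  set.seed(sub_seed(seed, 900L + length %% 97L))
  paste(sample(AA_CANONICAL, length, replace = TRUE), collapse = "")
}

#' Build the demonstration peptide library
#'
#' Assembles a 762-peptide synthetic library with the four arms of the
#' discovery campaign: 329 tiles of a 671-residue synthetic parent
#' lectin (15-mers stepping by 2), 172 modified peptides (86 point
#' mutants to Lys plus 86 scrambles of tiles), 38 de novo peptides (the
#' Lys/Gly repeat series plus random 15-mers) and 223 external random
#' sequences. The parent protein is synthetic — generated from the
#' seed — so the library reproduces the arm arithmetic and length
#' structure of a real campaign without reproducing any real sequences.
#'
#' @param seed Integer seed.
#' @param parent_length Parent protein length (default 671, which
#'   yields 329 tiles at window 15, step 2).
#' @return List: `library` (762-row peptide data frame), `arms` (named
#'   arm sizes), `parent_seq`.
#' @export
build_demo_library <- function(seed = 1L, parent_length = 671L) {
  parent <- random_sequence(parent_length, seed)
  tiles <- tile_sequence(parent, tiling_spec(15L, 2L), parent_id = "parent",
                         id_prefix = "I", acetylated = TRUE)
  # modified arm: Lys point mutants of tiles 1-86, scrambles of 87-172
  mutants <- lapply(1:86, function(k) {
    tile <- tiles[k, ]
    pos <- which(seq_chars(tile$sequence) != "K")[1]
    point_mutate(tile, pos, "K", id = sprintf("M-P%d", k))
  })
  scrambles <- lapply(87:172, function(k)
    scramble_peptide(tiles[k, ], seed = sub_seed(seed, k),
                     id = sprintf("M-P%d", k)))
  denovo <- c(
    list(make_repeat_peptide("KG", 15, id = "D-P1"),
         make_repeat_peptide("KGGG", 15, id = "D-P2"),
         make_repeat_peptide("KGGG", 15, phase = 2, id = "D-P3")),
    lapply(4:38, function(k)
      peptide_record(sprintf("D-P%d", k),
                     random_sequence(15L, sub_seed(seed, 200L + k)),
                     origin = "de_novo")))
  external <- lapply(1:223, function(k)
    peptide_record(sprintf("X-P%d", k),
                   random_sequence(15L, sub_seed(seed, 400L + k)),
                   origin = "external"))
  lib <- do.call(rbind, c(list(tiles), mutants, scrambles, denovo, external))
  rownames(lib) <- NULL
  validate_library(lib)
  list(library = lib,
       arms = c(tiling = nrow(tiles), modified = 172L, de_novo = 38L,
                external = 223L),
       parent_seq = parent)
}

#' Run the end-to-end demonstration workflow
#'
#' Wires every stage of the pipeline on synthetic data with known
#' ground truth: library design, physicochemistry, microarray
#' simulation and aggregation, top-binder selection, competitive
#' selectivity, residue enrichment, anisotropy titration fitting,
#' contact mapping, and cell-screen rank analysis. A set of 41 strong
#' binders (the highest-charge peptides) is planted with elevated
#' intensity and high competitor retention; the first 38 of them form
#' the designated top-binder set.
#'
#' All tables are written to `out_dir` as TSV/CSV plus a YAML summary;
#' figures are written as PNG when `figures = TRUE`. Every number in
#' the summary comes from a stage output table. The run is
#' deterministic for a fixed `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param figures Emit PNG figures (default `TRUE`).
#' @return Invisibly, a list with all stage outputs: `library`, `arms`,
#'   `properties`, `aggregated` (both conditions), `top_set`,
#'   `planted_top`, `selectivity`, `selective_subset`,
#'   `planted_selective`, `enrichment_class`, `enrichment_residue`,
#'   `decile_profile`, `fa_fits`, `fa_truth`, `contacts`,
#'   `cell_ranks`, `cell_spearman`, `summary`.
#' @export
run_demo <- function(config = pipeline_config(), out_dir = tempfile("demo"),
                     figures = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  ## 1. library design
  design <- build_demo_library(seed)
  lib <- design$library
  props <- peptide_properties(lib)

  ## 2. plant strong/selective binders: the 41 highest-charge peptides
  charges <- setNames(props$net_charge, props$id)
  strong_ids <- props$id[order(-props$net_charge, props$id)][1:41]
  planted_top <- strong_ids[1:38]
  effects <- setNames(rep(4.2, length(strong_ids)), strong_ids)
  retention <- setNames(rep(0.95, length(strong_ids)), strong_ids)

  ## 3. microarray screen simulation + aggregation
  sim <- gen_microarray(screen_sim_spec(
    lib, peptide_effects = effects, selective_set = retention,
    default_retention = 0.30,
    competitor_fractions = config$competitor_fraction,
    noise_cv = config$noise_cv, assay_scale_sd = config$assay_scale_sd,
    seed = sub_seed(seed, 1L)))
  aggs <- aggregate_replicates(sim$spots, config$cv_threshold)
  agg_un <- aggs[aggs$condition_id == "uncompeted", , drop = FALSE]
  agg_co <- aggs[aggs$condition_id ==
                   paste0("competed_", config$competitor_fraction), ,
                 drop = FALSE]

  ## 4. top binders, selectivity, enrichment
  top_set <- select_top_fraction(agg_un, config$top_fraction)
  sel <- selectivity_table(agg_un, agg_co, config$competitor_fraction)
  subset_ids <- build_selectivity_subset(
    agg_un, sel, config$background_fraction, config$weak_fraction,
    config$selectivity_cut)
  seq_of <- setNames(lib$sequence, lib$id)
  enr_class <- compositional_enrichment(seq_of[top_set], lib$sequence,
                                        grouping = "class")
  enr_res <- compositional_enrichment(seq_of[top_set], lib$sequence,
                                      grouping = "residue")
  deciles <- intensity_decile_profile(agg_un, charges)

  ## 5. anisotropy titrations for three representative affinities
  fa_truth <- data.frame(
    peptide_id = c("I-P24", "II-P104", "II-P341"),
    y0 = 0.01, bmax = c(0.050, 0.060, 0.040),
    kd_uM = c(521, 388, 1290), hill = 1)
  tit <- gen_titration(titration_sim_spec(
    fa_truth, noise_sd = config$noise_cv * 0.6,
    seed = sub_seed(seed, 2L)))
  curves <- process_titration(tit$titrations, g_factor = config$g_factor)
  fa_fits <- fa_fit_table(curves, fix_hill = config$fix_hill)

  ## 6. contact map of a scripted trajectory
  script <- data.frame(frame = c(1, 2, 2, 3, 3, 3),
                       res_a = c(3, 3, 5, 3, 5, 7),
                       res_b = c(2, 2, 4, 2, 4, 6))
  fsed <- gen_frames(3, 8, 6, script, jitter_sd = 0.05,
                     seed = sub_seed(seed, 3L))
  cmap <- contact_map(fsed, config$contact_cutoff)

  ## 7. cell screen on the first 59 tiles
  tiles59 <- lib[lib$origin == "tiling", ][1:59, ]
  cells <- gen_cell_screen(tiles59,
                           enriched_regions = list(c(74, 88), c(128, 152)),
                           seed = sub_seed(seed, 4L))
  rk1 <- rank_binding(cells$cells_1, cells$control)
  rk2 <- rank_binding(cells$cells_2, cells$control)
  rho <- stats::cor.test(rk1$rank, rk2$rank, method = "spearman",
                         exact = FALSE)
  cell_ranks <- data.frame(peptide_id = rk1$peptide_id,
                           rank_cells_1 = rk1$rank, rank_cells_2 = rk2$rank)

  ## 8. report
  summary_list <- list(
    schema = "psapep-report/1",
    thresholds = unclass(config)[-1],
    library_size = nrow(lib), arms = as.list(design$arms),
    n_top = length(top_set),
    n_planted_top_recovered = length(intersect(top_set, planted_top)),
    n_selective = length(subset_ids),
    n_planted_selective_recovered =
      length(intersect(subset_ids, strong_ids)),
    cell_spearman_rho = unname(rho$estimate),
    cell_spearman_p = rho$p.value,
    max_interaction_frame = max_interaction_frame(fsed,
                                                  config$contact_cutoff))
  tsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  write_peptide_csv(lib, file.path(out_dir, "library.csv"))
  tsv(props, "properties.tsv")
  tsv(aggs, "aggregated.tsv")
  writeLines(top_set, file.path(out_dir, "top_set.txt"))
  tsv(sel, "selectivity.tsv")
  writeLines(subset_ids, file.path(out_dir, "selective_subset.txt"))
  tsv(enr_class, "enrichment_class.tsv")
  tsv(enr_res, "enrichment_residue.tsv")
  tsv(deciles, "decile_profile.tsv")
  tsv(fa_fits, "fa_fits.tsv")
  write_contact_map(cmap, file.path(out_dir, "contact_map.tsv"),
                    file.path(out_dir, "contact_map_long.tsv"))
  tsv(cell_ranks, "cell_ranks.tsv")
  yaml::write_yaml(summary_list, file.path(out_dir, "summary.yaml"))
  if (figures) demo_figures(out_dir, deciles, enr_class, curves, cell_ranks)

  invisible(list(library = lib, arms = design$arms, properties = props,
                 aggregated = aggs, top_set = top_set,
                 planted_top = planted_top, selectivity = sel,
                 selective_subset = subset_ids,
                 planted_selective = strong_ids,
                 enrichment_class = enr_class, enrichment_residue = enr_res,
                 decile_profile = deciles, fa_fits = fa_fits,
                 fa_truth = fa_truth, contacts = cmap,
                 cell_ranks = cell_ranks,
                 cell_spearman = list(rho = unname(rho$estimate),
                                      p = rho$p.value),
                 summary = summary_list, out_dir = out_dir))
}

# four quick-look PNGs mirroring the report tables
demo_figures <- function(out_dir, deciles, enr_class, curves, cell_ranks) {
  fig <- function(name, expr) {
    png(file.path(out_dir, name), width = 900, height = 700, res = 120)
    on.exit(dev.off(), add = TRUE)
    force(expr)
  }
  fig("fig_charge_deciles.png", {
    plot(deciles$decile, deciles$mean_charge, type = "b", pch = 19,
         xlab = "intensity decile (1 = weakest)", ylab = "mean net charge",
         main = "Charge dependence of binding")
  })
  fig("fig_enrichment_class.png", {
    m <- rbind(library = enr_class$library_prop,
               subset = enr_class$subset_prop)
    colnames(m) <- enr_class$key
    barplot(m, beside = TRUE, legend.text = TRUE,
            ylab = "residue fraction", main = "Class composition")
  })
  fig("fig_fa_curves.png", {
    xs <- unlist(lapply(curves, `[[`, "conc"))
    ys <- unlist(lapply(curves, `[[`, "r"))
    plot(NA, xlim = range(xs[xs > 0]), ylim = range(ys, na.rm = TRUE),
         log = "x", xlab = "ligand (uM)", ylab = "anisotropy (shifted)",
         main = "Anisotropy titrations")
    for (i in seq_along(curves)) {
      cv <- curves[[i]]
      pos <- cv$conc > 0
      points(cv$conc[pos], cv$r[pos], col = i, pch = 19)
      lines(cv$conc[pos], cv$r[pos], col = i)
    }
    legend("topleft", legend = names(curves), col = seq_along(curves),
           pch = 19, bty = "n")
  })
  fig("fig_cell_ranks.png", {
    plot(cell_ranks$rank_cells_1, cell_ranks$rank_cells_2, pch = 19,
         xlab = "rank (condition 1)", ylab = "rank (condition 2)",
         main = "Cell-screen rank agreement")
  })
  invisible(NULL)
}
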