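# Independent oracles used across test files. These deliberately use the
# dumbest possible implementations (exhaustive enumeration, nested loops,
# closed forms) so they share no code with the package paths they check.

# every full window start position, by direct enumeration
enumerate_tiles <- function(seq, window, step) {
  window <- as.integer(window[[1]]); step <- as.integer(step[[1]])
  starts <- integer(0)
  s <- 1L
  while (s + window - 1L <= nchar(seq)) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

# per-frame boolean contacts by triple nested loops over atoms
naive_frame_contacts <- function(frame, cutoff) {
  na <- length(frame$a); nb <- length(frame$b)
  m <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      ma <- frame$a[[i]]; mb <- frame$b[[j]]
      hit <- FALSE
      for (p in seq_len(nrow(ma))) {
        for (q in seq_len(nrow(mb))) {
          if (sqrt(sum((ma[p, ] - mb[q, ])^2)) <= cutoff) hit <- TRUE
        }
      }
      m[i, j] <- hit
    }
  }
  m
}

# Spearman rho closed form for tie-free data
spearman_closed_form <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# small random canonical sequence
random_aa <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# a tiny spot table: one peptide/condition, given per-assay replicate values
spots_from_assays <- function(assays, peptide_id = "p1",
                              condition_id = "CA10") {
  do.call(rbind, lapply(seq_along(assays), function(a)
    data.frame(peptide_id = peptide_id, condition_id = condition_id,
               assay_id = a, replicate = seq_along(assays[[a]]),
               intensity = assays[[a]])))
}

# bare 4PL fit object for exercising the reliability rule in isolation
fake_fit <- function(kd_mM, se_kd_mM, bmax = 0.05, se_bmax = 0.01) {
  structure(list(peptide_id = "x", y0 = 0, bmax = bmax,
                 kd_uM = kd_mM * 1000, kd_mM = kd_mM,
                 hill = 1, se_kd_uM = se_kd_mM * 1000,
                 se_kd_mM = se_kd_mM, se_bmax = se_bmax,
                 r_squared = 0.99, reliable = NA,
                 binding_potential = bmax / kd_mM, converged = TRUE,
                 message = "ok"), class = "fourpl_fit")
}
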