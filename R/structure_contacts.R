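#' Construct a frame set for contact analysis
#'
#' A frame set holds multi-frame coordinates for two residue groups
#' (e.g. peptide vs glycan). Each frame is a list with elements `a` and
#' `b`, each a list of per-residue atom coordinate matrices (n_atoms x
#' 3, Angstrom); atom counts per residue must be constant across
#' frames.
#'
#' @param frames List of frames as described above.
#' @param labels_a,labels_b Residue labels for the two groups; defaults
#'   are sequential numbers starting at the residue offsets.
#' @param residue_offset_a,residue_offset_b First-residue numbers used
#'   for default labelling (e.g. 28 for a mature-domain numbering).
#' @return List of class `"frame_set"`.
#' @export
frame_set <- function(frames, labels_a = NULL, labels_b = NULL,
                      residue_offset_a = 1L, residue_offset_b = 1L) {
  stopifnot(length(frames) >= 1L)
  na <- length(frames[[1]]$a); nb <- length(frames[[1]]$b)
  if (na == 0L || nb == 0L)
    stop("both residue groups must be non-empty", call. = FALSE)
  for (f in frames) {
    if (length(f$a) != na || length(f$b) != nb)
      stop("residue counts differ across frames", call. = FALSE)
    for (m in c(f$a, f$b))
      if (!is.matrix(m) || ncol(m) != 3L || !all(is.finite(m)))
        stop("each residue must be a finite n x 3 coordinate matrix",
             call. = FALSE)
  }
  if (is.null(labels_a))
    labels_a <- as.character(residue_offset_a + seq_len(na) - 1L)
  if (is.null(labels_b))
    labels_b <- as.character(residue_offset_b + seq_len(nb) - 1L)
  stopifnot(length(labels_a) == na, length(labels_b) == nb)
  structure(list(frames = frames, labels_a = labels_a, labels_b = labels_b),
            class = "frame_set")
}

# min inter-atomic distance between two residue coordinate matrices
min_residue_distance <- function(ma, mb) {
  # all-pairs Euclidean distances without loops
  d2 <- outer(rowSums(ma^2), rowSums(mb^2), "+") - 2 * ma %*% t(mb)
  sqrt(max(min(d2), 0))
}

#' Boolean residue contact matrix for one frame
#'
#' A residue pair is in contact when the minimum distance over all atom
#' pairs is at or below `cutoff` (default 3.0 Angstrom, the standard
#' polar-contact cut).
#'
#' @param frame One frame (list with residue lists `a` and `b`).
#' @param cutoff Contact distance in Angstrom.
#' @return Logical matrix, residues of `a` in rows, of `b` in columns.
#' @export
residue_contacts <- function(frame, cutoff = 3.0) {
  na <- length(frame$a); nb <- length(frame$b)
  stopifnot(na > 0, nb > 0)
  m <- matrix(FALSE, na, nb)
  for (i in seq_len(na))
    for (j in seq_len(nb))
      m[i, j] <- min_residue_distance(frame$a[[i]], frame$b[[j]]) <= cutoff
  m
}

#' Normalized residue contact map over frames
#'
#' Counts, per residue pair, the number of frames in which the pair is
#' in contact (a pair contributes at most once per frame) and
#' normalizes by the global maximum raw count, so the map spans
#' \[0, 1\] with the hottest pair at 1 — matching a 0-to-1 colour
#' scale. An all-zero map stays all zero. Per-row normalization (each
#' residue of group a scaled by its own maximum) is available as an
#' option.
#'
#' @param fs A [frame_set()].
#' @param cutoff Contact distance in Angstrom (default 3.0).
#' @param normalize `"global"` or `"row"`.
#' @return List of class `"contact_map"`: `map` (normalized, labelled),
#'   `raw_counts`, `cutoff`, `n_frames`.
#' @export
contact_map <- function(fs, cutoff = 3.0, normalize = c("global", "row")) {
  stopifnot(inherits(fs, "frame_set"))
  normalize <- match.arg(normalize)
  raw <- Reduce(`+`, lapply(fs$frames, function(f)
    residue_contacts(f, cutoff) * 1L))
  dimnames(raw) <- list(fs$labels_a, fs$labels_b)
  norm <- raw
  if (normalize == "global") {
    mx <- max(raw)
    if (mx > 0) norm <- raw / mx
  } else {
    for (i in seq_len(nrow(raw))) {
      mx <- max(raw[i, ])
      if (mx > 0) norm[i, ] <- raw[i, ] / mx
    }
  }
  structure(list(map = norm, raw_counts = raw, cutoff = cutoff,
                 n_frames = length(fs$frames)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("Contact map:", nrow(x$map), "x", ncol(x$map), "residues,",
      x$n_frames, "frame(s), cutoff", x$cutoff, "A, max raw count",
      max(x$raw_counts), "\n")
  invisible(x)
}

#' Frame of greatest interaction
#'
#' @param fs A [frame_set()].
#' @param cutoff Contact distance in Angstrom.
#' @return Index of the frame with the most residue pairs in contact;
#'   the earliest frame wins ties.
#' @export
max_interaction_frame <- function(fs, cutoff = 3.0) {
  stopifnot(inherits(fs, "frame_set"))
  counts <- vapply(fs$frames, function(f) sum(residue_contacts(f, cutoff)),
                   numeric(1))
  which.max(counts)  # which.max returns the first maximum
}

#' Top contacting residues of a map
#'
#' Ranks residues of one group by their summed normalized contact
#' values; ties are broken by residue order (label position), so the
#' ranking is deterministic.
#'
#' @param cm A [contact_map()].
#' @param side `"a"` (rows) or `"b"` (columns).
#' @param k Number of residues returned.
#' @return Character vector of residue labels, strongest first.
#' @export
top_contact_residues <- function(cm, side = c("a", "b"), k = 5L) {
  stopifnot(inherits(cm, "contact_map"))
  side <- match.arg(side)
  sums <- if (side == "a") rowSums(cm$map) else colSums(cm$map)
  ord <- order(-sums, seq_along(sums))
  head(names(sums)[ord], k)
}

#' Read a multi-model PDB into a frame set
#'
#' MODEL/ENDMDL records delimit frames; residues are grouped by chain
#' identifier and residue number. All atoms participate unless
#' `heavy_only` drops hydrogens.
#'
#' @param path PDB file path.
#' @param chain_a,chain_b Chain identifiers selecting the two groups.
#' @param heavy_only Drop hydrogen atoms (element/atom name starting H).
#' @return A [frame_set()] labelled by residue number.
#' @export
read_frames_pdb <- function(path, chain_a, chain_b, heavy_only = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  keep <- rep(TRUE, nrow(atom))
  if (heavy_only) keep <- !grepl("^H", trimws(atom$elety))
  sel_a <- which(atom$chain == chain_a & keep)
  sel_b <- which(atom$chain == chain_b & keep)
  if (!length(sel_a) || !length(sel_b))
    stop("chain(s) not found: need atoms in chains ", chain_a, " and ",
         chain_b, call. = FALSE)
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  res_a <- split(sel_a, atom$resno[sel_a])
  res_b <- split(sel_b, atom$resno[sel_b])
  res_a <- res_a[order(as.integer(names(res_a)))]
  res_b <- res_b[order(as.integer(names(res_b)))]
  frame_of <- function(fi) {
    coords <- matrix(xyz[fi, ], ncol = 3, byrow = TRUE)
    list(a = lapply(res_a, function(ix) coords[ix, , drop = FALSE]),
         b = lapply(res_b, function(ix) coords[ix, , drop = FALSE]))
  }
  frames <- lapply(seq_len(nrow(xyz)), frame_of)
  frame_set(frames, labels_a = names(res_a), labels_b = names(res_b))
}

#' Write a frame set as a multi-model PDB
#'
#' Group a becomes chain A and group b chain B; every atom is written
#' as a CA pseudo-atom of residue type GLY with the group's residue
#' numbering. Round-trips through [read_frames_pdb()].
#'
#' @param fs A [frame_set()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(fs, path) {
  stopifnot(inherits(fs, "frame_set"))
  f1 <- fs$frames[[1]]
  n_at_a <- vapply(f1$a, nrow, integer(1))
  n_at_b <- vapply(f1$b, nrow, integer(1))
  resno <- c(rep(as.integer(fs$labels_a), n_at_a),
             rep(as.integer(fs$labels_b), n_at_b))
  chain <- c(rep("A", sum(n_at_a)), rep("B", sum(n_at_b)))
  n_atoms <- sum(n_at_a) + sum(n_at_b)
  xyz <- t(vapply(fs$frames, function(f)
    as.numeric(t(do.call(rbind, c(f$a, f$b)))), numeric(3 * n_atoms)))
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno,
                   chain = chain, resid = rep("GLY", n_atoms),
                   eleno = seq_len(n_atoms), elety = rep("CA", n_atoms))
  invisible(path)
}

#' Write a contact map as TSV
#'
#' Writes the normalized matrix (residues of group a in rows) and,
#' optionally, a long-format table `res_a`, `res_b`, `value`.
#'
#' @param cm A [contact_map()].
#' @param path Output TSV path for the matrix.
#' @param long_path Optional path for the long-format table.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cm, path, long_path = NULL) {
  stopifnot(inherits(cm, "contact_map"))
  df <- data.frame(res_a = rownames(cm$map), cm$map, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(long_path)) {
    long <- expand.grid(res_a = rownames(cm$map), res_b = colnames(cm$map),
                        stringsAsFactors = FALSE)
    long$value <- as.vector(cm$map)
    utils::write.table(long, long_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
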