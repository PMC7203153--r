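#' Construct a peptide record
#'
#' A peptide record is one row of a peptide library table: a designed
#' peptide together with its provenance (how it was derived and from
#' where in a parent sequence). Libraries are plain data frames of such
#' rows so they compose directly with the screen-analysis functions.
#'
#' @param id Short unique label, e.g. `"I-P24"`.
#' @param sequence Peptide sequence over the 20 canonical one-letter
#'   amino-acid codes (uppercase).
#' @param origin One of `"tiling"`, `"mutation"`, `"scramble"`,
#'   `"de_novo"`, `"external"`.
#' @param parent_id Optional label of the source peptide or protein.
#' @param parent_start Optional 1-based start position within the parent
#'   protein (required for `origin = "tiling"`).
#' @param mutation_note Optional string of the form `"<orig><pos><new>"`
#'   (e.g. `"E6R"`; required for `origin = "mutation"`).
#' @param nterm_acetylated Logical; protein-derived microarray peptides
#'   are N-terminally acetylated to match the parent fragment charge.
#' @return A one-row data frame with columns `id`, `sequence`, `origin`,
#'   `parent_id`, `parent_start`, `mutation_note`, `nterm_acetylated`.
#' @examples
#' peptide_record("I-P24", "FKGRTSPKTGAPVAT", "external")
#' @export
peptide_record <- function(id, sequence,
                           origin = c("external", "tiling", "mutation",
                                      "scramble", "de_novo"),
                           parent_id = NA_character_,
                           parent_start = NA_integer_,
                           mutation_note = NA_character_,
                           nterm_acetylated = FALSE) {
  origin <- match.arg(origin)
  assert_canonical(sequence, paste0("sequence of ", id))
  if (origin == "tiling" && (is.na(parent_id) || is.na(parent_start)))
    stop("tiling records require parent_id and parent_start", call. = FALSE)
  if (origin == "mutation") {
    if (is.na(mutation_note) || !grepl("^[A-Z][0-9]+[A-Z]$", mutation_note))
      stop("mutation records require a mutation_note of form '<orig><pos><new>'",
           call. = FALSE)
  }
  data.frame(id = as.character(id), sequence = sequence, origin = origin,
             parent_id = as.character(parent_id),
             parent_start = as.integer(parent_start),
             mutation_note = as.character(mutation_note),
             nterm_acetylated = isTRUE(nterm_acetylated),
             stringsAsFactors = FALSE)
}

#' Tiling specification for epitope mapping
#'
#' @param window Peptide length in residues (default 15, the library
#'   standard for linear epitope mapping).
#' @param step Offset between consecutive windows (default 2, i.e. 13
#'   residues of overlap between neighbours).
#' @param start_offset 1-based residue at which tiling begins on the
#'   parent protein; use e.g. 28 when tiling a mature chain whose
#'   numbering starts after a signal peptide.
#' @return A list of class `"tiling_spec"`.
#' @export
tiling_spec <- function(window = 15L, step = 2L, start_offset = 1L) {
  window <- as.integer(window); step <- as.integer(step)
  start_offset <- as.integer(start_offset)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (step < 1L || step > window)
    stop("step must satisfy 1 <= step <= window", call. = FALSE)
  structure(list(window = window, step = step, start_offset = start_offset),
            class = "tiling_spec")
}

#' Tile a parent sequence into overlapping peptides
#'
#' Slides a fixed-length window along a parent protein, emitting one
#' peptide per step. Trailing partial windows shorter than `window` are
#' dropped (no padding), so the number of peptides is
#' `floor((L - window) / step) + 1` for a parent of length `L`.
#'
#' @param parent_seq Parent amino-acid sequence (canonical, uppercase).
#' @param spec A [tiling_spec()].
#' @param parent_id Label recorded as the parent of every tile.
#' @param id_prefix Ids are generated as `"<id_prefix>-P<k>"` with `k`
#'   numbering tiles from 1 in parent order.
#' @param acetylated Logical; set `TRUE` for protein-derived arms, which
#'   are N-terminally acetylated on the array.
#' @return A data frame of peptide records ordered along the parent;
#'   `parent_start` of tile `k` (1-based) is
#'   `start_offset + (k - 1) * step`.
#' @examples
#' tile_sequence("FKGRTSPKTGAPVATNNAGV", tiling_spec(15, 2), "parent")
#' @export
tile_sequence <- function(parent_seq, spec = tiling_spec(),
                          parent_id = "parent", id_prefix = "I",
                          acetylated = TRUE) {
  assert_canonical(parent_seq, "parent_seq")
  stopifnot(inherits(spec, "tiling_spec"))
  L <- nchar(parent_seq)
  if (L < spec$window)
    stop("parent sequence (length ", L, ") is shorter than the tiling window (",
         spec$window, ")", call. = FALSE)
  n <- (L - spec$window) %/% spec$step + 1L
  starts <- 1L + (seq_len(n) - 1L) * spec$step
  recs <- lapply(seq_len(n), function(k) {
    peptide_record(id = sprintf("%s-P%d", id_prefix, k),
                   sequence = substr(parent_seq, starts[k],
                                     starts[k] + spec$window - 1L),
                   origin = "tiling", parent_id = parent_id,
                   parent_start = spec$start_offset + (k - 1L) * spec$step,
                   nterm_acetylated = acetylated)
  })
  do.call(rbind, recs)
}

#' Introduce a single point mutation
#'
#' @param parent A one-row peptide record (see [peptide_record()]).
#' @param position 1-based position to mutate.
#' @param new_residue Canonical one-letter code; must differ from the
#'   parent residue at `position` (a silent "mutation" is an error).
#' @param id Id for the mutant; default appends the mutation note.
#' @return A peptide record with `origin = "mutation"`, `mutation_note`
#'   of form `"<orig><pos><new>"`, and `parent_id` set to the parent id.
#' @examples
#' p <- peptide_record("I-P330", "WFKGRTSPKTGAPVA", "external")
#' point_mutate(p, 5, "K")$sequence   # "WFKGKTSPKTGAPVA"
#' @export
point_mutate <- function(parent, position, new_residue, id = NULL) {
  stopifnot(is.data.frame(parent), nrow(parent) == 1L)
  seq <- parent$sequence
  position <- as.integer(position)
  if (position < 1L || position > nchar(seq))
    stop("position ", position, " is out of range for a ", nchar(seq),
         "-mer", call. = FALSE)
  if (!new_residue %in% AA_CANONICAL)
    stop("new_residue must be a canonical amino-acid code", call. = FALSE)
  orig <- substr(seq, position, position)
  if (orig == new_residue)
    stop("mutation must change the sequence: position ", position,
         " is already ", orig, call. = FALSE)
  note <- paste0(orig, position, new_residue)
  mutated <- seq
  substr(mutated, position, position) <- new_residue
  peptide_record(id = if (is.null(id)) paste0(parent$id, "_", note) else id,
                 sequence = mutated, origin = "mutation",
                 parent_id = parent$id, mutation_note = note,
                 nterm_acetylated = parent$nterm_acetylated)
}

#' Scramble a peptide sequence
#'
#' Returns a seeded Fisher-Yates permutation of the parent with the same
#' residue multiset but a different order; resampled until the order
#' differs, so a homopolymer (or any sequence with fewer than two
#' distinct residues) is an error.
#'
#' @param parent A one-row peptide record.
#' @param seed Integer seed; the same parent and seed always give the
#'   same scramble.
#' @param id Id for the scramble; default appends `"_scr"`.
#' @return A peptide record with `origin = "scramble"`.
#' @export
scramble_peptide <- function(parent, seed, id = NULL) {
  stopifnot(is.data.frame(parent), nrow(parent) == 1L)
  chars <- seq_chars(parent$sequence)
  if (length(chars) < 2L || length(unique(chars)) < 2L)
    stop("cannot scramble '", parent$sequence,
         "': fewer than two distinct residues", call. = FALSE)
  out <- local({
    set.seed(as.integer(seed))
    repeat {
      perm <- sample(chars)
      if (!identical(perm, chars)) return(paste(perm, collapse = ""))
    }
  })
  peptide_record(id = if (is.null(id)) paste0(parent$id, "_scr") else id,
                 sequence = out, origin = "scramble", parent_id = parent$id,
                 nterm_acetylated = parent$nterm_acetylated)
}

#' Build a de novo repeat peptide
#'
#' Truncates the infinite repeat of `unit`, started at `phase`, to
#' `length` residues. This is how the lysine/glycine repeat series
#' (e.g. `"KGKGKGKGKGKGKGK"`) is generated.
#'
#' @param unit Repeat unit (canonical amino-acid string).
#' @param length Total peptide length in residues.
#' @param phase 0-based offset into the unit at which the repeat starts.
#' @param id Record id.
#' @return A peptide record with `origin = "de_novo"`.
#' @examples
#' make_repeat_peptide("KG", 15)$sequence      # "KGKGKGKGKGKGKGK"
#' make_repeat_peptide("KGGG", 15, phase = 2)$sequence
#' @export
make_repeat_peptide <- function(unit, length, phase = 0L, id = "denovo") {
  assert_canonical(unit, "unit")
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  u <- seq_chars(unit)
  idx <- ((as.integer(phase) + seq_len(length) - 1L) %% length(u)) + 1L
  peptide_record(id = id, sequence = paste(u[idx], collapse = ""),
                 origin = "de_novo")
}

#' Validate a peptide library table
#'
#' Checks the record invariants: canonical uppercase sequences, unique
#' ids, tiling rows carrying parent coordinates, and parseable mutation
#' notes.
#'
#' @param lib Data frame of peptide records.
#' @return `lib`, invisibly; errors describe the first violation.
#' @export
validate_library <- function(lib) {
  need <- c("id", "sequence", "origin", "parent_id", "parent_start",
            "mutation_note", "nterm_acetylated")
  miss <- setdiff(need, names(lib))
  if (length(miss))
    stop("library is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(lib$id))
    stop("duplicate peptide id(s): ",
         paste(unique(lib$id[duplicated(lib$id)]), collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(lib))) {
    assert_canonical(lib$sequence[i], paste0("sequence of ", lib$id[i]))
    if (lib$origin[i] == "tiling" &&
        (is.na(lib$parent_id[i]) || is.na(lib$parent_start[i])))
      stop("tiling record ", lib$id[i], " lacks parent_id/parent_start",
           call. = FALSE)
    if (lib$origin[i] == "mutation" &&
        (is.na(lib$mutation_note[i]) ||
         !grepl("^[A-Z][0-9]+[A-Z]$", lib$mutation_note[i])))
      stop("mutation record ", lib$id[i], " has unparseable mutation_note",
           call. = FALSE)
  }
  invisible(lib)
}
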