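#' Read and write peptide libraries as FASTA or CSV
#'
#' The FASTA dialect stores one record per sequence with the id as the
#' first header token and the remaining record fields as `key=value`
#' pairs after it, e.g.
#' `>I-P1 origin=tiling parent_id=siglec11 parent_start=1 nterm_acetylated=true`.
#' Missing optional fields are simply omitted. The CSV dialect has one
#' column per record field. Both round-trip exactly through their
#' readers.
#'
#' @param lib Data frame of peptide records ([peptide_record()]).
#' @param path File path.
#' @return The writers return `path` invisibly; the readers return a
#'   validated peptide library data frame.
#' @seealso [validate_library()]
#' @export
write_peptide_fasta <- function(lib, path) {
  validate_library(lib)
  headers <- vapply(seq_len(nrow(lib)), function(i) {
    kv <- c(origin = lib$origin[i],
            parent_id = lib$parent_id[i],
            parent_start = lib$parent_start[i],
            mutation_note = lib$mutation_note[i],
            nterm_acetylated = tolower(as.character(lib$nterm_acetylated[i])))
    kv <- kv[!is.na(kv) & kv != "NA"]
    paste(lib$id[i], paste(names(kv), unname(kv), sep = "=", collapse = " "))
  }, character(1))
  seqinr::write.fasta(as.list(lib$sequence), names = headers,
                      file.out = path, nbchar = 10000L)
  invisible(path)
}

#' @rdname write_peptide_fasta
#' @export
read_peptide_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           whole.header = TRUE)
  recs <- lapply(fa, function(s) {
    header <- attr(s, "name")
    toks <- strsplit(header, " +")[[1]]
    kv <- toks[grepl("=", toks, fixed = TRUE)]
    vals <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    get <- function(key, default = NA_character_)
      if (key %in% names(vals)) vals[[key]] else default
    peptide_record(
      id = toks[1], sequence = toupper(as.character(s)),
      origin = get("origin", "external"),
      parent_id = get("parent_id"),
      parent_start = suppressWarnings(as.integer(get("parent_start"))),
      mutation_note = get("mutation_note"),
      nterm_acetylated = identical(get("nterm_acetylated", "false"), "true"))
  })
  lib <- do.call(rbind, unname(recs))
  rownames(lib) <- NULL
  validate_library(lib)
  lib
}

#' @rdname write_peptide_fasta
#' @export
write_peptide_csv <- function(lib, path) {
  validate_library(lib)
  write.csv(lib, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_peptide_fasta
#' @export
read_peptide_csv <- function(path) {
  lib <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(id = "character", sequence = "character",
                                 origin = "character", parent_id = "character",
                                 parent_start = "integer",
                                 mutation_note = "character",
                                 nterm_acetylated = "logical"))
  validate_library(lib)
  lib
}
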