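#' Read a SMILES file into molecule records
#'
#' One molecule per line, whitespace-delimited: the SMILES string first,
#' an optional identifier second. Blank lines are skipped; molecules
#' without an identifier are auto-numbered by line position.
#'
#' @param path path to a `.smi`/`.txt` SMILES file.
#' @return data frame of molecule records with columns `id`, `smiles` and
#'   `canonical_smiles` (NA until [canonicalize_and_dedup()] is run).
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("SMILES file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(data.frame(id = character(), smiles = character(),
                      canonical_smiles = character()))
  }
  tokens <- strsplit(trimws(lines), "[[:space:]]+")
  smiles <- vapply(tokens, `[[`, character(1), 1L)
  ids <- vapply(seq_along(tokens), function(i) {
    if (length(tokens[[i]]) >= 2L) tokens[[i]][[2L]]
    else sprintf("mol_%d", lineno[i])
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate molecule identifiers in ", path)
  data.frame(id = ids, smiles = smiles, canonical_smiles = NA_character_)
}

# locate the python interpreter used for RDKit work; overridable via
# options(chemmaps.python = "/path/to/python")
chemmaps_python <- function() {
  py <- getOption("chemmaps.python", Sys.which("python"))
  if (!nzchar(py)) {
    stop("no python interpreter found; the fingerprint module needs a ",
         "python with the RDKit installed (see ?compute_fingerprints)")
  }
  py
}

# run the bundled RDKit helper on (id, smiles) records; returns the
# id -> result map as a character vector in input order
run_rdkit_helper <- function(records, subcommand, extra = character()) {
  script <- system.file("python", "rdkit_fp.py", package = "chemmaps",
                        mustWork = TRUE)
  infile <- tempfile(fileext = ".tsv")
  outfile <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(infile, outfile)))
  writeLines(paste(records$id, records$smiles, sep = "\t"), infile)
  status <- system2(chemmaps_python(),
                    c(shQuote(script), subcommand, shQuote(infile),
                      shQuote(outfile), extra),
                    stdout = FALSE, stderr = "")
  if (status != 0L) stop("RDKit helper failed (exit status ", status, ")")
  out <- read.delim(outfile, header = FALSE, sep = "\t",
                    colClasses = "character", na.strings = NULL,
                    quote = "", fill = TRUE, comment.char = "")
  if (nrow(out) != nrow(records) || !identical(out[[1L]], records$id)) {
    stop("RDKit helper output does not match the input records")
  }
  if (ncol(out) < 2L) out[[2L]] <- ""
  out[[2L]]
}

#' Canonicalize SMILES and remove duplicate molecules
#'
#' Computes the RDKit canonical SMILES for every record, drops records
#' whose SMILES cannot be parsed (each rejection is reported with its
#' identifier), and removes duplicates: records sharing a canonical SMILES
#' are collapsed to the first occurrence, preserving the relative input
#' order. The operation is idempotent.
#'
#' @param records molecule records from [read_smiles()], or any data frame
#'   with columns `id` and `smiles`.
#' @return the retained records with `canonical_smiles` filled in.
#' @export
canonicalize_and_dedup <- function(records) {
  stopifnot(all(c("id", "smiles") %in% names(records)))
  if (nrow(records) == 0L) {
    records$canonical_smiles <- character(0)
    return(records)
  }
  canon <- run_rdkit_helper(records, "canon")
  bad <- !nzchar(canon)
  if (any(bad)) {
    message("dropping ", sum(bad), " unparseable SMILES: ",
            paste(records$id[bad], collapse = ", "))
  }
  records <- records[!bad, , drop = FALSE]
  records$canonical_smiles <- canon[!bad]
  records <- records[!duplicated(records$canonical_smiles), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Compute binary fingerprints for canonicalized molecule records
#'
#' Generates one of the three RDKit fingerprint families used throughout
#' the package: MACCS structural keys (166 bits; RDKit's unused position 0
#' is dropped), ECFP4 (Morgan circular fingerprint of radius 2 folded to
#' 1024 bits) or the RDKit topological path fingerprint (2048 bits, toolkit
#' defaults). Generation is deterministic: the same records always yield a
#' bit-identical matrix.
#'
#' Requires a python interpreter with the RDKit on the `PATH` (or set
#' `options(chemmaps.python = ...)`).
#'
#' @param records canonicalized molecule records
#'   (see [canonicalize_and_dedup()]).
#' @param family `"maccs"`, `"ecfp4"` or `"rdkit"`.
#' @return an [fpmatrix] with one row per record, in record order.
#' @export
compute_fingerprints <- function(records, family = c("maccs", "ecfp4", "rdkit")) {
  family <- match.arg(family)
  stopifnot(all(c("id", "smiles") %in% names(records)))
  if (nrow(records) == 0L) stop("no molecule records to fingerprint")
  smi <- if ("canonical_smiles" %in% names(records) &&
             !anyNA(records$canonical_smiles)) {
    records$canonical_smiles
  } else records$smiles
  bitstrings <- run_rdkit_helper(
    data.frame(id = records$id, smiles = smi), "fp",
    extra = c("--family", family))
  expected <- fp_family_bits()[[family]]
  if (any(nchar(bitstrings) != expected)) {
    stop("fingerprint generation returned the wrong width for: ",
         paste(records$id[nchar(bitstrings) != expected], collapse = ", "))
  }
  bits <- matrix(as.integer(unlist(strsplit(bitstrings, "", fixed = TRUE))),
                 nrow = nrow(records), ncol = expected, byrow = TRUE)
  fpmatrix(bits, ids = records$id, family = family)
}

#' Write and read fingerprint matrices
#'
#' The matrix is stored as a headered CSV (an `id` column followed by one
#' column per bit) with a JSON sidecar (`<path>.json`) recording the
#' fingerprint family and width, so that a write/read round trip is exact
#' including metadata. Reading rejects files with non-binary entries.
#'
#' @param x an [fpmatrix].
#' @param path CSV file path.
#' @return `write_fpmatrix` returns `path` invisibly; `read_fpmatrix`
#'   returns an [fpmatrix].
#' @export
write_fpmatrix <- function(x, path) {
  stopifnot(inherits(x, "fpmatrix"))
  df <- data.frame(id = x$ids, x$bits, check.names = FALSE)
  names(df) <- c("id", paste0("b", seq_len(x$n_bits)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  jsonlite::write_json(list(family = x$family, n_bits = x$n_bits,
                            n_molecules = nrow(x$bits)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fpmatrix
#' @export
read_fpmatrix <- function(path) {
  if (!file.exists(path)) stop("fingerprint matrix file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "id") {
    stop("expected an 'id' column followed by bit columns in ", path)
  }
  bits <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(bits) || !all(bits == 0 | bits == 1)) {
    stop("fingerprint matrix file contains non-binary entries: ", path)
  }
  family <- "custom"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$family)) family <- meta$family
    if (!is.null(meta$n_bits) && meta$n_bits != ncol(bits)) {
      stop("sidecar metadata disagrees with the matrix width in ", path)
    }
  }
  fpmatrix(bits, ids = as.character(df$id), family = family)
}
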