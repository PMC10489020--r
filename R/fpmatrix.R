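#' Binary fingerprint matrix
#'
#' The universal substrate of the package: an `N x M` binary matrix with one
#' row per molecule and one column per fingerprint bit, together with
#' molecule identifiers and the fingerprint family that produced it.
#'
#' @param bits integer or numeric matrix containing only 0s and 1s, one row
#'   per molecule.
#' @param ids character vector of unique molecule identifiers, one per row.
#'   Defaults to `mol_1 ... mol_N`.
#' @param family fingerprint family label. One of `"maccs"`, `"ecfp4"`,
#'   `"rdkit"` for RDKit-generated fingerprints (bit widths 166, 1024 and
#'   2048 respectively), or a free-form label such as `"synthetic"` for
#'   matrices that did not come from a chemistry toolkit.
#'
#' @return An object of class `fpmatrix`: a list with elements `bits`
#'   (integer matrix), `ids`, `family` and `n_bits`.
#' @examples
#' m <- fpmatrix(rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1)))
#' m
#' @export
fpmatrix <- function(bits, ids = NULL, family = "custom") {
  bits <- as.matrix(bits)
  if (nrow(bits) < 1L) stop("fingerprint matrix needs at least one row")
  if (!all(bits == 0L | bits == 1L)) {
    stop("fingerprint matrix entries must all be 0 or 1")
  }
  storage.mode(bits) <- "integer"
  if (is.null(ids)) ids <- paste0("mol_", seq_len(nrow(bits)))
  ids <- as.character(ids)
  if (length(ids) != nrow(bits)) stop("length(ids) must equal nrow(bits)")
  if (anyDuplicated(ids)) stop("molecule identifiers must be unique")
  family <- as.character(family)[1L]
  known <- fp_family_bits()
  if (family %in% names(known) && ncol(bits) != known[[family]]) {
    stop(sprintf("family '%s' requires %d bits, got %d columns",
                 family, known[[family]], ncol(bits)))
  }
  dimnames(bits) <- NULL
  structure(list(bits = bits, ids = ids, family = family,
                 n_bits = ncol(bits)),
            class = "fpmatrix")
}

# advertised widths of the three toolkit families
fp_family_bits <- function() c(maccs = 166L, ecfp4 = 1024L, rdkit = 2048L)

#' @export
print.fpmatrix <- function(x, ...) {
  cat(sprintf("Fingerprint matrix: %d molecules x %d bits (family: %s)\n",
              nrow(x$bits), x$n_bits, x$family))
  dens <- mean(x$bits)
  cat(sprintf("  mean on-bit density: %.3f\n", dens))
  invisible(x)
}

#' @export
dim.fpmatrix <- function(x) dim(x$bits)

#' Extract the bit matrix from a fingerprint object
#'
#' Accepts either an [fpmatrix] or a plain binary matrix, so that every
#' computational entry point in the package can take both.
#'
#' @param x an `fpmatrix` or a binary matrix.
#' @return integer matrix of 0/1 values.
#' @keywords internal
fp_bits <- function(x) {
  if (inherits(x, "fpmatrix")) return(x$bits)
  b <- as.matrix(x)
  if (!all(b == 0L | b == 1L)) stop("matrix entries must all be 0 or 1")
  storage.mode(b) <- "integer"
  dimnames(b) <- NULL
  b
}

fp_ids <- function(x) {
  if (inherits(x, "fpmatrix")) return(x$ids)
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("mol_", seq_len(nrow(x)))
  ids
}
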