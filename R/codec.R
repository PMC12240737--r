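# Codec method implementations and the batch decode-and-filter step.

.checkDim <- function(codec, z) {
  if (!is.numeric(z) || length(z) != codec@dim)
    cmomoStop("dimensionMismatch",
              sprintf("latent vector has length %d, codec dimension is %d",
                      length(z), codec@dim))
  invisible(TRUE)
}

# Full-precision, locale-independent coordinate serialization so that
# encode(decode(z)) == z bitwise for the coordinate codec.
.formatCoords <- function(z) paste(sprintf("%.17g", z), collapse = ",")

.parseCoords <- function(s, dim = NULL) {
  v <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]]))
  if (anyNA(v) || (!is.null(dim) && length(v) != dim)) return(NULL)
  v
}

#' @rdname codec-api
setMethod("encodeMolecule", "TableCodec", function(codec, smiles) {
  canon <- parseSmiles(smiles)
  i <- match(canon, codec@smiles)
  if (is.na(i))
    cmomoStop("unknownMolecule",
              sprintf("molecule '%s' is not a table entry", canon))
  codec@latent[i, ]
})

#' @rdname codec-api
setMethod("decodeVector", "TableCodec", function(codec, z) {
  .checkDim(codec, z)
  # squared Euclidean distance to every entry; which.min takes the lowest
  # index on ties, which is the documented tie-break
  d2 <- colSums((t(codec@latent) - z)^2)
  codec@smiles[which.min(d2)]
})

#' @rdname codec-api
setMethod("canonicalizeInput", "TableCodec", function(codec, s) {
  rec <- chemDescriptors(s)[[1L]]
  if (!isTRUE(rec$valid)) NA_character_ else rec$canonical
})

#' @rdname codec-api
setMethod("encodeMolecule", "IdentityCodec", function(codec, smiles) {
  v <- .parseCoords(smiles, codec@dim)
  if (is.null(v))
    cmomoStop("unknownMolecule",
              sprintf("'%s' is not a %d-coordinate string", smiles, codec@dim))
  v
})

#' @rdname codec-api
setMethod("decodeVector", "IdentityCodec", function(codec, z) {
  .checkDim(codec, z)
  .formatCoords(z)
})

#' @rdname codec-api
setMethod("canonicalizeInput", "IdentityCodec", function(codec, s) {
  v <- .parseCoords(s, codec@dim)
  if (is.null(v)) NA_character_ else .formatCoords(v)
})

#' @rdname codec-api
setMethod("encodeMolecule", "FunctionCodec", function(codec, smiles) {
  z <- tryCatch(codec@encodeFun(smiles), error = function(e)
    cmomoStop("codecError", sprintf("plug-in encode failed for '%s': %s",
                                    smiles, conditionMessage(e))))
  if (!is.numeric(z) || length(z) != codec@dim)
    cmomoStop("codecError", "plug-in encode returned a wrong-dimension vector")
  as.numeric(z)
})

#' @rdname codec-api
setMethod("decodeVector", "FunctionCodec", function(codec, z) {
  .checkDim(codec, z)
  out <- tryCatch(codec@decodeFun(z), error = function(e) NA_character_)
  if (is.null(out) || length(out) != 1L || is.na(out)) NA_character_
  else as.character(out)
})

#' @rdname codec-api
setMethod("canonicalizeInput", "FunctionCodec", function(codec, s) {
  rec <- chemDescriptors(s)[[1L]]
  if (!isTRUE(rec$valid)) NA_character_ else rec$canonical
})

#' Decode a batch of latent vectors and keep the valid, distinct survivors
#'
#' Decodes every vector, drops decode failures and invalid (unparsable)
#' outputs, canonicalizes the survivors, and removes duplicates by canonical
#' identifier keeping the first occurrence, preserving input order.
#' Optionally also drops molecules already present in `exclude` (used to
#' dedupe offspring against the parent population).
#'
#' @param codec a codec object.
#' @param zs a list of latent vectors, or a matrix with one row per vector.
#' @param exclude character vector of canonical identifiers to drop.
#' @return data.frame with columns `index` (position in the input batch) and
#'   `smiles` (canonical identifier); zero rows if nothing survives.
#' @export
decodeValidBatch <- function(codec, zs, exclude = character(0)) {
  if (is.matrix(zs)) zs <- asplit(zs, 1L)
  decoded <- vapply(zs, function(z) {
    out <- decodeVector(codec, as.numeric(z))
    if (is.na(out)) NA_character_ else canonicalizeInput(codec, out)
  }, character(1))
  ok <- !is.na(decoded)
  idx <- which(ok)
  canon <- decoded[ok]
  keep <- !duplicated(canon) & !(canon %in% exclude)
  data.frame(index = idx[keep], smiles = canon[keep],
             stringsAsFactors = FALSE)
}

#' Read or write a TableCodec as CSV
#'
#' Schema: column `smiles` followed by `z_0 ... z_{D-1}`.
#'
#' @param codec a [TableCodec-class].
#' @param path CSV file path.
#' @return `readTableCodec` returns a [TableCodec-class];
#'   `writeTableCodec` returns `path` invisibly.
#' @export
writeTableCodec <- function(codec, path) {
  df <- data.frame(smiles = codec@smiles, codec@latent,
                   stringsAsFactors = FALSE)
  names(df) <- c("smiles", paste0("z_", seq_len(codec@dim) - 1L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTableCodec
#' @param bounds bounds for the reconstructed codec (default unit hypercube).
#' @export
readTableCodec <- function(path, bounds = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df) || ncol(df) < 2L)
    cmomoStop("configError", sprintf("'%s' is not a TableCodec CSV", path))
  tableCodec(df$smiles, as.matrix(df[, -1L, drop = FALSE]), bounds = bounds,
             canonicalize = FALSE)
}
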