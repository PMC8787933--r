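#' One-hot and index encodings of a categorical registry
#'
#' Classical models consume full one-hot indicators (no reference level
#' is dropped, even for two-level features); the embedding network
#' consumes integer level indices.  Column and index order always follow
#' the schema's feature order and level order — never data frequency —
#' so encodings are stable across datasets, which is what makes
#' embedding transfer between models meaningful.  The survival input set
#' appends the CA feature (taken from `ca_performed`) as the final
#' feature.
#'
#' @param registry registry data frame (see [read_registry()]).
#' @param schema a [feature_schema()].
#' @param input_set `"decision"` (23-feature analogue) or `"survival"`
#'   (decision features + CA).
#' @param allow_unknown if `TRUE`, a level absent from the schema encodes
#'   as an all-zero block (one-hot) or `NA` (index) instead of erroring.
#' @return `one_hot_encode`: object of class `encoded_matrix` with
#'   `matrix` (n x total levels, 0/1), `column_map` (data frame feature /
#'   level per column) and `feature_offsets` (named list of column
#'   ranges).  `index_encode`: object of class `index_matrix` with
#'   `matrix` (n x features, 0-based level indices) and
#'   `level_dictionaries`.
#' @export
one_hot_encode <- function(registry, schema,
                           input_set = c("decision", "survival"),
                           allow_unknown = FALSE) {
  input_set <- match.arg(input_set)
  feats <- schema_inputs(schema, input_set)
  idx <- encode_indices(registry, schema, feats, allow_unknown)
  n <- nrow(registry)
  widths <- vapply(schema$features[feats], length, integer(1))
  total <- sum(widths)
  offs <- cumsum(c(0L, widths[-length(widths)]))
  names(offs) <- feats
  m <- matrix(0L, n, total)
  for (j in seq_along(feats)) {
    ok <- !is.na(idx[, j])
    m[cbind(which(ok), offs[j] + idx[ok, j] + 1L)] <- 1L
  }
  column_map <- data.frame(
    feature = rep(feats, widths),
    level = unlist(schema$features[feats], use.names = FALSE),
    stringsAsFactors = FALSE)
  colnames(m) <- paste(column_map$feature, column_map$level, sep = "=")
  feature_offsets <- lapply(seq_along(feats), function(j)
    (offs[[j]] + 1L):(offs[[j]] + widths[[j]]))
  names(feature_offsets) <- feats
  structure(list(matrix = m, column_map = column_map,
                 feature_offsets = feature_offsets, input_set = input_set),
            class = "encoded_matrix")
}

#' @rdname one_hot_encode
#' @export
index_encode <- function(registry, schema,
                         input_set = c("decision", "survival"),
                         allow_unknown = FALSE) {
  input_set <- match.arg(input_set)
  feats <- schema_inputs(schema, input_set)
  idx <- encode_indices(registry, schema, feats, allow_unknown)
  dict <- lapply(schema$features[feats], function(lv)
    stats::setNames(seq_along(lv) - 1L, lv))
  structure(list(matrix = idx, level_dictionaries = dict,
                 features = feats, input_set = input_set),
            class = "index_matrix")
}

# Shared worker: n x features matrix of 0-based level indices.
encode_indices <- function(registry, schema, feats, allow_unknown) {
  n <- nrow(registry)
  idx <- matrix(NA_integer_, n, length(feats),
                dimnames = list(NULL, feats))
  for (j in seq_along(feats)) {
    f <- feats[j]
    v <- if (f == schema$ca_feature && !f %in% names(registry))
      as.character(registry$ca_performed) else as.character(registry[[f]])
    if (is.null(v)) stop(sprintf("registry lacks feature column '%s'", f))
    m <- match(v, schema$features[[f]])
    if (anyNA(m) && !allow_unknown) {
      bad <- which(is.na(m))[1]
      stop(sprintf("record %d: unknown level '%s' for feature '%s'",
                   bad, v[bad], f))
    }
    idx[, j] <- m - 1L
  }
  idx
}

#' Decode encodings back to level strings
#'
#' Both encodings are lossless for schema-conformant data; decoding
#' returns a data frame of level strings in schema feature order.
#'
#' @param encoded an `encoded_matrix` or `index_matrix`.
#' @param schema the schema used to encode.
#' @return data frame of feature-level strings.
#' @export
decode_encoding <- function(encoded, schema) {
  if (inherits(encoded, "index_matrix")) {
    feats <- encoded$features
    out <- lapply(feats, function(f)
      schema$features[[f]][encoded$matrix[, f] + 1L])
  } else if (inherits(encoded, "encoded_matrix")) {
    feats <- names(encoded$feature_offsets)
    out <- lapply(feats, function(f) {
      block <- encoded$matrix[, encoded$feature_offsets[[f]], drop = FALSE]
      schema$features[[f]][max.col(block, ties.method = "first")]
    })
  } else stop("not an encoding object")
  names(out) <- feats
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Export a one-hot matrix with its column map for audit
#' @param encoded an `encoded_matrix`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_encoded <- function(encoded, path) {
  stopifnot(inherits(encoded, "encoded_matrix"))
  utils::write.csv(as.data.frame(encoded$matrix), path, row.names = FALSE)
  invisible(path)
}
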