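# Plain-text model serialization.
#
# Models are written as JSON, with every double encoded as a %.17g string so
# the round trip is bit-exact (17 significant digits uniquely identify an
# IEEE-754 double). The same writer serves PCA models, SVM fits, HMMs and
# full hybrid bundles, since all are plain S3 lists.

encode_node <- function(x) {
  if (is.null(x)) return(list(t = "null"))
  if (is.numeric(x)) {
    v <- if (is.integer(x)) as.character(x) else {
      out <- sprintf("%.17g", x)
      out[!is.finite(x)] <- as.character(x[!is.finite(x)])  # Inf/-Inf/NaN/NA
      out
    }
    list(t = "num", storage = typeof(x), dim = as.integer(dim(x)),
         names = names(x), v = v)
  } else if (is.character(x)) {
    list(t = "chr", dim = as.integer(dim(x)), names = names(x), v = x)
  } else if (is.logical(x)) {
    list(t = "lgl", dim = as.integer(dim(x)), names = names(x), v = x)
  } else if (is.list(x)) {
    cls <- attr(x, "class")
    list(t = "list", class = cls, names = names(x),
         items = lapply(unname(unclass(x)), encode_node))
  } else {
    stop(sprintf("cannot serialize object of type %s", typeof(x)))
  }
}

decode_node <- function(node) {
  t <- node$t
  if (t == "null") return(NULL)
  if (t == "num") {
    v <- if (identical(node$storage, "integer")) {
      suppressWarnings(as.integer(node$v))
    } else {
      vv <- suppressWarnings(as.numeric(node$v))
      vv[node$v == "NA"] <- NA_real_
      vv
    }
    if (length(node$dim)) dim(v) <- node$dim
    if (length(node$names)) names(v) <- node$names
    return(v)
  }
  if (t == "chr" || t == "lgl") {
    v <- if (t == "lgl") as.logical(node$v) else as.character(node$v)
    if (length(node$dim)) dim(v) <- node$dim
    if (length(node$names)) names(v) <- node$names
    return(v)
  }
  if (t == "list") {
    items <- lapply(node$items, decode_node)
    if (length(node$names)) names(items) <- node$names
    if (length(node$class)) class(items) <- unlist(node$class)
    return(items)
  }
  stop(sprintf("unknown node type '%s'", t))
}

#' Serialize a model to a structured text file
#'
#' Writes any of the package's models (`"wsvm_hmm"`, `"wsvm"`,
#' `"activity_hmm"`, `"activity_pca"`, `"range_normalizer"`, ...) to a JSON
#' file. Doubles are stored at 17 significant digits, so
#' [read_model_file()] reproduces the object exactly.
#'
#' @param model The model object (an S3 list).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model_file <- function(model, path) {
  json <- jsonlite::toJSON(encode_node(model), auto_unbox = FALSE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a model written by [write_model_file()]
#'
#' @param path Path to the JSON model file.
#' @return The deserialized model object.
#' @export
read_model_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  node <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  decode_node(node)
}
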