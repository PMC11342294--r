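.MODEL_SCHEMA <- "oligomind-model-1"

#' Serialize a fitted model to JSON
#'
#' Lossless (full double precision) JSON round trip; see
#' [readMindModel()]. Refitting from the same table yields an identical
#' file.
#'
#' @param model A [MindModel-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeMindModel <- function(model, path) {
  stopifnot(is(model, "MindModel"))
  obj <- list(schema = .MODEL_SCHEMA,
              chemistry = model@chemistry,
              alpha = model@alpha, beta = model@beta,
              lines = model@lines,
              cuts = model@cuts,
              curves = lapply(model@curves, as.list),
              curve_names = names(model@curves),
              am_ma = model@amMa,
              k = model@k,
              provenance = model@provenance)
  # 17 significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path File written by [writeMindModel()].
#' @return A [MindModel-class].
#' @export
readMindModel <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse model file: ", conditionMessage(e)))
  if (!identical(obj$schema, .MODEL_SCHEMA))
    stop("model file schema mismatch: expected '", .MODEL_SCHEMA,
         "', found '", obj$schema %||% "<none>", "'")
  need <- c("chemistry", "alpha", "beta", "lines", "cuts", "curves",
            "am_ma", "k")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("model file is missing field(s): ", paste(miss, collapse = ", "))
  curves <- lapply(obj$curves, function(cv)
    data.frame(mass = as.numeric(cv$mass),
               propUpper = as.numeric(cv$propUpper)))
  names(curves) <- obj$curve_names
  lines <- as.data.frame(obj$lines)
  lines$branch <- as.integer(lines$branch)
  new("MindModel", chemistry = obj$chemistry,
      alpha = as.numeric(obj$alpha), beta = as.numeric(obj$beta),
      lines = lines, cuts = as.numeric(obj$cuts), curves = curves,
      amMa = as.numeric(obj$am_ma), k = as.integer(obj$k),
      provenance = as.list(obj$provenance))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
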