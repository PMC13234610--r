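#' Save a fitted model bundle to a JSON model file
#'
#' Serializes the z-score reference, event set, subtype model and run
#' configuration as a single JSON document with reals at 17 significant
#' digits, plus provenance (format version, creation time, seed and an
#' MD5 digest of the training z-matrix when supplied).
#'
#' @param model fitted `sustain_model`
#' @param path output path (`.json`)
#' @param zscore_model optional `zscore_model`
#' @param config optional `run_config`
#' @param Z optional training z-matrix, digested into provenance
#' @return `path`, invisibly
#' @export
save_model <- function(model, path, zscore_model = NULL, config = NULL,
                       Z = NULL) {
  es <- model$event_set
  bundle <- list(
    format = "sustainz-model",
    version = 1L,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (!is.null(config)) config$seed else NA_integer_,
    input_digest = if (!is.null(Z)) matrix_digest(Z) else NA_character_,
    event_set = list(regions = es$regions,
                     thresholds = unname(es$thresholds),
                     z_max = unname(es$z_max)),
    model = list(sequences = model$sequences,
                 fractions = model$fractions,
                 sigma = model$sigma,
                 loglik = model$loglik,
                 trace = model$trace),
    zscore = if (!is.null(zscore_model))
      list(regions = zscore_model$regions, mu = unname(zscore_model$mu),
           sd = unname(zscore_model$sd),
           n_controls = zscore_model$n_controls),
    config = if (!is.null(config)) unclass(config)
  )
  jsonlite::write_json(bundle, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a model bundle saved by [save_model()]
#'
#' @param path JSON model file
#' @return list: `model` (`sustain_model`), `zscore_model` (or `NULL`),
#'   `config` (or `NULL`), `seed`, `input_digest`, `created`
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  b <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stopf("cannot parse model file: %s",
                                          conditionMessage(e)))
  if (!identical(b$format, "sustainz-model"))
    stopf("not a sustainz model file")
  if (!identical(as.integer(b$version), 1L))
    stopf("unsupported model file version: %s", b$version)
  th <- b$event_set$thresholds
  if (is.matrix(th)) th <- lapply(seq_len(nrow(th)), function(i) th[i, ])
  if (!is.list(th)) th <- as.list(th)
  if (length(th) != length(b$event_set$regions))
    stopf("model file inconsistent: %d regions but %d threshold vectors",
          length(b$event_set$regions), length(th))
  es <- event_set(b$event_set$regions, th, b$event_set$z_max)
  seqs <- b$model$sequences
  if (is.matrix(seqs)) seqs <- lapply(seq_len(nrow(seqs)),
                                      function(i) as.integer(seqs[i, ]))
  if (!is.list(seqs)) seqs <- list(as.integer(seqs))
  seqs <- lapply(seqs, as.integer)
  for (S in seqs)
    if (!is_valid_sequence(S, es))
      stopf("model file inconsistent: invalid event sequence")
  model <- new_sustain_model(es, seqs, b$model$fractions, b$model$sigma,
                             loglik = b$model$loglik %||% NA_real_,
                             trace = b$model$trace %||% numeric(0))
  zs <- NULL
  if (!is.null(b$zscore)) {
    zs <- structure(list(regions = b$zscore$regions,
                         mu = stats::setNames(b$zscore$mu, b$zscore$regions),
                         sd = stats::setNames(b$zscore$sd, b$zscore$regions),
                         n_controls = as.integer(b$zscore$n_controls)),
                    class = "zscore_model")
    if (length(zs$mu) != length(es$regions))
      stopf("model file inconsistent: z-score reference region count")
  }
  cfg <- if (!is.null(b$config)) {
    c2 <- b$config
    class(c2) <- "run_config"
    c2
  }
  list(model = model, zscore_model = zs, config = cfg,
       seed = b$seed, input_digest = b$input_digest, created = b$created)
}

#' MD5 digest of a numeric matrix
#'
#' Canonical digest used for model-file provenance: the matrix is
#' written to a temporary file at 17 significant digits and hashed.
#'
#' @param Z numeric matrix
#' @return hex digest string
#' @export
matrix_digest <- function(Z) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(c(paste(dim(Z), collapse = "x"),
               paste(colnames(Z), collapse = ","),
               apply(format(Z, digits = 17, scientific = TRUE,
                            trim = TRUE), 1, paste, collapse = ",")),
             tmp)
  unname(tools::md5sum(tmp))
}
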