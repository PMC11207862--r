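#' Result bundles: serializable per-stage outputs
#'
#' A result bundle maps stage names to JSON-serializable result records and
#' carries provenance (config hash, master seed). [write_results()] lays it
#' out as one JSON file per stage plus a manifest with deterministic key
#' order; [read_results()] restores it losslessly.
#'
#' @param stages Named list of stage results (lists / vectors / data frames).
#' @param seed Master seed recorded in provenance.
#' @param config Optional configuration object; hashed into provenance.
#' @return An object of class `result_bundle`.
#' @export
result_bundle <- function(stages = list(), seed = NA_integer_, config = NULL) {
  if (length(stages) > 0 && (is.null(names(stages)) || any(names(stages) == "")))
    stop("all stages must be named")
  structure(list(
    stages = stages,
    provenance = list(
      seed = seed,
      config_hash = config_hash(config),
      created = format(Sys.time(), tz = "UTC")
    )
  ), class = "result_bundle")
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  s <- jsonlite::toJSON(sort_keys(config), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash (mod a Mersenne prime, exact in doubles);
  # avoids a digest dependency
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x) > 0) {
    x <- x[order(names(x))]
    lapply(x, sort_keys)
  } else if (is.list(x)) {
    lapply(x, sort_keys)
  } else x
}

#' @rdname result_bundle
#' @param bundle A `result_bundle`.
#' @param dir Output directory (created if absent).
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character(0)
  for (stage in names(bundle$stages)) {
    f <- file.path(dir, paste0(stage, ".json"))
    jsonlite::write_json(sort_keys(bundle$stages[[stage]]), f,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    files <- c(files, basename(f))
  }
  manifest <- list(stages = as.list(sort(names(bundle$stages))),
                   files = as.list(sort(files)),
                   provenance = bundle$provenance)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c("manifest.json", files))
}

#' @rdname result_bundle
#' @export
read_results <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  stages <- list()
  for (stage in manifest$stages) {
    stages[[stage]] <- jsonlite::read_json(
      file.path(dir, paste0(stage, ".json")), simplifyVector = TRUE)
  }
  b <- result_bundle(stages, seed = manifest$provenance$seed)
  b$provenance <- manifest$provenance
  b
}
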