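#' Save or load a model checkpoint
#'
#' A checkpoint is a JSON header (`<path>.json`) holding the architecture
#' description and the shapes of every parameter array, plus a flat binary
#' payload (`<path>.bin`) of the parameter and running-moment values in
#' header order, little-endian doubles.
#'
#' @param model a `voxsal_model`.
#' @param path file stem; two files are written.
#' @return invisibly the two file paths.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "voxsal_model"))
  tab <- param_table(model)
  paths <- lapply(tab, `[[`, "path")
  # running moments ride along so evaluation-mode forward passes reproduce
  for (i in seq_along(model$blocks)) {
    for (nm in c("bn1", "bn2", "proj_bn")) {
      if (is.null(model$blocks[[i]][[nm]])) next
      paths <- c(paths, list(list("blocks", i, nm, "rm")),
                 list(list("blocks", i, nm, "rv")))
    }
  }
  paths <- c(paths, list(list("stem_bn", "rm")), list(list("stem_bn", "rv")))
  arrays <- lapply(paths, function(p) get_path(model, p))
  header <- list(
    package = "voxsal",
    spec = unclass(model$spec),
    arrays = lapply(seq_along(paths), function(i) {
      a <- arrays[[i]]
      list(path = paste(vapply(paths[[i]], as.character, character(1)),
                        collapse = "/"),
           dim = if (is.null(dim(a))) length(a) else dim(a))
    }))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (a in arrays) writeBin(as.numeric(a), con, size = 8, endian = "little")
  invisible(paste0(path, c(".json", ".bin")))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
  stages <- header$spec$stages
  if (is.matrix(stages))   # simplifyVector collapses the stage list
    stages <- lapply(seq_len(nrow(stages)), function(i) stages[i, ])
  spec <- do.call(architecture_spec, c(
    header$spec[c("in_channels", "stem_channels", "stem_kernel",
                  "stem_stride", "stem_pool", "dropout", "n_classes")],
    list(stages = stages)))
  model <- build_model(spec)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  for (i in seq_len(nrow(header$arrays))) {
    parts <- strsplit(header$arrays$path[i], "/", fixed = TRUE)[[1]]
    p <- lapply(parts, function(s)
      if (grepl("^[0-9]+$", s)) as.integer(s) else s)
    dims <- header$arrays$dim[[i]]
    vals <- readBin(con, "double", n = prod(dims), size = 8,
                    endian = "little")
    cur <- get_path(model, p)
    if (!is.null(dim(cur))) dim(vals) <- dims
    model <- set_path(model, p, vals)
  }
  model
}
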