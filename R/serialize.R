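#' Save and load trained models
#'
#' A model file is a single versioned archive: a manifest (format version,
#' package version, object class, specs, seeds, and a hash of the specs)
#' together with the weight matrices. Loading verifies the format version
#' and the spec hash, and reproduces scores bit-exactly.
#'
#' @param object Any trained editnet object.
#' @param path Destination file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored object.
#' @export
save_model <- function(object, path) {
  cls <- class(object)[1]
  if (!cls %in% c("editnet_net", "editnet_ensemble", "editnet_module",
                  "editnet_component", "editnet_model")) {
    stop_("not a trained editnet object")
  }
  specs <- collect_specs(object)
  archive <- list(
    manifest = list(
      format_version = 1L,
      package_version = as.character(utils::packageVersion("editnet")),
      class = cls,
      specs = specs,
      spec_hash = spec_hash(specs)
    ),
    object = object
  )
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_("model file not found: ", path)
  archive <- readRDS(path)
  if (!is.list(archive) || is.null(archive$manifest)) {
    stop_("not an editnet model archive: ", path)
  }
  man <- archive$manifest
  if (!identical(man$format_version, 1L)) {
    stop_("unsupported model format version: ", man$format_version)
  }
  if (!identical(spec_hash(man$specs), man$spec_hash)) {
    stop_("model archive is corrupt: spec hash mismatch")
  }
  if (!identical(spec_hash(collect_specs(archive$object)), man$spec_hash)) {
    stop_("model archive is corrupt: object specs disagree with manifest")
  }
  archive$object
}

# Pull the spec/seed skeleton out of a trained object (no weights) for
# fingerprinting.
collect_specs <- function(object) {
  switch(class(object)[1],
    editnet_net = list(spec = object$spec, seed = object$seed),
    editnet_ensemble = list(spec = object$spec, seed = object$seed,
                            members = lapply(object$members, collect_specs)),
    editnet_module = list(spec = object$spec, seed = object$seed,
                          ensembles = lapply(object$ensembles, collect_specs)),
    editnet_component = list(spec = object$spec, seed = object$seed,
                             modules = lapply(object$modules, collect_specs)),
    editnet_model = list(separate = collect_specs(object$separate),
                         pooled = collect_specs(object$pooled)),
    stop_("not a trained editnet object")
  )
}
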