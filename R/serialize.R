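# JSON model serialization. One file per model, format-version tagged;
# numbers are written at full precision (17 significant digits), so a
# round trip reproduces predictions to double precision and identical
# models serialize to identical text.

FORMAT_VERSION <- "cpqsar-model-1"

scaling_to_list <- function(s) {
  if (is.null(s)) return(NULL)
  list(mean = as.list(s$mean), sd = as.list(s$sd),
       sd_convention = s$sd_convention)
}

scaling_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  structure(
    list(mean = unlist(l$mean), sd = unlist(l$sd),
         sd_convention = l$sd_convention),
    class = "scaling_params"
  )
}

#' Serialize a fitted model to JSON
#'
#' Writes a `cpann` or `qsar_mlr` model to a single JSON file (weights
#' flattened, config and scaling embedded, format-version tagged). The
#' round trip through [read_model()] reproduces predictions to full double
#' precision, and identical models always serialize to identical text.
#'
#' @param model A `cpann` or `qsar_mlr` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- model_to_list(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE,
                       digits = I(17), # lossless double round trip
                       null = "null", pretty = TRUE)
  invisible(path)
}

model_to_list <- function(model) {
  if (inherits(model, "cpann")) {
    list(
      format = FORMAT_VERSION, type = "cpann",
      task = model$task,
      grid_rows = model$grid_rows, grid_cols = model$grid_cols,
      descriptor_names = model$descriptor_names,
      kohonen_weights = as.vector(model$kohonen_weights),
      output_weights = model$output_weights,
      ed_crt = model$ed_crt,
      n_train = model$n_train,
      rmse_history = as.list(model$rmse_history),
      config = unclass(model$config),
      scaling = scaling_to_list(model$scaling)
    )
  } else if (inherits(model, "qsar_mlr")) {
    list(
      format = FORMAT_VERSION, type = "mlr",
      task = model$task,
      descriptor_names = model$descriptor_names,
      coefficients = as.list(model$coefficients),
      gram_inverse = as.vector(model$gram_inverse),
      hat_star = model$hat_star,
      n_train = model$n_train,
      sigma2 = model$sigma2,
      r_squared = model$r_squared,
      scaling = scaling_to_list(model$scaling)
    )
  } else {
    abort("can only serialize cpann or qsar_mlr models")
  }
}

#' Read a model serialized by [write_model()]
#'
#' @param path JSON file path.
#' @return The restored `cpann` or `qsar_mlr` object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_from_list(obj)
}

model_from_list <- function(obj) {
  if (!identical(obj$format, FORMAT_VERSION)) {
    abort(paste0("unsupported model format: ", obj$format %||% "<missing>"))
  }
  if (obj$type == "cpann") {
    n_neurons <- obj$grid_rows * obj$grid_cols
    w <- matrix(obj$kohonen_weights, n_neurons,
                length(obj$descriptor_names))
    colnames(w) <- obj$descriptor_names
    cfg <- obj$config
    structure(
      list(
        kohonen_weights = w,
        output_weights = obj$output_weights,
        grid_rows = obj$grid_rows, grid_cols = obj$grid_cols,
        descriptor_names = obj$descriptor_names,
        scaling = scaling_from_list(obj$scaling),
        ed_crt = obj$ed_crt,
        task = obj$task,
        config = do.call(cpann_config, cfg[setdiff(names(cfg), "toroidal")]),
        rmse_history = unlist(obj$rmse_history) %||% numeric(0),
        n_train = obj$n_train
      ),
      class = "cpann"
    )
  } else if (obj$type == "mlr") {
    p1 <- length(obj$coefficients)
    g <- matrix(obj$gram_inverse, p1, p1)
    dimnames(g) <- list(names(obj$coefficients), names(obj$coefficients))
    structure(
      list(
        coefficients = unlist(obj$coefficients),
        descriptor_names = obj$descriptor_names,
        scaling = scaling_from_list(obj$scaling),
        gram_inverse = g,
        hat_star = obj$hat_star,
        n_train = obj$n_train,
        task = obj$task,
        sigma2 = obj$sigma2,
        r_squared = obj$r_squared
      ),
      class = "qsar_mlr"
    )
  } else {
    abort(paste0("unknown model type: ", obj$type))
  }
}

#' Serialize a trained battery to a directory of JSON files
#'
#' Writes every model of a battery plus a manifest (roles, masks, seeds,
#' consensus modes) so a screening run can be reproduced from disk.
#'
#' @param battery A `qsar_battery` from [run_modeling_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_battery <- function(battery, dir) {
  stopifnot(inherits(battery, "qsar_battery"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(battery$classifiers)) {
    write_model(battery$classifiers[[nm]], file.path(dir, paste0(nm, ".json")))
  }
  for (nm in names(battery$regressors)) {
    write_model(battery$regressors[[nm]]$model,
                file.path(dir, paste0(nm, ".json")))
    write_model(battery$regressors[[nm]]$leverage_model,
                file.path(dir, paste0(nm, "-leverage.json")))
  }
  manifest <- list(
    format = "cpqsar-battery-1",
    seed = battery$seed,
    classifiers = names(battery$classifiers),
    regressors = names(battery$regressors),
    masks = lapply(battery$masks, function(m) as.integer(m)),
    descriptor_pool = battery$descriptor_pool,
    activity_threshold = battery$activity_threshold
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}

#' Restore a battery written by [write_battery()]
#'
#' @param dir Directory containing the manifest and model files.
#' @return A `qsar_battery`.
#' @export
read_battery <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "cpqsar-battery-1")) {
    abort("unsupported battery format")
  }
  classifiers <- lapply(setNames(nm = manifest$classifiers), function(nm) {
    read_model(file.path(dir, paste0(nm, ".json")))
  })
  regressors <- lapply(setNames(nm = manifest$regressors), function(nm) {
    list(model = read_model(file.path(dir, paste0(nm, ".json"))),
         leverage_model = read_model(file.path(dir, paste0(nm, "-leverage.json"))))
  })
  structure(
    list(
      classifiers = classifiers,
      regressors = regressors,
      masks = lapply(manifest$masks, function(m) as.logical(m)),
      descriptor_pool = manifest$descriptor_pool,
      activity_threshold = manifest$activity_threshold,
      seed = manifest$seed
    ),
    class = "qsar_battery"
  )
}
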