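#' Serialize a fitted model to JSON
#'
#' Writes everything needed to reproduce predictions on new raw data:
#' the standardization scaler, centers, shared width, readout weights,
#' view weights and kernels (for the regularized model), the control
#' parameters, and provenance fields (package version, seed).
#'
#' @param model an [rbfn()] or [mlaprbfn()] fit.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  kind <- class(model)[1L]
  if (!kind %in% c("rbfn", "mlaprbfn")) stop("unsupported model class")
  obj <- list(
    kind = kind,
    version = as.character(utils::packageVersion("mlaprbfn")),
    column_names = model$column_names,
    target_names = model$target_names,
    scaler = list(mean = unname(model$scaler$mean),
                  sd = unname(model$scaler$sd)),
    centers = model$basis$centers,
    sigma = model$basis$sigma,
    W = model$W
  )
  if (kind == "mlaprbfn") {
    obj$eta <- model$eta
    obj$kernels <- model$kernels
    obj$control <- unclass(model$control)
    obj$objective_trace <- model$objective_trace
  } else {
    obj$p <- model$p
    obj$seed <- model$seed
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized model
#'
#' @param path JSON path written by [save_model()].
#' @return An object of class `rbfn` or `mlaprbfn` usable with `predict()`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- list(mean = as.numeric(obj$scaler$mean),
                 sd = as.numeric(obj$scaler$sd))
  names(scaler$mean) <- obj$column_names
  names(scaler$sd) <- obj$column_names
  basis <- structure(list(centers = as.matrix(obj$centers),
                          sigma = obj$sigma,
                          p = nrow(as.matrix(obj$centers))),
                     class = "rbf_basis")
  W <- as.matrix(obj$W)
  common <- list(basis = basis, W = W, scaler = scaler,
                 column_names = obj$column_names,
                 target_names = obj$target_names)
  if (obj$kind == "mlaprbfn") {
    ctl <- obj$control
    control <- mlap_control(p = ctl$p, tmax = ctl$tmax,
                            lambda1 = ctl$lambda1, lambda2 = ctl$lambda2,
                            rho = ctl$rho, gamma = ctl$gamma,
                            kernels = ctl$kernels, eps_irls = ctl$eps_irls,
                            eps_trace = ctl$eps_trace, seed = ctl$seed)
    structure(c(common, list(eta = as.numeric(obj$eta),
                             kernels = as.integer(obj$kernels),
                             control = control,
                             objective_trace = as.numeric(obj$objective_trace))),
              class = "mlaprbfn")
  } else {
    structure(c(common, list(p = obj$p, seed = obj$seed)), class = "rbfn")
  }
}

# Resolve a run configuration from a list or a YAML/JSON file.
resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the 'yaml' package")
      }
      cfg <- yaml::read_yaml(config)
      # YAML 1.1 parses the bare key `n` as boolean FALSE; undo it
      names(cfg)[names(cfg) == "FALSE"] <- "n"
      cfg
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  config
}

# md5 of the canonical JSON form of a config, for provenance stamping.
# The output location is not part of the scientific configuration.
config_hash <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]
  config <- config[order(names(config))]
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

control_from_config <- function(config) {
  defaults <- formals(mlap_control)
  keys <- intersect(names(config), names(defaults))
  do.call(mlap_control, config[keys])
}

#' Run a cross-validation experiment and write its reports
#'
#' Loads (or generates) a cohort, runs [kfold_cv()] for the configured
#' model, and writes the metric report, agreement report, pooled
#' predictions, and the resolved configuration (with seed, package
#' version and config hash, for provenance) into `out_dir`.
#'
#' Recognised config keys: `input` (cohort CSV; omit to simulate with
#' `n`), `target` (target column, default `"dry_weight"`), `model`
#' (`"mlaprbfn"`/`"rbfn"`), `folds`, `seed`, `out_dir`, `n` (simulated
#' cohort size), plus any [mlap_control()] field.
#'
#' @param config a named list, or a path to a YAML/JSON file of one.
#' @return Invisibly, a list with the `cv_result` and the output paths.
#' @export
run_cv_experiment <- function(config) {
  config <- resolve_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  folds <- if (is.null(config$folds)) 10L else as.integer(config$folds)
  model <- if (is.null(config$model)) "mlaprbfn" else config$model
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  config$seed <- seed
  if (!is.null(config$input)) {
    target <- if (is.null(config$target)) "dry_weight" else config$target
    cohort <- read_cohort_csv(config$input, target = target)
  } else {
    n <- if (is.null(config$n)) 476L else as.integer(config$n)
    cohort <- generate_cohort(cohort_spec(n = n, seed = seed))
  }
  control <- control_from_config(config)
  control$seed <- seed
  cv <- kfold_cv(cohort, k = folds, seed = seed, model = model,
                 control = control)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  prov <- list(version = as.character(utils::packageVersion("mlaprbfn")),
               seed = seed, config_hash = config_hash(config))
  paths <- list(
    metrics = file.path(out_dir, "metrics.json"),
    agreement = file.path(out_dir, "agreement.json"),
    predictions = file.path(out_dir, "predictions.csv"),
    config = file.path(out_dir, "config.json")
  )
  jsonlite::write_json(c(unclass(cv$metrics), prov), paths$metrics,
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(unclass(cv$agreement), prov), paths$agreement,
                       auto_unbox = TRUE, digits = NA)
  pred_df <- data.frame(row = seq_len(nrow(cv$predictions)),
                        fold = cv$fold,
                        prediction = cv$predictions[, 1L],
                        reference = cohort$Y[, 1L])
  utils::write.csv(pred_df, paths$predictions, row.names = FALSE)
  jsonlite::write_json(c(config, prov), paths$config, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(cv = cv, paths = paths))
}

#' Grid search over solver hyperparameters by cross-validated RMSE
#'
#' Evaluates every combination of the supplied value lists with a shared
#' CV seed and reports the pooled-prediction RMSE per cell; failed cells
#' are recorded with `NA` and the error message, and the run continues.
#'
#' @param cohort a raw [cohort_table()].
#' @param grid named list of value vectors over [mlap_control()] fields
#'   (e.g. `list(p = c(20, 60, 140), lambda1 = 2^(-5:0))`).
#' @param k folds (default 10).
#' @param seed shared CV seed.
#' @param model `"mlaprbfn"` or `"rbfn"`.
#' @param control base [mlap_control()] supplying the non-gridded fields.
#' @return A data frame with one row per grid cell (`rmse`, `r_squared`,
#'   `error` columns appended); the arg-min row index is attached as
#'   attribute `"best"`.
#' @export
tune_grid <- function(cohort, grid, k = 10L, seed = 1L,
                      model = c("mlaprbfn", "rbfn"),
                      control = mlap_control()) {
  model <- match.arg(model)
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    stop("grid must contain at least one non-empty value list")
  }
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cells$rmse <- NA_real_
  cells$r_squared <- NA_real_
  cells$error <- NA_character_
  for (i in seq_len(nrow(cells))) {
    ctl <- control
    for (key in names(grid)) ctl[[key]] <- cells[[key]][i]
    res <- tryCatch(kfold_cv(cohort, k = k, seed = seed, model = model,
                             control = ctl),
                    error = function(e) e)
    if (inherits(res, "error")) {
      cells$error[i] <- conditionMessage(res)
    } else {
      cells$rmse[i] <- res$metrics$rmse
      cells$r_squared[i] <- res$metrics$r_squared
    }
  }
  if (all(is.na(cells$rmse))) {
    attr(cells, "best") <- NA_integer_
  } else {
    attr(cells, "best") <- which.min(cells$rmse)
  }
  cells
}
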