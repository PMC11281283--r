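#' Configuration of an end-to-end prediction study
#'
#' Bundles every knob of the simulation-to-evaluation chain: the synthetic
#' design/SPAD/scene parameters, the altitude ladder, the variable sets, the
#' model families, the 8:2 split and the RFE settings. A single master seed
#' makes the whole study reproducible; per-stage seeds are derived from it.
#'
#' @param seed Master integer seed.
#' @param altitudes Flight altitudes (meters) for the altitude study.
#' @param variable_sets Variable sets (subset of [variable_set_names()]) for
#'   the variable-set study.
#' @param models Model families to fit.
#' @param scene A [scene_params()]; its `seed` is overridden from the master
#'   seed.
#' @param effect A [spad_effect_params()].
#' @param protocol A [spad_protocol()].
#' @param glcm A [glcm_config()].
#' @param train_fraction,folds Split and CV settings.
#' @param rfe Run RFE selection before model fitting (otherwise all columns
#'   are used).
#' @param rfe_rule Learning-curve rule, `"argmax"` or `"onese"`.
#' @param resplit_per_cell Draw a fresh 8:2 split per grid cell instead of
#'   one shared split per study.
#' @param output_dir Optional directory; when set, studies write their CSV /
#'   JSON outputs there.
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1,
                         altitudes = c(20, 40, 60, 80, 100, 120),
                         variable_sets = variable_set_names(),
                         models = c("ridge", "rf", "svr", "bpnn"),
                         scene = scene_params(),
                         effect = spad_effect_params(),
                         protocol = spad_protocol(),
                         glcm = glcm_config(),
                         train_fraction = 0.8, folds = 5,
                         rfe = TRUE, rfe_rule = "argmax",
                         resplit_per_cell = FALSE,
                         output_dir = NULL) {
  stopifnot(all(variable_sets %in% variable_set_names()),
            all(models %in% c("ridge", "rf", "svr", "bpnn")))
  structure(
    list(seed = as.integer(seed), altitudes = altitudes,
         variable_sets = variable_sets, models = models, scene = scene,
         effect = effect, protocol = protocol, glcm = glcm,
         train_fraction = train_fraction, folds = folds, rfe = rfe,
         rfe_rule = rfe_rule, resplit_per_cell = resplit_per_cell,
         output_dir = output_dir),
    class = "study_config"
  )
}

# simulate the shared inputs of a study: design, SPAD tables, base scene
simulate_study_inputs <- function(config) {
  design <- generate_design(config$seed)
  truth <- simulate_true_spad(design, config$effect, seed = config$seed + 1L)
  spad <- simulate_measured_spad(truth, config$protocol, seed = config$seed + 2L)
  scene_par <- config$scene
  scene_par$seed <- config$seed + 3L
  scene <- render_scene(design, truth, scene_par)
  list(design = design, spad = spad, scene = scene)
}

# run RFE (optional) + the four models for one grid cell; returns metric rows
evaluate_cell <- function(fm, spad, config, split, label_col, label,
                          cell_seed) {
  feats <- attr(fm, "feature_names")
  x <- as.matrix(fm[, feats, drop = FALSE])
  y <- fm$spad_measured
  tr <- split$train; te <- split$test

  selected <- feats
  rfe_res <- NULL
  if (isTRUE(config$rfe) && length(feats) >= 2) {
    rfe_res <- rfe_cv(x[tr, , drop = FALSE], y[tr], folds = config$folds,
                      seed = cell_seed, rule = config$rfe_rule)
    selected <- rfe_res$optimal_set
  }
  xs <- x[, selected, drop = FALSE]

  rows <- lapply(seq_along(config$models), function(mi) {
    fam <- config$models[mi]
    model <- tryCatch(
      train_model(xs[tr, , drop = FALSE], y[tr], family = fam,
                  folds = config$folds, seed = cell_seed + mi * 1000L),
      error = function(e) {
        warning("cell ", label, " / ", fam, " failed: ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(model)) return(NULL)
    m_tr <- compute_metrics(y[tr], predict(model, xs[tr, , drop = FALSE]))
    m_te <- compute_metrics(y[te], predict(model, xs[te, , drop = FALSE]))
    row <- data.frame(
      label = label, model = fam,
      r2_train = m_tr$r2, rmse_train = m_tr$rmse,
      rrmse_train = m_tr$rrmse, rpd_train = m_tr$rpd,
      r2_test = m_te$r2, rmse_test = m_te$rmse,
      rrmse_test = m_te$rrmse, rpd_test = m_te$rpd,
      n_features = length(selected), n_train = length(tr), n_test = length(te)
    )
    names(row)[1] <- label_col
    row
  })
  list(metrics = do.call(rbind, rows), rfe = rfe_res, selected = selected)
}

study_provenance <- function(result, config, selected) {
  attr(result, "seed") <- config$seed
  # hash the scientific configuration, not where the outputs happen to land
  attr(result, "config_hash") <-
    rlang::hash(unclass(config)[setdiff(names(config), "output_dir")])
  attr(result, "selected_features") <- selected
  result
}

#' SPAD prediction across UAV flight altitudes (vegetation indices only)
#'
#' Simulates the field and base 20 m scene from the master seed, then for
#' each altitude: degrades the scene by nearest-neighbor resampling, extracts
#' the 22 vegetation indices per plot, selects variables by RFE on the
#' training split, fits the configured model families on the shared 8:2
#' split and records train/test metrics.
#'
#' @param config A [study_config()].
#' @return `data.frame` with one row per altitude x model cell (metrics for
#'   train and test partitions); attributes carry the seed, a config hash,
#'   and the per-altitude selected feature sets. If `config$output_dir` is
#'   set, metrics and RFE outputs are written there under
#'   `altitude_study/`.
#' @export
run_altitude_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  inputs <- simulate_study_inputs(config)
  split <- split_dataset(nrow(inputs$spad), config$train_fraction,
                         seed = config$seed + 4L)
  out <- list(); sel <- list(); rfes <- list()
  for (ai in seq_along(config$altitudes)) {
    alt <- config$altitudes[ai]
    scene_a <- simulate_altitude(inputs$scene, alt)
    fm <- build_feature_matrix(scene_a, inputs$spad, set = "VIs")
    cell_split <- if (config$resplit_per_cell) {
      split_dataset(nrow(fm), config$train_fraction,
                    seed = config$seed + 4L + ai)
    } else {
      split
    }
    cell <- evaluate_cell(fm, inputs$spad, config, cell_split,
                          label_col = "altitude_m", label = alt,
                          cell_seed = config$seed + 10L * ai)
    out[[ai]] <- cell$metrics
    sel[[as.character(alt)]] <- cell$selected
    rfes[[as.character(alt)]] <- cell$rfe
  }
  result <- do.call(rbind, out)
  rownames(result) <- NULL
  result <- study_provenance(result, config, sel)
  if (!is.null(config$output_dir)) {
    write_study_results(result, rfes,
                        file.path(config$output_dir, "altitude_study"))
  }
  result
}

#' SPAD prediction across the seven variable sets (20 m baseline)
#'
#' At the base altitude only, extracts the VI (22), texture (40) and wavelet
#' (20) feature tables once, then for each configured variable set pools the
#' corresponding columns, selects variables by RFE on the training split,
#' fits the model families and records train/test metrics.
#'
#' @param config A [study_config()].
#' @return `data.frame` with one row per variable set x model cell; same
#'   attributes and optional outputs as [run_altitude_study()], written
#'   under `variable_set_study/`.
#' @export
run_variable_set_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  inputs <- simulate_study_inputs(config)
  split <- split_dataset(nrow(inputs$spad), config$train_fraction,
                         seed = config$seed + 4L)
  tables <- list(
    VIs = if (any(grepl("VIs", config$variable_sets))) vi_features(inputs$scene),
    TIs = if (any(grepl("TIs", config$variable_sets)))
      texture_features(inputs$scene, config$glcm),
    DWT = if (any(grepl("DWT", config$variable_sets)))
      wavelet_features(inputs$scene)
  )
  out <- list(); sel <- list(); rfes <- list()
  for (si in seq_along(config$variable_sets)) {
    set <- config$variable_sets[si]
    fm <- build_feature_matrix(inputs$scene, inputs$spad, set = set,
                               tables = tables, glcm = config$glcm)
    cell_split <- if (config$resplit_per_cell) {
      split_dataset(nrow(fm), config$train_fraction,
                    seed = config$seed + 4L + si)
    } else {
      split
    }
    cell <- evaluate_cell(fm, inputs$spad, config, cell_split,
                          label_col = "variable_set", label = set,
                          cell_seed = config$seed + 10L * si)
    out[[si]] <- cell$metrics
    sel[[set]] <- cell$selected
    rfes[[set]] <- cell$rfe
  }
  result <- do.call(rbind, out)
  rownames(result) <- NULL
  result <- study_provenance(result, config, sel)
  if (!is.null(config$output_dir)) {
    write_study_results(result, rfes,
                        file.path(config$output_dir, "variable_set_study"))
  }
  result
}

#' Write study outputs (metrics table, learning curves, selected sets)
#'
#' @param result Metrics table from a study run.
#' @param rfes Named list of `rfe_result`s per cell (may contain `NULL`s).
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(result, rfes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result, file.path(dir, "metrics.csv"), row.names = FALSE,
            quote = FALSE)
  sel <- attr(result, "selected_features")
  jsonlite::write_json(
    list(seed = attr(result, "seed"),
         config_hash = attr(result, "config_hash"),
         selected_features = sel),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA
  )
  for (nm in names(rfes)) {
    if (!is.null(rfes[[nm]])) {
      write_rfe_results(rfes[[nm]], dir, prefix = gsub("[^A-Za-z0-9]+", "_", nm))
    }
  }
  invisible(dir)
}
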