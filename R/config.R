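#' Load and validate an experiment configuration
#'
#' Reads a YAML configuration with sections `data`, `model`, `train`,
#' `imputation` and `output`, fills defaults, rejects unknown keys, and
#' validates values through the same constructors the R API uses
#' ([train_config()], [backbone_config()], [imputation_policy()]).
#'
#' @param path YAML file path.
#' @return A validated `negdrop_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_negdrop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c("data", "model", "train", "imputation", "output")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop_negdrop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  take <- function(section, allowed) {
    s <- raw[[section]]
    if (is.null(s)) s <- list()
    bad <- setdiff(names(s), allowed)
    if (length(bad)) {
      stop_negdrop("unknown key(s) in '", section, "': ",
                   paste(bad, collapse = ", "))
    }
    s
  }
  data_keys <- c("source", "path", "label_col", "boolean_features",
                 "continuous_features", "separation",
                 "missing_count", "generator_seed", "max_missing",
                 "train_fraction", "split_seed")
  dat <- utils::modifyList(
    list(source = "synthetic", path = NULL, label_col = "label",
         separation = 1, missing_count = 275L, generator_seed = 20230713L,
         max_missing = 3L, train_fraction = 0.7, split_seed = 1L),
    take("data", data_keys))
  imp <- take("imputation", c("boolean_strategy", "fill_value", "seed",
                              "statistics"))
  if (is.null(imp$boolean_strategy)) imp$boolean_strategy <- "mode"
  if (imp$boolean_strategy %in% c("random", "bayesian") && is.null(imp$seed)) {
    imp$seed <- 1L
  }
  trn <- take("train", c(names(formals(train_config)), "ablation_axis"))
  ablation_axis <- trn$ablation_axis
  trn$ablation_axis <- NULL
  mdl <- take("model", setdiff(names(formals(backbone_config)),
                               c("n_features", "n_classes")))
  out <- utils::modifyList(list(dir = "negdrop_output"),
                           take("output", c("dir")))
  cfg <- list(data = dat,
              imputation = do.call(imputation_policy, imp),
              train = do.call(train_config, trn),
              ablation_axis = ablation_axis,
              model = mdl,
              output = out)
  class(cfg) <- "negdrop_config"
  cfg
}

#' Run an end-to-end experiment
#'
#' Executes the full pipeline -- generate or read data, filter rows by
#' missingness, impute, stratified split, multi-trial training -- and
#' writes a reproducibility manifest (`manifest.json`), per-trial metrics
#' (`metrics.json`) and the first trial's training history
#' (`history.csv`) to the output directory.
#'
#' @param config A `negdrop_config` from [load_config()].
#' @param out_dir Output directory (default from the config).
#' @return The `ExperimentManifest`-style list, invisibly.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.null(out_dir)) out_dir <- config$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- config$data
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_negdrop("[stage ", name, "] ", conditionMessage(e))
    })
  }
  input_hash <- NA_character_
  tab <- stage("data", {
    if (identical(dat$source, "synthetic")) {
      spec <- clinical_profile(separation = dat$separation,
                               missing_count = dat$missing_count,
                               seed = dat$generator_seed)
      generate_clinical_dataset(spec)
    } else if (identical(dat$source, "csv")) {
      if (is.null(dat$boolean_features) && is.null(dat$continuous_features)) {
        stop_negdrop("csv source needs boolean_features/continuous_features")
      }
      input_hash <- paste0("size:", file.size(dat$path))
      raw <- utils::read.csv(dat$path, colClasses = "character",
                             check.names = FALSE, na.strings = character(0))
      fn <- c(dat$boolean_features, dat$continuous_features)
      sch <- feature_schema(
        fn,
        c(rep("boolean", length(dat$boolean_features)),
          rep("continuous", length(dat$continuous_features))),
        class_labels = sort(unique(trimws(raw[[dat$label_col]]))))
      read_clinical_csv(dat$path, sch, label_col = dat$label_col)
    } else {
      stop_negdrop("unknown data source '", dat$source, "'")
    }
  })
  tab <- stage("filter", filter_rows_by_missingness(tab, dat$max_missing))
  split <- stage("split", stratified_split(tab, dat$train_fraction,
                                           dat$split_seed))
  mdl_args <- c(list(n_features = n_features(tab$schema),
                     n_classes = n_classes_of(tab$schema)), config$model)
  mdl_args$dropout_rate <- config$train$dropout_rate
  backbone <- do.call(backbone_config, mdl_args)
  if (!is.null(config$ablation_axis)) {
    raw_train <- tab[split$train_indices]
    raw_test <- tab[split$test_indices]
    abl <- stage("ablate", run_ablation(config$ablation_axis, raw_train,
                                        raw_test, config$train, backbone))
    utils::write.csv(abl, file.path(out_dir, "ablation.csv"),
                     row.names = FALSE)
  }
  tab <- stage("impute", impute_table(tab, config$imputation))
  train_tab <- tab[split$train_indices]
  test_tab <- tab[split$test_indices]
  res <- stage("train", run_trials(train_tab, test_tab, config$train,
                                   backbone))
  manifest <- list(
    package_version = as.character(utils::packageVersion("negdrop")),
    config = list(data = dat,
                  imputation = unclass(config$imputation),
                  train = unclass(config$train),
                  model = config$model),
    input_hash = input_hash,
    seeds = list(generator = dat$generator_seed, split = dat$split_seed,
                 base = config$train$base_seed,
                 trial = config$train$base_seed +
                   seq_len(config$train$n_trials) - 1L),
    n_rows = nrow(tab$values),
    split = list(train = length(split$train_indices),
                 test = length(split$test_indices)),
    metrics = as.list(res$summary))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(summary = as.list(res$summary),
         trials = res$trials),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  tc <- config$train
  tc$n_trials <- 1L
  model <- build_backbone(backbone, seed = tc$base_seed)
  fit <- train_model(model, train_tab, test_tab, tc)
  utils::write.csv(fit$history$steps, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
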