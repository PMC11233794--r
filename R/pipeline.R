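# End-to-end orchestration: dataset intake, stratified split, phase 1
# (preprocess + binarize), phase 2 (train + evaluate), reproducible outputs.

#' Load a labeled image dataset from per-class folders
#'
#' Scans `root_dir` for class folders (case-insensitive match of the five
#' labels, tolerating a trailing " Tumor" or " Brain MRI image" suffix) and
#' lists every readable PNG/JPEG inside, in deterministic lexicographic
#' order.  Unreadable files are skipped with a warning count.
#'
#' @param root_dir Directory containing one subfolder per class.
#' @return Manifest data.frame with columns `path`, `label`, `split` (NA
#'   until [split_dataset()]).
#' @export
load_dataset <- function(root_dir) {
  if (!dir.exists(root_dir)) stop("dataset root does not exist", call. = FALSE)
  dirs <- list.dirs(root_dir, recursive = FALSE)
  labs <- vapply(basename(dirs), match_label, character(1L))
  keep <- !is.na(labs)
  if (!any(keep)) stop("no recognized class folders under the root", call. = FALSE)
  rows <- list()
  skipped <- 0L
  for (i in which(keep)) {
    files <- list.files(dirs[i], pattern = "\\.(png|jpg|jpeg)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files, method = "radix")
    ok <- vapply(files, function(f) {
      !inherits(try(read_gray(f), silent = TRUE), "try-error")
    }, logical(1L))
    skipped <- skipped + sum(!ok)
    if (any(ok)) {
      rows[[length(rows) + 1L]] <- data.frame(
        path = unname(files[ok]), label = unname(labs[i]),
        split = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L) warning(sprintf("skipped %d unreadable file(s)", skipped),
                            call. = FALSE)
  if (length(rows) == 0L) stop("no readable images found", call. = FALSE)
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  manifest[order(manifest$label, manifest$path, method = "radix"), ,
           drop = FALSE] -> manifest
  rownames(manifest) <- NULL
  manifest
}

# Folder name -> class label, or NA.
match_label <- function(name) {
  n <- tolower(trimws(name))
  n <- sub("\\s+(tumor|brain mri images?)$", "", n)
  lv <- grade_levels()
  hit <- match(n, tolower(lv))
  if (!is.na(hit)) lv[hit] else NA_character_
}

#' Stratified train/test split
#'
#' Assigns each manifest row to `train` or `test`, stratified per class:
#' the class's rows are shuffled with the seeded generator and the first
#' `round(fraction * n_class)` become training.
#'
#' @param manifest Data.frame from [load_dataset()] (or
#'   [generate_dataset()]).
#' @param fraction Training fraction, default 0.9.
#' @param seed Integer seed.
#' @return The manifest with its `split` column filled.
#' @export
split_dataset <- function(manifest, fraction = 0.9, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)", call. = FALSE)
  counts <- table(manifest$label)
  if (any(counts < 2L)) {
    stop("every class needs at least 2 images to split", call. = FALSE)
  }
  set.seed(as.integer(seed))
  manifest$split <- NA_character_
  for (label in sort(unique(manifest$label))) {
    rows <- which(manifest$label == label)
    n_train <- round(fraction * length(rows))
    shuffled <- rows[sample.int(length(rows))]
    manifest$split[shuffled[seq_len(n_train)]] <- "train"
    if (n_train < length(rows)) {
      manifest$split[shuffled[(n_train + 1L):length(rows)]] <- "test"
    }
  }
  manifest
}

#' Pipeline configuration
#'
#' Bundles the parameters of both phases.  The threshold defaults here
#' differ from [adaptive_threshold()]'s own defaults: for tumor masks the
#' neighborhood must be larger than the largest tumor (otherwise the
#' adaptive threshold hollows out large uniform blobs) and only pixels
#' clearly brighter than their surroundings should survive, so the pipeline
#' uses `mean_plus_c` with a 201-px window and `C = 60`.
#'
#' @param size Standard image side after resizing (default 600).
#' @param wiener [wiener_params()] for denoising.
#' @param threshold_window,threshold_c,threshold_mode Parameters of
#'   [adaptive_threshold()].
#' @param se_size Structuring-element side for [clean_mask()] (default 22).
#' @param bcnn A [bcnn_config()].
#' @param split_fraction Training fraction (default 0.9).
#' @param seed Master seed for split and training.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(size = 600L,
                            wiener = wiener_params(),
                            threshold_window = 201L,
                            threshold_c = 60,
                            threshold_mode = "mean_plus_c",
                            se_size = 22L,
                            bcnn = bcnn_config(),
                            split_fraction = 0.9,
                            seed = 1L) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(size = as.integer(size), wiener = wiener,
         threshold_window = as.integer(threshold_window),
         threshold_c = threshold_c, threshold_mode = threshold_mode,
         se_size = as.integer(se_size), bcnn = bcnn,
         split_fraction = split_fraction, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Phase 1 for a single image
#'
#' Resize, Wiener-filter, adaptively threshold and morphologically open one
#' grayscale image into a candidate tumor mask.
#'
#' @param img Numeric matrix, 0--255.
#' @param config A [pipeline_config()].
#' @return Binary mask matrix.
#' @export
phase1_mask <- function(img, config = pipeline_config()) {
  pre <- preprocess_image(img, config$size, config$wiener)
  bin <- adaptive_threshold(pre, config$threshold_window, config$threshold_c,
                            config$threshold_mode)
  clean_mask(bin, se_square(config$se_size))
}

stage_log <- function(stage, t0, detail) {
  message(sprintf("[%s] %.2fs %s", stage,
                  as.numeric(Sys.time()) - t0, detail))
}

#' Run the full two-phase pipeline
#'
#' Loads the labeled dataset, performs the stratified ~90/10 split,
#' converts every image to a binary tumor mask (phase 1), trains the binary
#' CNN on the training masks and evaluates on the held-out masks (phase 2).
#' Writes to `out_dir`: the processed masks (`masks/<label>/`), the model
#' checkpoint (`model.rds`), per-epoch `train_report.csv`, `metrics.json`,
#' the split manifest (`manifest.csv`) and a machine-readable
#' `run_manifest.json` (config hash, seed, versions, counts).  Identical
#' dataset + config + seed reproduce identical outputs.
#'
#' @param root_dir Dataset root with per-class folders.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return List with `manifest`, `report`, `train_metrics`, `metrics` and
#'   output paths.
#' @export
run_pipeline <- function(root_dir, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  manifest <- tryCatch(load_dataset(root_dir),
                       error = function(e) stop("stage load: ", conditionMessage(e), call. = FALSE))
  stage_log("load", t0, sprintf("%d images, %d classes", nrow(manifest),
                                length(unique(manifest$label))))
  t0 <- as.numeric(Sys.time())
  manifest <- split_dataset(manifest, config$split_fraction, config$seed)
  stage_log("split", t0, sprintf("%d train / %d test",
                                 sum(manifest$split == "train"),
                                 sum(manifest$split == "test")))

  t0 <- as.numeric(Sys.time())
  masks <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- read_gray(manifest$path[i])
    masks[[i]] <- tryCatch(phase1_mask(img, config),
                           error = function(e) stop("stage phase1: ", conditionMessage(e), call. = FALSE))
    mdir <- file.path(out_dir, "masks", manifest$label[i])
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    write_mask(masks[[i]], file.path(mdir, basename(manifest$path[i])))
  }
  stage_log("phase1", t0, sprintf("%d masks written", length(masks)))

  t0 <- as.numeric(Sys.time())
  tr <- manifest$split == "train"
  te <- manifest$split == "test"
  cfg_bcnn <- config$bcnn
  cfg_bcnn$seed <- config$seed
  fit <- tryCatch(
    bcnn_train(masks[tr], manifest$label[tr], cfg_bcnn),
    error = function(e) stop("stage train: ", conditionMessage(e), call. = FALSE))
  stage_log("train", t0, sprintf("%d epochs, final train acc %.2f%%",
                                 nrow(fit$report$epochs),
                                 fit$report$epochs$accuracy[nrow(fit$report$epochs)]))

  t0 <- as.numeric(Sys.time())
  train_metrics <- bcnn_evaluate(fit$model, masks[tr], manifest$label[tr])
  metrics <- tryCatch(
    bcnn_evaluate(fit$model, masks[te], manifest$label[te]),
    error = function(e) stop("stage evaluate: ", conditionMessage(e), call. = FALSE))
  stage_log("evaluate", t0, sprintf("test acc %.2f%%", metrics$accuracy))

  # outputs
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(fit$report$epochs, file.path(out_dir, "train_report.csv"),
            row.names = FALSE)
  bcnn_save(fit$model, file.path(out_dir, "model.rds"))
  metrics_out <- list(
    train = list(accuracy = train_metrics$accuracy,
                 precision = train_metrics$precision,
                 recall = train_metrics$recall,
                 f_measure = train_metrics$f_measure),
    test = list(accuracy = metrics$accuracy, precision = metrics$precision,
                recall = metrics$recall, f_measure = metrics$f_measure),
    confusion = as.data.frame.matrix(metrics$confusion)
  )
  jsonlite::write_json(metrics_out, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  run_manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("bcnngrade")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_images = nrow(manifest),
    n_train = sum(tr), n_test = sum(te)
  )
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, report = fit$report,
                 model = fit$model,
                 train_metrics = train_metrics, metrics = metrics,
                 out_dir = out_dir))
}

# Strip S3 classes/functions so a config serializes cleanly to JSON.
unclass_deep <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
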