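#' Count ears in a set of images
#'
#' End-to-end counting. For `method = "cnn"`: SLIC superpixel
#' partition, per-region network prediction, stitching, binarization,
#' median-filter + watershed counting, and (when a ground standard is given
#' or auto-detected) conversion to ears per square metre. For
#' `method = "edge"`: the handcrafted Sobel baseline. Writes one overlay PNG
#' per image and a summary CSV.
#'
#' @param images character vector of image paths.
#' @param method `"cnn"` or `"edge"`.
#' @param model trained model (or checkpoint path) — required for
#'   `"cnn"`.
#' @param out_dir output directory; created if missing. `NULL` disables file
#'   output.
#' @param slic [slic_params()].
#' @param edge [edge_params()].
#' @param threshold binarization threshold.
#' @param standard `"none"`, `"auto"`, or a [ground_standard()] (or a numeric
#'   vector `c(x0, y0, ..., x3, y3)` of corners) applied to every image.
#' @param seed integer seed logged with the run (counting itself is
#'   deterministic).
#' @return data frame with one row per image (`image`, `count`,
#'   `ears_per_m2`), invisibly the per-image `count_result`s as attribute
#'   `"results"`.
#' @export
run_count <- function(images, method = c("cnn", "edge"), model = NULL,
                      out_dir = NULL, slic = slic_params(),
                      edge = edge_params(), threshold = 0.5,
                      standard = "none", seed = 1L) {
  method <- match.arg(method)
  if (method == "cnn") {
    if (is.character(model)) model <- load_model(model)
    if (is.null(model) || !isTRUE(model$trained))
      stop("`cnn` needs a trained model or checkpoint", call. = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  rows <- list(); results <- list(); failed <- 0L
  for (path in images) {
    img <- tryCatch(read_image(path), error = function(e) {
      message("skipping unreadable image ", path, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(img)) { failed <- failed + 1L; next }
    if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (method == "cnn") {
      map <- slic_segment(img, slic)
      regions <- extract_regions(img, map)
      maps <- lapply(regions, function(r) predict_region(model, r))
      prob <- stitch_predictions(regions, maps, dim(img)[1:2])
      res <- count_ears(binarize(prob, threshold))
    } else {
      res <- edge_count(img, edge)
    }
    gs <- NULL
    if (inherits(standard, "ground_standard")) {
      gs <- standard
    } else if (is.numeric(standard) && length(standard) == 8L) {
      gs <- ground_standard(matrix(standard, 4L, 2L, byrow = TRUE))
    } else if (identical(standard, "auto")) {
      gs <- tryCatch(detect_ground_standard(img), error = function(e) {
        message("ground standard not detected in ", path, "; ",
                "density not computed")
        NULL
      })
    }
    if (!is.null(gs))
      res$ears_per_m2 <- ears_per_m2(res$count, gs, dim(img)[1:2])
    id <- tools::file_path_sans_ext(basename(path))
    if (!is.null(out_dir))
      write_image(render_overlay(img, res),
                  file.path(out_dir, paste0(id, "_overlay.png")))
    rows[[length(rows) + 1L]] <- data.frame(
      image = id, count = res$count,
      ears_per_m2 = ifelse(is.na(res$ears_per_m2), NA_real_, res$ears_per_m2))
    results[[id]] <- res
  }
  if (length(images) > 0L && failed == length(images))
    stop("all images failed to load", call. = FALSE)
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image = character(), count = integer(),
               ears_per_m2 = numeric())
  if (!is.null(out_dir))
    utils::write.csv(summary, file.path(out_dir, "counts.csv"),
                     row.names = FALSE)
  attr(summary, "results") <- results
  summary
}

#' Train a counting model
#'
#' Builds a patch set (from VIA annotations and images, or synthetically),
#' splits it 80/20, optionally augments the training half, trains the
#' network, and saves a checkpoint plus history CSV.
#'
#' @param out_dir directory for `model.rds`(+`.json`) and `history.csv`;
#'   `NULL` disables file output.
#' @param annotations VIA JSON path (with `images`: named list of arrays or a
#'   directory of image files), or `NULL` to use synthetic patches.
#' @param images named list of RGB arrays or a directory path.
#' @param synthetic_n ear/background patches per class when `annotations` is
#'   `NULL`, default 100.
#' @param scene [scene_params()] for synthetic patches.
#' @param config [model_config()].
#' @param cfg [train_config()].
#' @param augment_each additional augmented copies per training patch,
#'   default 0.
#' @param aug [augment_params()].
#' @param seed master seed (patch generation, split, init, shuffling).
#' @return the trained model (with `$history`).
#' @export
run_train <- function(out_dir = NULL, annotations = NULL, images = NULL,
                      synthetic_n = 100L, scene = scene_params(),
                      config = model_config(), cfg = train_config(),
                      augment_each = 0L, aug = augment_params(), seed = 1L) {
  if (is.null(annotations)) {
    set <- generate_patchset(scene, n_per_class = synthetic_n, seed = seed)
  } else {
    if (is.character(images) && length(images) == 1L && dir.exists(images)) {
      paths <- list.files(images, full.names = TRUE,
                          pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                          ignore.case = TRUE)
      images <- stats::setNames(lapply(paths, read_image), basename(paths))
    }
    shapes <- read_via_annotations(annotations)
    if (!length(shapes)) stop("annotation source is empty", call. = FALSE)
    set <- build_patches(images, shapes)
  }
  halves <- split_train_val(set, val_fraction = 0.2, seed = seed)
  if (augment_each > 0L) {
    set.seed(seed + 1L)
    extra <- list()
    for (p in halves$train$patches)
      for (i in seq_len(augment_each))
        extra[[length(extra) + 1L]] <- augment(p, aug)
    halves$train <- new_patchset(c(halves$train$patches, extra))
  }
  cfg$seed <- seed
  model <- build_model(config, seed = seed)
  model <- train_model(model, halves$train, halves$val, cfg)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    save_model(model, file.path(out_dir, "model.rds"))
    utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  }
  model
}

#' Evaluate predicted counts against reference counts
#'
#' Joins two CSV files (columns `image`/`id` and `count`/`reference`...) on
#' image id and runs [compare_counts()]. Unmatched ids are listed in a
#' warning and excluded.
#'
#' @param pred_csv CSV of estimated counts (`image`, `count`).
#' @param ref_csv CSV of reference counts (`image`, `count`).
#' @param out optional path for the metrics CSV.
#' @return [compare_counts()] report.
#' @export
run_evaluate <- function(pred_csv, ref_csv, out = NULL) {
  read_counts <- function(path) {
    df <- utils::read.csv(path)
    idc <- intersect(c("image", "id"), names(df))[1]
    cnt <- intersect(c("count", "reference", "estimated"), names(df))[1]
    if (is.na(idc) || is.na(cnt))
      stop("CSV ", path, " needs an id and a count column", call. = FALSE)
    data.frame(id = as.character(df[[idc]]), count = df[[cnt]])
  }
  p <- read_counts(pred_csv); r <- read_counts(ref_csv)
  common <- intersect(p$id, r$id)
  if (!length(common)) stop("no matching image ids", call. = FALSE)
  missed <- setdiff(union(p$id, r$id), common)
  if (length(missed))
    warning("ids without a match excluded: ", paste(missed, collapse = ", "),
            call. = FALSE)
  rep <- compare_counts(r$count[match(common, r$id)],
                        p$count[match(common, p$id)])
  if (!is.null(out)) write_metrics_csv(rep, out)
  rep
}

#' Materialize the standard synthetic fixture suite
#'
#' Writes a set of seeded scenes (PNG + mask + instance labels + JSON
#' sidecar) to a directory, for eyeballing or for driving the CLI.
#'
#' @param out_dir destination directory.
#' @param n_scenes number of scenes, default 5.
#' @param params base [scene_params()]; seeds `1..n_scenes` are used.
#' @return paths of the written prefixes, invisibly.
#' @export
make_fixtures <- function(out_dir, n_scenes = 5L, params = scene_params()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  prefixes <- character(n_scenes)
  for (i in seq_len(n_scenes)) {
    params$seed <- i
    sc <- generate_scene(params)
    prefixes[i] <- file.path(out_dir, sprintf("scene_%02d", i))
    write_scene(sc, prefixes[i])
  }
  invisible(prefixes)
}
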