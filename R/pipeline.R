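# Deep-feature extraction adapter, pipeline configuration, and the
# end-to-end run: load-or-generate features -> select -> evaluate -> report.

#' Backbone adapter for deep-feature extraction
#'
#' Describes how image pixels become a feature vector. The `stub` backbone
#' needs no external weights: it computes per-channel summary statistics and
#' expands them through a seeded Gaussian random projection, giving
#' deterministic features suitable for exercising the pipeline offline.
#' Named CNN backbones (squeezenet, resnet50, alexnet, googlenet) require a
#' user-supplied `extract_fun` closing over the pretrained weights; weights
#' are never downloaded by this package.
#'
#' @param backbone One of `"stub"`, `"squeezenet"`, `"resnet50"`,
#'   `"alexnet"`, `"googlenet"`.
#' @param extract_fun For non-stub backbones, a function taking an image
#'   array (height x width x channels, values in `[0, 1]`) and returning a
#'   numeric feature vector — typically the penultimate pooled activation of
#'   the pretrained network.
#' @param output_dim Stub feature dimension (default 64).
#' @param layer_tag Label recorded in reports for the layer the features come
#'   from (default `"penultimate"`).
#' @param input_size Height/width the adapter resizes to before extraction
#'   (recorded; the stub is resolution-agnostic).
#' @param seed Seed of the stub's projection matrix.
#' @return An object of class `backbone_adapter`.
#' @export
backbone_adapter <- function(backbone = c("stub", "squeezenet", "resnet50",
                                          "alexnet", "googlenet"),
                             extract_fun = NULL, output_dim = 64L,
                             layer_tag = "penultimate",
                             input_size = c(227L, 227L), seed = 1L) {
  backbone <- match.arg(backbone)
  if (backbone != "stub" && !is.function(extract_fun)) {
    stop(sprintf(
      "backbone '%s' needs a user-supplied `extract_fun` wrapping its pretrained weights",
      backbone), call. = FALSE)
  }
  structure(
    list(backbone = backbone, extract_fun = extract_fun,
         output_dim = as.integer(output_dim), layer_tag = layer_tag,
         input_size = as.integer(input_size), seed = as.integer(seed)),
    class = "backbone_adapter"
  )
}

# Decode an image file to a numeric array in [0, 1]. PNG and TIFF are read
# natively; other formats need a decoder function in the adapter's stead.
read_image_array <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG images requires the 'png' package", call. = FALSE)
    }
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF images requires the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (requireNamespace("EBImage", quietly = TRUE)) {
      arr <- EBImage::imageData(EBImage::readImage(path))
      aperm(arr, if (length(dim(arr)) == 3L) c(2L, 1L, 3L) else c(2L, 1L))
    } else {
      stop("reading JPEG images requires the 'EBImage' package",
           call. = FALSE)
    }
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
}

# Stub feature extractor: moment/quantile summary per channel, expanded by a
# seeded Gaussian projection. Deterministic in (image, adapter seed).
stub_extract <- function(img, output_dim, seed) {
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  ch_stats <- function(x) {
    c(mean(x), stats::sd(x), min(x), max(x),
      stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
  }
  stats_vec <- unlist(lapply(seq_len(dim(img)[3]),
                             function(k) ch_stats(img[, , k])))
  stats_vec <- rep_len(stats_vec, 21L)  # pad/cycle to a fixed input width
  proj <- with_seed(seed,
                    matrix(stats::rnorm(output_dim * 22L), output_dim, 22L))
  as.numeric(tanh(proj %*% c(1, stats_vec)))
}

#' Extract a feature table from a directory of labelled images
#'
#' Expects the two-class layout of the colon histopathology collections:
#' class subfolders (by default `colon_aca` = adenocarcinoma, `colon_n` =
#' benign tissue) containing image files. One row per image, in sorted path
#' order, labels inferred from the subfolder name. Unreadable images are
#' skipped with a warning and listed in the result's `skipped` attribute.
#'
#' @param image_dir Directory containing the class subfolders.
#' @param adapter A [backbone_adapter()].
#' @param classes Named character vector mapping labels to subfolder names;
#'   default `c(benign = "colon_n", tumor = "colon_aca")`.
#' @return A [feature_table()] with positive class `"tumor"` and a `skipped`
#'   attribute listing unreadable files.
#' @export
extract_features <- function(image_dir, adapter = backbone_adapter(),
                             classes = c(benign = "colon_n",
                                         tumor = "colon_aca")) {
  stopifnot(inherits(adapter, "backbone_adapter"))
  if (!dir.exists(image_dir)) {
    stop("image directory not found: ", image_dir, call. = FALSE)
  }
  subdirs <- sort(list.dirs(image_dir, recursive = FALSE, full.names = FALSE))
  unknown <- setdiff(subdirs, classes)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown class subfolder(s) %s; recognized classes: %s",
                 paste(sQuote(unknown), collapse = ", "),
                 paste(sprintf("%s (%s)", classes, names(classes)),
                       collapse = ", ")), call. = FALSE)
  }
  extract_one <- if (adapter$backbone == "stub") {
    function(img) stub_extract(img, adapter$output_dim, adapter$seed)
  } else {
    adapter$extract_fun
  }
  rows <- list()
  labels <- character()
  skipped <- character()
  for (lab in names(classes)) {
    cls_dir <- file.path(image_dir, classes[[lab]])
    if (!dir.exists(cls_dir)) next
    files <- sort(list.files(cls_dir, full.names = TRUE))
    if (length(files) == 0L) {
      stop("empty class folder: ", cls_dir, call. = FALSE)
    }
    for (fp in files) {
      feat <- tryCatch(extract_one(read_image_array(fp)),
                       error = function(e) e)
      if (inherits(feat, "error")) {
        warning(sprintf("skipping unreadable image %s: %s", fp,
                        conditionMessage(feat)), call. = FALSE)
        skipped <- c(skipped, fp)
        next
      }
      rows[[length(rows) + 1L]] <- feat
      labels <- c(labels, lab)
    }
  }
  if (length(rows) == 0L) {
    stop("no readable images under ", image_dir, call. = FALSE)
  }
  values <- do.call(rbind, rows)
  colnames(values) <- sprintf("%s_%s_%03d", adapter$backbone,
                              adapter$layer_tag, seq_len(ncol(values)))
  tab <- feature_table(values, factor(labels, levels = names(classes)),
                       positive = "tumor")
  attr(tab, "skipped") <- skipped
  tab
}

#' Pipeline configuration
#'
#' Bundles exactly one input source with the optimizer, fitness, and
#' evaluation settings of an end-to-end run. The pipeline `seed` is the
#' single root of all randomness: the optimizer runs on `seed` and the
#' cross-validation folds on `seed + 1`.
#'
#' @param source The input: a [feature_table()], a [synthetic_spec()], a path
#'   to a feature-table file, or an image directory (with `adapter`).
#' @param adapter A [backbone_adapter()], used only when `source` is an image
#'   directory.
#' @param goa A [goa_config()] or `NULL` for the defaults (population 25,
#'   80 iterations on the unit box).
#' @param fitness A [fitness_spec()] or `NULL` for the defaults.
#' @param classifiers Classifiers to report, subset of
#'   `c("svm", "decision_tree")`.
#' @param out_dir Output directory for the report bundle, or `NULL` to skip
#'   writing.
#' @param seed Integer root seed.
#' @param verbose Log progress to stderr.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(source, adapter = backbone_adapter(),
                            goa = NULL, fitness = NULL,
                            classifiers = c("svm", "decision_tree"),
                            out_dir = NULL, seed = 1L, verbose = FALSE) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (!is.null(goa)) stopifnot(inherits(goa, "goa_config"))
  if (!is.null(fitness)) stopifnot(inherits(fitness, "fitness_spec"))
  structure(
    list(source = source, adapter = adapter, goa = goa, fitness = fitness,
         classifiers = classifiers, out_dir = out_dir,
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

resolve_source <- function(cfg) {
  src <- cfg$source
  if (inherits(src, "feature_table")) return(src)
  if (inherits(src, "synthetic_spec")) return(generate_features(src))
  if (is.character(src) && length(src) == 1L) {
    if (dir.exists(src)) return(extract_features(src, cfg$adapter))
    if (file.exists(src)) return(read_feature_table(src))
    stop("input source not found: ", src, call. = FALSE)
  }
  stop("`source` must be a feature table, a synthetic spec, a file path, ",
       "or an image directory", call. = FALSE)
}

#' Run the full selection-and-evaluation pipeline
#'
#' Loads or generates the feature table, runs grasshopper wrapper selection,
#' evaluates each requested classifier on the selected columns by pooled
#' stratified cross-validation, and (optionally) writes the report bundle:
#' `selection.json`, `trace.tsv`, `metrics.json`, `metrics.csv`, and
#' `log.txt` with full config and seed provenance.
#'
#' @param cfg A [pipeline_config()].
#' @return A list with `table`, `selection` (the `selection_result`),
#'   `metrics` (one row per classifier: method, sensitivity, specificity,
#'   accuracy, precision, f1, selected features), and `seed`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (cfg$verbose) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  say("pipeline seed: %d", cfg$seed)
  table <- stage("input", resolve_source(cfg))
  say("feature table: %d samples x %d features", nrow(table$values),
      ncol(table$values))

  d <- ncol(table$values)
  goa <- if (is.null(cfg$goa)) {
    goa_config(lower = 0, upper = 1, dim = d, seed = cfg$seed)
  } else {
    g <- cfg$goa
    g$seed <- cfg$seed
    g
  }
  spec <- if (is.null(cfg$fitness)) fitness_spec(seed = cfg$seed + 1L) else {
    s <- cfg$fitness
    s$seed <- cfg$seed + 1L
    s
  }

  selection <- stage("selection", select_features(table, goa = goa,
                                                  spec = spec))
  say("selected %d/%d features; fitness %.5f -> %.5f",
      selection$selected_count, d, selection$fitness_trace[1],
      selection$final_fitness)

  metric_rows <- lapply(cfg$classifiers, function(cl) {
    ev <- stage(paste0("evaluate/", cl),
                train_eval(table, mask = selection$mask, classifier = cl,
                           n_folds = spec$n_folds, seed = spec$seed))
    say("%s: accuracy %.2f%%", cl, ev$metrics$accuracy)
    data.frame(method = cl,
               sensitivity = ev$metrics$sensitivity,
               specificity = ev$metrics$specificity,
               accuracy = ev$metrics$accuracy,
               precision = ev$metrics$precision,
               f1 = ev$metrics$f1,
               selected = selection$selected_count,
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, metric_rows)

  if (!is.null(cfg$out_dir)) {
    stage("report", {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_selection(selection, file.path(cfg$out_dir, "selection.json"))
      write_trace(selection, file.path(cfg$out_dir, "trace.tsv"))
      jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                           dataframe = "rows", digits = NA)
      data.table::fwrite(metrics, file.path(cfg$out_dir, "metrics.csv"))
      writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))
    })
  }

  list(table = table, selection = selection, metrics = metrics,
       seed = cfg$seed)
}

#' Benchmark selection over several feature tables
#'
#' Runs the full pipeline on each table of a named list (for example,
#' deep-feature tables from different backbones, or synthetic stand-ins) and
#' stacks the metric panels into one comparison table, one row per
#' table-classifier pair.
#'
#' @param tables Named list of [feature_table()] objects or
#'   [synthetic_spec()]s.
#' @param ... Passed to [pipeline_config()] (e.g. `goa`, `fitness`,
#'   `classifiers`, `seed`).
#' @return A data frame with a `backbone` column plus the pipeline metric
#'   columns.
#' @export
benchmark_features <- function(tables, ...) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  rows <- lapply(names(tables), function(nm) {
    rep <- run_pipeline(pipeline_config(source = tables[[nm]], ...))
    cbind(backbone = nm, rep$metrics, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
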