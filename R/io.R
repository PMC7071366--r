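# Run configuration, persistence and plotting.

#' Build a run configuration
#'
#' @param global_seed Integer seed for the whole run.
#' @param output_dir Directory for result artifacts.
#' @param profile `"ci"` (5 networks x 50 samples) or `"full"` (30 x 100).
#' @param sets Experiment set ids to run.
#' @param centers Centre stimulus types to test.
#' @param noise_grid Centre noise variances.
#' @param train Named list of [train_config()] overrides.
#' @param n_networks,n_samples Optional protocol-scale overrides.
#' @return A validated `run_config` object.
#' @export
run_config <- function(global_seed = 1L, output_dir = "results",
                       profile = "ci",
                       sets = c("1", "2", "3", "4A", "4B", "5", "6"),
                       centers = c("ambiguous", "target"),
                       noise_grid = noise_grid_default(),
                       train = list(), n_networks = NULL, n_samples = NULL) {
  cfg <- list(global_seed = global_seed, output_dir = output_dir,
              profile = profile, sets = sets, centers = centers,
              noise_grid = noise_grid, train = train,
              n_networks = n_networks, n_samples = n_samples)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, key, why) {
    if (!ok) problems <<- c(problems, sprintf("%s: %s", key, why))
  }
  chk(is.numeric(cfg$global_seed) && length(cfg$global_seed) == 1 &&
        cfg$global_seed == round(cfg$global_seed), "global_seed",
      "must be a single integer")
  chk(is.character(cfg$output_dir) && length(cfg$output_dir) == 1, "output_dir",
      "must be a single path")
  chk(cfg$profile %in% c("ci", "full"), "profile", "must be 'ci' or 'full'")
  chk(all(cfg$sets %in% set_table()$set_id), "sets",
      paste("must be a subset of", paste(set_table()$set_id, collapse = ", ")))
  chk(all(cfg$centers %in% c("ambiguous", "target")), "centers",
      "must be a subset of ambiguous, target")
  chk(is.numeric(cfg$noise_grid) && all(cfg$noise_grid >= 0), "noise_grid",
      "must be non-negative numbers")
  if (length(cfg$train)) {
    allowed <- names(formals(train_config))
    bad <- setdiff(names(cfg$train), allowed)
    chk(length(bad) == 0, "train",
        paste("unknown fields:", paste(bad, collapse = ", ")))
    if (!is.null(cfg$train$train_noise_variance)) {
      chk(cfg$train$train_noise_variance >= 0, "train.train_noise_variance",
          "must be >= 0")
    }
  }
  for (key in c("n_networks", "n_samples")) {
    if (!is.null(cfg[[key]])) {
      chk(is.numeric(cfg[[key]]) && cfg[[key]] >= 1, key, "must be >= 1")
    }
  }
  if (length(problems)) {
    stop("invalid run configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Load and validate a YAML run configuration
#'
#' Unknown or ill-typed keys produce an error naming every offending key.
#'
#' @param path Path to a YAML file whose keys mirror [run_config()].
#' @return A `run_config` object.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("invalid run configuration:\n  unknown keys: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, raw)
}

#' Execute a configured run and persist its artifacts
#'
#' Runs the selected experiment sets and writes `results.csv` (tidy table:
#' set, centre, sigma2, probability, se, n), `per_item.csv`, and
#' `manifest.json` (seeds, protocol scale, per-network convergence) into
#' the output directory. Identical configurations produce byte-identical
#' CSVs.
#'
#' @param cfg A `run_config` (or path to a YAML file).
#' @param verbose Print progress.
#' @return The `experiment_tables` object, invisibly.
#' @export
execute_run <- function(cfg, verbose = TRUE) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  validate_run_config(cfg)
  tc <- do.call(train_config, cfg$train)
  res <- run_all(seed = as.integer(cfg$global_seed), profile = cfg$profile,
                 sets = cfg$sets, centers = cfg$centers,
                 noise_grid = cfg$noise_grid, train_cfg = tc,
                 n_networks = cfg$n_networks, n_samples = cfg$n_samples,
                 verbose = verbose)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$table, file.path(cfg$output_dir, "results.csv"),
                   row.names = FALSE)
  per_item <- do.call(rbind, lapply(res$results, function(r) r$per_item))
  rownames(per_item) <- NULL
  utils::write.csv(per_item, file.path(cfg$output_dir, "per_item.csv"),
                   row.names = FALSE)
  manifest <- list(
    global_seed = cfg$global_seed, profile = cfg$profile,
    n_networks = res$n_networks, n_samples = res$n_samples,
    sets = cfg$sets, centers = cfg$centers, noise_grid = cfg$noise_grid,
    networks = lapply(res$results, function(r) r$manifest[c("span", "converged",
                                                            "final_loss", "epochs")]))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Save / load trained networks
#'
#' Round-trips a `trained_network` (spec, weights, training history)
#' through a file.
#'
#' @param network A `trained_network`.
#' @param path Destination file.
#' @return `load_network` returns the `trained_network`.
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "trained_network"))
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "trained_network"))
  net
}

#' Export a stimulus as a PNG image
#'
#' Writes a greyscale PNG of a glyph or noisy stimulus (values rescaled to
#' the unit interval for display). Requires the `png` package.
#'
#' @param stimulus Any stimulus accepted by [stimulus_pixels()].
#' @param path Output file.
#' @export
export_glyph_png <- function(stimulus, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  px <- stimulus_pixels(stimulus)
  rng <- range(px)
  img <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  png::writePNG(1 - img, target = path) # foreground dark on white
  invisible(path)
}

#' Plot classification probability against noise level
#'
#' Line plot of the per-set mean classification probabilities over the
#' noise grid, one panel per centre type. Requires `ggplot2`.
#'
#' @param x An `experiment_tables` object from [run_all()].
#' @return A ggplot object.
#' @export
plot_results <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("the 'ggplot2' package is required for plotting")
  }
  tab <- x$table
  ggplot2::ggplot(tab, ggplot2::aes(x = sigma2, y = probability,
                                    colour = set_id, group = set_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~center) +
    ggplot2::labs(x = expression(sigma^2), y = "classification probability",
                  colour = "set") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

utils::globalVariables(c("sigma2", "probability", "set_id"))
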