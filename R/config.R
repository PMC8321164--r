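# Run configuration (YAML), run manifests, and atomic JSON output.

#' Default run configuration
#'
#' Every default matches the published setting where one exists: MHI
#' tau = 5, delta = 1, xi = 20; 30-frame units; SGD lr 0.001 with
#' milestones 100/200; 250 epochs; batch 128 (coarse/dry) and 25
#' (refinement).
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    paths = list(videos = NULL, labels = NULL, models = NULL,
                 output = NULL),
    unit_len = 30L,
    mhi = list(tau = 5, delta = 1, xi = 20),
    coarse_net = list(variant = "conv5_fc1", streams = "rgb_mhi",
                      n_classes = 3L, input_size = 32L,
                      channel_widths = c(32L, 64L, 128L, 256L, 512L)),
    train = list(coarse = "coarse", refinement = "refinement",
                 dry_hands = "dry_hands"),
    vocab = standard7,
    seed = 1L,
    wall_flip = FALSE), class = "run_config")
}

#' Load a YAML run configuration
#'
#' Values present in the file override the defaults; all referenced paths
#' must exist.
#'
#' @param path YAML file.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_in(base[[nm]], over[[nm]])
      } else {
        over[[nm]]
      }
    }
    base
  }
  cfg <- merge_in(cfg, user)
  for (nm in names(cfg$paths)) {
    p <- cfg$paths[[nm]]
    if (!is.null(p) && nm != "output" && !file.exists(p)) {
      stop("configured path does not exist: ", nm, " = ", p)
    }
  }
  cfg
}

#' Write JSON atomically (write-then-rename)
#'
#' @param x object to serialise.
#' @param path destination.
#' @export
write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a seeded, versioned run manifest
#'
#' Records the package version, the configuration (and its MD5), the seed
#' and the timestamp: enough to reproduce the run.
#'
#' @param cfg run configuration (any serialisable list).
#' @param seed the seed used.
#' @param path output JSON path.
#' @export
write_run_manifest <- function(cfg, seed, path) {
  tmp <- tempfile()
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  write_json_atomic(list(
    package = "hygiene2stage",
    version = as.character(utils::packageVersion("hygiene2stage")),
    config = cfg, config_md5 = h, seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), path)
}

#' Serialise a hygiene report to JSON
#'
#' @param report a `hygiene_report`.
#' @param path output path (atomic write).
#' @export
report_to_json <- function(report, path) {
  write_json_atomic(list(
    schema = "hygiene2stage/report/v1",
    mode = report$mode,
    hygiene_located = report$hygiene_located,
    existence = report$existence,
    durations_s = as.list(report$durations_s),
    rubbing_at_least_20s = report$rubbing_at_least_20s,
    refinement_fraction = report$refinement_fraction,
    frames = report$frames,
    unit_labels = report$unit_labels), path)
}
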