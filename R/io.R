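# Readers/writers and the flat key = value configuration format.

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are coerced
#' to numeric/logical where possible. Unknown keys are rejected by
#' [run_config()] when the result is spliced into it.
#'
#' @param path File path.
#' @return Named list of parsed values.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(toupper(val))
      else val
  }
  out
}

#' Write encoder outputs as CSV grids with a JSON parameter sidecar
#'
#' @param enc A [encode_image()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_encoding <- function(enc, dir) {
  stopifnot(inherits(enc, "scene_encoding"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(contrast = file.path(dir, "contrast.csv"),
             freq = file.path(dir, "freq.csv"),
             lambda_pos = file.path(dir, "lambda_pos.csv"),
             lambda_neg = file.path(dir, "lambda_neg.csv"),
             params = file.path(dir, "params.json"))
  write.table(enc$contrast, paths["contrast"], sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(enc$freq, paths["freq"], sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(enc$lambda_pos, paths["lambda_pos"], sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(enc$lambda_neg, paths["lambda_neg"], sep = ",",
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(c(enc$params, list(o_r = enc$o_r, dims = enc$dims)),
                       paths["params"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write per-pixel phase traces in long format
#'
#' Columns `time`, `pixel` (column-major linear index), `psi`.
#'
#' @param sim A [simulate_layer1()] (or [simulate_chain()]) result.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_phases <- function(sim, path) {
  nt <- length(sim$times)
  P <- nrow(sim$phases)
  df <- data.frame(time = rep(sim$times, each = P),
                   pixel = rep(seq_len(P), nt),
                   psi = as.vector(sim$phases))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the artifacts bundle of a pipeline run
#'
#' Emits the label map (CSV and gray-level PNG), per-group mean phases and
#' phase-std series, the central-unit phase, the lock report, metrics and a
#' manifest JSON with the resolved configuration and MD5 content hashes of
#' every output.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "vishift_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(labels = file.path(dir, "labels.csv"),
             labels_png = file.path(dir, "labels.png"),
             group_phases = file.path(dir, "group_phases.csv"),
             phase_std = file.path(dir, "phase_std.csv"),
             central = file.path(dir, "central_phase.csv"),
             locks = file.path(dir, "lock_report.json"),
             metrics = file.path(dir, "metrics.json"))
  write.table(run$labels, paths["labels"], sep = ",",
              row.names = FALSE, col.names = FALSE)
  k <- max(run$labels)
  EBImage::writeImage(t(run$labels) / max(k, 1), paths["labels_png"])
  gids <- sort(unique(as.vector(run$labels)))
  labv <- as.vector(run$labels)
  mp <- vapply(gids, function(g)
    colMeans(run$layer1$phases[labv == g, , drop = FALSE]),
    numeric(length(run$layer1$times)))
  df <- data.frame(time = run$layer1$times, mp)
  names(df) <- c("time", paste0("group_", gids))
  write.csv(df, paths["group_phases"], row.names = FALSE)
  ps <- data.frame(time = run$metrics$phase_std_times,
                   t(run$metrics$phase_std))
  names(ps) <- c("time", paste0("group_", rownames(run$metrics$phase_std)))
  write.csv(ps, paths["phase_std"], row.names = FALSE)
  write.csv(data.frame(time = run$attention$times, psi = run$attention$psi),
            paths["central"], row.names = FALSE)
  jsonlite::write_json(run$schedule, paths["locks"], digits = NA)
  jsonlite::write_json(
    list(transitions = run$transitions,
         salience_order = run$salience_order,
         entropy_per_label = as.list(run$metrics$entropy$per_label),
         mean_object_entropy = run$metrics$entropy$mean_object),
    paths["metrics"], auto_unbox = TRUE, digits = NA)
  manifest <- file.path(dir, "manifest.json")
  cfg <- run$config
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(
    list(config = cfg,
         outputs = as.list(setNames(unname(tools::md5sum(paths)), names(paths)))),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, manifest = manifest))
}
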