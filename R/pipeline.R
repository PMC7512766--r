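#' Full-model run configuration
#'
#' Collects every tunable parameter of the two-layer model with its default:
#' solver (`alpha` 0.9, `h` 0.01, `memory_length` 2000 steps), encoder
#' (`delta_o` 0.35, `sigma` 0.8, `theta_sim` 0.1, `lambda_max_pos` 0.05,
#' `lambda_max_neg` 0.02), controller (`K` 1, `t1` 20, `F_t` 10, `gap` 0.01,
#' `lock_bound` pi) and readout (`readout_time` 100, segmentation
#' `gap_threshold` 1.2, `keep_every` 10). The pipeline-level `delta_o` and
#' `sigma` defaults are wider than the op-level ones because both are
#' image-dependent: on uniform-background scenes the attainable contrast
#' stays below ~0.35, and these values keep the binding coupling and the
#' inter-object frequency gaps effective over that range (see the methods
#' vignette). `resize` (`c(width, height)`) and `blur` are passed to the
#' encoder; `seed` drives all random initial conditions; `tail` extends the
#' simulation past the last epoch.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(alpha = 0.9, h = 0.01, memory_length = 2000,
              delta_o = 0.35, sigma = 0.8, theta_sim = 0.1,
              lambda_max_pos = 0.05, lambda_max_neg = 0.02,
              K = 1, t1 = 20, F_t = 10, gap = 0.01, lock_bound = pi,
              readout_time = 100, gap_threshold = 1.2, keep_every = 10,
              seed = 1L, resize = NULL, blur = FALSE, tail = 5,
              scale = 0.2)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

resolve_scene <- function(input, config) {
  if (inherits(input, "synthetic_scene")) return(input)
  if (inherits(input, "scene_spec")) return(make_scene(input))
  if (is.character(input) && input %in% c("three-object", "five-object"))
    return(make_scene(scene_preset(input, scale = config$scale)))
  if (is.character(input)) {
    img <- read_scene_image(input)
    return(list(image = img, labels = NULL))
  }
  if (is.array(input) || is.matrix(input)) {
    img <- if (is.matrix(input)) array(rep(input, 3), c(dim(input), 3)) else input
    return(list(image = img, labels = NULL))
  }
  stop("`input` must be a preset name, scene spec, image array or file path")
}

#' Run the full visual selection-and-shifting pipeline
#'
#' Executes every stage of the model on one scene: encode the image into
#' frequencies/couplings; simulate the first-layer oscillator grid; segment
#' the scene by phase at the readout time; rank the groups by salience
#' (phase velocity); build the time-division attention schedule; replay the
#' (deterministic) first layer recording each group's hybrid signals; run
#' the actively controlled central unit over the schedule; and compute
#' synchronization and segmentation metrics.
#'
#' @param input A preset name (`"three-object"`, `"five-object"`), a
#'   [scene_spec()], a [make_scene()] result, an image array (`H x W x 3` in
#'   `[0, 1]`), or an image file path.
#' @param config A [run_config()].
#' @return An object of class `vishift_run` with the scene, encoding,
#'   segmentation `labels`, `salience_order`, `schedule`, the first-layer
#'   simulation (`layer1`), the central-unit `attention` run, `transitions`
#'   count and `metrics` (per-group phase-std series, segmentation entropy).
#' @examples
#' \donttest{
#' run <- run_pipeline("three-object",
#'                     run_config(readout_time = 20, F_t = 4, t1 = 8,
#'                                scale = 0.1, seed = 1))
#' summary(run)
#' }
#' @export
run_pipeline <- function(input, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  scene <- resolve_scene(input, config)
  enc <- encode_image(scene$image, delta_o = config$delta_o,
                      sigma = config$sigma,
                      lambda_max_pos = config$lambda_max_pos,
                      lambda_max_neg = config$lambda_max_neg,
                      theta = config$theta_sim, blur = config$blur,
                      resize = config$resize)
  fcfg1 <- frac_config(config$alpha, config$h, config$readout_time,
                       config$memory_length, config$seed)
  sim1 <- simulate_layer1(enc, fcfg1, keep_every = config$keep_every)

  nt <- length(sim1$times)
  labels <- segment_by_phase(matrix(sim1$phases[, nt], enc$dims[1], enc$dims[2]),
                             gap_threshold = config$gap_threshold)
  order <- rank_groups_by_salience(
    sim1$phases, sim1$times, as.vector(labels),
    window = c(config$readout_time / 2, config$readout_time))
  schedule <- build_schedule(order, t1 = config$t1, span = config$F_t,
                             gap = config$gap)
  t_end <- max(schedule$offset) + config$tail
  fcfg2 <- frac_config(config$alpha, config$h, t_end,
                       config$memory_length, config$seed)
  sim2 <- simulate_layer1(enc, fcfg2, groups = labels, init = sim1$init,
                          keep_every = config$keep_every)
  att <- run_attention(sim2, schedule, gains = config$K,
                       lock_bound = config$lock_bound)

  gids <- sort(unique(as.vector(labels)))
  phase_std <- vapply(seq_along(sim2$times), function(ti)
    vapply(gids, function(g)
      group_phase_std(sim2$phases, as.vector(labels), g, ti), numeric(1)),
    numeric(length(gids)))
  phase_std <- matrix(phase_std, nrow = length(gids),
                      dimnames = list(gids, NULL))
  ent <- segmentation_entropy(labels, scene$image)

  structure(list(scene = scene, encoding = enc, labels = labels,
                 salience_order = order, schedule = att$schedule,
                 layer1 = sim2, attention = att,
                 transitions = att$transitions,
                 metrics = list(phase_std = phase_std,
                                phase_std_times = sim2$times,
                                entropy = ent),
                 config = config),
            class = "vishift_run")
}

#' @export
print.vishift_run <- function(x, ...) {
  cat(sprintf("<vishift_run> %d x %d scene, %d groups, %d/%d epochs locked\n",
              nrow(x$labels), ncol(x$labels), length(unique(as.vector(x$labels))),
              x$transitions, nrow(x$schedule)))
  invisible(x)
}

#' @export
summary.vishift_run <- function(object, ...) {
  x <- object
  gids <- sort(unique(as.vector(x$labels)))
  ctr <- vapply(gids, function(g)
    mean(x$encoding$contrast[x$labels == g]), numeric(1))
  cat("Two-layer visual selection and shifting run\n")
  cat(sprintf("  scene: %d x %d pixels; segmentation found %d groups\n",
              nrow(x$labels), ncol(x$labels), length(gids)))
  cat(sprintf("  mean contrast by group: %s\n",
              paste(sprintf("%d: %.3f", gids, ctr), collapse = ", ")))
  cat(sprintf("  salience order (fastest first): %s\n",
              paste(x$salience_order, collapse = " > ")))
  cat(sprintf("  attention: %d transitions over %d epochs (F_t = %g, t1 = %g)\n",
              x$transitions, nrow(x$schedule), x$config$F_t, x$config$t1))
  print(x$schedule, row.names = FALSE)
  cat(sprintf("  mean object entropy: %.4f bits\n",
              x$metrics$entropy$mean_object))
  invisible(x)
}

#' @export
plot.vishift_run <- function(x, which = c("phase", "std"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  gids <- sort(unique(as.vector(x$labels)))
  labv <- as.vector(x$labels)
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if ("phase" %in% which) {
    mp <- t(vapply(gids, function(g)
      colMeans(x$layer1$phases[labv == g, , drop = FALSE]),
      numeric(length(x$layer1$times))))
    graphics::matplot(x$layer1$times, t(mp), type = "l", lty = 1,
                      xlab = "time", ylab = "mean unwrapped phase",
                      main = "group phase growth and central unit")
    graphics::lines(x$attention$times, x$attention$psi, lwd = 2, lty = 2)
    graphics::legend("topleft", bty = "n", lty = c(rep(1, length(gids)), 2),
                     col = c(seq_along(gids), 1), lwd = c(rep(1, length(gids)), 2),
                     legend = c(paste("group", gids), "central unit"))
  }
  if ("std" %in% which) {
    graphics::matplot(x$metrics$phase_std_times, t(x$metrics$phase_std),
                      type = "l", lty = 1, xlab = "time",
                      ylab = "phase std", main = "within-group phase spread")
    graphics::legend("topleft", bty = "n", lty = 1,
                     col = seq_len(nrow(x$metrics$phase_std)),
                     legend = paste("group", rownames(x$metrics$phase_std)))
  }
  invisible(x)
}
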