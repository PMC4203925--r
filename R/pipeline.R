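default_tracers_phantom <- function() list(
  list(name = "A",   source = "a", threshold = list(method = "percent_max", value = 40)),
  list(name = "B3h", source = "b", threshold = list(method = "absolute_suv", value = 1.4)))

#' Validate and normalize a pipeline run configuration
#'
#' Accepts a YAML file path, YAML text, or an R list. Missing settings are
#' filled with the study defaults: base dose 45 Gy, maximum escalation 150%,
#' five dose levels, QI band [0.95, 1.05], bin-mode Dice, 0.5 Gy histogram
#' bins; for a phantom input, tracer A thresholded at 40% of SUV_max and
#' tracer B at absolute SUV 1.4. A `tumor_to_muscle` threshold without a
#' value defaults to ratio 2.0 (reported in all outputs; no published ratio
#' exists for late hypoxia-tracer scans). All violations are reported in a
#' single error.
#'
#' @param x path to a YAML file, a YAML string, or a list.
#' @return An object of class `run_config`.
#' @export
validate_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    raw <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  } else if (is.list(x)) raw <- x
  else stop("config must be a YAML path, YAML text, or a list")
  if (is.null(raw)) raw <- list()

  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  known <- c("version", "case_id", "seed", "outdir", "input", "tracers",
             "prescription", "comparison")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) note(paste("unknown config keys:", paste(unknown, collapse = ", ")))

  cfg <- list(version = raw$version %||% 1L,
              case_id = raw$case_id %||% "case",
              seed = as.integer(raw$seed %||% 1L),
              outdir = raw$outdir,
              input = raw$input %||% list(phantom = list()),
              tracers = raw$tracers,
              prescription = utils::modifyList(
                list(base_dose_gy = 45, max_escalation_pct = 150,
                     n_levels = 5L, delivery_sigma_mm = 0),
                raw$prescription %||% list()),
              comparison = utils::modifyList(
                list(band = c(0.95, 1.05), dice_mode = "bin", bin_width_gy = 0.5),
                raw$comparison %||% list()))

  has_phantom <- !is.null(cfg$input$phantom)
  has_files <- !is.null(cfg$input$files)
  if (has_phantom == has_files)
    note("input must have exactly one of 'phantom' or 'files'")

  if (is.null(cfg$tracers)) {
    if (has_phantom && !has_files) cfg$tracers <- default_tracers_phantom()
    else note("tracers must be given for file input")
  }
  for (i in seq_along(cfg$tracers)) {
    tr <- cfg$tracers[[i]]
    if (is.null(tr$name)) note(sprintf("tracer %d: missing name", i))
    th <- tr$threshold
    if (is.null(th$method)) {
      note(sprintf("tracer %d: missing threshold method", i))
    } else if (!th$method %in% c("percent_max", "absolute_suv", "tumor_to_muscle")) {
      note(sprintf("tracer %d: unknown threshold method '%s'", i, th$method))
    } else {
      if (is.null(th$value))
        cfg$tracers[[i]]$threshold$value <- if (th$method == "tumor_to_muscle") 2.0
          else { note(sprintf("tracer %d: missing threshold value", i)); NA }
      else if (th$value <= 0) note(sprintf("tracer %d: threshold value must be > 0", i))
      if (th$method == "percent_max" && !is.null(th$value) && th$value > 100)
        note(sprintf("tracer %d: percent_max value must be in (0, 100]", i))
    }
    if (has_files && is.null(tr$source))
      note(sprintf("tracer %d: missing source (volume path) for file input", i))
    if (has_files && !is.null(tr$source) && !file.exists(tr$source))
      note(sprintf("tracer %d: volume file not found: %s", i, tr$source))
  }
  if (has_files) {
    for (key in c("gtv", "muscle")) {
      p <- cfg$input$files[[key]]
      if (key == "gtv" && is.null(p)) note("input$files$gtv is required")
      if (!is.null(p) && !file.exists(p)) note(paste0("input$files$", key, " not found: ", p))
    }
  }

  pr <- cfg$prescription
  if (pr$base_dose_gy <= 0) note("prescription: base_dose_gy must be > 0")
  if (pr$max_escalation_pct <= 100) note("prescription: max_escalation_pct must exceed 100")
  if (pr$n_levels < 1) note("prescription: n_levels must be >= 1")
  if (pr$delivery_sigma_mm < 0) note("prescription: delivery_sigma_mm must be >= 0")
  cm <- cfg$comparison
  if (length(cm$band) != 2L || cm$band[1] > cm$band[2]) note("comparison: band not ascending")
  if (cm$bin_width_gy <= 0) note("comparison: bin_width_gy must be > 0")
  if (!cm$dice_mode %in% c("bin", "cumulative")) note("comparison: dice_mode must be bin or cumulative")

  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full dose-painting analysis for one case
#'
#' Executes segmentation (cut-off, dose levels, degeneracy check),
#' prescription-map painting, and all pairwise plan comparisons for the
#' configured tracers. With an `outdir`, writes per-tracer NIfTI dose maps
#' and level-label volumes, per-level dose/volume CSV tables, a QI-fraction
#' and Dice CSV, and one JSON report per tracer pair carrying a provenance
#' block (seed, package version, full configuration) from which the run can
#' be regenerated. Dropped levels are logged with tracer, level index and
#' slice count.
#'
#' @param config a `run_config` from [validate_config] (or anything it
#'   accepts).
#' @return An object of class `case_result`: per-tracer cut-offs, level sets
#'   and dose maps, plus a named list of `comparison_report`s
#'   (`"<a>_vs_<b>"`).
#' @export
run_case <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$input$phantom)) {
      p <- do.call(phantom_params, c(config$input$phantom, list(seed = config$seed)))
      case <- generate_phantom(p)
      volumes <- list(a = case$tracer_a, b = case$tracer_b)
      gtv <- case$gtv; muscle <- case$muscle
    } else {
      f <- config$input$files
      gtv <- read_mask(f$gtv, label = "GTV")
      muscle <- if (!is.null(f$muscle)) read_mask(f$muscle, label = "muscle")
      volumes <- NULL
    }
    pr <- config$prescription
    params <- prescription_params(pr$base_dose_gy, pr$max_escalation_pct,
                                  pr$n_levels, pr$delivery_sigma_mm)
    stage <- "segmentation"
    tracers <- lapply(config$tracers, function(tr) {
      vol <- if (is.null(volumes)) read_volume(tr$source) else volumes[[tr$source]]
      assert_same_grid(vol, gtv)
      spec <- threshold_spec(tr$threshold$method, tr$threshold$value)
      cutoff <- compute_cutoff(vol, gtv, spec, muscle = muscle)
      levels <- build_dose_levels(vol, gtv, cutoff, params$n_levels)
      levels <- withCallingHandlers(
        drop_degenerate_levels(levels),
        message = function(m) {
          message(sprintf("[%s/%s] %s", config$case_id, tr$name,
                          sub("\n$", "", conditionMessage(m))))
          invokeRestart("muffleMessage")
        })
      list(name = tr$name, threshold = spec, cutoff_suv = cutoff, levels = levels)
    })
    stage <- "prescription"
    for (i in seq_along(tracers)) {
      map <- build_prescription_map(gtv, tracers[[i]]$levels, params)
      if (params$delivery_sigma_mm > 0)
        map <- emulate_delivery(map, params$delivery_sigma_mm)
      tracers[[i]]$map <- map
    }
    stage <- "comparison"
    comparisons <- list()
    n <- length(tracers)
    if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      key <- paste0(tracers[[i]]$name, "_vs_", tracers[[j]]$name)
      comparisons[[key]] <- compare_plans(
        tracers[[i]]$map, tracers[[i]]$levels,
        tracers[[j]]$map, tracers[[j]]$levels, gtv,
        config = c(config$comparison, list(case_id = paste(config$case_id, key))))
    }
    structure(list(case_id = config$case_id, tracers = tracers, gtv = gtv,
                   comparisons = comparisons, config = config,
                   provenance = list(seed = config$seed,
                                     package_version = as.character(utils::packageVersion("dosepaint")),
                                     config = unclass(config))),
              class = "case_result")
  }, error = function(e) {
    stop(sprintf("case '%s' failed at stage '%s': %s",
                 config$case_id, stage, conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(config$outdir)) write_case_outputs(result, config$outdir)
  result
}

# Per-level dose table in the layout of the study's dose-level summary:
# level, iso percentage, prescribed dose (Gy), volume (ccm).
level_dose_table <- function(tracer, params) {
  lv <- tracer$levels
  data.frame(level = seq_len(lv$n_levels),
             iso_pct = lv$iso_pct,
             dose_gy = tracer$map$level_doses_gy,
             volume_ccm = vapply(lv$level_masks, volume_ccm, numeric(1)),
             dropped = seq_len(lv$n_levels) %in% lv$dropped_levels)
}

write_case_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rnd <- function(x, d) round(x, d)
  for (tr in result$tracers) {
    base <- file.path(outdir, paste0(result$case_id, "_", tr$name))
    write_volume(tr$map, paste0(base, "_dose.nii.gz"))
    write_level_labels(tr$levels, paste0(base, "_levels.nii.gz"))
    tab <- level_dose_table(tr, tr$map$params)
    tab$iso_pct <- rnd(tab$iso_pct, 1)
    tab$dose_gy <- rnd(tab$dose_gy, 1)
    tab$volume_ccm <- rnd(tab$volume_ccm, 1)
    utils::write.csv(tab, paste0(base, "_levels.csv"), row.names = FALSE)
  }
  qi <- data.frame(pair = names(result$comparisons),
                   qi_fraction = rnd(vapply(result$comparisons,
                                            function(r) r$qvh$qi_fraction, numeric(1)), 2))
  utils::write.csv(qi, file.path(outdir, paste0(result$case_id, "_qi.csv")),
                   row.names = FALSE)
  dice <- do.call(rbind, lapply(names(result$comparisons), function(key) {
    d <- result$comparisons[[key]]$dice$per_level
    cbind(pair = key, d)
  }))
  utils::write.csv(dice, file.path(outdir, paste0(result$case_id, "_dice.csv")),
                   row.names = FALSE)
  for (key in names(result$comparisons)) {
    rep <- result$comparisons[[key]]
    path <- file.path(outdir, paste0(result$case_id, "_", key, ".json"))
    write_comparison_report(rep, path)
  }
  jsonlite::write_json(result$provenance,
                       file.path(outdir, paste0(result$case_id, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' Summarize a cohort of case results
#'
#' Per-case QI fractions for every tracer pairing plus their unweighted
#' arithmetic means, mean per-level Dice, and mean per-level volumes across
#' cases — the layout of a multi-case study summary.
#'
#' @param results list of `case_result` objects (>= 1), all run with the
#'   same tracer configuration.
#' @return list of data.frames: `qi` (one row per case plus a `Mean` row),
#'   `dice_mean` (pair x level), `level_volumes_mean` (tracer x level, ccm).
#' @export
summarize_cases <- function(results) {
  stopifnot(length(results) >= 1L)
  pairs <- names(results[[1]]$comparisons)
  qi <- data.frame(case = vapply(results, `[[`, character(1), "case_id"))
  for (p in pairs)
    qi[[p]] <- vapply(results, function(r) r$comparisons[[p]]$qvh$qi_fraction,
                      numeric(1))
  mean_row <- data.frame(case = "Mean")
  for (p in pairs) mean_row[[p]] <- mean(qi[[p]])
  qi <- rbind(qi, mean_row)

  dice_mean <- do.call(rbind, lapply(pairs, function(p) {
    mat <- sapply(results, function(r) r$comparisons[[p]]$dice$per_level$dice)
    mat <- matrix(mat, ncol = length(results))
    data.frame(pair = p, level = seq_len(nrow(mat)),
               mean_dice = rowMeans(mat, na.rm = TRUE))
  }))

  tracer_names <- vapply(results[[1]]$tracers, `[[`, character(1), "name")
  level_volumes_mean <- do.call(rbind, lapply(seq_along(tracer_names), function(i) {
    mat <- sapply(results, function(r)
      vapply(r$tracers[[i]]$levels$level_masks, volume_ccm, numeric(1)))
    mat <- matrix(mat, ncol = length(results))
    data.frame(tracer = tracer_names[i], level = seq_len(nrow(mat)),
               mean_volume_ccm = rowMeans(mat))
  }))

  list(qi = qi, dice_mean = dice_mean, level_volumes_mean = level_volumes_mean)
}
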