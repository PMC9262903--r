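GAZE_TSV_COLUMNS <- c("participant_id", "age_group", "trial_id", "direction",
                      "speed", "path", "t_s", "x_px", "y_px", "valid")

#' Write gaze streams to the TSV interchange dialect
#'
#' One row per sample with columns participant_id, age_group, trial_id,
#' direction, speed, path, t_s, x_px, y_px, valid (0/1). Coordinates are
#' written in raster pixels (origin top-left, y down) via the single px/deg
#' constant; invalid samples carry empty coordinate fields. The writer is
#' canonical: numbers are formatted deterministically so that
#' read -> write round-trips are byte-identical.
#'
#' @param streams list of [gaze_stream()] objects.
#' @param path output file path.
#' @param screen_px display size in pixels for the deg->px conversion.
#' @return `path`, invisibly.
#' @export
write_gaze_tsv <- function(streams, path, screen_px = c(1024, 768)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(GAZE_TSV_COLUMNS, collapse = "\t"), con)
  for (s in streams) {
    px <- deg_to_px(s$x_deg, s$y_deg, screen_px)
    xs <- ifelse(s$valid, sprintf("%.4f", px$x), "")
    ys <- ifelse(s$valid, sprintf("%.4f", px$y), "")
    writeLines(paste(s$participant_id, s$age_group, s$trial_id, s$direction,
                     s$speed, s$path, sprintf("%.9f", s$t_s), xs, ys,
                     as.integer(s$valid), sep = "\t"), con)
  }
  invisible(path)
}

#' Read gaze streams from the TSV interchange dialect
#'
#' Parses and validates the dialect written by [write_gaze_tsv()]: required
#' columns present, validity flags in \{0, 1\}, timestamps strictly
#' increasing within each trial. Malformed rows are rejected with their line
#' numbers. Pixel coordinates are converted to centered degrees once on
#' input.
#'
#' @param path input file path.
#' @param screen_px display size in pixels for the px->deg conversion.
#' @return Named list of [gaze_stream()] objects (possibly empty).
#' @export
read_gaze_tsv <- function(path, screen_px = c(1024, 768)) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header, GAZE_TSV_COLUMNS))
    stop("missing or misordered columns; expected: ",
         paste(GAZE_TSV_COLUMNS, collapse = ", "))
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c(rep("character", 6),
                                        rep("numeric", 3), "integer"),
                         na.strings = "", stringsAsFactors = FALSE)
  if (nrow(d) == 0L) return(list())
  bad_valid <- which(!d$valid %in% c(0L, 1L))
  if (length(bad_valid))
    stop("validity flag not in {0,1} at line(s) ",
         paste(utils::head(bad_valid + 1L, 5), collapse = ", "))
  streams <- list()
  for (tid in unique(d$trial_id)) {
    rows <- which(d$trial_id == tid)
    sub <- d[rows, ]
    if (nrow(sub) > 1 && any(diff(sub$t_s) <= 0)) {
      at <- rows[which(diff(sub$t_s) <= 0)[1] + 1L] + 1L
      stop("non-monotone timestamps in trial ", tid, " at line ", at)
    }
    deg <- px_to_deg(sub$x_px, sub$y_px, screen_px)
    streams[[tid]] <- gaze_stream(
      sub$t_s, deg$x, deg$y, valid = sub$valid == 1L,
      trial_id = tid, participant_id = sub$participant_id[1],
      age_group = sub$age_group[1], direction = sub$direction[1],
      speed = sub$speed[1], path = sub$path[1])
  }
  streams
}

#' Default pipeline configuration
#'
#' A run configuration for the simulate -> score -> analyze pipeline:
#' cohort-design block, behavioral presets, per-stage seeds, denominator-df
#' preference and output directory. Round-trips losslessly through YAML via
#' [read_run_config()] / [write_run_config()].
#'
#' @param out_dir output directory for the run.
#' @param seed base seed; per-stage seeds are derived deterministically.
#' @param n_per_group participants per age group.
#' @param age_groups age-group labels.
#' @param include_benchmark simulate benchmark trials.
#' @param df_method `"kenward-roger"` or `"satterthwaite"`.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("flowgaze_run_"), seed = 1L,
                       n_per_group = 20L, age_groups = AGE_GROUPS,
                       include_benchmark = TRUE,
                       df_method = "kenward-roger") {
  structure(list(
    out_dir = out_dir,
    seeds = list(cohort = as.integer(seed),
                 stats = as.integer(seed) + 1000L),
    design = list(age_groups = age_groups,
                  n_per_group = as.integer(n_per_group),
                  include_benchmark = include_benchmark,
                  trial_duration_s = 10, sample_rate_hz = 60),
    df_method = df_method), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for the writer).
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Run the full pipeline
#'
#' Executes simulate-cohort -> score -> analyze as one reproducible run:
#' writes the gaze TSV and truth table, the per-trial scores and condition
#' means, the seven statistics outputs (three-way ANOVAs for AOI looking
#' time, latency and AOIW looking time; simple effects; pairwise age post
#' hocs; asymmetry-index t-tests; benchmark ANOVA) and a JSON manifest with
#' seeds and file checksums. A failure in any stage aborts with the stage
#' name.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[flowgaze] %s done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  cohort <- stage("simulate-cohort", {
    design <- cohort_design(config$design$age_groups,
                            config$design$n_per_group,
                            config$design$include_benchmark,
                            config$design$trial_duration_s,
                            config$design$sample_rate_hz)
    co <- generate_cohort(design, seed = config$seeds$cohort)
    write_gaze_tsv(co$streams, out("gaze.tsv"))
    utils::write.csv(co$truth, out("truth.csv"), row.names = FALSE)
    co
  })

  scored <- stage("score", {
    sc <- score_dataset(cohort$streams)
    utils::write.csv(sc, out("scores.csv"), row.names = FALSE)
    sc
  })

  stage("analyze", {
    set.seed(config$seeds$stats)
    means <- aggregate_scores(scored)
    utils::write.csv(means, out("condition_means.csv"), row.names = FALSE)
    dfm <- config$df_method
    a_look <- fit_threeway_lmm(means, "looking_time_aoi_s", dfm)
    a_lat <- fit_threeway_lmm(means, "latency_aoi_s", dfm)
    a_aoiw <- fit_threeway_lmm(means, "looking_time_aoiw_s", dfm)
    utils::write.csv(as.data.frame(a_look), out("anova_looking.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(a_lat), out("anova_latency.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(a_aoiw), out("anova_aoiw.csv"), row.names = FALSE)
    se <- simple_effects_by_age(means, "looking_time_aoi_s", dfm,
                                model = attr(a_look, "model"))
    utils::write.csv(se, out("simple_effects.csv"), row.names = FALSE)
    pw <- rbind(cbind(direction = "expansion",
                      pairwise_ages(means, "looking_time_aoi_s", "expansion",
                                    dfm, model = attr(a_look, "model"))),
                cbind(direction = "contraction",
                      pairwise_ages(means, "looking_time_aoi_s", "contraction",
                                    dfm, model = attr(a_look, "model"))))
    utils::write.csv(pw, out("pairwise_ages.csv"), row.names = FALSE)
    at <- asymmetry_ttests(asymmetry_table(scored))
    utils::write.csv(at, out("asymmetry_tests.csv"), row.names = FALSE)
    bench <- scored[scored$direction == "benchmark", ]
    ba <- if (nrow(bench) > 0)
      benchmark_anova(bench, "latency_aoi_s", dfm)
    else data.frame(term = "age", F = NA, df1 = NA, df2 = NA, p = NA,
                    partial_eta_sq = NA)
    utils::write.csv(ba, out("benchmark_anova.csv"), row.names = FALSE)
  })

  manifest <- stage("manifest", {
    files <- c("gaze.tsv", "truth.csv", "scores.csv", "condition_means.csv",
               "anova_looking.csv", "anova_latency.csv", "anova_aoiw.csv",
               "simple_effects.csv", "pairwise_ages.csv",
               "asymmetry_tests.csv", "benchmark_anova.csv")
    m <- list(package_version = as.character(utils::packageVersion("flowgaze")),
              format_version = "1",
              seeds = config$seeds,
              df_method = config$df_method,
              design = config$design,
              checksums = as.list(tools::md5sum(file.path(config$out_dir, files))))
    names(m$checksums) <- files
    jsonlite::write_json(m, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    m
  })
  invisible(manifest)
}
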