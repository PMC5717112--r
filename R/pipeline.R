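# Orchestration: per-subject runs (preprocess -> segment -> haemodynamics)
# and the full two-cohort comparison with shared-geometry statistics.

#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline in one place; the configuration
#' (and its hash) is embedded in every report for provenance.
#'
#' @param viscosity_cP dynamic viscosity, cP.
#' @param noise_floor_fraction noise-mask threshold fraction.
#' @param segment_threshold PC-MRA segmentation threshold fraction.
#' @param keep_band optional axial slice range for segmentation.
#' @param sd_threshold static-tissue velocity sd bound (eddy correction).
#' @param inclusion_fraction shared-geometry coverage fraction.
#' @param alpha significance level for p-value maps.
#' @param min_n minimum per-cohort samples per tested location.
#' @param seed master seed for all randomized steps (registration starts).
#' @param out_dir optional output directory; when set, runs write CSV/NIfTI
#'   outputs there.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(viscosity_cP = 3.2,
                            noise_floor_fraction = 0.1,
                            segment_threshold = 0.02,
                            keep_band = NULL,
                            sd_threshold = 0.05,
                            inclusion_fraction = 0.6,
                            alpha = 0.05,
                            min_n = 7,
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(viscosity_cP > 0,
            noise_floor_fraction > 0, noise_floor_fraction < 1,
            segment_threshold > 0, segment_threshold < 1,
            inclusion_fraction > 0, inclusion_fraction <= 1,
            alpha > 0, alpha < 1, min_n >= 1)
  cfg <- list(viscosity_cP = viscosity_cP,
              noise_floor_fraction = noise_floor_fraction,
              segment_threshold = segment_threshold,
              keep_band = keep_band,
              sd_threshold = sd_threshold,
              inclusion_fraction = inclusion_fraction,
              alpha = alpha, min_n = min_n,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Hash of a pipeline configuration
#'
#' MD5 of the JSON-serialized configuration; embedded in outputs so equal
#' hashes imply equal numeric results.
#'
#' @param config \code{pipeline_config}.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{pipeline_config} (for \code{read_pipeline_config}).
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

#' @rdname read_pipeline_config
#' @param config \code{pipeline_config} to write.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the single-subject pipeline
#'
#' Pre-processing (eddy-current correction, unwrapping, noise masking,
#' PC-MRA), segmentation, wall extraction and the peak-systolic
#' haemodynamic summary. Any stage error produces a machine-readable
#' failure record instead of aborting the caller.
#'
#' @param config \code{pipeline_config}.
#' @param subject in-memory subject (list with \code{velocity},
#'   \code{magnitude}, \code{id}) or a directory path readable by
#'   \code{\link{read_subject}}.
#' @return list: \code{summary} (one-row tibble), \code{mask}, \code{wall},
#'   \code{wss}, \code{el}, \code{peak_speed} (3D array), \code{pcmra},
#'   \code{failure} (NULL on success, else list(id, stage, message)).
#' @export
run_subject <- function(config, subject) {
  if (is.character(subject)) {
    subject <- tryCatch(read_subject(subject), error = function(e) e)
    if (inherits(subject, "error")) {
      return(list(failure = list(id = NA_character_, stage = "read",
                                 message = conditionMessage(subject))))
    }
  }
  id <- subject$id %||% "subject"
  stage <- "preprocess"
  res <- tryCatch({
    pre <- preprocess_subject(subject$velocity, subject$magnitude,
                              floor_fraction = config$noise_floor_fraction,
                              sd_threshold = config$sd_threshold)
    stage <- "segment"
    mask <- segment_vessel(pre$pcmra, config$segment_threshold,
                           config$keep_band, vessel_support = pre$mask)
    wall <- extract_wall(mask)
    stage <- "hemodynamics"
    summ <- summarize_hemodynamics(pre$field, mask, wall,
                                   mu = viscosity(config$viscosity_cP))
    wss <- attr(summ, "wss_map")
    el <- attr(summ, "el_map")
    peak_arr <- attr(summ, "peak_frame_arr")
    summ_row <- dplyr::mutate(summ, id = id, .before = 1)
    list(summary = summ_row, mask = mask, wall = wall, wss = wss, el = el,
         peak_speed = speed_volume(peak_arr), pcmra = pre$pcmra,
         failure = NULL)
  }, error = function(e) {
    list(failure = list(id = id, stage = stage, message = conditionMessage(e)))
  })
  if (is.null(res$failure) && !is.null(config$out_dir)) {
    dir.create(file.path(config$out_dir, id), showWarnings = FALSE,
               recursive = TRUE)
    utils::write.csv(res$summary,
                     file.path(config$out_dir, id, "summary.csv"),
                     row.names = FALSE)
    write_wall_table(res$wss, file.path(config$out_dir, id, "wss_wall.tsv"))
  }
  res
}

#' Run the full two-cohort comparison
#'
#' Runs every subject, builds the shared geometry from the pooled masks of
#' both cohorts, maps each subject's peak-systolic speed, wall |WSS| and
#' energy-loss density into it, averages per cohort, and computes p-value
#' maps with significance fractions plus the conventional group table.
#'
#' @param config \code{pipeline_config}.
#' @param cohorts output of \code{\link{generate_cohorts}}, or a list with
#'   \code{stented} and \code{stentless} lists of subjects/paths.
#' @return object of class \code{cohort_report}: list with
#'   \code{group_table}, \code{fractions} (tibble metric x direction),
#'   \code{pmaps} (velocity, wss, el), \code{shared}, \code{summaries},
#'   \code{excluded}, \code{config}, \code{config_hash}.
#' @export
run_cohort_comparison <- function(config, cohorts) {
  subjects <- c(cohorts$stented, cohorts$stentless)
  groups <- c(rep("stented", length(cohorts$stented)),
              rep("stentless", length(cohorts$stentless)))
  if (min(table(groups)) < 2) {
    stop("need at least two subjects per group", call. = FALSE)
  }
  runs <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    runs[[i]] <- run_subject(config, subjects[[i]])
  }
  failed <- vapply(runs, function(r) !is.null(r$failure), TRUE)
  excluded <- lapply(runs[failed], `[[`, "failure")
  ok <- which(!failed)
  if (length(ok) < 4) stop("too few successful subjects", call. = FALSE)

  masks <- lapply(runs[ok], `[[`, "mask")
  shared <- build_shared_geometry(masks, config$inclusion_fraction,
                                  seed = config$seed)

  # one affine registration per subject, shared by all three value maps
  fits <- lapply(seq_along(ok), function(j) {
    register_masks(runs[[ok[j]]]$mask, shared$mask, "affine",
                   init = shared$transforms[[j]],
                   seed = derive_seed(config$seed, ok[j]))
  })
  map_one <- function(j, what) {
    r <- runs[[ok[j]]]
    tryCatch(switch(what,
      velocity = map_subject(r$peak_speed, r$mask, shared, "volume",
                             fit = fits[[j]]),
      el = map_subject(r$el$density, r$mask, shared, "volume",
                       fit = fits[[j]]),
      # flagged/inlet-outlet wall points are not vessel wall; they enter
      # the shared map as missing
      wss = map_subject(ifelse(r$wss$excluded, NA_real_, r$wss$wss_mag),
                        r$mask, shared, "wall",
                        wall = r$wss, fit = fits[[j]])),
      aortaflow_registration_error = function(e) NULL)
  }

  report_fractions <- list()
  pmaps <- list()
  for (what in c("velocity", "wss", "el")) {
    maps <- lapply(seq_along(ok), function(j) map_one(j, what))
    reg_ok <- !vapply(maps, is.null, TRUE)
    gA <- groups[ok] == "stented" & reg_ok
    gB <- groups[ok] == "stentless" & reg_ok
    cmA <- cohort_average(maps[gA])
    cmB <- cohort_average(maps[gB])
    pm <- pvalue_map(cmA, cmB, alpha = config$alpha, min_n = config$min_n)
    pmaps[[what]] <- pm
    fr <- attr(pm, "fractions")
    fr$metric <- what
    report_fractions[[what]] <- fr
  }

  summaries <- dplyr::bind_rows(lapply(runs[ok], `[[`, "summary"))
  summaries$group <- groups[ok]
  group_table <- compare_group_summaries(
    summaries[summaries$group == "stented", ],
    summaries[summaries$group == "stentless", ])

  report <- structure(list(
    group_table = group_table,
    fractions = dplyr::bind_rows(report_fractions),
    pmaps = pmaps,
    shared = shared,
    summaries = summaries,
    excluded = excluded,
    config = config,
    config_hash = config_hash(config)
  ), class = "cohort_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report$group_table,
                     file.path(config$out_dir, "group_table.csv"),
                     row.names = FALSE)
    utils::write.csv(report$fractions,
                     file.path(config$out_dir, "significance_fractions.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
                     row.names = FALSE)
    writeLines(report$config_hash,
               file.path(config$out_dir, "config_hash.txt"))
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects (%d excluded), config %s\n",
              nrow(x$summaries), length(x$excluded),
              substr(x$config_hash, 1, 8)))
  cat("\nGroup comparison (stented = A, stentless = B):\n")
  print(x$group_table)
  cat("\nSignificance fractions (% of testable locations):\n")
  print(x$fractions)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
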