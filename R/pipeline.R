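# End-to-end study orchestration: phantom cohort -> reconstruction ->
# wall measurement -> orientation mapping -> symmetry scoring -> cohort
# statistics, under a single master seed.

#' Build a study run configuration
#'
#' All parameters of a full synthetic study in one serializable list. The
#' default cohort mirrors a small biopsy series: 6 thin-intima and 6
#' intimal-hyperplasia sections (the 12 negatives) plus 4 GCA-like
#' sections.
#'
#' @param seed master seed; with the config it reproduces every numeric
#'   output exactly.
#' @param n_normal,n_hyperplasia,n_gca cohort sizes per class (0 omits the
#'   class).
#' @param class_specs per-class parameter ranges ([default_class_specs()]).
#' @param projection_method z-projection statistic (default "mean").
#' @param n_profiles,selection,n_angles,smoothing_window_um,min_jump_fraction
#'   wall measurement parameters, see [measure_layers()].
#' @param gabor a [gabor_bank()].
#' @param orientation_floor relative response floor for
#'   [orientation_map()].
#' @param symmetry_floor confidence floor for [symmetry_score()].
#' @param do_orientation logical; compute orientation maps and symmetry
#'   scores (the costly stages).
#' @param phantom list of overrides applied to every [phantom_spec()]
#'   (e.g. \code{image_size_px}, \code{n_slices}, \code{speckle_sigma}).
#' @param write_images logical; write per-sample TIFF/PNG artifacts when
#'   an output directory is given.
#' @return object of class \code{run_config}.
#' @export
study_config <- function(seed = 1L, n_normal = 6L, n_hyperplasia = 6L,
                         n_gca = 4L, class_specs = default_class_specs(),
                         projection_method = "mean", n_profiles = 3L,
                         selection = "best_confidence", n_angles = 64L,
                         smoothing_window_um = 6, min_jump_fraction = 0.15,
                         gabor = gabor_bank(), orientation_floor = 0.05,
                         symmetry_floor = 0.1, do_orientation = TRUE,
                         phantom = list(), write_images = FALSE) {
  cfg <- structure(list(
    seed = as.integer(seed), n_normal = as.integer(n_normal),
    n_hyperplasia = as.integer(n_hyperplasia), n_gca = as.integer(n_gca),
    class_specs = class_specs, projection_method = projection_method,
    n_profiles = as.integer(n_profiles), selection = selection,
    n_angles = as.integer(n_angles),
    smoothing_window_um = smoothing_window_um,
    min_jump_fraction = min_jump_fraction,
    gabor = unclass(gabor), orientation_floor = orientation_floor,
    symmetry_floor = symmetry_floor,
    do_orientation = isTRUE(do_orientation), phantom = phantom,
    write_images = isTRUE(write_images)
  ), class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$n_normal >= 0, cfg$n_hyperplasia >= 0, cfg$n_gca >= 0,
            cfg$n_profiles >= 1, cfg$n_angles >= 4,
            cfg$projection_method %in% c("mean", "max", "median"),
            cfg$selection %in% c("best_confidence", "fixed_angles"),
            cfg$min_jump_fraction > 0, cfg$min_jump_fraction < 1)
  if (cfg$n_normal + cfg$n_hyperplasia + cfg$n_gca < 1) {
    stop("the cohort must contain at least one sample")
  }
  invisible(cfg)
}

#' Serialize a run configuration to YAML
#'
#' @param config a [study_config()].
#' @param path output YAML file.
#' @return \code{path}, invisibly.
#' @export
config_to_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Fields missing from the file take the [study_config()] defaults; the
#' round trip serialize -> parse is the identity on configurations.
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- study_config()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (nm == "class_specs") {
      for (cl in names(v)) {
        for (f in names(v[[cl]])) base$class_specs[[cl]][[f]] <- v[[cl]][[f]]
      }
    } else if (nm %in% c("gabor", "phantom")) {
      base[[nm]] <- v
    } else {
      base[[nm]] <- if (is.integer(base[[nm]])) as.integer(v) else v
    }
  }
  validate_run_config(base)
  base
}

study_log <- function(env, stage, msg) {
  env$log <- c(env$log, sprintf("[%s] %s", stage, msg))
}

#' Run a full synthetic study
#'
#' Generates the configured cohort, processes every section through
#' z-projection, center estimation, wall measurement and (optionally)
#' orientation mapping plus symmetry scoring, and assembles per-sample
#' rows and cohort summaries: measured-I/M medians and IQRs per group,
#' pairwise rank-sum p values, Pearson r between measured and true intima
#' and media thickness, and symmetry-score separation between the intact
#' classes and the GCA-like class. A failed stage flags the sample and the
#' run continues.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory; when given, writes
#'   \code{report.csv}, \code{summary.json}, \code{run.log} and (with
#'   \code{write_images}) per-sample TIFF/PNG artifacts.
#' @return object of class \code{tab_study}: \code{report} (one row per
#'   sample), \code{summary} (cohort statistics and notices),
#'   \code{config}, \code{log}.
#' @export
run_study <- function(config, out_dir = NULL) {
  validate_run_config(config)
  env <- new.env(); env$log <- character(0)
  study_log(env, "config", sprintf("seed=%d cohort=%d+%d+%d", config$seed,
                                   config$n_normal, config$n_hyperplasia,
                                   config$n_gca))
  classes <- c(normal = config$n_normal, hyperplasia = config$n_hyperplasia,
               gca = config$n_gca)
  classes <- classes[classes > 0]
  phantoms <- list()
  manifest <- NULL
  for (ci in seq_along(classes)) {
    cl <- names(classes)[ci]
    coh <- do.call(generate_cohort, c(list(
      n_per_class = classes[[ci]], classes = cl,
      class_specs = config$class_specs,
      seed = derive_seed(config$seed, match(cl, c("normal", "hyperplasia",
                                                  "gca")) * 100000L)
    ), config$phantom))
    phantoms <- c(phantoms, coh)
    manifest <- rbind(manifest, attr(coh, "manifest"))
    study_log(env, "phantom", sprintf("generated %d %s phantoms",
                                      classes[[ci]], cl))
  }

  bank <- do.call(gabor_bank, config$gabor)
  rows <- vector("list", length(phantoms))
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    id <- manifest$sample_id[i]
    row <- list(sample_id = id, true_class = manifest$class[i],
                true_im_ratio = manifest$true_im_ratio[i],
                true_intima_um = manifest$intima_um[i],
                true_media_um = manifest$media_um[i],
                intima_um = NA_real_, media_um = NA_real_,
                adventitia_um = NA_real_, im_ratio = NA_real_,
                class_label = "unquantifiable", n_profiles_used = 0L,
                center_row = NA_real_, center_col = NA_real_,
                symmetry_score = NA_real_, n_pixel_pairs = NA_integer_,
                mean_axial_mismatch_deg = NA_real_,
                error = "")
    sec <- zproject(ph$stack, config$projection_method)
    res <- tryCatch({
      ctr <- estimate_center(sec)
      m <- measure_layers(sec, ctr, n_profiles = config$n_profiles,
                          selection = config$selection,
                          n_angles = config$n_angles,
                          smoothing_window_um = config$smoothing_window_um,
                          min_jump_fraction = config$min_jump_fraction)
      row$intima_um <- m$intima_um; row$media_um <- m$media_um
      row$adventitia_um <- m$adventitia_um; row$im_ratio <- m$im_ratio
      row$class_label <- m$class_label
      row$n_profiles_used <- m$n_profiles_used
      row$center_row <- ctr[1]; row$center_col <- ctr[2]
      if (config$do_orientation) {
        omap <- orientation_map(sec, bank, config$orientation_floor)
        mask <- wall_annulus_mask(m, dim(sec$pixels), sec$pixel_size_um)
        sym <- symmetry_score(omap, ctr, mask, config$symmetry_floor)
        row$symmetry_score <- sym$score
        row$n_pixel_pairs <- sym$n_pixel_pairs
        row$mean_axial_mismatch_deg <- sym$mean_axial_mismatch_deg
        if (!is.null(out_dir) && config$write_images) {
          write_orientation_tiff(omap, file.path(out_dir,
                                                 paste0(id, "_orient.tif")),
                                 file.path(out_dir, paste0(id, "_orient.png")))
        }
      }
      if (!is.null(out_dir) && config$write_images) {
        write_section_tiff(sec, file.path(out_dir, paste0(id, "_section.tif")))
      }
      "ok"
    }, error = function(e) conditionMessage(e))
    if (!identical(res, "ok")) {
      row$error <- res
      study_log(env, "sample", sprintf("%s FAILED: %s", id, res))
    } else {
      study_log(env, "sample", sprintf(
        "%s measured I/M=%s class=%s symmetry=%s", id,
        format(row$im_ratio, digits = 4), row$class_label,
        format(row$symmetry_score, digits = 4)))
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)

  summary <- summarize_study(report, env)
  out <- structure(list(config = config, report = report,
                        summary = summary, log = env$log),
                   class = "tab_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    writeLines(env$log, file.path(out_dir, "run.log"))
    config_to_yaml(config, file.path(out_dir, "config.yaml"))
  }
  out
}

summarize_study <- function(report, env) {
  notices <- character(0)
  groups <- split(report, report$true_class)
  im_summary <- lapply(groups, function(g) {
    q <- g$im_ratio[!is.na(g$im_ratio)]
    list(n = nrow(g), n_quantifiable = length(q),
         median_im = if (length(q)) stats::median(q) else NA,
         iqr_im = if (length(q)) iqr_pair(q) else c(NA, NA))
  })
  pairs <- utils::combn(names(groups), min(2, length(groups)),
                        simplify = FALSE)
  rank_sum <- list()
  if (length(groups) >= 2) {
    for (pr in Filter(function(p) length(p) == 2, pairs)) {
      a <- groups[[pr[1]]]$im_ratio; a <- a[!is.na(a)]
      b <- groups[[pr[2]]]$im_ratio; b <- b[!is.na(b)]
      key <- paste(pr, collapse = "_vs_")
      if (length(a) >= 1 && length(b) >= 1) {
        rs <- rank_sum_test(a, b)
        rank_sum[[key]] <- list(u = rs$u_statistic, p = rs$p_two_tailed,
                                method = rs$method)
      } else {
        notices <- c(notices, sprintf("rank-sum %s skipped: empty group", key))
      }
    }
  }
  q <- report[!is.na(report$im_ratio), ]
  correlation <- list()
  for (layer in c("intima", "media")) {
    mx <- q[[paste0(layer, "_um")]]
    tx <- q[[paste0("true_", layer, "_um")]]
    if (length(mx) >= 3 && stats::sd(mx) > 0 && stats::sd(tx) > 0) {
      pc <- pearson_correlation(tx, mx)
      correlation[[layer]] <- list(r = pc$r, n = pc$n, p = pc$p_two_tailed)
    } else {
      notices <- c(notices,
                   sprintf("correlation for %s skipped: too few quantifiable samples",
                           layer))
    }
  }
  symmetry <- NULL
  hs <- report$symmetry_score[report$true_class %in%
                                c("normal", "hyperplasia")]
  gs <- report$symmetry_score[report$true_class == "gca"]
  hs <- hs[!is.na(hs)]; gs <- gs[!is.na(gs)]
  if (length(hs) >= 1 && length(gs) >= 1) {
    cs <- cohort_separation(hs, gs)
    symmetry <- list(healthy_median = cs$healthy_median,
                     gca_median = cs$gca_median,
                     p = cs$rank_sum$p_two_tailed,
                     threshold = cs$threshold,
                     balanced_accuracy = cs$balanced_accuracy)
  } else {
    notices <- c(notices,
                 "symmetry separation omitted: need scores in both a healthy and a gca group")
  }
  if (!is.null(env)) for (n in notices) study_log(env, "summary", n)
  list(n_samples = nrow(report), im_groups = im_summary,
       rank_sum = rank_sum, thickness_correlation = correlation,
       symmetry_separation = symmetry, notices = notices)
}

#' @export
print.tab_study <- function(x, ...) {
  cat(sprintf("tab_study: %d samples (seed %d)\n", nrow(x$report),
              x$config$seed))
  tab <- table(x$report$true_class, x$report$class_label)
  print(tab)
  invisible(x)
}

#' @export
summary.tab_study <- function(object, ...) {
  s <- object$summary
  cat(sprintf("Study of %d samples\n", s$n_samples))
  for (cl in names(s$im_groups)) {
    g <- s$im_groups[[cl]]
    cat(sprintf("  %-12s n=%d quantifiable=%d median I/M=%s IQR=[%s, %s]\n",
                cl, g$n, g$n_quantifiable, format(g$median_im, digits = 3),
                format(g$iqr_im[1], digits = 3),
                format(g$iqr_im[2], digits = 3)))
  }
  for (k in names(s$rank_sum)) {
    cat(sprintf("  rank-sum %s: p = %.4g\n", k, s$rank_sum[[k]]$p))
  }
  for (k in names(s$thickness_correlation)) {
    cat(sprintf("  measured-vs-true %s thickness: r = %.3f (n = %d)\n",
                k, s$thickness_correlation[[k]]$r,
                s$thickness_correlation[[k]]$n))
  }
  if (!is.null(s$symmetry_separation)) {
    cat(sprintf("  symmetry: healthy median %.3f vs gca %.3f (p = %.4g, bal.acc %.2f)\n",
                s$symmetry_separation$healthy_median,
                s$symmetry_separation$gca_median,
                s$symmetry_separation$p,
                s$symmetry_separation$balanced_accuracy))
  }
  for (n in s$notices) cat("  note:", n, "\n")
  invisible(s)
}
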