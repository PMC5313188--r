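# End-to-end measurement: refine the APP, fit the MSP, build the
# intrinsic frame, fit each hip's opening circle, and report the six
# orientation angles plus pelvic posture.

#' Measurement options
#'
#' @param app_region_mm APP refinement search radius (default 10 mm).
#' @param msp_region_mm ASIS point-cloud radius for the MSP (default 25 mm).
#' @param icp_max_iter,icp_tol ICP iteration cap and RMS-change tolerance.
#' @param circle_tol convergence tolerance of the geometric circle
#'   refinement.
#' @return list of options for [measure_acetabulum()].
#' @export
measure_control <- function(app_region_mm = 10, msp_region_mm = 25,
                            icp_max_iter = 100, icp_tol = 1e-6,
                            circle_tol = 1e-10) {
  list(app_region_mm = app_region_mm, msp_region_mm = msp_region_mm,
       icp_max_iter = icp_max_iter, icp_tol = icp_tol,
       circle_tol = circle_tol)
}

#' Measure 3D acetabular orientation
#'
#' Runs the full pipeline on a pelvic surface mesh and initial landmark
#' picks: iterative APP refinement, ICP mirror-plane MSP, intrinsic
#' frame and posture, then per hip the least-squares opening circle, the
#' acetabular axis, and the anatomic, radiographic, and operative
#' anteversion/inclination.  A hip without rim points is skipped with a
#' warning; an error in one hip's fit does not abort the other.
#'
#' @param mesh a [pelvic_mesh()].
#' @param landmarks a [pelvic_landmarks()] with initial picks and rim
#'   points.
#' @param control options from [measure_control()].
#' @param subject optional subject identifier carried into reports.
#' @return object of class `acetabulometry`: `frame`, `posture`,
#'   `app` (refinement result), per-hip entries in `hips` (each with
#'   `circle`, `axis`, `angles` by definition), `subject`, `control`.
#' @export
measure_acetabulum <- function(mesh, landmarks, control = measure_control(),
                               subject = NA_character_) {
  stopifnot(inherits(mesh, "pelvic_mesh"), inherits(landmarks, "pelvic_landmarks"))
  app <- refine_app(mesh, landmarks, region_radius_mm = control$app_region_mm)
  msp <- fit_msp(mesh, app$points, region_radius_mm = control$msp_region_mm,
                 max_iter = control$icp_max_iter, tol = control$icp_tol)
  frame <- build_frame(app$plane, msp, app$points)
  posture <- posture_angles(frame)
  hips <- list()
  for (side in c("left", "right")) {
    rim <- landmarks[[paste0("rim_", side)]]
    if (is.null(rim)) {
      warning("no rim points for the ", side, " hip; skipping")
      next
    }
    hips[[side]] <- tryCatch({
      circle <- fit_opening_circle(rim, tol = control$circle_tol)
      axis <- make_axis(circle, frame, side)
      angles <- lapply(stats::setNames(ANGLE_DEFINITIONS, ANGLE_DEFINITIONS),
                       function(d) axis_to_angles(axis, d))
      list(circle = circle, axis = axis, angles = angles,
           rim_path = build_rim_path(rim))
    }, error = function(e) {
      warning("measurement failed for the ", side, " hip: ", conditionMessage(e))
      NULL
    })
  }
  structure(list(frame = frame, posture = posture, app = app, hips = hips,
                 subject = subject, control = control),
            class = "acetabulometry")
}

#' @export
print.acetabulometry <- function(x, ...) {
  cat("3D acetabular orientation measurement\n")
  cat(sprintf("  pelvic posture: tilt %.2f, rotation %.2f, obliqueness %.2f (deg)\n",
              x$posture[1], x$posture[2], x$posture[3]))
  cm <- coef(x)
  if (nrow(cm)) {
    cat("  angles (deg):\n")
    print(round(cm, 2))
  } else cat("  no hips measured\n")
  invisible(x)
}

#' @export
coef.acetabulometry <- function(object, ...) {
  nm <- c("anatomic_av", "anatomic_inc", "radiographic_av",
          "radiographic_inc", "operative_av", "operative_inc")
  rows <- lapply(object$hips, function(h) {
    if (is.null(h)) return(NULL)
    vals <- unlist(lapply(ANGLE_DEFINITIONS, function(d)
      c(h$angles[[d]]$anteversion, h$angles[[d]]$inclination)))
    stats::setNames(vals, nm)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(numeric(0), 0, 6, dimnames = list(NULL, nm))
  out
}

#' @export
summary.acetabulometry <- function(object, ...) {
  cat("Intrinsic pelvic frame\n")
  print(object$frame)
  cat(sprintf("APP refinement: %d iterations, %s\n", object$app$iterations,
              if (object$app$converged) "converged" else "not converged"))
  cat(sprintf("Posture: tilt %.2f, rotation %.2f, obliqueness %.2f deg\n",
              object$posture[1], object$posture[2], object$posture[3]))
  for (side in names(object$hips)) {
    h <- object$hips[[side]]
    if (is.null(h)) next
    cat(sprintf("%s hip: opening circle radius %.2f mm, center (%.1f, %.1f, %.1f)\n",
                side, h$circle$radius, h$circle$center[1], h$circle$center[2],
                h$circle$center[3]))
  }
  print(round(coef(object), 2))
  invisible(object)
}

#' @export
#' @importFrom graphics plot points lines legend
plot.acetabulometry <- function(x, side = names(x$hips)[1], ...) {
  h <- x$hips[[side]]
  if (is.null(h)) stop("no measured hip to plot")
  B <- orthobasis(h$circle$normal)
  proj <- function(p) {
    d <- sweep(rbind3(p), 2, h$circle$center)
    cbind(d %*% B[, 1], d %*% B[, 2])
  }
  rim2 <- proj(h$rim_path$points)
  path2 <- proj(h$rim_path$resample(200))
  th <- seq(0, 2 * pi, length.out = 181)
  circ2 <- h$circle$radius * cbind(cos(th), sin(th))
  lim <- range(rim2, circ2) * 1.1
  plot(rim2, asp = 1, xlim = lim, ylim = lim, pch = 19,
       xlab = "in-plane u (mm)", ylab = "in-plane v (mm)",
       main = sprintf("%s acetabular opening (radius %.1f mm)", side,
                      h$circle$radius), ...)
  lines(path2[c(seq_len(nrow(path2)), 1), ], col = "darkgreen")
  lines(circ2, col = "blue", lwd = 2)
  legend("topright", legend = c("rim picks", "rim path", "best-fit circle"),
         col = c("black", "darkgreen", "blue"), pch = c(19, NA, NA),
         lty = c(NA, 1, 1), bty = "n", cex = 0.8)
  invisible(x)
}

# ---- measurement report IO -------------------------------------------------

#' Write and read measurement reports
#'
#' The JSON report round-trips every measured value (angles, circle,
#' axis, posture, provenance); the CSV report is one row per hip with
#' the six angles plus posture and circle parameters.
#'
#' @param x an `acetabulometry` measurement.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @param provenance optional named list (input files, parameters, seed)
#'   stored verbatim.
#' @return `write_report`: invisible list of paths;
#'   `read_report`: the parsed report list.
#' @export
write_report <- function(x, json_path = NULL, csv_path = NULL,
                         provenance = list()) {
  stopifnot(inherits(x, "acetabulometry"))
  rep_ <- list(
    subject = x$subject,
    software = paste("acetabulometry", as.character(utils::packageVersion("acetabulometry"))),
    posture = as.list(x$posture),
    frame = list(origin = x$frame$origin, axes = x$frame$axes),
    hips = lapply(x$hips, function(h) {
      if (is.null(h)) return(NULL)
      list(circle = list(center = h$circle$center, radius = h$circle$radius,
                         normal = h$circle$normal),
           axis = h$axis$direction,
           angles = lapply(h$angles, function(a)
             list(anteversion = a$anteversion, inclination = a$inclination)))
    }),
    provenance = provenance)
  if (!is.null(json_path))
    jsonlite::write_json(rep_, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", matrix = "rowmajor")
  if (!is.null(csv_path)) {
    cm <- coef(x)
    df <- data.frame(subject = x$subject, side = rownames(cm), cm,
                     tilt = x$posture[1], rotation = x$posture[2],
                     obliqueness = x$posture[3],
                     circle_radius = vapply(x$hips[rownames(cm)],
                                            function(h) h$circle$radius, 0),
                     row.names = NULL, check.names = FALSE)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(list(json = json_path, csv = csv_path))
}

#' @rdname write_report
#' @param path JSON report path.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Measure a mesh + landmarks file pair
#'
#' File-level wrapper around [measure_acetabulum()]: reads the mesh
#' (STL/PLY/OBJ) and the landmarks JSON, runs the pipeline, and
#' optionally writes the JSON/CSV reports with provenance.
#'
#' @param mesh_file,landmarks_file input paths.
#' @param json_path,csv_path optional report outputs.
#' @param control options from [measure_control()].
#' @param subject subject id (defaults to the mesh file stem).
#' @return the `acetabulometry` object, invisibly when reports are written.
#' @export
measure_files <- function(mesh_file, landmarks_file, json_path = NULL,
                          csv_path = NULL, control = measure_control(),
                          subject = NULL) {
  mesh <- read_mesh(mesh_file)
  lmk <- read_landmarks(landmarks_file)
  if (is.null(subject))
    subject <- tools::file_path_sans_ext(basename(mesh_file))
  m <- measure_acetabulum(mesh, lmk, control = control, subject = subject)
  if (!is.null(json_path) || !is.null(csv_path))
    write_report(m, json_path, csv_path,
                 provenance = list(mesh_file = mesh_file,
                                   landmarks_file = landmarks_file,
                                   control = control))
  m
}

# ---- validation and reliability protocols ---------------------------------

#' Specs for a standardized validation suite
#'
#' Deterministic grid of phantom specifications spanning anatomic
#' anteversion 5-35 degrees and inclination 40-65 degrees, the ranges
#' used for the systematic-error protocol.
#'
#' @param n_models number of models (default 15).
#' @param av_range,inc_range anatomic anteversion / inclination spans,
#'   degrees.
#' @param mesh_resolution target mesh edge length, mm.
#' @param seed base seed recorded in the specs.
#' @return list of [phantom_spec()]s.
#' @export
validation_specs <- function(n_models = 15, av_range = c(5, 35),
                             inc_range = c(40, 65), mesh_resolution = 1,
                             seed = 1L) {
  av <- seq(av_range[1], av_range[2], length.out = n_models)
  inc <- seq(inc_range[1], inc_range[2], length.out = n_models)
  # pair anteversion with a shuffled-phase inclination grid so the suite
  # covers the rectangle rather than its diagonal
  inc <- inc[((seq_len(n_models) - 1) * 7) %% n_models + 1]
  lapply(seq_len(n_models), function(i)
    phantom_spec(true_anatomic_left = c(av[i], inc[i]),
                 true_anatomic_right = c(av[i], inc[i]),
                 mesh_resolution = mesh_resolution,
                 seed = seed + i))
}

#' Systematic-error protocol on standardized phantoms
#'
#' Generates the standardized models, runs the full measurement pipeline
#' on each noiseless mesh with exact initial landmarks, and summarizes
#' the absolute angular error against the predetermined ground truth
#' over all models and all six angle measures.
#'
#' @param specs list of [phantom_spec()]s, e.g. from [validation_specs()].
#' @param control measurement options.
#' @return list of class `validation_result`: `summary` (an
#'   `error_summary`), `truth` and `measured` matrices (rows =
#'   model x side), `per_model` mean error.
#' @export
validate_phantom_suite <- function(specs, control = measure_control()) {
  truth <- list(); measured <- list()
  for (i in seq_along(specs)) {
    ph <- make_standard_pelvis(specs[[i]])
    m <- measure_acetabulum(ph$mesh, ph$landmarks, control = control)
    for (side in c("left", "right")) {
      truth[[paste(i, side)]] <- truth_angles(ph$truth, side)
      measured[[paste(i, side)]] <- coef(m)[side, ]
    }
  }
  tm <- do.call(rbind, truth); mm <- do.call(rbind, measured)
  structure(list(summary = systematic_error(tm, mm), truth = tm, measured = mm,
                 per_model = rowMeans(abs(mm - tm))),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("Phantom validation (", nrow(x$truth), " hip measurements)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Simulated-rater reliability protocol
#'
#' Generates phantoms with angles drawn from the simulated population,
#' runs [simulate_raters()], and computes the per-definition
#' single-measure absolute-agreement ICC (two-way random across raters).
#'
#' @param n_phantoms number of phantom pelves (default 16, i.e. 32 hips).
#' @param n_raters raters (default 3).
#' @param landmark_noise_mm,rim_noise_mm pick perturbations, mm.
#' @param mesh_resolution phantom mesh edge length, mm.
#' @param seed RNG seed (phantom draw and rater noise).
#' @return list of class `reliability_result`: `icc` (per definition),
#'   `trials` (the raw trial table).
#' @export
reliability_study <- function(n_phantoms = 16, n_raters = 3,
                              landmark_noise_mm = 5, rim_noise_mm = 1,
                              mesh_resolution = 1, seed = 1L) {
  pop <- sample_population(max(2, ceiling(n_phantoms / 2)), seed = seed)
  pop <- pop[seq_len(n_phantoms), ]
  specs <- lapply(seq_len(n_phantoms), function(i)
    phantom_spec(true_anatomic_left = c(pop$aa_left[i], pop$ai_left[i]),
                 true_anatomic_right = c(pop$aa_right[i], pop$ai_right[i]),
                 mesh_resolution = mesh_resolution, seed = seed + i))
  trials <- simulate_raters(specs, n_raters = n_raters, n_trials = 1,
                            landmark_noise_mm = landmark_noise_mm,
                            rim_noise_mm = rim_noise_mm, seed = seed)
  icc <- lapply(stats::setNames(ANGLE_DEFINITIONS, ANGLE_DEFINITIONS),
                function(d) icc_single(ratings_matrix(trials, d, trial = 1),
                                       model = "two-way-random"))
  structure(list(icc = icc, trials = trials), class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat("Simulated-rater reliability (single-measure absolute agreement)\n")
  for (d in names(x$icc)) {
    r <- x$icc[[d]]
    cat(sprintf("  %-12s ICC %.5f (95%% CI %.5f to %.5f)\n", d, r$icc,
                r$ci[1], r$ci[2]))
  }
  invisible(x)
}
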