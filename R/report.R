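# Pipeline runner: chains binding -> FRET -> peak shifts -> kinetics ->
# calibration from a single YAML config into one JSON summary.

#' Read a pipeline run configuration
#'
#' The config is YAML with one section per stage (`binding`, `peaks`,
#' `fret`, `kinetics`, `calibration`); stages absent from the config are
#' skipped. File paths inside the config are resolved relative to the
#' config file's directory. A canonical example ships with the package:
#' `system.file("extdata", "config_demo.yaml", package = "specbind")`.
#'
#' @param path YAML file path.
#' @return A named list (the config), with an attribute `dir` recording
#'   the directory against which relative paths resolve.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  attr(cfg, "dir") <- dirname(normalizePath(path))
  cfg
}

.resolvePath <- function(p, dir) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) return(p)
  file.path(dir, p)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline and write a JSON summary
#'
#' Executes every stage present in the config and writes `report.json`
#' (the summary) and `report.log` (package version, config checksum,
#' stages run) to the output directory. The JSON is deterministic: two
#' runs on the same inputs and config are byte-identical; timestamps go
#' only to the log.
#'
#' @param config a config list from [readRunConfig()] or a path to a
#'   YAML config.
#' @param outDir output directory; defaults to the config's
#'   `output_dir`, or the current directory.
#' @return The summary, invisibly (a named list mirroring the JSON).
#' @export
runReport <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  dir <- attr(config, "dir") %||% getwd()
  outDir <- outDir %||% config$output_dir %||% "."
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  stages <- list()

  if (!is.null(config$binding)) {
    stages$binding <- .stage("binding", {
      b <- config$binding
      tr <- readTitration(.resolvePath(b$titration_csv, dir),
                          proteinTotal = b$protein_total,
                          unit = b$ligand_unit %||% "uM")
      fit <- fitBinding(tr, fixI0 = isTRUE(b$fix_I0))
      p <- fit@params
      list(I0 = p@I0, I_inf = p@Iinf, n = p@n, K_per_M = p@K,
           stderr_n = fit@stderr[["n"]], stderr_K = fit@stderr[["K"]],
           rss = fit@rss, warnings = as.list(fit@warnings))
    })
  }

  if (!is.null(config$peaks)) {
    stages$peaks <- .stage("peaks", {
      pk <- config$peaks
      kind <- pk$kind %||% "emission"
      ref <- readSpectrum(.resolvePath(pk$reference_csv, dir), kind = kind,
                          deltaLambda = pk$delta_lambda %||% NA_real_)
      trt <- readSpectrum(.resolvePath(pk$treated_csv, dir), kind = kind,
                          deltaLambda = pk$delta_lambda %||% NA_real_)
      win <- pk$smooth_window
      list(reference_peak_nm = findPeak(ref, win)@peakWavelength,
           treated_peak_nm = findPeak(trt, win)@peakWavelength,
           shift_nm = peakShift(ref, trt, win))
    })
  }

  if (!is.null(config$fret)) {
    stages$fret <- .stage("fret", {
      fr <- config$fret
      const <- FretConstants(
        kappa2 = fr$kappa2 %||% (2 / 3), phi = fr$phi %||% 0.118,
        refIndex = fr$ref_index %||% 1.366,
        convention = fr$convention %||% "standard_A6")
      donor <- readSpectrum(.resolvePath(fr$donor_csv, dir), "emission")
      acceptor <- readSpectrum(.resolvePath(fr$acceptor_csv, dir),
                               "absorption")
      res <- fretChain(donor, acceptor, f = fr$F, f0 = fr$F0, const)
      list(J_M1cm1nm4 = res@J, J_cm3_M1 = res@Jcm3, R0_nm = res@R0,
           E = res@E, r_nm = res@r, valid_r_lt_7nm = res@validDistance,
           valid_range = res@validRange, convention = res@convention)
    })
  }

  if (!is.null(config$kinetics)) {
    stages$kinetics <- .stage("kinetics", {
      kn <- config$kinetics
      eps <- kn$epsilon_mM %||% 27.9
      vk <- kn$value_kind %||% "concentration"
      loadTrace <- function(csv)
        asConcentration(readKineticTrace(.resolvePath(csv, dir), vk), eps)
      base <- loadTrace(kn$baseline_csv)
      baseFit <- fitCubic(base)
      baseRel <- finalRelease(base)
      treated <- lapply(kn$treated, function(tt) {
        trc <- loadTrace(tt$csv)
        ft <- fitCubic(trc)
        inh <- percentInhibition(baseRel, finalRelease(trc))
        list(label = tt$label, v0_nM_per_min = ft@v0,
             released_uM = inh@treatedReleased,
             percent_decrease = round(inh@percentDecrease, 2))
      })
      list(baseline = list(v0_nM_per_min = baseFit@v0,
                           released_uM = baseRel),
           treated = treated)
    })
  }

  if (!is.null(config$calibration)) {
    stages$calibration <- .stage("calibration", {
      cl <- config$calibration
      relTol <- cl$rel_tol %||% 0.05
      fitOne <- function(csv) {
        pts <- readCalibration(.resolvePath(csv, dir))
        fitStandardCurve(pts$conc_uM, pts$a562)
      }
      ref <- fitOne(cl$reference_csv)
      others <- lapply(cl$others, function(oo) {
        crv <- fitOne(oo$csv)
        list(label = oo$label, slope_per_uM = crv@slope,
             intercept = crv@intercept, r2 = crv@r2,
             equivalent = curvesEquivalent(ref, crv, relTol))
      })
      list(reference = list(slope_per_uM = ref@slope,
                            intercept = ref@intercept, r2 = ref@r2),
           others = others, rel_tol = relTol)
    })
  }

  cfgTxt <- yaml::as.yaml(config)
  summary <- list(
    package = "specbind",
    version = as.character(utils::packageVersion("specbind")),
    config_checksum = .checksum(cfgTxt),
    seed = config$seed %||% NA,
    stages = stages)

  jsonPath <- file.path(outDir, "report.json")
  jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  writeLines(c(
    sprintf("specbind %s", summary$version),
    sprintf("config checksum: %s", summary$config_checksum),
    sprintf("stages: %s", paste(names(stages), collapse = ", ")),
    sprintf("written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    file.path(outDir, "report.log"))
  invisible(summary)
}

#' Structural validation of a report summary
#'
#' Checks a summary (as returned by [runReport()] or re-read from
#' `report.json`) against the shipped schema
#' (`inst/schema/report.schema.json`): required top-level keys, and the
#' required keys of every stage that is present.
#'
#' @param summary a named list.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validateReportSummary <- function(summary) {
  need <- c("package", "version", "config_checksum", "stages")
  miss <- setdiff(need, names(summary))
  if (length(miss)) .stopf("summary lacks required keys: %s",
                           paste(miss, collapse = ", "))
  req <- list(
    binding = c("I0", "I_inf", "n", "K_per_M", "rss"),
    peaks = c("reference_peak_nm", "treated_peak_nm", "shift_nm"),
    fret = c("J_M1cm1nm4", "R0_nm", "E", "r_nm", "valid_r_lt_7nm",
             "valid_range"),
    kinetics = c("baseline", "treated"),
    calibration = c("reference", "others"))
  for (nm in names(summary$stages)) {
    if (!nm %in% names(req)) .stopf("unknown stage '%s' in summary", nm)
    miss <- setdiff(req[[nm]], names(summary$stages[[nm]]))
    if (length(miss))
      .stopf("stage '%s' lacks required keys: %s", nm,
             paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
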