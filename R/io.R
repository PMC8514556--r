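#' Read a multichannel time series from delimited text
#'
#' Expects a header row of channel names and one row per sample, comma- or
#' tab-delimited. Non-numeric cells and missing values are rejected with the
#' offending row numbers, since every downstream operation assumes finite,
#' uniformly sampled data.
#'
#' @param path file path.
#' @param dt sampling interval to attach (default 1).
#' @param sep field separator; `NULL` (default) picks "," or tab from the
#'   header line.
#' @return A [TimeSeries-class].
#' @export
readTimeSeriesCSV <- function(path, dt = 1, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- tryCatch(
    read.csv(path, sep = sep, check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric column(s): ", paste(names(df)[bad], collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df)
  badRows <- which(!apply(is.finite(m), 1L, all))
  if (length(badRows))
    stop("missing or non-finite values at row(s): ",
         paste(head(badRows, 10L), collapse = ", "), call. = FALSE)
  TimeSeries(m, dt = dt, labels = colnames(m))
}

#' Write a time series as CSV
#'
#' Full-precision round trip with [readTimeSeriesCSV()].
#'
#' @param series a [TimeSeries-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTimeSeriesCSV <- function(series, path) {
  df <- as.data.frame(tsValues(series))
  # format() at 17 significant digits preserves doubles exactly
  out <- vapply(df, function(col) format(col, digits = 17, trim = TRUE),
                character(nrow(df)))
  write.csv(as.data.frame(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Canned seeded fixtures for tests and documentation
#'
#' Small, deterministic datasets exercising specific code paths:
#' \describe{
#'   \item{identical-pair}{a logistic-map trace duplicated into two equal
#'     channels (maximal coupling score in both directions); a
#'     [TimeSeries-class].}
#'   \item{independent-noise}{two independent white-noise channels (null
#'     case); a [TimeSeries-class].}
#'   \item{lm-unidirectional}{a two-variable logistic map with x driving y
#'     at K = 0.35; a [TrialResult-class] with truth matrix.}
#'   \item{vdp-synchronous}{two Van der Pol oscillators under strong
#'     symmetric coupling (the synchrony regime that defeats
#'     neighborhood-based cross mapping); a [TrialResult-class].}
#'   \item{regime-switch-triad}{a three-oscillator recording with a
#'     scripted coupling switch; a list of `series`, `schedule`,
#'     `regimes`.}
#' }
#'
#' @param name fixture tag.
#' @param seed RNG seed (default 1).
#' @param L length (samples) for the pairwise fixtures.
#' @return See tag descriptions.
#' @export
makeFixture <- function(name = c("identical-pair", "independent-noise",
                                 "lm-unidirectional", "vdp-synchronous",
                                 "regime-switch-triad"),
                        seed = 1L, L = 400L) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop("unknown fixture tag '",
                                            name[1L], "'", call. = FALSE))
  switch(name,
    "identical-pair" = {
      tr <- simulateLogisticMap(
        makeTopologies("two_var", K = c(0, 0))[[1L]], L,
        NoiseSpec(seed = seed))
      x <- tsValues(trialSeries(tr))[, 1L]
      TimeSeries(cbind(x = x, y = x))
    },
    "independent-noise" = withSeed(seed,
      TimeSeries(cbind(x = rnorm(L), y = rnorm(L)))),
    "lm-unidirectional" = simulateLogisticMap(
      makeTopologies("two_var", K = c(0.35, 0))[[1L]], L,
      NoiseSpec(seed = seed)),
    "vdp-synchronous" = simulateVDP(
      makeTopologies("two_var", K = c(0.5, 0.5), system = "VDP")[[1L]], L,
      NoiseSpec(seed = seed)),
    "regime-switch-triad" = {
      off <- matrix(0, 3, 3)
      fwd <- off; fwd[1L, 2L] <- 0.4; fwd[1L, 3L] <- 0.4
      regimeSwitchTriad(list(off, fwd), schedule = c(1L, 2L, 1L, 2L),
                        segmentLen = max(64L, L %/% 4L),
                        noise = NoiseSpec(seed = seed))
    })
}

#' Read an experiment configuration
#'
#' YAML mirroring the function arguments of the scoring and evaluation
#' entry points; unknown keys are kept verbatim so configurations round-trip
#' losslessly.
#'
#' @param path YAML file.
#' @return A named list.
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading configurations requires the yaml package")
  yaml::read_yaml(path)
}

#' @rdname readRunConfig
#' @param config named list to serialize.
#' @export
writeRunConfig <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("writing configurations requires the yaml package")
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration, seeds, and package version needed to
#' reproduce a run's outputs bit for bit along deterministic paths.
#'
#' @param config named list of run settings (including seeds).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(config, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing manifests requires the jsonlite package")
  manifest <- list(
    package = "crosssort",
    version = as.character(utils::packageVersion("crosssort")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
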