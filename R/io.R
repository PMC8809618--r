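#' @include AllClasses.R simulate.R
NULL

# fixed scientific notation with 10 significant digits, for reproducible
# diffs of numeric output tables
.fmtNum <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "e", digits = 9))
}

# write a data.frame as TSV with one header line, numbers in fixed
# scientific notation
.writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- .fmtNum(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write and read cohorts of trajectories as TSV
#'
#' Positions are written as a tab-separated table with columns
#' `individual_id`, `t_s`, `x_um`, `y_um`; exclusion windows as a sidecar
#' table with columns `individual_id`, `start_s`, `end_s`.  Numbers are
#' printed in fixed scientific notation with 10 significant digits.
#'
#' @param cohort List of [Trajectory-class] objects.
#' @param path Positions TSV path.
#' @param exclusionPath Sidecar exclusion-window TSV path (optional on
#'   write, `NULL` to skip; optional on read).
#' @param arenaRadius Arena radius (um) to attach on reading; when `NULL`,
#'   the maximum observed radial distance is used.
#' @return `readTrajectories` returns a list of [Trajectory-class];
#'   `writeTrajectories` returns `path` invisibly.
#' @name trajectoryIO
NULL

#' @rdname trajectoryIO
#' @export
writeTrajectories <- function(cohort, path, exclusionPath = NULL) {
  tabs <- lapply(cohort, function(tr)
    data.frame(individual_id = tr@individualId, t_s = tr@t,
               x_um = tr@x, y_um = tr@y))
  .writeTsv(do.call(rbind, tabs), path)
  if (!is.null(exclusionPath)) {
    ew <- lapply(cohort, function(tr) {
      w <- tr@excludedWindows
      if (nrow(w) == 0) return(NULL)
      data.frame(individual_id = tr@individualId,
                 start_s = w[, 1], end_s = w[, 2])
    })
    ew <- do.call(rbind, ew)
    if (is.null(ew))
      ew <- data.frame(individual_id = character(0), start_s = numeric(0),
                       end_s = numeric(0))
    .writeTsv(ew, exclusionPath)
  }
  invisible(path)
}

#' @rdname trajectoryIO
#' @export
readTrajectories <- function(path, exclusionPath = NULL,
                             arenaRadius = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("individual_id", "t_s", "x_um", "y_um")
  if (!all(need %in% names(tab)))
    stop("positions table must have columns: ",
         paste(need, collapse = ", "))
  ewTab <- NULL
  if (!is.null(exclusionPath)) {
    ewTab <- utils::read.table(exclusionPath, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    if (!all(c("individual_id", "start_s", "end_s") %in% names(ewTab)))
      stop("exclusion table must have columns: individual_id, start_s, end_s")
  }
  lapply(split(tab, tab$individual_id), function(sub) {
    sub <- sub[order(sub$t_s), ]
    r <- if (is.null(arenaRadius))
      max(sqrt(sub$x_um^2 + sub$y_um^2), 1e-9) else arenaRadius
    ew <- matrix(numeric(0), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
    if (!is.null(ewTab)) {
      sel <- ewTab$individual_id == sub$individual_id[1]
      if (any(sel))
        ew <- cbind(start = ewTab$start_s[sel], end = ewTab$end_s[sel])
    }
    new("Trajectory", individualId = as.character(sub$individual_id[1]),
        t = sub$t_s, x = sub$x_um, y = sub$y_um, arenaRadius = r,
        excludedWindows = ew)
  })
}

# ---- minimal flat TOML (key = value pairs, optional [section] headers) ----

.tomlValue <- function(v) {
  if (is.character(v)) sprintf('"%s"', v)
  else if (is.logical(v)) tolower(as.character(v))
  else if (length(v) > 1)
    sprintf("[%s]", paste(format(v, digits = 15, scientific = FALSE,
                                 trim = TRUE), collapse = ", "))
  else format(v, digits = 15, scientific = FALSE, trim = TRUE)
}

.parseTomlScalar <- function(s) {
  s <- trimws(s)
  if (grepl('^".*"$', s)) return(gsub('^"|"$', "", s))
  if (s %in% c("true", "false")) return(s == "true")
  if (grepl("^\\[.*\\]$", s)) {
    inner <- trimws(gsub("^\\[|\\]$", "", s))
    if (inner == "") return(numeric(0))
    return(as.numeric(trimws(strsplit(inner, ",")[[1]])))
  }
  as.numeric(s)
}

# read a flat TOML file into a (possibly sectioned) named list
.readToml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln) && !grepl("=", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed TOML line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- .parseTomlScalar(substr(ln, eq + 1, nchar(ln)))
    if (is.null(section)) out[[key]] <- val
    else out[[section]][[key]] <- val
  }
  out
}

.writeToml <- function(x, path) {
  lines <- character(0)
  scalars <- x[!vapply(x, is.list, logical(1))]
  sections <- x[vapply(x, is.list, logical(1))]
  for (nm in names(scalars))
    lines <- c(lines, sprintf("%s = %s", nm, .tomlValue(scalars[[nm]])))
  for (nm in names(sections)) {
    lines <- c(lines, "", sprintf("[%s]", nm))
    for (k in names(sections[[nm]]))
      lines <- c(lines,
                 sprintf("%s = %s", k, .tomlValue(sections[[nm]][[k]])))
  }
  writeLines(lines, path)
  invisible(path)
}

# snake_case key mapping for the generator TOML schema
.generatorKeys <- c(
  arena_radius = "arenaRadius", n_days = "nDays",
  frame_interval = "frameInterval",
  mean_day0_block_total = "meanDay0BlockTotal",
  population_decline_rate = "populationDeclineRate",
  individual_rate_sd = "individualRateSd",
  individual_level_sd = "individualLevelSd",
  day_level_volatility = "dayLevelVolatility",
  intraday_volatility = "intradayVolatility",
  intraday_timescale = "intradayTimescale",
  active_speed_scale = "activeSpeedScale",
  dwell_speed_fraction = "dwellSpeedFraction",
  turning_kappa = "turningKappa",
  edge_attraction_strength = "edgeAttractionStrength",
  edge_ring_fraction = "edgeRingFraction",
  stim_times = "stimTimes", seed = "seed")

.rateKeys <- c(rate_roam_to_dwell = "roamToDwell",
               rate_dwell_to_roam = "dwellToRoam",
               rate_dwell_to_quiescent = "dwellToQuiescent",
               rate_quiescent_to_dwell = "quiescentToDwell")

#' Read and write a generator configuration as TOML
#'
#' Flat TOML with snake_case keys mirroring the [GeneratorConfig-class]
#' fields (`arena_radius`, `n_days`, `frame_interval`,
#' `mean_day0_block_total`, `population_decline_rate`, ...); the four state
#' transition probabilities are the keys `rate_roam_to_dwell`,
#' `rate_dwell_to_roam`, `rate_dwell_to_quiescent`,
#' `rate_quiescent_to_dwell`.  Keys omitted from the file keep their
#' defaults.
#'
#' @param config A [GeneratorConfig-class].
#' @param path TOML file path.
#' @return `readGeneratorConfig` returns a [GeneratorConfig-class];
#'   `writeGeneratorConfig` returns `path` invisibly.
#' @name generatorConfigIO
NULL

#' @rdname generatorConfigIO
#' @export
writeGeneratorConfig <- function(config, path) {
  validObject(config)
  x <- list()
  for (k in names(.generatorKeys))
    x[[k]] <- slot(config, .generatorKeys[[k]])
  for (k in names(.rateKeys))
    x[[k]] <- unname(config@stateTransitionRates[[.rateKeys[[k]]]])
  .writeToml(x, path)
}

#' @rdname generatorConfigIO
#' @export
readGeneratorConfig <- function(path) {
  x <- .readToml(path)
  args <- list()
  for (k in names(.generatorKeys))
    if (!is.null(x[[k]])) args[[.generatorKeys[[k]]]] <- x[[k]]
  rates <- formals(generatorConfig)$stateTransitionRates
  rates <- eval(rates)
  for (k in names(.rateKeys))
    if (!is.null(x[[k]])) rates[[.rateKeys[[k]]]] <- x[[k]]
  args$stateTransitionRates <- rates
  if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
  do.call(generatorConfig, args)
}
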