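#' @importFrom utils read.csv write.csv count.fields packageVersion
NULL

.DATA_FILE_RX <- "\\.(csv|xlsx|xls)$"

# Parse one rectangular checkerboard block (list of character row vectors)
# into doses + response matrix. Layout: first row = doses of drug A
# (columns), first column = doses of drug B (rows), body = % control;
# the top-left cell is ignored or holds "agent A / agent B".
.parseGrid <- function(cells, label) {
  lens <- lengths(cells)
  if (length(unique(lens)) != 1L) {
    stop(sprintf(
      "%s: ragged grid (row %d has %d fields, row 1 has %d)",
      label, which(lens != lens[1])[1], lens[lens != lens[1]][1], lens[1]
    ))
  }
  m <- do.call(rbind, cells)
  if (nrow(m) < 3L || ncol(m) < 3L) {
    stop(sprintf("%s: grid must be at least 2 x 2 doses plus headers", label))
  }
  num <- function(x, what, idx) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.finite(v) & nzchar(trimws(x)))
    if (length(bad) || anyNA(v)) {
      at <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stop(sprintf(
        "%s: non-numeric value '%s' at %s %d", label, x[at], what, idx(at)
      ))
    }
    v
  }
  dosesA <- num(m[1, -1], "dose column", function(i) i + 1L)
  dosesB <- num(m[-1, 1], "dose row", function(i) i + 1L)
  body <- matrix(NA_real_, nrow(m) - 1L, ncol(m) - 1L)
  for (i in seq_len(nrow(body))) {
    body[i, ] <- num(m[i + 1L, -1], sprintf("row %d, column", i + 1L),
      function(j) j + 1L
    )
  }
  corner <- trimws(m[1, 1])
  agents <- c(NA_character_, NA_character_)
  if (nzchar(corner) && grepl("/", corner, fixed = TRUE)) {
    agents <- trimws(strsplit(corner, "/", fixed = TRUE)[[1]][1:2])
  }
  list(dosesA = dosesA, dosesB = dosesB, values = body, agents = agents)
}

.readGridCSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cells <- strsplit(lines, ",", fixed = TRUE)
  # trailing empty field from lines ending in a comma
  cells <- lapply(cells, function(x) {
    while (length(x) && !nzchar(trimws(x[length(x)]))) x <- x[-length(x)]
    x
  })
  list(.parseGrid(cells, basename(path)))
}

.readGridXLSX <- function(path) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading .xlsx/.xls requires the 'readxl' package")
  }
  sheets <- readxl::excel_sheets(path)
  lapply(sheets, function(s) {
    df <- readxl::read_excel(path, sheet = s, col_names = FALSE,
      col_types = "text", .name_repair = "minimal"
    )
    cells <- lapply(seq_len(nrow(df)), function(i) {
      x <- as.character(unlist(df[i, ], use.names = FALSE))
      x[is.na(x)] <- ""
      x
    })
    .parseGrid(cells, sprintf("%s[%s]", basename(path), s))
  })
}

.stemOf <- function(path) {
  sub("_rep[0-9]+$", "", sub(.DATA_FILE_RX, "", basename(path)))
}

#' Read a combination experiment from file(s)
#'
#' Accepts a single CSV/XLSX file, a character vector of replicate files, or
#' a directory holding one experiment's file(s). Replicates may be laid out
#' as sibling files sharing a stem (`name_rep1.csv`, `name_rep2.csv`, ...)
#' or as multiple sheets of one workbook; a single file whose name carries a
#' `_rep<k>` suffix pulls in its siblings automatically. Dose grids are
#' sorted ascending (matrices permuted to match), so any row/column
#' permutation of the file yields the same canonical experiment. Values
#' outside \[-20, 200\] % control are retained but listed in
#' [qcWarnings()].
#'
#' File layout (a template ships in `inst/extdata/template_experiment.csv`):
#' first row holds the drug A doses (columns), first column the drug B
#' doses (rows), the body the responses in % control; the top-left cell is
#' ignored unless it names the drugs as `"drug A / drug B"`. Lines starting
#' with `#` are skipped.
#'
#' @param path file, files or directory as above.
#' @param rawNormalize if `TRUE`, treat inputs as raw readouts and rescale
#'   each replicate to its own untreated (0, 0) cell x 100; by default the
#'   data are assumed to be in % control already.
#' @param name experiment identifier; defaults to the file stem (or
#'   directory name).
#' @return A validated [CombinationExperiment-class].
#' @export
readExperiment <- function(path, rawNormalize = FALSE, name = NULL) {
  if (length(path) == 1L && dir.exists(path)) {
    files <- sort(list.files(path, pattern = .DATA_FILE_RX, full.names = TRUE))
    if (!length(files)) stop("no .csv/.xlsx experiment files in ", path)
    if (is.null(name)) name <- basename(normalizePath(path))
  } else if (length(path) == 1L && grepl("_rep[0-9]+\\.", basename(path))) {
    stem <- .stemOf(path)
    sibs <- sort(list.files(dirname(path),
      pattern = .DATA_FILE_RX, full.names = TRUE
    ))
    files <- sibs[vapply(sibs, .stemOf, character(1)) == stem]
  } else {
    files <- path
  }
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("file not found: ", missing[1])
  if (is.null(name)) name <- .stemOf(files[1])

  grids <- unlist(lapply(files, function(f) {
    if (grepl("\\.(xlsx|xls)$", f)) .readGridXLSX(f) else .readGridCSV(f)
  }), recursive = FALSE)

  g1 <- grids[[1]]
  for (g in grids[-1]) {
    if (!isTRUE(all.equal(sort(g$dosesA), sort(g1$dosesA))) ||
      !isTRUE(all.equal(sort(g$dosesB), sort(g1$dosesB)))) {
      stop("replicates disagree on the dose grids")
    }
  }
  reps <- lapply(grids, function(g) {
    # canonicalize each replicate's ordering before stacking
    m <- g$values[order(g$dosesB), order(g$dosesA), drop = FALSE]
    if (rawNormalize) {
      ctrl <- m[which(sort(g$dosesB) == 0), which(sort(g$dosesA) == 0)]
      if (!is.finite(ctrl) || ctrl == 0) {
        stop("raw normalization: untreated control cell is zero or missing")
      }
      m <- m / ctrl * 100
    }
    m
  })
  agents <- grids[[1]]$agents
  CombinationExperiment(
    dosesA = sort(g1$dosesA), dosesB = sort(g1$dosesB), replicates = reps,
    name = name,
    agentA = if (is.na(agents[1])) "Drug A" else agents[1],
    agentB = if (is.na(agents[2])) "Drug B" else agents[2]
  )
}

#' Write an experiment as template CSV files
#'
#' One file per replicate (`<name>_rep<k>.csv`) in the layout accepted by
#' [readExperiment()], so generated data also exercise the parser.
#'
#' @param exp a [CombinationExperiment-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeExperiment <- function(exp, dir) {
  stopifnot(is(exp, "CombinationExperiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- agentNames(exp)
  header <- c(sprintf("%s / %s", nm["a"], nm["b"]), format(dosesA(exp),
    trim = TRUE, digits = 15
  ))
  paths <- character(0)
  for (k in seq_len(nReplicates(exp))) {
    m <- replicates(exp)[[k]]
    rows <- vapply(seq_along(dosesB(exp)), function(i) {
      paste(c(
        format(dosesB(exp)[i], trim = TRUE, digits = 15),
        format(m[i, ], trim = TRUE, digits = 15)
      ), collapse = ",")
    }, character(1))
    p <- file.path(dir, sprintf("%s_rep%d.csv", experimentName(exp), k))
    writeLines(c(paste(header, collapse = ","), rows), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a surface or synergy matrix as CSV
#'
#' Mirrors the input layout: doses of drug A across the first row, doses of
#' drug B down the first column.
#'
#' @param x a [ReferenceSurface-class], [SynergyDistribution-class] or plain
#'   matrix (with `dosesA`/`dosesB` supplied).
#' @param path output file.
#' @param dosesA,dosesB dose grids, taken from `x` when it carries them.
#' @return Invisibly, `path`.
#' @export
writeSurface <- function(x, path, dosesA = NULL, dosesB = NULL) {
  if (is(x, "ReferenceSurface") || is(x, "SynergyDistribution")) {
    dosesA <- CombiSurf::dosesA(x)
    dosesB <- CombiSurf::dosesB(x)
    m <- surfaceValues(x)
  } else {
    m <- x
  }
  header <- paste(c("", format(dosesA, trim = TRUE, digits = 15)),
    collapse = ","
  )
  rows <- vapply(seq_along(dosesB), function(i) {
    paste(c(
      format(dosesB[i], trim = TRUE, digits = 15),
      format(m[i, ], trim = TRUE, digits = 15)
    ), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write the screen-level metrics table
#'
#' Takes the long table produced by [runBatch()] / [computeMetrics()] (one
#' row per experiment x model) and writes a wide CSV with experiments as
#' rows and `MODEL_metric` columns; numeric values survive a read-back via
#' [readMetricsTable()] beyond 6 significant digits.
#'
#' @param records long-form `data.frame` with columns `experiment`, `model`
#'   and the metric columns, or a list of such one-row frames.
#' @param path output CSV.
#' @param provenance optional character line written as a leading `#`
#'   comment (tool version, configuration hash).
#' @return Invisibly, the wide `data.frame` that was written.
#' @export
writeMetricsTable <- function(records, path, provenance = NULL) {
  if (is.list(records) && !is.data.frame(records)) {
    if (!length(records)) stop("no metrics records to write")
    cols <- lapply(records, names)
    if (length(unique(vapply(cols, paste, character(1), collapse = "|"))) != 1L) {
      stop("inconsistent metric sets across records")
    }
    records <- do.call(rbind, records)
  }
  if (!is.data.frame(records) || !nrow(records)) {
    stop("no metrics records to write")
  }
  if (!all(c("experiment", "model") %in% names(records))) {
    stop("records must have 'experiment' and 'model' columns")
  }
  metricCols <- setdiff(names(records), c("experiment", "model"))
  experiments <- sort(unique(records$experiment))
  models <- unique(records$model)
  wide <- data.frame(experiment = experiments, stringsAsFactors = FALSE)
  for (mod in models) {
    sub <- records[records$model == mod, , drop = FALSE]
    if (anyDuplicated(sub$experiment)) {
      stop("duplicate (experiment, model) rows")
    }
    idx <- match(experiments, sub$experiment)
    for (mc in metricCols) {
      wide[[paste(mod, mc, sep = "_")]] <- sub[[mc]][idx]
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste("#", provenance), con)
  write.csv(format(wide, digits = 15, trim = TRUE, scientific = FALSE),
    con,
    row.names = FALSE, quote = FALSE
  )
  invisible(wide)
}

#' @rdname writeMetricsTable
#' @return `readMetricsTable()` returns the wide `data.frame`.
#' @export
readMetricsTable <- function(path) {
  read.csv(path, comment.char = "#", check.names = FALSE,
    stringsAsFactors = FALSE
  )
}
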