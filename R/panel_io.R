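## Data model + readers/writers for plate exports, manifests, LOD tables,
## clinical annotations and intermediate level files.

#' Construct a measurement matrix
#'
#' The central container of the pipeline: one row per injected sample, one
#' column per analyte, with a parallel per-cell status flag matrix.  Cells
#' flagged `below_LOD` keep a missing value (or a recorded-but-flagged
#' number) and are never silently treated as valid concentrations.
#'
#' @param samples data.frame with columns `sample_id`, `subject_id`,
#'   `plate_id`, `well_id`, `role`, and optionally `duplicate_group` and
#'   `flag`.  `sample_id` must be unique.
#' @param values numeric matrix (samples x analytes), concentrations in uM;
#'   `NA` encodes a missing value.
#' @param status character matrix of the same dimension with entries in
#'   `valid`, `below_LOD`, `below_LLOQ`, `semi_quant`, `imputed`, `missing`.
#' @return An object of class `measurement_matrix`.
#' @export
measurement_matrix <- function(samples, values, status = NULL) {
  stopifnot(is.data.frame(samples), is.matrix(values))
  need <- c("sample_id", "subject_id", "plate_id", "well_id", "role")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop2("samples table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop2("duplicate sample_id in samples table")
  if (nrow(samples) != nrow(values))
    stop2("samples table and value matrix row counts differ")
  if (is.null(samples$duplicate_group))
    samples$duplicate_group <- rep(NA_character_, nrow(samples))
  if (is.null(samples$flag)) samples$flag <- rep("", nrow(samples))
  if (is.null(status)) {
    status <- matrix("valid", nrow(values), ncol(values))
    status[is.na(values)] <- "missing"
  }
  storage.mode(values) <- "double"
  if (!all(status %in% .statuses))
    stop2("unknown status flag(s): ",
          paste(unique(setdiff(status, .statuses)), collapse = ", "))
  bad <- status == "below_LOD" & !is.na(values) & values < 0
  if (any(bad)) stop2("negative concentration in below_LOD cell")
  rownames(values) <- rownames(status) <- samples$sample_id
  dimnames(status) <- dimnames(values)
  rownames(samples) <- NULL
  structure(list(samples = samples, values = values, status = status),
            class = "measurement_matrix")
}

#' @export
dim.measurement_matrix <- function(x) dim(x$values)

#' @export
print.measurement_matrix <- function(x, ...) {
  cat(sprintf("measurement_matrix: %d samples x %d analytes\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  st <- table(factor(x$status, levels = .statuses))
  cat("  cells:", paste(sprintf("%s=%d", names(st), st), collapse = ", "),
      "\n")
  invisible(x)
}

#' Analyte identifiers of a measurement matrix
#' @param x a `measurement_matrix`
#' @return character vector of analyte ids (column order).
#' @export
analyte_ids <- function(x) colnames(x$values)

#' Subset a measurement matrix
#' @param x a `measurement_matrix`
#' @param i,j row (sample) and column (analyte) indices
#' @param ... ignored
#' @export
`[.measurement_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  measurement_matrix(x$samples[i, , drop = FALSE],
                     x$values[i, j, drop = FALSE],
                     x$status[i, j, drop = FALSE])
}

#' Construct a plate-run descriptor
#'
#' One physical 96-well plate: its well manifest (role and sample identity
#' per well, in injection order) and its plate-specific per-analyte limit
#' of detection.
#'
#' @param plate_id plate identifier
#' @param wells data.frame with columns `well_id`, `role`, `sample_id` and
#'   optionally `subject_id`, `injection_position`
#' @param lod named numeric vector, analyte id -> LOD concentration (uM),
#'   each `>= 0` (a zero LOD means the analyte is never censored)
#' @return object of class `plate_run`
#' @export
plate_run <- function(plate_id, wells, lod = numeric()) {
  stopifnot(is.data.frame(wells))
  if (!all(c("well_id", "role", "sample_id") %in% names(wells)))
    stop2("wells table needs well_id, role, sample_id")
  bad <- !is_valid_role(wells$role)
  if (any(bad))
    stop2("plate ", plate_id, ": well without recognized role: ",
          paste(unique(wells$role[bad]), collapse = ", "))
  if (anyDuplicated(wells$well_id))
    stop2("plate ", plate_id, ": duplicate well_id")
  if (length(lod) && (any(is.na(lod)) || any(lod < 0)))
    stop2("plate ", plate_id, ": LOD values must be finite and >= 0")
  if (is.null(wells$injection_position))
    wells$injection_position <- seq_len(nrow(wells))
  structure(list(plate_id = plate_id, wells = wells, lod = lod),
            class = "plate_run")
}

#' @export
print.plate_run <- function(x, ...) {
  cat(sprintf("plate_run %s: %d wells (%d study), %d analyte LODs\n",
              x$plate_id, nrow(x$wells), sum(x$wells$role == "study"),
              length(x$lod)))
  invisible(x)
}

## ---- cell encoding -------------------------------------------------------

## "<LOD" / "<LLOQ" sentinels (case-insensitive) for flagged-missing cells;
## "value|status" when a numeric value carries a non-valid flag.
encode_cells <- function(values, status) {
  out <- fmt_num(values)
  out[status == "missing"] <- ""
  lod_na <- status == "below_LOD" & is.na(values)
  lloq_na <- status == "below_LLOQ" & is.na(values)
  out[lod_na] <- "<LOD"
  out[lloq_na] <- "<LLOQ"
  flagged <- status != "valid" & status != "missing" & !is.na(values)
  out[flagged] <- paste0(fmt_num(values[flagged]), "|", status[flagged])
  dim(out) <- dim(values)
  out
}

decode_cells <- function(txt) {
  txt <- trimws(txt)
  n <- length(txt)
  values <- rep(NA_real_, n)
  status <- rep("missing", n)
  low <- tolower(txt)
  is_lod <- low == "<lod"
  is_lloq <- low == "<lloq"
  status[is_lod] <- "below_LOD"
  status[is_lloq] <- "below_LLOQ"
  piped <- grepl("|", txt, fixed = TRUE)
  if (any(piped)) {
    parts <- strsplit(txt[piped], "|", fixed = TRUE)
    values[piped] <- as.numeric(vapply(parts, `[`, "", 1L))
    st <- vapply(parts, `[`, "", 2L)
    if (!all(st %in% .statuses))
      stop2("unknown status token in cell(s): ",
            paste(unique(setdiff(st, .statuses)), collapse = ", "))
    status[piped] <- st
  }
  plain <- !is_lod & !is_lloq & !piped & txt != ""
  v <- suppressWarnings(as.numeric(txt[plain]))
  if (anyNA(v))
    stop2("unparseable cell value(s): ",
          paste(utils::head(unique(txt[plain][is.na(v)]), 3), collapse = ", "))
  values[plain] <- v
  status[plain] <- "valid"
  list(values = values, status = status)
}

## ---- readers -------------------------------------------------------------

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  utils::read.csv(path, check.names = FALSE, colClasses = "character",
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a well manifest
#'
#' @param path CSV with columns `plate_id`, `well_id`, `role`, `sample_id`
#'   and optionally `subject_id`, `injection_position`.
#' @return data.frame
#' @export
read_manifest <- function(path) {
  m <- read_csv_strict(path)
  need <- c("plate_id", "well_id", "role", "sample_id")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop2("manifest lacks column(s): ",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(m[c("plate_id", "well_id")]))
    stop2("manifest has duplicate (plate_id, well_id) entries")
  bad <- !is_valid_role(m$role)
  if (any(bad))
    stop2("manifest well without recognized role: ",
          paste(unique(m$role[bad]), collapse = ", "))
  if (is.null(m$subject_id)) m$subject_id <- m$sample_id
  if (!is.null(m$injection_position))
    m$injection_position <- as.integer(m$injection_position)
  m
}

#' Read a plate-specific LOD table
#' @param path CSV with columns `plate_id`, `analyte_id`, `lod`
#' @return data.frame with numeric `lod`
#' @export
read_lod_table <- function(path) {
  x <- read_csv_strict(path)
  miss <- setdiff(c("plate_id", "analyte_id", "lod"), names(x))
  if (length(miss)) stop2("LOD table lacks column(s): ",
                          paste(miss, collapse = ", "))
  x$lod <- as.numeric(x$lod)
  if (any(is.na(x$lod) | x$lod < 0)) stop2("LOD table has invalid lod values")
  x
}

#' Read a clinical annotation table
#'
#' @param path CSV with columns `subject_id`, `fasting` (TRUE/FALSE), `bmi`
#'   (kg/m^2, may be empty) and `has_baseline_med_record` (TRUE/FALSE).
#' @return data.frame; `subject_id` unique.
#' @export
read_clinical <- function(path) {
  x <- read_csv_strict(path)
  need <- c("subject_id", "fasting", "bmi", "has_baseline_med_record")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop2("clinical table lacks column(s): ",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(x$subject_id)) stop2("clinical subject_id not unique")
  x$fasting <- as.logical(x$fasting)
  x$bmi <- suppressWarnings(as.numeric(x$bmi))
  x$has_baseline_med_record <- as.logical(x$has_baseline_med_record)
  x
}

#' Read Level-0 plate exports
#'
#' Assembles per-plate concentration exports and a well manifest into a
#' [measurement_matrix()] (one row per injected sample) plus one
#' [plate_run()] per plate.  Sentinel cells (`<LOD`, `<LLOQ`,
#' case-insensitive) become missing values with the corresponding status
#' flag.  Duplicate groups are derived from subjects contributing exactly
#' two study samples (blinded analytical duplicates after unblinding).
#'
#' @param plate_files character vector of per-plate CSV paths; each file
#'   has a `well_id` column followed by one column per analyte.  The plate
#'   id is taken from a `plate_id` column if present, otherwise from the
#'   file name (without extension).
#' @param manifest path to the well manifest CSV (see [read_manifest()])
#' @param lod optional path to the plate LOD table (see [read_lod_table()])
#' @param panel optional character vector of known analyte ids; any other
#'   analyte column is rejected by name
#' @return list with elements `matrix` (measurement_matrix) and `plates`
#'   (named list of plate_run)
#' @export
read_level0 <- function(plate_files, manifest, lod = NULL, panel = NULL) {
  man <- if (is.data.frame(manifest)) manifest else read_manifest(manifest)
  lod_tab <- if (is.null(lod)) NULL
             else if (is.data.frame(lod)) lod else read_lod_table(lod)
  rows <- list()
  plates <- list()
  analytes <- NULL
  for (pf in plate_files) {
    tab <- read_csv_strict(pf)
    if (!"well_id" %in% names(tab)) stop2(pf, ": no well_id column")
    pid <- if ("plate_id" %in% names(tab)) tab$plate_id[1]
           else sub("\\.[^.]*$", "", basename(pf))
    acols <- setdiff(names(tab), c("plate_id", "well_id"))
    if (!is.null(panel)) {
      unknown <- setdiff(acols, panel)
      if (length(unknown))
        stop2(pf, ": unknown analyte column(s): ",
              paste(unknown, collapse = ", "))
    }
    if (is.null(analytes)) analytes <- acols
    else if (!identical(analytes, acols))
      stop2(pf, ": analyte columns differ from first plate file")
    wm <- man[man$plate_id == pid, , drop = FALSE]
    if (!nrow(wm)) stop2(pf, ": plate ", pid, " absent from manifest")
    orphan <- setdiff(tab$well_id, wm$well_id)
    if (length(orphan))
      stop2(pf, ": well without role in manifest: ",
            paste(orphan, collapse = ", "))
    if (anyDuplicated(tab$well_id))
      stop2(pf, ": duplicate (plate, well): ",
            paste(tab$well_id[duplicated(tab$well_id)], collapse = ", "))
    idx <- match(tab$well_id, wm$well_id)
    dec <- decode_cells(as.matrix(tab[acols]))
    vals <- matrix(dec$values, nrow(tab), length(acols),
                   dimnames = list(NULL, acols))
    stat <- matrix(dec$status, nrow(tab), length(acols),
                   dimnames = list(NULL, acols))
    smp <- data.frame(sample_id = wm$sample_id[idx],
                      subject_id = wm$subject_id[idx],
                      plate_id = pid,
                      well_id = tab$well_id,
                      role = wm$role[idx],
                      stringsAsFactors = FALSE)
    rows[[pid]] <- list(samples = smp, values = vals, status = stat)
    plod <- numeric()
    if (!is.null(lod_tab)) {
      lp <- lod_tab[lod_tab$plate_id == pid, , drop = FALSE]
      plod <- stats::setNames(lp$lod, lp$analyte_id)
    }
    wells <- wm[c("well_id", "role", "sample_id", "subject_id")]
    if (!is.null(wm$injection_position))
      wells$injection_position <- wm$injection_position
    plates[[pid]] <- plate_run(pid, wells, plod)
  }
  samples <- do.call(rbind, lapply(rows, `[[`, "samples"))
  values <- do.call(rbind, lapply(rows, `[[`, "values"))
  status <- do.call(rbind, lapply(rows, `[[`, "status"))
  ## duplicate groups: subjects with exactly two study samples
  st <- samples[samples$role == "study", ]
  cnt <- table(st$subject_id)
  if (any(cnt > 2))
    stop2("subject(s) with more than two study samples: ",
          paste(names(cnt)[cnt > 2], collapse = ", "))
  dups <- names(cnt)[cnt == 2]
  samples$duplicate_group <- ifelse(
    samples$role == "study" & samples$subject_id %in% dups,
    samples$subject_id, NA_character_)
  list(matrix = measurement_matrix(samples, values, status),
       plates = plates)
}

## ---- level file writer/reader -------------------------------------------

#' Write an intermediate or final level file
#'
#' Deterministic CSV with a commented header recording the level, package
#' version and a hash of the pipeline configuration; cell encodings keep
#' value and status flags losslessly (bit-exact round trip through
#' [read_level()]).
#'
#' @param matrix a [measurement_matrix()]
#' @param level integer 1..5
#' @param path output file path
#' @param config optional pipeline configuration (hashed into the header)
#' @param log2_analytes analytes stored on the log2 scale (Level 5)
#' @return `path`, invisibly
#' @export
write_level <- function(matrix, level, path, config = NULL,
                        log2_analytes = character()) {
  stopifnot(inherits(matrix, "measurement_matrix"))
  if (!(is.numeric(level) && level %in% 1:5)) stop2("level must be in 1..5")
  hdr <- c(sprintf("# level: %d", as.integer(level)),
           sprintf("# pipeline_version: %s",
                   as.character(utils::packageVersion("p180curate"))),
           sprintf("# config_hash: %s", config_hash(config)))
  if (length(log2_analytes))
    hdr <- c(hdr, sprintf("# log2_analytes: %s",
                          paste(log2_analytes, collapse = ";")))
  s <- matrix$samples
  blank_na <- function(v) ifelse(is.na(v), "", as.character(v))
  meta <- data.frame(sample_id = blank_na(s$sample_id),
                     subject_id = blank_na(s$subject_id),
                     plate_id = blank_na(s$plate_id),
                     well_id = blank_na(s$well_id),
                     role = blank_na(s$role),
                     duplicate_group = blank_na(s$duplicate_group),
                     flag = blank_na(s$flag %||% ""),
                     stringsAsFactors = FALSE)
  cells <- encode_cells(matrix$values, matrix$status)
  colnames(cells) <- colnames(matrix$values)
  out <- cbind(meta, as.data.frame(cells, stringsAsFactors = FALSE,
                                   check.names = FALSE))
  con <- file(path, open = "wb")  # binary: fixed "\n" on every platform
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

#' Read a level file written by [write_level()]
#'
#' @param path file path
#' @return a [measurement_matrix()] with attributes `level`, `config_hash`
#'   and `log2_analytes`
#' @export
read_level <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  hdr <- character()
  con <- file(path, open = "r")
  on.exit(close(con), add = TRUE)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  close(con); on.exit()
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", comment.char = "#")
  meta_cols <- c("sample_id", "subject_id", "plate_id", "well_id", "role",
                 "duplicate_group", "flag")
  acols <- setdiff(names(tab), meta_cols)
  samples <- tab[intersect(meta_cols, names(tab))]
  samples$duplicate_group[samples$duplicate_group == ""] <- NA_character_
  if (nrow(tab)) {
    dec <- decode_cells(as.matrix(tab[acols]))
    values <- matrix(dec$values, nrow(tab), length(acols),
                     dimnames = list(NULL, acols))
    status <- matrix(dec$status, nrow(tab), length(acols),
                     dimnames = list(NULL, acols))
  } else {
    values <- matrix(numeric(), 0, length(acols),
                     dimnames = list(NULL, acols))
    status <- matrix(character(), 0, length(acols),
                     dimnames = list(NULL, acols))
  }
  mm <- measurement_matrix(samples, values, status)
  get_hdr <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, ": "), "", ln[1]) else NA_character_
  }
  attr(mm, "level") <- as.integer(get_hdr("level"))
  attr(mm, "config_hash") <- get_hdr("config_hash")
  lg <- get_hdr("log2_analytes")
  attr(mm, "log2_analytes") <-
    if (is.na(lg)) character() else strsplit(lg, ";", fixed = TRUE)[[1]]
  mm
}
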