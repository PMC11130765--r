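#' Read a step-parameter trajectory from disk
#'
#' Two on-disk dialects are supported. The native dialect is a flat TSV with a
#' header line `snapshot step tilt roll twist [shift slide rise]` (angles in
#' degrees, translations in nm, one row per snapshot/step) preceded by `#`
#' comment lines that carry the base-pair sequence and snapshot spacing. The
#' `x3dna-par` dialect mimics 3DNA-style step-parameter output: one block per
#' snapshot, a `snapshot <index>` title line, then one row per step with the
#' dinucleotide label followed by Shift Slide Rise Tilt Roll Twist in 3DNA
#' column order; comment lines beginning `#` are ignored. Only the rise and
#' the three angles are consumed from `.par`-style files; the sequence is
#' recovered from the step labels of the first block.
#'
#' @param path File to read.
#' @param dialect `"native-tsv"` (default) or `"x3dna-par"`.
#' @return A [step_table()].
#' @seealso [write_step_table()]
#' @export
read_step_table <- function(path, dialect = c("native-tsv", "x3dna-par")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "helixbend_io_error")
  }
  switch(dialect,
    "native-tsv" = read_native_tsv(path),
    "x3dna-par" = read_x3dna_par(path)
  )
}

read_header_meta <- function(path) {
  meta <- list(sequence = NULL, time_step = 2)
  for (line in readLines(path, n = 20L)) {
    if (!startsWith(line, "#")) break
    m <- regmatches(line, regexec("sequence=([ACGUTNacgutn]+)", line))[[1]]
    if (length(m) == 2) meta$sequence <- m[2]
    m <- regmatches(line, regexec("time_step_ps=([0-9.eE+-]+)", line))[[1]]
    if (length(m) == 2) meta$time_step <- as.numeric(m[2])
  }
  meta
}

read_native_tsv <- function(path) {
  meta <- read_header_meta(path)
  df <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  required <- c("snapshot", "step", "tilt", "roll", "twist")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "native-tsv file lacks column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "helixbend_format_error"
    )
  }
  step_table(df, sequence = meta$sequence, time_step = meta$time_step)
}

read_x3dna_par <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  title <- grepl("^\\s*snapshot\\s+\\d+", lines)
  if (!any(title)) {
    abort("no 'snapshot <index>' block titles found in x3dna-par file",
      class = "helixbend_format_error"
    )
  }
  block_id <- cumsum(title)
  if (block_id[1] == 0) {
    abort("x3dna-par file must start with a snapshot block title",
      class = "helixbend_structure_error"
    )
  }
  snap_idx <- as.integer(sub("^\\s*snapshot\\s+(\\d+).*$", "\\1", lines[title]))
  body <- lines[!title]
  body_block <- block_id[!title]
  sizes <- tabulate(body_block, nbins = max(block_id))
  if (length(unique(sizes)) != 1) {
    abort("ragged snapshot blocks in x3dna-par file",
      class = "helixbend_structure_error"
    )
  }
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7)) {
    abort("each x3dna-par step row needs label + 6 numeric columns",
      class = "helixbend_format_error"
    )
  }
  m <- matrix(as.numeric(unlist(lapply(fields, `[`, 2:7))),
    ncol = 6, byrow = TRUE
  )
  labels <- vapply(fields, `[`, "", 1)
  n_steps <- sizes[1]
  first_labels <- labels[seq_len(n_steps)]
  sequence <- paste0(
    paste(substr(first_labels, 1, 1), collapse = ""),
    substr(first_labels[n_steps], 2, 2)
  )
  df <- tibble(
    snapshot = rep(snap_idx, each = n_steps),
    step = rep(seq_len(n_steps), times = length(snap_idx)),
    tilt = m[, 4], roll = m[, 5], twist = m[, 6], rise = m[, 3]
  )
  meta <- read_header_meta(path)
  if (grepl("[^ACGUTN]", sequence)) sequence <- meta$sequence
  step_table(df, sequence = sequence, time_step = meta$time_step)
}

#' Write a step-parameter trajectory to disk
#'
#' The inverse of [read_step_table()]: `read_step_table(write_step_table(t))`
#' reproduces `t` to six decimal places in either dialect (for `x3dna-par`,
#' shift and slide are carried in the file but only rise and the angles are
#' read back, matching the read-side contract).
#'
#' @param table A [step_table()].
#' @param path Output file.
#' @inheritParams read_step_table
#' @return `path`, invisibly.
#' @export
write_step_table <- function(table, path,
                             dialect = c("native-tsv", "x3dna-par")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "step_table"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(paste0("directory does not exist: ", dir),
      class = "helixbend_io_error"
    )
  }
  header <- sprintf(
    "# helixbend step table; sequence=%s time_step_ps=%g",
    bp_sequence(table), time_step(table)
  )
  if (dialect == "native-tsv") {
    writeLines(header, path)
    readr::write_tsv(as_tibble(as.data.frame(table)), path,
      append = TRUE,
      col_names = TRUE, progress = FALSE
    )
  } else {
    labels <- step_labels(table)
    nk <- n_steps(table)
    col_or <- function(nm, default) {
      if (nm %in% names(table)) table[[nm]] else rep(default, nrow(table))
    }
    sh <- col_or("shift", 0)
    sl <- col_or("slide", 0)
    ri <- col_or("rise", 0.2954)
    rows <- sprintf(
      "%-4s %9.6f %9.6f %9.6f %9.6f %9.6f %9.6f",
      rep(labels, times = n_snapshots(table)),
      sh, sl, ri, table$tilt, table$roll, table$twist
    )
    snaps <- unique(table$snapshot)
    out <- character(0)
    for (i in seq_along(snaps)) {
      out <- c(
        out, sprintf("snapshot %d", snaps[i]),
        rows[seq.int((i - 1) * nk + 1, i * nk)]
      )
    }
    writeLines(c(
      header,
      "#    step   Shift     Slide     Rise      Tilt      Roll      Twist",
      out
    ), path)
  }
  invisible(path)
}

#' Read and write base-pair centre coordinate series
#'
#' Plain-TSV coordinate series: columns `snapshot atom x y z` (nm), one row
#' per atom per snapshot, with the same `#`-comment metadata header as the
#' native step-table dialect.
#'
#' @param path File path.
#' @return `read_coordinate_series()` returns a tibble with attribute
#'   `time_step` (ps).
#' @name coordinate-io
#' @export
read_coordinate_series <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "helixbend_io_error")
  }
  meta <- read_header_meta(path)
  df <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  validate_coordinate_series(df)
  structure(as_tibble(df), time_step = meta$time_step)
}

#' @rdname coordinate-io
#' @param coords Coordinate tibble (`snapshot`, `atom`, `x`, `y`, `z`).
#' @export
write_coordinate_series <- function(coords, path) {
  validate_coordinate_series(coords)
  writeLines(sprintf(
    "# helixbend coordinates; time_step_ps=%g",
    attr(coords, "time_step") %||% 2
  ), path)
  readr::write_tsv(as_tibble(as.data.frame(coords)), path,
    append = TRUE,
    col_names = TRUE, progress = FALSE
  )
  invisible(path)
}

validate_coordinate_series <- function(coords) {
  required <- c("snapshot", "atom", "x", "y", "z")
  if (!all(required %in% names(coords))) {
    abort("coordinate series needs columns snapshot, atom, x, y, z",
      class = "helixbend_format_error"
    )
  }
  if (!all(is.finite(as.matrix(coords[, c("x", "y", "z")])))) {
    abort("non-finite coordinates", class = "helixbend_structure_error")
  }
  counts <- table(coords$snapshot)
  if (length(unique(as.integer(counts))) != 1) {
    abort("atom count differs between snapshots",
      class = "helixbend_structure_error"
    )
  }
  invisible(coords)
}
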