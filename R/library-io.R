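#' @importFrom rlang %||% abort warn .data :=
#' @importFrom stats predict sd quantile rnorm qnorm setNames aggregate
#' @importFrom utils head tail
NULL

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Construct a promoter library from a data frame
#'
#' A promoter library is a tibble with one row per measured sequence and at
#' least an `id`, a `sequence` and one expression column. All sequences must
#' have identical length and use the DNA alphabet A/C/G/T only. The returned
#' tibble carries the expression-column names, the common sequence length and
#' the genomic position labels (by default `-R ... -1`, i.e. upstream of a
#' transcription start at 0) as attributes.
#'
#' @param data A data frame holding the library.
#' @param id,sequence Names of the identifier and sequence columns in `data`.
#' @param expression Character vector of expression-measurement column names.
#' @param sd,n_replicates Optional names of standard-deviation and
#'   replicate-count columns.
#' @param position_labels Optional integer vector of per-position coordinates
#'   (length R, strictly increasing). Defaults to `-R ... -1`.
#'
#' @return A `promoter_library` tibble with canonical columns `id`,
#'   `sequence`, the expression column(s), and optionally `sd` and
#'   `n_replicates`.
#' @examples
#' lib <- promoter_library(
#'   data.frame(ID = c("p1", "p2"), Seq = c("ACGT", "AAGT"), Expr = c(1, 2)),
#'   id = "ID", sequence = "Seq", expression = "Expr"
#' )
#' seq_length(lib)
#' @export
promoter_library <- function(data, id = "id", sequence = "sequence",
                             expression = "expression", sd = NULL,
                             n_replicates = NULL, position_labels = NULL) {
  stopifnot(is.data.frame(data))
  needed <- c(id, sequence, expression, sd, n_replicates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Configured column(s) not found in input: ",
                 paste(missing_cols, collapse = ", ")),
          class = "promoterkit_config_error")
  }
  lib <- tibble::tibble(
    id = as.character(data[[id]]),
    sequence = toupper(as.character(data[[sequence]]))
  )
  for (col in expression) {
    vals <- data[[col]]
    if (!is.numeric(vals)) {
      suppressWarnings(vals <- as.numeric(as.character(vals)))
      if (anyNA(vals)) {
        abort(paste0("Non-numeric expression value in column '", col, "'"),
              class = "promoterkit_parse_error")
      }
    }
    lib[[col]] <- vals
  }
  if (!is.null(sd)) {
    lib$sd <- as.numeric(data[[sd]])
    if (any(lib$sd < 0, na.rm = TRUE)) {
      abort("Standard deviations must be >= 0", class = "promoterkit_value_error")
    }
  }
  if (!is.null(n_replicates)) {
    lib$n_replicates <- as.integer(data[[n_replicates]])
    if (any(lib$n_replicates < 1, na.rm = TRUE)) {
      abort("Replicate counts must be >= 1", class = "promoterkit_value_error")
    }
  }
  validate_sequences(lib$sequence, lib$id)
  if (anyDuplicated(lib$id)) {
    abort(paste0("Duplicate ids: ",
                 paste(unique(lib$id[duplicated(lib$id)]), collapse = ", ")),
          class = "promoterkit_duplicate_id_error")
  }
  R <- nchar(lib$sequence[1])
  if (is.null(position_labels)) position_labels <- seq.int(-R, -1L)
  if (length(position_labels) != R || any(diff(position_labels) <= 0)) {
    abort("position_labels must be strictly increasing and of length R",
          class = "promoterkit_value_error")
  }
  new_promoter_library(lib, expr_cols = expression,
                       position_labels = as.integer(position_labels))
}

new_promoter_library <- function(tbl, expr_cols, position_labels) {
  attr(tbl, "expr_cols") <- expr_cols
  attr(tbl, "position_labels") <- position_labels
  class(tbl) <- unique(c("promoter_library", class(tbl)))
  tbl
}

validate_sequences <- function(sequences, ids = NULL) {
  if (length(sequences) == 0) {
    abort("Library contains no records", class = "promoterkit_empty_error")
  }
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad)) {
    who <- if (!is.null(ids)) paste(ids[bad], collapse = ", ") else
      paste(which(bad), collapse = ", ")
    abort(paste0("Sequence(s) contain characters outside A/C/G/T: ", who),
          class = "promoterkit_alphabet_error")
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    abort(paste0("Sequences must all have identical length; found lengths ",
                 paste(sort(unique(lens)), collapse = ", ")),
          class = "promoterkit_length_error")
  }
  invisible(TRUE)
}

#' Sequence length, expression columns and position labels of a library
#'
#' Accessors for the metadata carried by a [promoter_library()]. They fall
#' back to recomputing from the data when attributes were stripped by
#' data-frame operations.
#'
#' @param lib A promoter library (or any data frame with `id`, `sequence`
#'   and expression columns).
#' @return `seq_length()` the common sequence length R; `expr_cols()` a
#'   character vector of expression column names; `position_labels()` an
#'   integer vector of length R.
#' @export
seq_length <- function(lib) nchar(lib$sequence[1])

#' @rdname seq_length
#' @export
expr_cols <- function(lib) {
  ec <- attr(lib, "expr_cols")
  if (!is.null(ec) && all(ec %in% names(lib))) return(ec)
  setdiff(names(lib)[vapply(lib, is.numeric, logical(1))],
          c("sd", "n_replicates"))
}

#' @rdname seq_length
#' @export
position_labels <- function(lib) {
  pl <- attr(lib, "position_labels")
  R <- seq_length(lib)
  if (!is.null(pl) && length(pl) == R) return(pl)
  seq.int(-R, -1L)
}

primary_expr <- function(lib, column = NULL) {
  column <- column %||% expr_cols(lib)[1]
  if (!column %in% names(lib)) {
    abort(paste0("Expression column '", column, "' not present"),
          class = "promoterkit_config_error")
  }
  column
}

#' Read a promoter library from a CSV file
#'
#' Reads a comma-separated table with a header line and maps the configured
#' columns onto the canonical library layout. The file must provide an
#' identifier, a DNA sequence (A/C/G/T, all of equal length) and at least one
#' numeric expression column; a standard deviation and replicate count may be
#' supplied for replicate regeneration.
#'
#' @param path Path to the CSV file.
#' @param config A [workflow_config()] (or list) naming the columns; defaults
#'   to columns `id`, `sequence`, `expression`.
#' @return A [promoter_library()] tibble preserving file order.
#' @export
read_promoter_library <- function(path, config = workflow_config()) {
  if (!file.exists(path)) {
    abort(paste0("Input file not found: ", path), class = "promoterkit_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  promoter_library(raw,
                   id = config$id_col, sequence = config$seq_col,
                   expression = config$expr_cols,
                   sd = config$sd_col, n_replicates = config$rep_col)
}

#' Write a promoter library to CSV
#'
#' @param lib A promoter library.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_promoter_library <- function(lib, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(lib)), path, progress = FALSE)
  invisible(path)
}

#' Workflow configuration
#'
#' Builds (or reads) the key-value configuration controlling column names and
#' workflow parameters. The file dialect is flat `key = value` lines with `#`
#' comments; list-valued keys (e.g. `expr_cols`) are comma-separated.
#'
#' @param id_col,seq_col,expr_cols,sd_col,rep_col Column names in the input CSV.
#' @param response_value Target coding: `0` regression on standardized
#'   values, `1` regression on raw values, `k >= 2` classification with k
#'   equal-frequency bins.
#' @param entropy_cutoff Positions with training-set entropy at or below this
#'   many bits are excluded from the feature set.
#' @param ratio Train fraction of the train/test split.
#' @param reference Optional reference sequence for diversity and design.
#' @param pairwise_limit Above this sample count, diversity switches from
#'   pairwise to reference mode automatically.
#' @param seed Integer seed for all randomness.
#' @param out_prefix,fig_format Output naming fields.
#' @return A list of class `workflow_config`.
#' @export
workflow_config <- function(id_col = "id", seq_col = "sequence",
                            expr_cols = "expression", sd_col = NULL,
                            rep_col = NULL, response_value = 1L,
                            entropy_cutoff = 0.2, ratio = 0.9,
                            reference = NULL, pairwise_limit = 1000L,
                            seed = 1L, out_prefix = "promoterkit",
                            fig_format = "png") {
  response_value <- as.integer(response_value)
  if (response_value < 0) abort("response_value must be >= 0",
                                class = "promoterkit_config_error")
  if (entropy_cutoff < 0 || entropy_cutoff > 2) {
    abort("entropy_cutoff must lie in [0, 2] bits",
          class = "promoterkit_config_error")
  }
  if (ratio <= 0 || ratio >= 1) abort("ratio must lie in (0, 1)",
                                      class = "promoterkit_config_error")
  structure(list(
    id_col = id_col, seq_col = seq_col, expr_cols = expr_cols,
    sd_col = sd_col, rep_col = rep_col, response_value = response_value,
    entropy_cutoff = entropy_cutoff, ratio = ratio, reference = reference,
    pairwise_limit = as.integer(pairwise_limit), seed = as.integer(seed),
    out_prefix = out_prefix, fig_format = fig_format
  ), class = "workflow_config")
}

#' @rdname workflow_config
#' @param path Path to a `key = value` configuration file.
#' @export
read_workflow_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "promoterkit_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) {
    abort(paste0("Malformed config line: ", lines[bad][1]),
          class = "promoterkit_config_error")
  }
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  known <- names(formals(workflow_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "promoterkit_config_error")
  }
  args <- as.list(setNames(vals, keys))
  for (k in c("response_value", "pairwise_limit", "seed")) {
    if (k %in% names(args)) args[[k]] <- as.integer(args[[k]])
  }
  for (k in c("entropy_cutoff", "ratio")) {
    if (k %in% names(args)) args[[k]] <- as.numeric(args[[k]])
  }
  if ("expr_cols" %in% names(args)) {
    args$expr_cols <- trimws(strsplit(args$expr_cols, ",")[[1]])
  }
  do.call(workflow_config, args)
}

#' Regenerate replicate measurements from mean and standard deviation
#'
#' Replaces every record by `n_replicates` records sharing its sequence, with
#' expression values drawn from a normal distribution using the record's mean
#' and standard deviation. Replicate ids are derived from the parent id
#' (`<id>_rep1`, `<id>_rep2`, ...). Draws are not truncated at zero; negative
#' expression values raise a warning only.
#'
#' @param lib A promoter library where every record has `sd` and
#'   `n_replicates`.
#' @param seed Integer seed; the same seed reproduces the draw exactly.
#' @return A promoter library with `sum(n_replicates)` records.
#' @export
regenerate_replicates <- function(lib, seed = 1L) {
  cols <- expr_cols(lib)
  if (!all(c("sd", "n_replicates") %in% names(lib))) {
    abort("Replicate regeneration needs 'sd' and 'n_replicates' columns",
          class = "promoterkit_config_error")
  }
  missing <- is.na(lib$sd) | is.na(lib$n_replicates)
  if (any(missing)) {
    abort(paste0("Records missing sd or replicate count: ",
                 paste(lib$id[missing], collapse = ", ")),
          class = "promoterkit_value_error")
  }
  expr_col <- cols[1]
  set.seed(seed)
  pieces <- lapply(seq_len(nrow(lib)), function(i) {
    n <- lib$n_replicates[i]
    vals <- rnorm(n, mean = lib[[expr_col]][i], sd = lib$sd[i])
    tibble::tibble(
      id = paste0(lib$id[i], "_rep", seq_len(n)),
      sequence = lib$sequence[i],
      !!expr_col := vals
    )
  })
  out <- dplyr::bind_rows(pieces)
  if (any(out[[expr_col]] < 0)) {
    warn("Regenerated replicates contain negative expression values")
  }
  new_promoter_library(out, expr_cols = expr_col,
                       position_labels = position_labels(lib))
}

#' Remove expression outliers by absolute z-score
#'
#' Drops records whose expression z-score (against the library mean and
#' standard deviation) exceeds `z_threshold` in absolute value. The ids of
#' removed records are attached as attribute `removed_ids`. The criterion is
#' deliberately simple and the step is opt-in in the workflow.
#'
#' @param lib A promoter library with at least 3 records.
#' @param z_threshold Absolute z-score cutoff (default 3).
#' @param column Expression column to screen; defaults to the first.
#' @return The filtered promoter library.
#' @export
remove_outliers <- function(lib, z_threshold = 3, column = NULL) {
  if (nrow(lib) < 3) {
    abort("Outlier removal needs at least 3 records",
          class = "promoterkit_value_error")
  }
  column <- primary_expr(lib, column)
  x <- lib[[column]]
  s <- sd(x)
  if (s == 0) {
    warn("Expression variance is zero; no outliers removed")
    attr(lib, "removed_ids") <- character(0)
    return(lib)
  }
  z <- abs((x - mean(x)) / s)
  drop <- z > z_threshold
  # never reduce below the 3-record minimum
  if (sum(!drop) < 3) {
    keep_extra <- order(z, decreasing = FALSE)[seq_len(3)]
    drop[keep_extra] <- FALSE
  }
  out <- lib[!drop, , drop = FALSE]
  out <- new_promoter_library(out, expr_cols = expr_cols(lib),
                              position_labels = position_labels(lib))
  attr(out, "removed_ids") <- lib$id[drop]
  out
}

#' Merge two promoter libraries
#'
#' Concatenates the records of `a` and `b` (in that order). Both libraries
#' must share the sequence length and expression columns, and their ids must
#' be disjoint — silent deduplication would corrupt replicate-joint
#' cross-validation grouping downstream.
#'
#' @param a,b Promoter libraries.
#' @return A promoter library with `nrow(a) + nrow(b)` records.
#' @export
merge_libraries <- function(a, b) {
  if (nrow(a) == 0) return(b)
  if (nrow(b) == 0) return(a)
  if (seq_length(a) != seq_length(b)) {
    abort("Libraries have different sequence lengths",
          class = "promoterkit_length_error")
  }
  if (!identical(expr_cols(a), expr_cols(b))) {
    abort("Libraries have different expression columns",
          class = "promoterkit_config_error")
  }
  shared <- intersect(a$id, b$id)
  if (length(shared) > 0) {
    abort(paste0("Libraries share id(s): ", paste(shared, collapse = ", ")),
          class = "promoterkit_duplicate_id_error")
  }
  out <- dplyr::bind_rows(tibble::as_tibble(as.data.frame(a)),
                          tibble::as_tibble(as.data.frame(b)))
  new_promoter_library(out, expr_cols = expr_cols(a),
                       position_labels = position_labels(a))
}
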