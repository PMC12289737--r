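# File formats. Canonical dialect is TSV, UTF-8, "." decimal separator;
# CSV is accepted on read (sniffed from the header line). Matrices are
# written features-in-rows with two header rows: sample ids, then group
# labels. Undetermined Ct values round-trip as the literal token
# "Undetermined".

UNDETERMINED_TOKEN <- "Undetermined"

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("\t", first) && grepl(",", first)) "," else "\t"
}

write_matrix_2header <- function(values, groups, path, format_cell) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(values)), collapse = "\t"), con)
  writeLines(paste(c("group", as.character(groups)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(values)), function(i)
    paste(c(rownames(values)[i], format_cell(values[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
}

read_matrix_2header <- function(path, parse_cell) {
  sep <- sniff_sep(path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("malformed file: need two header rows")
  split1 <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(split1)
  if (length(unique(widths)) != 1L)
    stop("ragged rows: lines differ in field count")
  header <- split1[[1L]]
  grouprow <- split1[[2L]]
  if (grouprow[1L] != "group")
    stop("malformed header: second row must start with 'group'")
  sample_ids <- header[-1L]
  groups <- grouprow[-1L]
  body <- split1[-(1:2)]
  ids <- vapply(body, `[`, character(1), 1L)
  cells <- t(vapply(body, function(x) x[-1L], character(length(sample_ids))))
  values <- parse_cell(cells)
  dimnames(values) <- list(ids, sample_ids)
  list(values = values, groups = groups)
}

#' Read and write Ct matrices
#'
#' TSV (or CSV) with features in rows and two header rows: sample ids,
#' then group labels. Undetermined reactions are written as the token
#' `"Undetermined"` and mapped back to the ceiling value on read.
#'
#' @param ct a [ct_matrix()].
#' @param path file path.
#' @param ceiling ceiling value substituted for the Undetermined token on
#'   read (default 40).
#'
#' @return `read_ct_matrix()` returns a [ct_matrix()];
#'   `write_ct_matrix()` returns `path` invisibly.
#' @export
write_ct_matrix <- function(ct, path) {
  stopifnot(inherits(ct, "ct_matrix"))
  fmt <- function(row) {
    out <- formatC(row, format = "g", digits = 10)
    out[row == ct$ceiling] <- UNDETERMINED_TOKEN
    out
  }
  write_matrix_2header(ct$values, ct$groups, path, fmt)
  invisible(path)
}

#' @rdname write_ct_matrix
#' @export
read_ct_matrix <- function(path, ceiling = 40) {
  parsed <- read_matrix_2header(path, function(cells) {
    und <- cells == UNDETERMINED_TOKEN
    suppressWarnings(num <- array(as.numeric(cells), dim(cells)))
    num[und] <- ceiling
    if (any(is.na(num) & !und))
      stop("non-numeric Ct value other than the Undetermined token")
    num
  })
  ct_matrix(parsed$values, parsed$groups, ceiling = ceiling)
}

#' Read and write expression matrices with detection flags
#'
#' The intensity matrix and the flag matrix are separate files with the
#' same two-header-row layout; flags use the tokens P/M/A.
#'
#' @param expr an [expression_matrix()].
#' @param path intensity-matrix path.
#' @param flags_path flag-matrix path; for writing, defaults to
#'   `<path>.flags`.
#'
#' @return `read_expression_matrix()` returns an [expression_matrix()].
#' @export
write_expression_matrix <- function(expr, path,
                                    flags_path = paste0(path, ".flags")) {
  stopifnot(inherits(expr, "expression_matrix"))
  write_matrix_2header(expr$values, expr$groups, path,
                       function(row) formatC(row, format = "g", digits = 10))
  write_matrix_2header(expr$flags, expr$groups, flags_path, identity)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path, flags_path = NULL) {
  parsed <- read_matrix_2header(path, function(cells) {
    num <- array(as.numeric(cells), dim(cells))
    if (anyNA(num)) stop("non-numeric intensity value")
    num
  })
  flags <- NULL
  if (!is.null(flags_path)) {
    fp <- read_matrix_2header(flags_path, identity)
    if (!identical(dim(fp$values), dim(parsed$values)))
      stop("flag matrix shape does not match the intensity matrix")
    flags <- fp$values
  }
  expression_matrix(parsed$values, parsed$groups, flags)
}

#' Read and write GMT gene-set collections
#'
#' Standard GMT dialect: one set per line, tab-separated, with the set
#' name, a description column, then the member ids. [write_gmt()] is also
#' the serializer for miRNA target maps (set name = miRNA id).
#'
#' @param collection named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to the set names).
#'
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
write_gmt <- function(collection, path, descriptions = names(collection)) {
  stopifnot(!is.null(names(collection)))
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], descriptions[i], collection[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("malformed GMT: each line needs a name and a description column")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Read and write three-column edge lists
#'
#' TSV with header `source interaction target`. Duplicate edges are
#' collapsed on read with a warning (the [knowledge_graph()] constructor
#' warns and deduplicates).
#'
#' @param graph a [knowledge_graph()] (writing) or file path (reading).
#' @param path file path.
#'
#' @return `read_edge_list()` returns the edge data.frame;
#'   `read_knowledge_graph()` wraps it into a [knowledge_graph()].
#' @export
write_edge_list <- function(graph, path) {
  edges <- if (inherits(graph, "knowledge_graph")) graph$edges else graph
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, sep = sniff_sep(path), stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("source", "interaction", "target") %in% names(df)))
    stop("edge list must have columns source, interaction, target")
  df
}

#' @rdname write_edge_list
#' @export
read_knowledge_graph <- function(path) knowledge_graph(read_edge_list(path))

#' Read and write direction label tables
#'
#' Two-column TSV (id, direction) with direction in `up`/`down`.
#'
#' @param directions named character vector, id -> direction.
#' @param path file path.
#'
#' @return `read_directions()` returns a named character vector.
#' @export
write_directions <- function(directions, path) {
  write.table(data.frame(id = names(directions),
                         direction = unname(directions)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_directions
#' @export
read_directions <- function(path) {
  df <- read.delim(path, sep = sniff_sep(path), stringsAsFactors = FALSE)
  if (!all(c("id", "direction") %in% names(df)))
    stop("directions file must have columns id, direction")
  if (!all(df$direction %in% c("up", "down")))
    stop("unknown direction label; expected 'up' or 'down'")
  setNames(df$direction, df$id)
}

#' Read and write id lists (one id per line)
#'
#' @param ids character vector.
#' @param path file path.
#' @return `read_id_list()` returns a character vector.
#' @export
write_id_list <- function(ids, path) {
  writeLines(ids, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_id_list
#' @export
read_id_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8")
  x[nzchar(x)]
}

#' Write a differential-expression table
#'
#' Serializes the `table` of an `mirna_de`/`mrna_de` fit (or any
#' data.frame) as TSV with deterministic row order.
#'
#' @param de a fit object or data.frame.
#' @param path file path.
#' @export
write_de_table <- function(de, path) {
  tab <- if (is.data.frame(de)) de else de$table
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  read.delim(path, sep = sniff_sep(path), stringsAsFactors = FALSE)
}

#' Write and read a run manifest
#'
#' A key-value TSV snapshot of a pipeline run: configuration, seed,
#' stage-by-stage feature counts, package version and a timestamp, enough
#' to re-run the step and reproduce its outputs byte-identically
#' (timestamps aside).
#'
#' @param path file path.
#' @param config named list (e.g. a [sim_config()]) flattened into the
#'   manifest.
#' @param seed integer seed of the run.
#' @param stage_counts named numeric vector of features surviving each
#'   stage; must be non-increasing.
#' @param extra optional named character vector of additional entries.
#'
#' @return `read_manifest()` returns a named character vector.
#' @export
write_manifest <- function(path, config = NULL, seed = NULL,
                           stage_counts = NULL, extra = NULL) {
  if (!is.null(stage_counts) && is.unsorted(rev(stage_counts)))
    stop("stage counts must be non-increasing across filter stages")
  kv <- c(tool = "integromir",
          version = as.character(utils::packageVersion("integromir")),
          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(seed)) kv <- c(kv, seed = as.character(seed))
  if (!is.null(config))
    kv <- c(kv, setNames(vapply(config, function(v)
      paste(format(v, trim = TRUE), collapse = ","), character(1)),
      paste0("config.", names(config))))
  if (!is.null(stage_counts))
    kv <- c(kv, setNames(as.character(stage_counts),
                         paste0("stage.", names(stage_counts))))
  if (!is.null(extra)) kv <- c(kv, extra)
  write.table(data.frame(key = names(kv), value = unname(kv)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  setNames(df$value, df$key)
}

#' Read a simulation config from YAML
#'
#' Reads a YAML mapping whose keys are [sim_config()] arguments and
#' validates it; absent keys take the defaults.
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}
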