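# Readers and writers for the pipeline's tabular and graph formats.
# Canonical dialect: tab-delimited UTF-8 text with "." decimals; CSV is
# accepted everywhere a `sep` argument is exposed.

META_COLS <- c("peptide_id", "protein_group", "is_unique", "isolation_purity")

#' Read a peptide-level TMT reporter-intensity table
#'
#' Expects the metadata columns `peptide_id`, `protein_group`, `is_unique`,
#' `isolation_purity` plus one intensity column per TMT channel named in
#' `channel_map`.  The channel-to-condition assignment is explicit
#' configuration, never inferred from column names.
#'
#' @param path TSV file path.
#' @param channel_map Data frame with columns `channel`, `condition`,
#'   `replicate` (one row per reporter channel).
#' @param fraction Optional compartment label (`"nucleus"`/`"cytoplasm"`)
#'   attached to the table.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return A data frame of class `"peptide_table"` with the channel map in
#'   `attr(, "channels")` and the fraction in `attr(, "fraction")`.
#' @export
read_peptide_table <- function(path, channel_map, fraction = NA_character_,
                               sep = "\t") {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  validate_channel_map(channel_map)
  missing_meta <- setdiff(META_COLS, names(df))
  if (length(missing_meta))
    stop_schema("missing required column(s): ", paste(missing_meta, collapse = ", "))
  missing_ch <- setdiff(channel_map$channel, names(df))
  if (length(missing_ch))
    stop_schema("missing intensity column(s): ", paste(missing_ch, collapse = ", "))
  if (anyDuplicated(df$peptide_id))
    stop_schema("duplicate (peptide, channel) cells: peptide id(s) ",
                paste(unique(df$peptide_id[duplicated(df$peptide_id)]), collapse = ", "),
                " appear more than once")
  for (ch in channel_map$channel) {
    v <- df[[ch]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_value("non-numeric intensity in column '", ch, "' at row ",
                 if (length(bad)) bad else "?", " of ", path)
    }
    if (anyNA(v))
      stop_value("missing intensity in column '", ch, "' at row ",
                 which(is.na(v))[1])
    if (any(v < 0))
      stop_value("negative intensity in column '", ch, "' at row ",
                 which(v < 0)[1])
  }
  if (!is.logical(df$is_unique)) df$is_unique <- as.logical(df$is_unique)
  if (any(df$isolation_purity < 0 | df$isolation_purity > 1))
    stop_value("isolation_purity must lie in [0, 1]")
  new_peptide_table(df, channel_map, fraction)
}

new_peptide_table <- function(df, channel_map, fraction = NA_character_) {
  df <- df[, c(META_COLS, channel_map$channel)]
  attr(df, "channels") <- channel_map
  attr(df, "fraction") <- fraction
  class(df) <- c("peptide_table", "data.frame")
  df
}

validate_channel_map <- function(channel_map) {
  need <- c("channel", "condition", "replicate")
  if (!is.data.frame(channel_map) || !all(need %in% names(channel_map)))
    stop_config("channel_map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(channel_map$channel))
    stop_config("duplicate channel in channel_map")
  invisible(channel_map)
}

#' @rdname read_peptide_table
#' @param x A `"peptide_table"`.
#' @export
write_peptide_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "peptide_table"))
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Channel metadata accessor.
#' @export
channels <- function(x) attr(x, "channels")

# Intensity submatrix of a peptide table (peptides x channels).
peptide_intensities <- function(x) {
  m <- as.matrix(as.data.frame(x)[, channels(x)$channel, drop = FALSE])
  rownames(m) <- x$peptide_id
  m
}

#' Read a gene-level log2 expression matrix
#'
#' First column = gene id, remaining columns = samples.  Every sample must
#' be assigned to exactly one group.
#'
#' @param path TSV path (genes x samples of log2 intensities).
#' @param group_labels Named character vector, `names = sample`, values =
#'   group, covering every sample column.
#' @param organism Optional organism tag carried on the object.
#' @param sep Field separator.
#' @return Numeric matrix of class `"expr_matrix"` with `attr(, "groups")`
#'   (a factor named by sample) and `attr(, "organism")`.
#' @export
read_expression_matrix <- function(path, group_labels, organism = NA_character_,
                                   sep = "\t") {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "", comment.char = ""),
    error = function(e) stop_schema("unreadable or empty matrix file ", path,
                                    ": ", conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop_schema("expression matrix is empty: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_schema("duplicated gene id(s): ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_value("non-numeric expression values in ", path)
  rownames(m) <- ids
  unlabeled <- setdiff(colnames(m), names(group_labels))
  if (length(unlabeled))
    stop_config("sample(s) without a group label: ", paste(unlabeled, collapse = ", "))
  groups <- factor(group_labels[colnames(m)])
  names(groups) <- colnames(m)
  if (any(table(groups) < 2L))
    warning("group(s) with a single sample: t statistics will be undefined",
            call. = FALSE)
  new_expr_matrix(m, groups, organism)
}

new_expr_matrix <- function(m, groups, organism = NA_character_) {
  stopifnot(is.matrix(m), length(groups) == ncol(m))
  groups <- factor(groups)
  names(groups) <- colnames(m)
  attr(m, "groups") <- groups
  attr(m, "organism") <- organism
  class(m) <- c("expr_matrix", class(m))
  m
}

#' @export
groups <- function(x) attr(x, "groups")

#' @rdname read_expression_matrix
#' @param x An `"expr_matrix"`.
#' @param id_col Name used for the gene-id column on write.
#' @export
write_expression_matrix <- function(x, path, id_col = "gene_id", sep = "\t") {
  df <- data.frame(rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write gene-set collections (GMT)
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members are deduplicated; empty sets are dropped with a warning.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (term -> members) with the
#'   descriptions in `attr(, "descriptions")`; class `"gene_set_collection"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_schema("malformed GMT line ", i, ": fewer than 3 fields")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("dropping empty gene set '", f[1], "' (line ", i, ")", call. = FALSE)
      next
    }
    if (f[1] %in% names(sets)) stop_schema("duplicate term '", f[1], "'")
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param sets Named list of member vectors (or a `"gene_set_collection"`).
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export a process network
#'
#' GraphML (via igraph; edge weights preserved as doubles) or SIF
#' (`source  dice  target` interaction lines; SIF itself carries no
#' weights).
#'
#' @param net A `"process_network"` (see [build_process_network()]).
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @export
write_network <- function(net, path, format = c("graphml", "sif")) {
  if (!is.character(format) || !all(format %in% c("graphml", "sif")))
    stop_usage("unknown network format: ", paste(setdiff(format, c("graphml", "sif")), collapse = ", "))
  format <- match.arg(format)
  stopifnot(inherits(net, "process_network"))
  if (format == "sif") {
    if (nrow(net$edges)) {
      lines <- paste(net$edges$from, "dice", net$edges$to, sep = "\t")
    } else {
      # isolated nodes: one-column lines keep them visible to graph tools
      lines <- net$nodes$term
    }
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# Convert a process network to an igraph object (node attrs: clusters,
# n_genes; edge attrs: shared, dice rounded to 6 decimals).
as_igraph <- function(net) {
  stopifnot(inherits(net, "process_network"))
  verts <- data.frame(name = net$nodes$term,
                      clusters = net$nodes$clusters,
                      n_genes = net$nodes$n_genes,
                      stringsAsFactors = FALSE)
  if (nrow(net$edges)) {
    ed <- data.frame(from = net$edges$from, to = net$edges$to,
                     shared = net$edges$shared,
                     weight = round(net$edges$dice, 6),
                     stringsAsFactors = FALSE)
  } else {
    ed <- data.frame(from = character(0), to = character(0),
                     shared = integer(0), weight = numeric(0))
  }
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}

# Generic result-table writer used by the CLI stages.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
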