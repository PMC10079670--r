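# ---- containers -------------------------------------------------------------

SCORE_MEASURES <- c("gene_effect", "dependency_probability")
FEATURE_KINDS <- c("expression_log2tpm", "copy_number", "mutation_binary",
                   "expression_tpm")

#' Screen-score matrix (cell lines x genes)
#'
#' A `score_matrix` holds real-valued screen scores indexed by cell line
#' (rows) and gene symbol (columns), together with the measure they
#' represent: CERES-style gene effect (more negative = stronger dependency)
#' or dependency probability (certainty in \[0, 1\] that knockout impairs
#' viability). Missing entries are `NA`.
#'
#' @param values Numeric matrix with unique, non-empty rownames (cell line
#'   ids) and colnames (gene symbols).
#' @param measure One of `"gene_effect"` or `"dependency_probability"`.
#' @return An object of class `score_matrix` with elements `values` and
#'   `measure`.
#' @export
score_matrix <- function(values, measure = c("gene_effect",
                                             "dependency_probability")) {
  measure <- match.arg(measure)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  check_dimnames(values)
  if (measure == "dependency_probability") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "dependency probabilities outside [0, 1] at %d cell(s), first: row '%s', column '%s' (value %g)",
        nrow(bad), rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
        values[bad[1, 1], bad[1, 2]]))
    }
  }
  structure(list(values = values, measure = measure), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix [%s]: %d cell lines x %d genes, %d missing\n",
              x$measure, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.score_matrix <- function(x) dim(x$values)

#' Feature matrix (cell lines x molecular features)
#'
#' Holds one kind of molecular feature per object: expression as
#' log2(TPM + 1) or raw TPM, gene-level copy number, or binary mutation
#' indicators (1 = mutated, 0 = wild type). Feature ids are gene symbols,
#' optionally suffixed with a variant class for mutation features
#' (e.g. `"RB1_nonsense"`).
#'
#' @param values Numeric matrix, cell lines in rows, features in columns.
#' @param kind One of `"expression_log2tpm"`, `"copy_number"`,
#'   `"mutation_binary"`, `"expression_tpm"`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, kind) {
  kind <- match.arg(kind, FEATURE_KINDS)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  check_dimnames(values)
  if (kind == "mutation_binary") {
    bad <- which(!is.na(values) & !(values %in% c(0, 1)), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "mutation_binary values must be 0, 1 or missing; offending cell row '%s', column '%s' (value %g)",
        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
        values[bad[1, 1], bad[1, 2]]))
    }
  }
  if (kind == "expression_tpm") {
    bad <- which(!is.na(values) & values < 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "expression_tpm values must be >= 0; offending cell row '%s', column '%s' (value %g)",
        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
        values[bad[1, 1], bad[1, 2]]))
    }
  }
  structure(list(values = values, kind = kind), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d cell lines x %d features, %d missing\n",
              x$kind, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Panel metadata
#'
#' One record per cell line: the id, whether it belongs to the disease
#' group (`group_flag = TRUE`) or the reference panel, and an optional
#' lineage annotation.
#'
#' @param cell_line_id Character vector of unique, non-empty ids.
#' @param group_flag Logical vector, `TRUE` for disease-group lines.
#' @param lineage Character vector of lineage labels; `NA` allowed.
#' @return A data frame of class `panel_metadata`.
#' @export
panel_metadata <- function(cell_line_id, group_flag,
                           lineage = NA_character_) {
  cell_line_id <- as.character(cell_line_id)
  if (anyDuplicated(cell_line_id)) {
    stop("duplicate cell line id: ",
         cell_line_id[duplicated(cell_line_id)][1])
  }
  if (any(!nzchar(cell_line_id))) stop("empty cell line id")
  out <- data.frame(cell_line_id = cell_line_id,
                    group_flag = as.logical(group_flag),
                    lineage = as.character(lineage),
                    stringsAsFactors = FALSE)
  class(out) <- c("panel_metadata", "data.frame")
  out
}

# Require metadata coverage and the minimal two-per-arm design.
check_metadata_for_differential <- function(meta, cell_lines) {
  missing_lines <- setdiff(cell_lines, meta$cell_line_id)
  if (length(missing_lines) > 0) {
    stop("cell lines absent from metadata: ",
         paste(utils::head(missing_lines, 5), collapse = ", "))
  }
  m <- meta[match(cell_lines, meta$cell_line_id), ]
  if (sum(m$group_flag) < 2 || sum(!m$group_flag) < 2) {
    stop("differential analysis needs >= 2 group and >= 2 reference lines")
  }
  invisible(m)
}

#' Gene coordinate table
#'
#' 0-based half-open intervals, one record per gene symbol; the midpoint
#' `floor((start + end) / 2)` anchors window-membership queries.
#'
#' @param gene_symbol,chromosome,start,end Coordinate columns.
#' @return A data frame of class `gene_coords` with a `midpoint` column.
#' @export
gene_coords <- function(gene_symbol, chromosome, start, end) {
  gene_symbol <- as.character(gene_symbol)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (anyDuplicated(gene_symbol)) {
    stop("duplicate gene symbol in coordinates: ",
         gene_symbol[duplicated(gene_symbol)][1])
  }
  if (any(start < 0)) stop("negative start coordinate")
  bad <- which(start >= end)
  if (length(bad) > 0) {
    stop(sprintf("start >= end for gene '%s' (%g >= %g)",
                 gene_symbol[bad[1]], start[bad[1]], end[bad[1]]))
  }
  out <- data.frame(gene_symbol = gene_symbol,
                    chromosome = as.character(chromosome),
                    start = start, end = end,
                    midpoint = floor((start + end) / 2),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_coords", "data.frame")
  out
}

#' Gene set collection
#'
#' A named list of gene-symbol sets, as read from GMT files. Sets must be
#' non-empty and names unique; member genes are de-duplicated.
#'
#' @param sets Named list of character vectors.
#' @param provenance Free-text origin string.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, provenance = "") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set needs a name")
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene set name: ", names(sets)[duplicated(names(sets))][1])
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) {
    stop("empty gene set: ", names(sets)[lengths(sets) == 0][1])
  }
  structure(list(sets = sets, provenance = provenance),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %d..%d)\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Undirected interaction table
#'
#' Protein-protein (or other) interaction edges with a confidence score in
#' \[0, 1\]. Edges are normalized to an undirected canonical form
#' (`gene_a < gene_b`); self-edges are dropped and duplicate pairs keep
#' their maximum confidence.
#'
#' @param gene_a,gene_b Character vectors of endpoints.
#' @param confidence Numeric vector in \[0, 1\].
#' @return A data frame of class `interaction_table`.
#' @export
interaction_table <- function(gene_a, gene_b, confidence) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  confidence <- as.numeric(confidence)
  if (any(is.na(confidence) | confidence < 0 | confidence > 1)) {
    stop("interaction confidence must lie in [0, 1]")
  }
  keep <- gene_a != gene_b
  gene_a <- gene_a[keep]; gene_b <- gene_b[keep]
  confidence <- confidence[keep]
  if (length(gene_a) == 0) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("interaction_table", "data.frame")
    return(out)
  }
  lo <- pmin(gene_a, gene_b)
  hi <- pmax(gene_a, gene_b)
  key <- paste(lo, hi, sep = "\r")
  # duplicate undirected pairs collapse to their strongest evidence
  conf <- tapply(confidence, key, max)
  parts <- strsplit(names(conf), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                    gene_b = vapply(parts, `[`, "", 2),
                    confidence = as.numeric(conf),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}

check_dimnames <- function(values) {
  rn <- rownames(values); cn <- colnames(values)
  if (is.null(rn) || is.null(cn)) stop("matrix needs row and column names")
  if (any(!nzchar(rn)) || any(!nzchar(cn))) {
    stop("empty row or column identifier")
  }
  if (anyDuplicated(rn)) stop("duplicate row id: ", rn[duplicated(rn)][1])
  if (anyDuplicated(cn)) stop("duplicate column id: ", cn[duplicated(cn)][1])
  invisible(values)
}

# ---- readers ----------------------------------------------------------------

sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# DepMap-style headers "SYMBOL (ENTREZ)" reduce to the bare symbol.
strip_symbol_suffix <- function(x) sub("\\s*\\(.*\\)\\s*$", "", x)

read_numeric_table <- function(path, sep = NULL, strip_headers = TRUE) {
  sep <- sniff_sep(path, sep)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", na.strings = NULL)
  if (ncol(raw) < 2) stop("expected at least one id column and one gene column in ", path)
  ids <- raw[[1]]
  genes <- colnames(raw)[-1]
  if (strip_headers) genes <- strip_symbol_suffix(genes)
  if (anyDuplicated(ids)) {
    stop("duplicate cell line id in ", path, ": ", ids[duplicated(ids)][1])
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene column in ", path, ": ", genes[duplicated(genes)][1])
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells %in% c("", "NA", "na", "NaN")] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell in %s at row '%s', column '%s': '%s'",
                 path, ids[bad[1, 1]], genes[bad[1, 2]],
                 cells[bad[1, 1], bad[1, 2]]))
  }
  dimnames(num) <- list(ids, genes)
  num
}

#' Read a screen-score matrix from CSV/TSV
#'
#' Expects the DepMap tabular convention: one header row of gene
#' identifiers, one leading column of cell-line identifiers, numeric or
#' empty cells. Headers of the form `"SYMBOL (ID)"` are reduced to the
#' bare symbol; empty cells and `NA` tokens become missing values (never
#' imputed). The delimiter is sniffed from the extension (`.csv` = comma,
#' anything else = tab) unless `sep` is given.
#'
#' @param path File path.
#' @param measure Score measure, see [score_matrix()].
#' @param sep Optional delimiter override.
#' @param verbose Emit a load report via `message()`.
#' @return A [score_matrix()].
#' @export
read_score_matrix <- function(path, measure = c("gene_effect",
                                                "dependency_probability"),
                              sep = NULL, verbose = FALSE) {
  measure <- match.arg(measure)
  num <- read_numeric_table(path, sep)
  out <- score_matrix(num, measure)
  if (verbose) message(load_report(num, path))
  out
}

#' Read a molecular feature table from CSV/TSV
#'
#' Same tabular dialect as [read_score_matrix()]; values are validated per
#' `kind` (mutations must be 0/1/missing, TPM must be non-negative).
#'
#' @inheritParams read_score_matrix
#' @param kind Feature kind, see [feature_matrix()].
#' @param meta Optional [panel_metadata()]; rows absent from it trigger a
#'   warning but are retained.
#' @return A [feature_matrix()].
#' @export
read_feature_table <- function(path, kind, sep = NULL, meta = NULL,
                               verbose = FALSE) {
  kind <- match.arg(kind, FEATURE_KINDS)
  num <- read_numeric_table(path, sep)
  if (!is.null(meta)) {
    unknown <- setdiff(rownames(num), meta$cell_line_id)
    if (length(unknown) > 0) {
      warning(length(unknown), " cell line(s) absent from metadata (kept): ",
              paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  out <- feature_matrix(num, kind)
  if (verbose) message(load_report(num, path))
  out
}

load_report <- function(num, path) {
  sprintf("loaded %s: %d rows, %d columns, %d missing",
          path, nrow(num), ncol(num), sum(is.na(num)))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: per line a set name, a description, then member genes,
#' tab-separated. Duplicate member genes are de-duplicated; a line with
#' fewer than three fields is an error.
#'
#' @param path File path.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(sets = list(), provenance = path),
                     class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 fields in ", path)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[`, "", 1)
  gene_set_collection(sets, provenance = path)
}

#' Write gene sets to a GMT file
#' @param gsc A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gene_sets <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$provenance, gsc$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene coordinates from BED
#'
#' BED4 (chrom, start, end, name), 0-based half-open, name = gene symbol.
#' Later duplicate symbols are rejected.
#'
#' @param path File path.
#' @return A [gene_coords()] table.
#' @export
read_gene_coords <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 4) stop("BED file needs chrom, start, end, name fields: ", path)
  gene_coords(gene_symbol = bed[[4]], chromosome = bed[[1]],
              start = bed[[2]], end = bed[[3]])
}

#' Write gene coordinates to BED4
#' @param coords A [gene_coords()] table.
#' @param path Output path.
#' @export
write_gene_coords <- function(coords, path) {
  utils::write.table(
    data.frame(coords$chromosome, format(coords$start, scientific = FALSE, trim = TRUE),
               format(coords$end, scientific = FALSE, trim = TRUE), coords$gene_symbol),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an interaction edge table from TSV
#'
#' Expects columns `gene_a`, `gene_b`, `confidence` (header required).
#'
#' @param path File path.
#' @return An [interaction_table()].
#' @export
read_interaction_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "confidence")
  if (!all(need %in% colnames(tab))) {
    stop("interaction table needs columns: ", paste(need, collapse = ", "))
  }
  interaction_table(tab$gene_a, tab$gene_b, tab$confidence)
}

#' Write a score or feature matrix to CSV/TSV
#'
#' Inverse of the readers: leading `cell_line_id` column, full numeric
#' precision (round-trips bit-exactly), missing values as empty cells.
#'
#' @param x A [score_matrix()] or [feature_matrix()].
#' @param path Output path; delimiter sniffed from the extension.
#' @param sep Optional delimiter override.
#' @export
write_matrix <- function(x, path, sep = NULL) {
  stopifnot(inherits(x, "score_matrix") || inherits(x, "feature_matrix"))
  sep <- sniff_sep(path, sep)
  v <- x$values
  chr <- matrix(vapply(v, function(z) {
    if (is.na(z)) "" else format(z, digits = 17, scientific = TRUE)
  }, ""), nrow = nrow(v), dimnames = dimnames(v))
  df <- data.frame(cell_line_id = rownames(chr), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a panel-metadata table from CSV/TSV
#'
#' Expects columns `cell_line_id`, `group_flag` (logical or 0/1), and
#' optionally `lineage`.
#'
#' @param path File path.
#' @param sep Optional delimiter override.
#' @return A [panel_metadata()] table.
#' @export
read_panel_metadata <- function(path, sep = NULL) {
  sep <- sniff_sep(path, sep)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("cell_line_id", "group_flag") %in% colnames(tab))) {
    stop("metadata needs columns cell_line_id and group_flag")
  }
  lineage <- if ("lineage" %in% colnames(tab)) tab$lineage else NA_character_
  panel_metadata(tab$cell_line_id, as.logical(tab$group_flag), lineage)
}

#' Write panel metadata
#' @param meta A [panel_metadata()].
#' @param path Output path.
#' @param sep Optional delimiter override.
#' @export
write_panel_metadata <- function(meta, path, sep = NULL) {
  sep <- sniff_sep(path, sep)
  utils::write.table(as.data.frame(meta), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged 38-gene interferon-stimulated-gene core signature
#'
#' Loads the ISG core signature shipped with the package
#' (`inst/extdata/isg_core.gmt`): 38 interferon-stimulated genes whose
#' mean ZMAD summarizes chronic type-I interferon pathway engagement.
#'
#' @return A [gene_set_collection()] with the single set `isg_core`.
#' @export
isg_core_signature <- function() {
  read_gene_sets(system.file("extdata", "isg_core.gmt", package = "depsel",
                             mustWork = TRUE))
}
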