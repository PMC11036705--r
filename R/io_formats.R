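# Containers and readers/writers for the formats the pipeline touches.
# Everything downstream consumes only the in-memory types built here.

#' Construct a count matrix
#'
#' The universal input container: raw integer counts for genes (rows) by
#' units (columns), where a unit is either a cell barcode (single-nucleus
#' reference) or a spot barcode (spatial slide).
#'
#' @param values Non-negative integer matrix, genes x units.
#' @param gene_ids Character vector of unique gene symbols (rows).
#' @param unit_ids Character vector of unique cell/spot barcodes (columns).
#' @param unit_kind `"cell"` or `"spot"`.
#' @return A `count_matrix` object: a list with elements `values` (the
#'   dimnamed matrix) and `unit_kind`.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         unit_ids = colnames(values),
                         unit_kind = c("cell", "spot")) {
  unit_kind <- match.arg(unit_kind)
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(unit_ids)) {
    stop("gene_ids and unit_ids are required (or supply dimnames)")
  }
  gene_ids <- as.character(gene_ids)
  unit_ids <- as.character(unit_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(unit_ids)) {
    stop("count_matrix dimension mismatch: values are ", nrow(values), " x ",
         ncol(values), " but ", length(gene_ids), " gene_ids and ",
         length(unit_ids), " unit_ids were given")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene_ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)])[1:min(3, sum(duplicated(gene_ids)))],
               collapse = ", "))
  }
  if (anyDuplicated(unit_ids)) {
    stop("duplicate unit_ids: ",
         paste(unique(unit_ids[duplicated(unit_ids)])[1], collapse = ", "))
  }
  if (anyNA(values) || any(values < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  if (any(values != round(values))) {
    stop("counts must be integral")
  }
  storage.mode(values) <- "double"   # keeps large library sizes safe
  dimnames(values) <- list(gene_ids, unit_ids)
  structure(list(values = values, unit_kind = unit_kind),
            class = "count_matrix")
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d %ss, %d nonzero entries\n",
              nrow(x$values), ncol(x$values), x$unit_kind,
              sum(x$values != 0)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
unit_ids <- function(x) colnames(x$values)

#' Subset a count matrix by genes and/or units
#'
#' @param x A `count_matrix`.
#' @param genes,units Character or logical/integer index vectors; `NULL`
#'   keeps everything.
#' @return A `count_matrix` restricted to the selection.
#' @export
subset_counts <- function(x, genes = NULL, units = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(units)) v <- v[, units, drop = FALSE]
  count_matrix(v, unit_kind = x$unit_kind)
}

# Locate one file of a 10x-style triplet inside a directory, tolerating .gz
# and the features/genes naming split.
.find_triplet_file <- function(dir, stems) {
  for (s in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(s, ext))
      if (file.exists(p)) return(p)
    }
  }
  stop("no file matching ", paste(stems, collapse = "/"), " under ", dir)
}

#' Read a count matrix from an MTX triplet or a dense CSV
#'
#' Accepts either a 10x-style MatrixMarket triplet (a directory containing
#' `matrix.mtx`, `features.tsv`/`genes.tsv`, `barcodes.tsv`, each optionally
#' gzipped, or an explicit named list of the three paths) or a dense CSV with
#' gene rows (first column = gene symbol, header = unit barcodes). Both
#' genes-in-rows and genes-in-columns MTX orientations are accepted; the
#' orientation is detected from the features/barcodes lengths.
#'
#' @param path Directory, CSV file path, or `list(matrix=, features=,
#'   barcodes=)`.
#' @param unit_kind `"cell"` or `"spot"`.
#' @return A `count_matrix`.
#' @export
read_counts <- function(path, unit_kind = c("cell", "spot")) {
  unit_kind <- match.arg(unit_kind)
  if (is.list(path)) {
    paths <- path
  } else if (dir.exists(path)) {
    paths <- list(
      matrix   = .find_triplet_file(path, c("matrix.mtx")),
      features = .find_triplet_file(path, c("features.tsv", "genes.tsv")),
      barcodes = .find_triplet_file(path, c("barcodes.tsv"))
    )
  } else {
    return(.read_counts_csv(path, unit_kind))
  }
  m <- as.matrix(Matrix::readMM(paths$matrix))
  feat <- utils::read.table(paths$features, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  # 10x features files carry (id, symbol, type); a bare one-column list is
  # taken as symbols directly
  genes <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  bcs <- utils::read.table(paths$barcodes, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
  if (nrow(m) == length(genes) && ncol(m) == length(bcs)) {
    # genes-in-rows
  } else if (nrow(m) == length(bcs) && ncol(m) == length(genes)) {
    m <- t(m)
  } else {
    stop("MTX dimensions ", nrow(m), " x ", ncol(m),
         " match neither orientation of ", length(genes), " features x ",
         length(bcs), " barcodes")
  }
  genes <- .dedupe_symbols(genes)
  count_matrix(m, gene_ids = genes, unit_ids = bcs, unit_kind = unit_kind)
}

.read_counts_csv <- function(path, unit_kind) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  count_matrix(m, gene_ids = genes, unit_ids = colnames(m),
               unit_kind = unit_kind)
}

# Gene symbols are the join key across inputs; collisions keep the first
# occurrence, with subsequent copies suffixed and a warning logged.
.dedupe_symbols <- function(genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("duplicated gene symbols made unique (first occurrence kept as-is): ",
            paste(utils::head(dup, 5), collapse = ", "))
    genes <- make.unique(genes, sep = ".dup")
  }
  genes
}

#' Write a count matrix
#'
#' @param x A `count_matrix`.
#' @param path Output directory (MTX triplet) or `.csv` file path (dense).
#' @param format `"mtx"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(gene = gene_ids(x), x$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(x$values, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    utils::write.table(
      data.frame(id = gene_ids(x), symbol = gene_ids(x),
                 type = "Gene Expression"),
      file.path(path, "features.tsv"), sep = "\t", row.names = FALSE,
      col.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(unit_ids(x)),
                       file.path(path, "barcodes.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read spot positions
#'
#' Parses a Visium-style tissue-positions CSV. Spots outside the tissue are
#' retained but flagged.
#'
#' @param path CSV path.
#' @param columns Character vector naming, in file order, which of
#'   `barcode`, `in_tissue`, `array_row`, `array_col`, `y`, `x` each column
#'   holds (the 10x ordering is the default).
#' @param header Whether the file carries a header row.
#' @return A `spot_geometry` data.frame with columns barcode, in_tissue
#'   (logical), array_row, array_col, y, x.
#' @export
read_spot_positions <- function(path,
                                columns = c("barcode", "in_tissue",
                                            "array_row", "array_col",
                                            "y", "x"),
                                header = TRUE) {
  required <- c("barcode", "in_tissue", "array_row", "array_col", "y", "x")
  if (!all(required %in% columns)) {
    stop("positions column spec is missing: ",
         paste(setdiff(required, columns), collapse = ", "))
  }
  df <- utils::read.csv(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < length(columns)) {
    stop("positions file has ", ncol(df), " columns; ", length(columns),
         " expected")
  }
  names(df)[seq_along(columns)] <- columns
  out <- data.frame(
    barcode = as.character(df$barcode),
    in_tissue = as.logical(as.integer(df$in_tissue)),
    array_row = as.integer(df$array_row),
    array_col = as.integer(df$array_col),
    y = as.numeric(df$y),
    x = as.numeric(df$x),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$barcode)) {
    stop("duplicate spot barcode in positions file: ",
         out$barcode[duplicated(out$barcode)][1])
  }
  if (!any(out$in_tissue)) stop("no in-tissue spots in positions file")
  class(out) <- c("spot_geometry", "data.frame")
  out
}

#' Write spot positions
#'
#' @param geom A `spot_geometry` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spot_positions <- function(geom, path) {
  df <- data.frame(barcode = geom$barcode,
                   in_tissue = as.integer(geom$in_tissue),
                   array_row = geom$array_row, array_col = geom$array_col,
                   y = geom$y, x = geom$x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cell-state signature gene lists
#'
#' Two-column CSV (`state`, `gene`) mapping each tumor cell state (MES-like,
#' AC-like, OPC-like, NPC-like in this study's usage) to its signature genes.
#' Duplicate genes within a state are dropped with a warning; an empty state
#' is an error. If a `count_matrix` is supplied, genes absent from it are
#' reported (but kept — the score step intersects again).
#'
#' @param path CSV path with columns state, gene.
#' @param counts Optional `count_matrix` to check gene coverage against.
#' @return Named list of character vectors (state -> genes), carrying the
#'   state order of first appearance.
#' @export
read_signatures <- function(path, counts = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("state", "gene") %in% names(df))) {
    names(df)[1:2] <- c("state", "gene")
  }
  states <- unique(df$state)
  sigs <- lapply(states, function(s) {
    g <- df$gene[df$state == s]
    g <- g[!is.na(g) & nzchar(g)]
    if (anyDuplicated(g)) {
      warning("signature '", s, "': ", sum(duplicated(g)),
              " duplicate gene(s) dropped")
      g <- unique(g)
    }
    g
  })
  names(sigs) <- states
  empty <- states[lengths(sigs) == 0]
  if (length(empty)) stop("signature state(s) with no genes: ",
                          paste(empty, collapse = ", "))
  if (!is.null(counts)) {
    for (s in states) {
      missing <- setdiff(sigs[[s]], gene_ids(counts))
      if (length(missing)) {
        warning("signature '", s, "': ", length(missing),
                " gene(s) absent from the count matrix")
      }
    }
  }
  sigs
}

#' Write signature gene lists
#'
#' @param sigs Named list of character vectors.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  df <- data.frame(state = rep(names(sigs), lengths(sigs)),
                   gene = unlist(sigs, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default chromosome ordering
#'
#' Autosomes 1-22 then X and Y; genomic positions throughout the package are
#' 0-based half-open.
#' @return Character vector of chromosome names in order.
#' @export
default_chromosomes <- function() c(as.character(1:22), "X", "Y")

#' Read gene genomic metadata
#'
#' CSV with columns gene, chromosome, start (0-based). At most one record per
#' gene; chromosomes must come from the declared ordered list.
#'
#' @param path CSV path.
#' @param chromosomes Declared ordered chromosome vocabulary.
#' @return data.frame (gene, chromosome, start) with `chromosome` a factor
#'   ordered by `chromosomes`.
#' @export
read_gene_meta <- function(path, chromosomes = default_chromosomes()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "chromosome", "start") %in% names(df))) {
    stop("gene metadata needs columns gene, chromosome, start")
  }
  df$chromosome <- as.character(df$chromosome)
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene in metadata: ", df$gene[duplicated(df$gene)][1])
  }
  bad <- setdiff(unique(df$chromosome), chromosomes)
  if (length(bad)) stop("chromosome(s) outside the declared list: ",
                        paste(bad, collapse = ", "))
  if (any(df$start < 0)) stop("negative start position in gene metadata")
  df$chromosome <- factor(df$chromosome, levels = chromosomes)
  df[c("gene", "chromosome", "start")]
}

#' Write gene genomic metadata
#' @param meta data.frame (gene, chromosome, start).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gene_meta <- function(meta, path) {
  utils::write.csv(
    data.frame(gene = meta$gene, chromosome = as.character(meta$chromosome),
               start = meta$start),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a region/niche annotation
#'
#' CSV mapping spot barcodes to region labels (e.g. necrosis, palisade,
#' perivascular, generic_tumor). If `counts` is given, every annotated
#' barcode must exist in it.
#'
#' @param path CSV path with columns barcode, label.
#' @param counts Optional spatial `count_matrix` to validate barcodes against.
#' @return data.frame (barcode, label).
#' @export
read_region_annotation <- function(path, counts = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "label") %in% names(df))) {
    names(df)[1:2] <- c("barcode", "label")
  }
  df <- df[c("barcode", "label")]
  if (anyDuplicated(df$barcode)) {
    stop("spot annotated more than once: ",
         df$barcode[duplicated(df$barcode)][1])
  }
  if (!is.null(counts)) {
    missing <- setdiff(df$barcode, unit_ids(counts))
    if (length(missing)) {
      stop(length(missing), " annotated barcode(s) absent from the spatial ",
           "matrix, e.g. ", missing[1])
    }
  }
  df
}

#' Write a region/niche annotation
#' @param ann data.frame (barcode, label).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_annotation <- function(ann, path) {
  utils::write.csv(ann[c("barcode", "label")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
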