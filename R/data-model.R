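#' Coerce and validate a community table
#'
#' A community table is an integer matrix of read counts with taxa (OTUs) in
#' rows and samples in columns, with unique row and column names. All
#' downstream machinery consumes this representation.
#'
#' @param x matrix or data frame of non-negative integer counts,
#'   taxa x samples.
#' @return integer matrix with validated dimnames.
#' @export
as_community_table <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("community table must be a matrix", call. = FALSE)
  if (nrow(x) == 0L) stop("no taxa", call. = FALSE)
  if (ncol(x) == 0L) stop("no samples", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("community table needs taxon row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate taxon ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids", call. = FALSE)
  if (!is.numeric(x) || anyNA(x)) stop("counts must be numeric, no NA", call. = FALSE)
  if (any(x < 0) || any(x != round(x))) {
    bad <- which(x < 0 | x != round(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer or negative count at taxon '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]), call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

#' Read an OTU table from TSV or BIOM
#'
#' TSV layout: first column taxon ids, header row of sample ids, integer
#' counts. BIOM files (classic JSON or HDF5) are read through the biomformat
#' package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param transpose set `TRUE` when the TSV has samples in rows.
#' @return integer taxa x samples matrix (see [as_community_table()]).
#' @export
read_community_table <- function(path, format = c("tsv", "biom"),
                                 transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM requires the 'biomformat' package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    x <- as(biomformat::biom_data(b), "matrix")
  } else {
    raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (nrow(raw) == 0L || ncol(raw) < 2L) stop("no taxa", call. = FALSE)
    ids <- as.character(raw[[1L]])
    if (anyDuplicated(ids)) stop("duplicate taxon ids", call. = FALSE)
    x <- as.matrix(raw[, -1L, drop = FALSE])
    if (!is.numeric(x)) {
      num <- suppressWarnings(array(as.numeric(x), dim = dim(x),
                                    dimnames = dimnames(x)))
      bad <- which(is.na(num) & !is.na(x), arr.ind = TRUE)
      if (nrow(bad)) {
        stop(sprintf("non-integer cell at taxon '%s', sample '%s'",
                     ids[bad[1L, 1L]], colnames(x)[bad[1L, 2L]]),
             call. = FALSE)
      }
      x <- num
    }
    rownames(x) <- ids
  }
  if (transpose) x <- t(x)
  as_community_table(x)
}

#' Write an OTU table as TSV
#'
#' @param table community table (taxa x samples).
#' @param path output file.
#' @export
write_community_table <- function(table, path) {
  table <- as_community_table(table)
  df <- data.frame(taxon_id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove dataset-wide singleton OTUs
#'
#' Drops every taxon whose total read count, summed over all samples, equals
#' exactly one. Such OTUs are typically sequencing errors, and phylogenetic
#' null models are sensitive to them.
#'
#' @param table community table.
#' @return community table without singleton taxa; sample set unchanged.
#' @export
remove_singletons <- function(table) {
  table <- as_community_table(table)
  keep <- rowSums(table) != 1L
  if (!any(keep)) stop("empty table after singleton filter", call. = FALSE)
  table[keep, , drop = FALSE]
}

#' Rarefy samples to a common read depth
#'
#' Random subsampling without replacement (hypergeometric) to exactly `depth`
#' reads per sample. Samples with fewer than `depth` total reads are dropped
#' with a warning.
#'
#' @param table community table.
#' @param depth target reads per sample.
#' @param seed RNG seed; the caller's RNG stream is left untouched.
#' @return community table whose column sums all equal `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  table <- as_community_table(table)
  if (length(depth) != 1L || depth < 1 || depth != round(depth)) {
    stop("depth must be a single positive integer", call. = FALSE)
  }
  tot <- colSums(table)
  keep <- tot >= depth
  if (!any(keep)) stop("no sample reaches depth ", depth, call. = FALSE)
  if (any(!keep)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(head(colnames(table)[!keep], 10), collapse = ", ")),
            call. = FALSE)
  }
  x <- table[, keep, drop = FALSE]
  out <- with_seed(seed, {
    # rrarefy's "observed counts" heuristic warning is immaterial here
    suppressWarnings(t(vegan::rrarefy(t(x), sample = depth)))
  })
  storage.mode(out) <- "integer"
  out
}

#' Reconcile a community table with a phylogenetic tree
#'
#' Prunes the tree to the taxa present in the table and drops table taxa
#' absent from the tree (with a warning), so the tip set equals the taxon
#' set — a prerequisite of every MNTD-family metric.
#'
#' @param table community table.
#' @param tree `ape::phylo` tree with branch lengths, tips labelled by
#'   taxon id.
#' @return list with elements `table` and `tree`.
#' @export
reconcile <- function(table, tree) {
  table <- as_community_table(table)
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object", call. = FALSE)
  common <- intersect(rownames(table), tree$tip.label)
  if (length(common) < 2L) {
    stop("fewer than 2 taxa shared between table and tree", call. = FALSE)
  }
  drop_tab <- setdiff(rownames(table), common)
  if (length(drop_tab)) {
    warning(sprintf("dropping %d taxa absent from tree: %s",
                    length(drop_tab), paste(head(drop_tab, 10), collapse = ", ")),
            call. = FALSE)
    table <- table[common, , drop = FALSE]
  }
  drop_tip <- setdiff(tree$tip.label, common)
  if (length(drop_tip)) tree <- ape::drop.tip(tree, drop_tip)
  list(table = table, tree = tree)
}

#' Read per-sample metadata
#'
#' TSV with a mandatory `sample_id` column; optional `pH`, `age`, `lat`,
#' `lon` and arbitrary extra numeric columns.
#'
#' @param path file path.
#' @return data frame keyed by `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  if (!"sample_id" %in% names(meta)) {
    stop("metadata needs a 'sample_id' column", call. = FALSE)
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids", call. = FALSE)
  if ("pH" %in% names(meta)) {
    ph <- meta$pH[!is.na(meta$pH)]
    if (any(ph < 0 | ph > 14)) stop("pH outside [0, 14]", call. = FALSE)
  }
  meta
}

#' Euclidean environmental distance between samples
#'
#' For a single variable this is `|x_i - x_j|`; for several variables the
#' row-wise Euclidean norm of the differences.
#'
#' @param meta metadata data frame with `sample_id`.
#' @param vars character vector of numeric metadata columns (default `"pH"`).
#' @return labelled symmetric matrix of distances.
#' @export
env_distance <- function(meta, vars = "pH") {
  meta <- validate_metadata(meta)
  miss_col <- setdiff(vars, names(meta))
  if (length(miss_col)) stop("missing metadata column(s): ",
                             paste(miss_col, collapse = ", "), call. = FALSE)
  x <- as.matrix(meta[, vars, drop = FALSE])
  if (!is.numeric(x)) stop("environmental variables must be numeric", call. = FALSE)
  if (anyNA(x)) {
    bad <- meta$sample_id[!complete.cases(x)]
    stop("missing values for samples: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  d <- as.matrix(dist(x))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  d
}

#' Great-circle spatial distance between samples
#'
#' Haversine distance in metres (sphere radius 6,371,000 m) from `lat`/`lon`
#' decimal-degree columns.
#'
#' @param meta metadata data frame with `sample_id`, `lat`, `lon`.
#' @return labelled symmetric matrix of distances in metres.
#' @export
spatial_distance <- function(meta) {
  meta <- validate_metadata(meta)
  if (!all(c("lat", "lon") %in% names(meta))) {
    stop("metadata needs 'lat' and 'lon' columns", call. = FALSE)
  }
  if (anyNA(meta$lat) || anyNA(meta$lon)) {
    bad <- meta$sample_id[is.na(meta$lat) | is.na(meta$lon)]
    stop("missing coordinates for samples: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- cbind(meta$lon, meta$lat)
  d <- geosphere::distm(p, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371000))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  d
}
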