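#' @useDynLib assemblyproc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor dist sd rmultinom rlnorm runif optim dbinom quantile
#'   complete.cases setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Derive a child seed from a master seed; keeps the result a valid
# 32-bit integer so independent stages get independent streams.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 1009 * k) %% 2147483647)
}

# Lower-triangle vector of a square matrix (column-major order).
lower_tri <- function(m) m[lower.tri(m)]

# Validate a symmetric pairwise matrix with labels; returns it invisibly.
check_pairwise <- function(m, tol = 1e-10, require_labels = TRUE) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("pairwise matrix must be square", call. = FALSE)
  }
  if (require_labels && (is.null(rownames(m)) || is.null(colnames(m)))) {
    stop("pairwise matrix must carry row and column labels", call. = FALSE)
  }
  if (!is.null(rownames(m)) && !identical(rownames(m), colnames(m))) {
    stop("pairwise matrix row/column labels differ", call. = FALSE)
  }
  d <- abs(m - t(m))
  if (any(d[!is.na(d)] > tol)) {
    stop("pairwise matrix is not symmetric", call. = FALSE)
  }
  invisible(m)
}

# Align a taxon distance matrix to the rows of a community table.
align_dist <- function(dist, taxa) {
  if (is.null(rownames(dist))) stop("distance matrix lacks labels", call. = FALSE)
  miss <- setdiff(taxa, rownames(dist))
  if (length(miss)) {
    stop("taxa absent from distance matrix: ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  dist[taxa, taxa, drop = FALSE]
}

# Long (sample_i, sample_j, value) form of the lower triangle of a
# labelled symmetric matrix; i < j in label order.
pairs_long <- function(m, value = "value") {
  lab <- rownames(m)
  ij <- which(lower.tri(m), arr.ind = TRUE)
  out <- data.frame(sample_i = lab[ij[, 2L]], sample_j = lab[ij[, 1L]],
                    stringsAsFactors = FALSE)
  out[[value]] <- m[ij]
  out
}
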