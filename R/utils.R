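# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's \code{.Random.seed} so generators behave
#' as pure functions of their seed and never perturb global random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Moore-Penrose pseudoinverse via SVD; minimum-norm least squares for
# rank-deficient designs.
pinv <- function(X, tol = NULL) {
  s <- svd(X)
  if (is.null(tol)) tol <- max(dim(X)) * .Machine$double.eps * s$d[1L]
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Truncate (not round) to k decimal places; used for display values that
# follow the truncating convention of printed tables.
truncate_decimal <- function(x, k = 3L) trunc(x * 10^k) / 10^k

#' Write a data frame as tab-separated text
#'
#' @param x data frame.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by \code{\link{write_tsv}}
#'
#' @param path input file.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Stop with a formatted message.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
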