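#' Spearman rank correlation with p-value
#'
#' Rho is computed on midranks (ties permitted). The two-sided p-value is
#' exact (permutation distribution) for n <= 9 without ties and uses the
#' t-approximation otherwise. Pairs with a missing value in either
#' variable are dropped (pairwise-complete deletion).
#'
#' @param x,y numeric vectors of equal length, >= 3 complete pairs.
#' @return list with `rho`, `p` and `n` (complete pairs used).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("undefined rho: constant vector")
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (n <= 9 && !ties))
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlate a marker panel and model scores with study endpoints
#'
#' Computes Spearman rho and p for every (marker-or-model, endpoint)
#' pair over the samples shared between the intensity data and the
#' endpoint table.
#'
#' @param values peptides x samples intensity matrix (rownames = marker
#'   ids), a named score vector, or a list mixing both: each element of
#'   a list may be a matrix or a named numeric vector (e.g. classifier
#'   scores), and rows are stacked.
#' @param endpoints data.frame with a `sample_id` column and one column
#'   per endpoint (histopathology and clinical chemistry scores).
#' @return object of class `endpoint_correlation`: matrices `rho`, `p`
#'   and `n` of dimension (markers + models) x endpoints.
#' @export
correlate_panel <- function(values, endpoints) {
  if (is.list(values) && !is.data.frame(values) && !is.matrix(values)) {
    rows <- lapply(values, function(v) {
      if (is.matrix(v)) v else matrix(v, 1, dimnames = list(NULL, names(v)))
    })
    common <- Reduce(intersect, lapply(rows, colnames))
    rn <- unlist(mapply(function(v, nm) {
      r <- rownames(v)
      if (is.null(r)) nm else r
    }, rows, names(rows), SIMPLIFY = FALSE))
    values <- do.call(rbind, lapply(rows, function(v) v[, common, drop = FALSE]))
    rownames(values) <- rn
  } else if (!is.matrix(values)) {
    values <- matrix(values, 1, dimnames = list("score", names(values)))
  }
  if (is.null(endpoints$sample_id)) stop("endpoints need a sample_id column")
  shared <- intersect(colnames(values), endpoints$sample_id)
  if (length(shared) < 3) stop("need >= 3 shared samples")
  ep_cols <- setdiff(names(endpoints), "sample_id")
  ep <- endpoints[match(shared, endpoints$sample_id), ep_cols, drop = FALSE]
  vals <- values[, shared, drop = FALSE]
  rho <- p <- n <- matrix(
    NA_real_, nrow(vals), length(ep_cols),
    dimnames = list(rownames(vals), ep_cols)
  )
  for (i in seq_len(nrow(vals))) {
    for (j in seq_along(ep_cols)) {
      res <- tryCatch(spearman(vals[i, ], ep[[j]]),
                      error = function(e) NULL)
      if (!is.null(res)) {
        rho[i, j] <- res$rho; p[i, j] <- res$p; n[i, j] <- res$n
      }
    }
  }
  structure(list(rho = rho, p = p, n = n), class = "endpoint_correlation")
}

#' @export
print.endpoint_correlation <- function(x, ...) {
  cat(sprintf("<endpoint_correlation> %d variables x %d endpoints\n",
              nrow(x$rho), ncol(x$rho)))
  print(round(x$rho, 3))
  invisible(x)
}

#' Read / write an endpoint table
#'
#' @param path CSV file with a `sample_id` column plus endpoint columns.
#' @export
read_endpoints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$sample_id)) stop("endpoint table needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  df
}

#' @rdname read_endpoints
#' @param corr an `endpoint_correlation`.
#' @export
write_correlation <- function(corr, path) {
  rho <- as.data.frame(corr$rho)
  p <- as.data.frame(corr$p)
  names(p) <- paste0(names(p), "_p")
  out <- cbind(variable = rownames(corr$rho), rho, p)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
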