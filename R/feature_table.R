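#' Construct a feature table
#'
#' Features (sub-OTUs or collapsed taxa) by samples matrix of non-negative
#' counts, optionally carrying per-sample metadata (chamber type and
#' generation).  Tables hold integer counts until explicitly normalised;
#' [total_sum_scale()] sets the `normalised` flag and downstream operations
#' that require one form refuse the other.
#'
#' @param counts numeric matrix, features in rows, samples in columns, with
#'   dimnames.
#' @param metadata optional data.frame with columns `sample_id`, `chamber`
#'   (`"DC"` or `"MT"`) and `generation` (1-3), one row per sample.
#' @param normalised logical; `TRUE` when columns are relative abundances
#'   summing to one.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(counts, metadata = NULL, normalised = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || (nrow(counts) > 0 && is.null(rownames(counts))))
    stop("counts must have feature and sample names as dimnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!normalised && any(counts != round(counts)))
    stop("unnormalised tables must hold integer counts")
  if (normalised && ncol(counts) > 0) {
    cs <- colSums(counts)
    if (any(abs(cs - 1) > 1e-9 & cs != 0))
      stop("normalised table columns must sum to 1")
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!all(c("sample_id", "chamber", "generation") %in% names(metadata)))
      stop("metadata needs columns sample_id, chamber, generation")
    if (!all(colnames(counts) %in% metadata$sample_id))
      stop("metadata missing samples: ",
           paste(setdiff(colnames(counts), metadata$sample_id), collapse = ", "))
    metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
    if (!all(metadata$chamber %in% c("DC", "MT")))
      stop("chamber must be 'DC' or 'MT'")
    if (!all(metadata$generation %in% 1:3))
      stop("generation must be 1, 2 or 3")
  }
  structure(list(counts = counts, metadata = metadata,
                 normalised = isTRUE(normalised)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d feature(s) x %d sample(s)%s%s\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalised) ", normalised" else ", counts",
              if (is.null(x$metadata)) "" else ", with metadata"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

ft_replace_counts <- function(x, counts, normalised = x$normalised) {
  feature_table(counts, metadata = x$metadata, normalised = normalised)
}

#' Sample library sizes
#' @param x a `feature_table`.
#' @return Named numeric vector of per-sample totals.
#' @export
library_sizes <- function(x) colSums(x$counts)
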