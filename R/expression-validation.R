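#' Construct an ExpressionMatrix
#'
#' @param values probe x sample numeric matrix (rownames = probe ids,
#'   colnames = sample ids)
#' @param culture per-sample culture labels ("2D"/"3D")
#' @param treatment per-sample treatment labels ("DMSO"/"crizotinib"/
#'   "alectinib")
#' @param scale "linear" or "log2"
#' @return an \linkS4class{ExpressionMatrix}
#' @examples
#' m <- expressionMatrix(matrix(2^rnorm(20, 8), 5, 4,
#'                              dimnames = list(paste0("p", 1:5),
#'                                              paste0("s", 1:4))),
#'                       culture = rep("2D", 4),
#'                       treatment = rep(c("DMSO", "crizotinib"), each = 2))
#' @export
expressionMatrix <- function(values, culture, treatment,
                             scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("probe_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(culture = culture,
                                   treatment = treatment,
                                   row.names = colnames(values)))
  new("ExpressionMatrix", se, exprScale = scale)
}

#' Expression matrix scale flag
#'
#' @name exprScale
#' @return "linear" or "log2"
NULL

#' Log2-transform a linear-scale expression matrix
#'
#' @param m an \linkS4class{ExpressionMatrix} on the linear scale with
#'   strictly positive values (or a positive \code{offset} added first)
#' @param offset optional pseudo-value added before the log to admit zeros
#' @return the matrix on the log2 scale (the scale flag flips)
#' @export
log2Transform <- function(m, offset = 0) {
  if (exprScale(m) == "log2") {
    warning("matrix is already log2 scale; returning unchanged")
    return(m)
  }
  v <- SummarizedExperiment::assay(m) + offset
  if (any(v <= 0))
    stop("non-positive values cannot be log-transformed; ",
         "supply a positive offset")
  SummarizedExperiment::assay(m) <- log2(v)
  m@exprScale <- "log2"
  m
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share the same value distribution: after
#' normalization, each column's sorted values equal the row-wise means of
#' the sorted columns; ties receive the average of their quantile values.
#' Delegates to \code{\link[limma]{normalizeQuantiles}} (ties = TRUE), the
#' standard implementation for array data. Within-column rank order is
#' preserved and the operation is idempotent.
#'
#' @param m an \linkS4class{ExpressionMatrix} with at least 2 samples
#' @return the normalized matrix (same scale flag)
#' @export
quantileNormalize <- function(m) {
  v <- SummarizedExperiment::assay(m)
  if (ncol(v) < 2L)
    stop("quantile normalization needs at least 2 samples")
  vn <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(vn) <- dimnames(v)
  SummarizedExperiment::assay(m) <- vn
  m
}

## linear-scale values regardless of the stored scale
linearValues <- function(m) {
  v <- SummarizedExperiment::assay(m)
  if (exprScale(m) == "log2") 2^v else v
}

#' Fold reduction of a probe between two treatment groups
#'
#' Computes mean(control) / mean(treated) on the linear scale (values are
#' de-logged first when the matrix is log2 scale), so values above 1 mean
#' the treatment reduced expression. Groups are selected by culture and
#' treatment label. When several probes are supplied (e.g. multiple array
#' probes for one gene) they are averaged first.
#'
#' @param m an \linkS4class{ExpressionMatrix}
#' @param probe one or more probe ids
#' @param culture culture label selecting both groups ("2D" or "3D")
#' @param control treatment label of the control group (default "DMSO")
#' @param treated treatment label of the treated group
#' @return the fold reduction (positive real)
#' @export
foldChange <- function(m, probe, culture, control = "DMSO", treated) {
  v <- linearValues(m)
  missing <- setdiff(probe, rownames(v))
  if (length(missing))
    stop("unknown probe(s): ", paste(missing, collapse = ", "))
  cd <- SummarizedExperiment::colData(m)
  ctrlCols <- cd$culture == culture & cd$treatment == control
  trtCols <- cd$culture == culture & cd$treatment == treated
  if (!any(ctrlCols) || !any(trtCols))
    stop("empty group: control n=", sum(ctrlCols),
         ", treated n=", sum(trtCols))
  probeVals <- colMeans(v[probe, , drop = FALSE])
  num <- mean(probeVals[ctrlCols])
  den <- mean(probeVals[trtCols])
  if (den == 0) stop("treated group mean is zero; fold change undefined")
  num / den
}

#' Read / write an expression matrix as TSV
#'
#' The matrix file has probe rows and sample columns; the annotation file
#' has columns sample, culture, treatment.
#'
#' @param valuesPath TSV of probe x sample values
#' @param annotationPath TSV of sample annotations
#' @param scale scale flag of the stored values
#' @return an \linkS4class{ExpressionMatrix}
#' @export
readExpressionMatrix <- function(valuesPath, annotationPath,
                                 scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  v <- as.matrix(read.delim(valuesPath, row.names = 1, check.names = FALSE))
  ann <- read.delim(annotationPath, stringsAsFactors = FALSE)
  if (!all(c("sample", "culture", "treatment") %in% names(ann)))
    stop("annotation needs columns sample, culture, treatment")
  idx <- match(colnames(v), ann$sample)
  if (anyNA(idx))
    stop("samples without annotation: ",
         paste(colnames(v)[is.na(idx)], collapse = ", "))
  expressionMatrix(v, culture = ann$culture[idx],
                   treatment = ann$treatment[idx], scale = scale)
}

#' @rdname readExpressionMatrix
#' @param m an \linkS4class{ExpressionMatrix}
#' @export
writeExpressionMatrix <- function(m, valuesPath, annotationPath) {
  v <- SummarizedExperiment::assay(m)
  write.table(data.frame(probe = rownames(v), v, check.names = FALSE),
              valuesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- SummarizedExperiment::colData(m)
  write.table(data.frame(sample = rownames(cd), culture = cd$culture,
                         treatment = cd$treatment),
              annotationPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(valuesPath, annotationPath))
}
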