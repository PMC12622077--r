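#' Estimate cell-type fractions by non-negative least squares
#'
#' For each sample, solves `min || S w - m ||_2` subject to `w >= 0` over the
#' signature genes, where `m` is the sample's linear-scale expression
#' (`2^x - 1` by default, the inverse of the generator's `log2(x + 1)`).
#' Fractions are the normalised coefficients `w / sum(w)`; the absolute
#' immune signal is `sum(w)`, proportional to the total signature-explained
#' signal of the sample.
#'
#' @param expr features x samples log2 expression matrix; must contain all
#'   signature genes.
#' @param signature a [SignatureMatrix-class].
#' @param unlog how to return to the linear scale: `"expm1_2"` for `2^x - 1`
#'   (default) or `"exp2"` for `2^x`.
#' @return a [CellFractionEstimates-class].
#' @examples
#' sig <- generateSignatureMatrix(60, 4, 10, 8, seed = 7)
#' w <- c(0.5, 0.3, 0.15, 0.05)
#' m <- log2(signatureValues(sig) %*% cbind(s1 = w) + 1)
#' cellFractions(estimateFractions(m, sig))
#' @export
estimateFractions <- function(expr, signature, unlog = c("expm1_2", "exp2")) {
  unlog <- match.arg(unlog)
  S <- signatureValues(signature)
  missing <- setdiff(rownames(S), rownames(expr))
  if (length(missing))
    stop("expression matrix lacks signature genes: ",
         paste(utils::head(missing, 3), collapse = ", "))
  E <- expr[rownames(S), , drop = FALSE]
  lin <- if (unlog == "expm1_2") pmax(2^E - 1, 0) else 2^E
  nS <- ncol(E)
  w <- matrix(0, nS, ncol(S),
              dimnames = list(colnames(E), colnames(S)))
  for (i in seq_len(nS))
    w[i, ] <- pracma::lsqnonneg(S, lin[, i])$x
  tot <- rowSums(w)
  if (any(tot <= 0))
    stop("degenerate sample (all-zero coefficients): ",
         paste(rownames(w)[tot <= 0], collapse = ", "))
  fr <- w / tot
  names(tot) <- rownames(w)
  new("CellFractionEstimates", fractions = fr, absoluteScore = tot)
}

#' Scaled cell-type covariate
#'
#' Z-scores one cell type's estimated fraction vector (mean 0, sd 1, sample
#' sd with divisor n-1), producing the scaled covariate used for continuous
#' adjustment.
#'
#' @param estimates a [CellFractionEstimates-class].
#' @param cellType column name of the cell type (default the first, the
#'   neutrophil component in generated signatures).
#' @return named numeric z-score vector.
#' @export
scaleCovariate <- function(estimates, cellType = NULL) {
  fr <- cellFractions(estimates)
  if (is.null(cellType)) cellType <- colnames(fr)[1]
  if (!cellType %in% colnames(fr))
    stop("unknown cell type: ", cellType)
  v <- fr[, cellType]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("cell-type fraction vector is constant; covariate undefined")
  (v - mean(v)) / s
}

#' Association of a covariate with principal components
#'
#' Computes sample scores of the first `nComponents` principal components of
#' the centred expression matrix and their Pearson correlation with a
#' covariate, reporting both signed r (under the arbitrary PC sign) and |r|,
#' with two-sided p-values.
#'
#' @param expr features x samples matrix.
#' @param covariate numeric of length `ncol(expr)`.
#' @param nComponents how many leading components to test.
#' @return data.frame with columns component, r, abs_r, p.
#' @export
covariatePcAssociation <- function(expr, covariate, nComponents = 5) {
  if (length(covariate) != ncol(expr))
    stop("covariate length must equal the number of samples")
  if (nComponents > min(dim(expr)))
    stop("nComponents exceeds matrix rank bound")
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE,
                      rank. = nComponents)
  res <- lapply(seq_len(nComponents), function(k) {
    ct <- stats::cor.test(pc$x[, k], covariate)
    data.frame(component = paste0("PC", k), r = unname(ct$estimate),
               abs_r = abs(unname(ct$estimate)), p = ct$p.value)
  })
  do.call(rbind, res)
}
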