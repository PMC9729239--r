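#' Construct an LD reference panel
#'
#' An `ld_panel` bundles a square matrix of pairwise variant correlations with
#' its variant index. It serves three purposes downstream: greedy r^2 pruning of
#' instruments, weighting of the correlated-instrument IVW/MVMR estimators, and
#' the by-chance-LD pleiotropy simulation.
#'
#' @param R square symmetric correlation matrix (unit diagonal).
#' @param variant_ids character vector, one per row of `R`.
#' @param chrom,pos integer vectors of per-variant coordinates (1-based bp).
#' @param a1,a2 optional allele columns (effect/other allele of the panel's
#'   correlation sign convention); used to sign-align `R` during harmonization.
#' @return an object of class `ld_panel`.
#' @export
ld_panel <- function(R, variant_ids, chrom = NULL, pos = NULL,
                     a1 = NULL, a2 = NULL) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("LD matrix must be square")
  if (length(variant_ids) != nrow(R)) {
    stop("variant_ids length must match LD matrix dimension")
  }
  if (anyDuplicated(variant_ids)) stop("duplicate variant IDs in LD panel")
  if (max(abs(R - t(R))) > 1e-10) stop("LD matrix not symmetric within 1e-10")
  if (max(abs(diag(R) - 1)) > 1e-10) stop("LD matrix diagonal must be 1")
  R <- (R + t(R)) / 2
  diag(R) <- 1
  dimnames(R) <- list(variant_ids, variant_ids)
  structure(
    list(variant_ids = as.character(variant_ids), R = R,
         chrom = if (is.null(chrom)) rep(NA_integer_, nrow(R)) else as.integer(chrom),
         pos = if (is.null(pos)) rep(NA_integer_, nrow(R)) else as.integer(pos),
         a1 = a1, a2 = a2),
    class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat("<ld_panel> ", length(x$variant_ids), " variants\n", sep = "")
  invisible(x)
}

#' Subset an LD panel, preserving the requested order
#'
#' @param panel an [ld_panel()].
#' @param ids variant IDs to keep, in the desired output order.
#' @return an `ld_panel` over `ids`.
#' @export
ld_subset <- function(panel, ids) {
  idx <- match(ids, panel$variant_ids)
  if (anyNA(idx)) {
    stop("variants absent from LD panel: ", paste(ids[is.na(idx)], collapse = ", "))
  }
  ld_panel(panel$R[idx, idx, drop = FALSE], panel$variant_ids[idx],
           panel$chrom[idx], panel$pos[idx],
           if (!is.null(panel$a1)) panel$a1[idx], if (!is.null(panel$a2)) panel$a2[idx])
}

#' Regularize a correlation matrix for inversion
#'
#' Real LD submatrices are near-singular; eigenvalues below `eps` are clipped to
#' `eps` before any inversion or square root, applied uniformly across the
#' package.
#'
#' @param C correlation matrix.
#' @param eps eigenvalue floor (default 1e-8).
#' @return list with components `inv` (C^-1), `inv_sqrt` (symmetric C^-1/2) and
#'   `C` (the clipped matrix).
#' @export
ld_regularize <- function(C, eps = 1e-8) {
  C <- as.matrix(C)
  if (nrow(C) == 1L) {
    v <- max(C[1, 1], eps)
    return(list(inv = matrix(1 / v, 1, 1), inv_sqrt = matrix(1 / sqrt(v), 1, 1),
                C = matrix(v, 1, 1)))
  }
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, eps)
  V <- e$vectors
  list(inv = V %*% (t(V) / lam),
       inv_sqrt = V %*% (t(V) / sqrt(lam)),
       C = V %*% (t(V) * lam))
}

#' Read / write a dense LD panel
#'
#' The on-disk representation is a whitespace-delimited square matrix plus a
#' sidecar variant-index file with columns `variant_id`, `chrom`, `pos` and
#' optionally `a1`, `a2`.
#'
#' @param matrix_path path to the matrix file.
#' @param index_path path to the sidecar index.
#' @return an [ld_panel()].
#' @export
read_ld_panel <- function(matrix_path, index_path) {
  R <- as.matrix(utils::read.table(matrix_path, header = FALSE))
  idx <- utils::read.delim(index_path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "chrom", "pos") %in% names(idx))) {
    stop("LD index must have columns variant_id, chrom, pos")
  }
  ld_panel(R, idx$variant_id, idx$chrom, idx$pos, idx$a1, idx$a2)
}

#' @rdname read_ld_panel
#' @param panel an [ld_panel()] to serialize.
#' @export
write_ld_panel <- function(panel, matrix_path, index_path) {
  utils::write.table(format(panel$R, digits = 10), matrix_path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  idx <- data.frame(variant_id = panel$variant_ids, chrom = panel$chrom,
                    pos = panel$pos, stringsAsFactors = FALSE)
  if (!is.null(panel$a1)) { idx$a1 <- panel$a1; idx$a2 <- panel$a2 }
  utils::write.table(idx, index_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, index_path))
}
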